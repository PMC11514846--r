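# Sequence design under the independence model: specify GC content and
# purine content, get a sequence whose per-base probabilities are the
# third-law products.

.design_bases <- c("A", "T", "G", "C")

#' Specification for a designed sequence
#'
#' @param target_s Target GC content in `[0,1]`.
#' @param target_r Target purine content in `[0,1]`.
#' @param length Sequence length (positive integer).
#' @param seed Integer seed; mandatory, because a design without a seed
#'   is not reproducible.
#' @param mode `"iid"` draws every position independently from the
#'   third-law base probabilities; `"exact"` fixes the base counts to a
#'   largest-remainder apportionment of `length` times those
#'   probabilities and shuffles their order.
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(target_s, target_r, length, seed,
                        mode = c("iid", "exact")) {
  mode <- match.arg(mode)
  for (v in list(target_s = target_s, target_r = target_r))
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 || v > 1)
      stop("target_s and target_r must be single numbers in [0, 1]")
  if (!is.numeric(length) || base::length(length) != 1L ||
      !is.finite(length) || length < 1 || length != round(length))
    stop("length must be a positive integer")
  if (missing(seed) || is.null(seed))
    stop("seed is mandatory: designs must be reproducible")
  if (!is.numeric(seed) || base::length(seed) != 1L || !is.finite(seed) ||
      seed != round(seed))
    stop("seed must be a single integer")
  structure(
    list(target_s = as.double(target_s), target_r = as.double(target_r),
         length = as.integer(length), seed = as.integer(seed), mode = mode),
    class = "design_spec"
  )
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf("<design_spec> s=%g r=%g length=%d seed=%d mode=%s\n",
              x$target_s, x$target_r, x$length, x$seed, x$mode))
  invisible(x)
}

#' Largest-remainder (Hamilton) apportionment
#'
#' Allocates `n` integer units to categories proportionally to `probs`:
#' each category gets the floor of its quota, and the leftover units go
#' to the largest fractional remainders. Ties are broken by category
#' order (here: A, T, G, C), so the result is deterministic.
#'
#' @param probs Non-negative weights summing to 1.
#' @param n Total units to allocate.
#' @return Integer vector of allocations summing to `n`.
#' @export
largest_remainder <- function(probs, n) {
  stopifnot(is.numeric(probs), all(probs >= 0), abs(sum(probs) - 1) < 1e-9,
            n >= 0, n == round(n))
  quota <- probs * n
  alloc <- floor(quota)
  remainder <- n - sum(alloc)
  if (remainder > 0) {
    ord <- order(-(quota - alloc), seq_along(probs))
    idx <- ord[seq_len(remainder)]
    alloc[idx] <- alloc[idx] + 1
  }
  as.integer(alloc)
}

# Run fn with the RNG seeded from `seed`, then restore the caller's RNG
# state so that designing a sequence never perturbs other simulations.
with_design_seed <- function(seed, fn) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old_seed <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) assign(".Random.seed", old_seed, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister")
  fn()
}

#' Design a sequence with specified GC and purine content
#'
#' Base probabilities are the third-law products
#' [estimate_profile()]`(target_s, target_r)`. In `iid` mode each
#' position is an independent draw; in `exact` mode the base counts are
#' fixed by [largest_remainder()] apportionment and only the order is
#' random. Identical spec (including seed) gives a byte-identical
#' sequence; the FASTA description records the spec and the PRNG.
#'
#' @param spec A [design_spec()].
#' @return A [genome_record()] whose description encodes the spec.
#' @export
design_sequence <- function(spec) {
  stopifnot(inherits(spec, "design_spec"))
  est <- estimate_profile(spec$target_s, spec$target_r)
  probs <- c(est$p_a, est$p_t, est$p_g, est$p_c)
  idx <- with_design_seed(spec$seed, function() {
    if (spec$mode == "iid") {
      sample.int(4L, spec$length, replace = TRUE, prob = probs)
    } else {
      counts <- largest_remainder(probs, spec$length)
      rep.int(1:4, counts)[sample.int(spec$length)]
    }
  })
  sequence <- paste(.design_bases[idx], collapse = "")
  id <- sprintf("design_%s_s%g_r%g_L%d_seed%d",
                spec$mode, spec$target_s, spec$target_r,
                spec$length, spec$seed)
  description <- sprintf(
    "target_s=%g target_r=%g length=%d seed=%d mode=%s prng=Mersenne-Twister generator=basecomp-%s",
    spec$target_s, spec$target_r, spec$length, spec$seed, spec$mode,
    as.character(utils::packageVersion("basecomp")))
  genome_record(id, sequence, description)
}

#' Verify a designed (or any) sequence against a design spec
#'
#' Compares the achieved GC and purine content with the targets. The
#' pass tolerance depends on the sampling mode: `exact` apportionment
#' can miss each target by at most 2/length, while `iid` sampling is
#' binomial, so each target is allowed four standard errors,
#' `4 * sqrt(p * (1-p) / length)`.
#'
#' @param record A [genome_record()].
#' @param spec The [design_spec()] to verify against.
#' @return An object of class `design_verification` with the achieved
#'   profile, per-target deviations and tolerances, and a `pass` flag.
#' @export
verify_design <- function(record, spec) {
  stopifnot(inherits(record, "genome_record"), inherits(spec, "design_spec"))
  achieved <- profile_from_counts(count_bases(record$sequence))
  dev_s <- abs(achieved$p_s - spec$target_s)
  dev_r <- abs(achieved$p_r - spec$target_r)
  n <- nchar(record$sequence)
  if (spec$mode == "exact") {
    tol_s <- 2 / n
    tol_r <- 2 / n
  } else {
    tol_s <- 4 * sqrt(spec$target_s * (1 - spec$target_s) / n)
    tol_r <- 4 * sqrt(spec$target_r * (1 - spec$target_r) / n)
  }
  structure(
    list(genome_id = record$id,
         achieved = achieved,
         target_s = spec$target_s, target_r = spec$target_r,
         deviation_s = dev_s, deviation_r = dev_r,
         tolerance_s = tol_s, tolerance_r = tol_r,
         mode = spec$mode, length = n,
         pass = dev_s <= tol_s && dev_r <= tol_r),
    class = "design_verification"
  )
}

#' @export
print.design_verification <- function(x, ...) {
  cat(sprintf("<design_verification> %s (%s, %d bp): %s\n", x$genome_id,
              x$mode, x$length, if (x$pass) "PASS" else "FAIL"))
  cat(sprintf("  GC     target %.4f achieved %.4f (|dev| %.2e <= tol %.2e: %s)\n",
              x$target_s, x$achieved$p_s, x$deviation_s, x$tolerance_s,
              x$deviation_s <= x$tolerance_s))
  cat(sprintf("  purine target %.4f achieved %.4f (|dev| %.2e <= tol %.2e: %s)\n",
              x$target_r, x$achieved$p_r, x$deviation_r, x$tolerance_r,
              x$deviation_r <= x$tolerance_r))
  invisible(x)
}
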