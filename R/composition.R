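#' Base-count tallies for one sequence set
#'
#' Integer tallies of the unambiguous bases A/T/G/C plus the number of
#' ambiguous IUPAC characters (non-ACGT) and the total length. The
#' invariant `n_total = n_a + n_t + n_g + n_c + n_ambiguous` always holds.
#'
#' @param n_a,n_t,n_g,n_c Non-negative integer counts of the four bases.
#' @param n_ambiguous Non-negative integer count of IUPAC non-ACGT
#'   characters.
#' @return An object of class `base_counts`.
#' @export
base_counts <- function(n_a, n_t, n_g, n_c, n_ambiguous = 0L) {
  vals <- c(n_a = n_a, n_t = n_t, n_g = n_g, n_c = n_c,
            n_ambiguous = n_ambiguous)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals != round(vals)))
    stop("base counts must be non-negative integers")
  structure(
    list(n_a = as.double(n_a), n_t = as.double(n_t), n_g = as.double(n_g),
         n_c = as.double(n_c), n_ambiguous = as.double(n_ambiguous),
         n_total = as.double(n_a) + as.double(n_t) + as.double(n_g) +
           as.double(n_c) + as.double(n_ambiguous)),
    class = "base_counts"
  )
}

#' @export
print.base_counts <- function(x, ...) {
  cat(sprintf("<base_counts> A=%g T=%g G=%g C=%g ambiguous=%g total=%g\n",
              x$n_a, x$n_t, x$n_g, x$n_c, x$n_ambiguous, x$n_total))
  invisible(x)
}

#' Count bases in a normalized sequence
#'
#' Tallies A/T/G/C exactly; IUPAC ambiguity codes (N, R, Y, S, W, K, M,
#' B, D, H, V) are tallied as ambiguous. The sequence must already be
#' normalized (uppercase, no gaps); see [normalize_sequence()].
#'
#' @param sequence Non-empty normalized IUPAC string.
#' @return A [base_counts()] object.
#' @export
count_bases <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence))
    stop("sequence must be a single string")
  if (!nzchar(sequence)) stop("sequence is empty")
  bad <- regexpr(.invalid_iupac_regex, sequence)
  if (bad > 0L)
    stop(sprintf("invalid character '%s' at position %d (is the sequence normalized?)",
                 substr(sequence, bad, bad), bad))
  freq <- Biostrings::alphabetFrequency(Biostrings::DNAString(sequence))
  n_a <- freq[["A"]]; n_c <- freq[["C"]]
  n_g <- freq[["G"]]; n_t <- freq[["T"]]
  base_counts(n_a, n_t, n_g, n_c,
              n_ambiguous = nchar(sequence) - (n_a + n_c + n_g + n_t))
}

#' Sum base counts across sequences
#'
#' Fieldwise sums, e.g. to collapse the contigs of a multi-record
#' assembly into one genome-level tally.
#'
#' @param counts_list Non-empty list of [base_counts()] objects.
#' @return A single [base_counts()] object.
#' @export
aggregate_counts <- function(counts_list) {
  if (inherits(counts_list, "base_counts")) counts_list <- list(counts_list)
  if (!is.list(counts_list) || length(counts_list) == 0L)
    stop("counts_list must be a non-empty list of base_counts")
  if (!all(vapply(counts_list, inherits, logical(1), "base_counts")))
    stop("counts_list must contain only base_counts objects")
  f <- function(field) sum(vapply(counts_list, `[[`, double(1), field))
  base_counts(f("n_a"), f("n_t"), f("n_g"), f("n_c"), f("n_ambiguous"))
}

# Internal profile constructor. Derived contents default to the sums of
# the base proportions; estimate_profile() overrides them so that the
# stored p_s/p_r are bit-identical to its inputs.
new_profile <- function(p_a, p_t, p_g, p_c,
                        p_s = p_g + p_c, p_w = p_a + p_t,
                        p_r = p_a + p_g, p_y = p_t + p_c,
                        ambiguous_fraction = NA_real_,
                        n_counted = NA_real_) {
  # strip any names riding in on the inputs so that downstream c(a = p_a,
  # ...) constructions keep clean names
  p_a <- as.vector(p_a); p_t <- as.vector(p_t)
  p_g <- as.vector(p_g); p_c <- as.vector(p_c)
  p_s <- as.vector(p_s); p_w <- as.vector(p_w)
  p_r <- as.vector(p_r); p_y <- as.vector(p_y)
  structure(
    list(p_a = p_a, p_t = p_t, p_g = p_g, p_c = p_c,
         p_s = p_s, p_w = p_w, p_r = p_r, p_y = p_y,
         ambiguous_fraction = ambiguous_fraction, n_counted = n_counted),
    class = "composition_profile"
  )
}

#' @export
print.composition_profile <- function(x, digits = 4, ...) {
  cat("<composition_profile>\n")
  cat(sprintf("  P(A)=%.*f P(T)=%.*f P(G)=%.*f P(C)=%.*f\n",
              digits, x$p_a, digits, x$p_t, digits, x$p_g, digits, x$p_c))
  cat(sprintf("  P(S)=%.*f P(W)=%.*f P(R)=%.*f P(Y)=%.*f\n",
              digits, x$p_s, digits, x$p_w, digits, x$p_r, digits, x$p_y))
  if (is.finite(x$n_counted))
    cat(sprintf("  n_counted=%g ambiguous_fraction=%.3g\n",
                x$n_counted, x$ambiguous_fraction))
  invisible(x)
}

#' Composition profile from base counts
#'
#' The eight proportions P(A), P(T), P(G), P(C), P(S) (GC content), P(W)
#' (AT content), P(R) (purine content), and P(Y) (pyrimidine content).
#' Proportions are computed over unambiguous bases only: ambiguous
#' characters are excluded from the denominator (N runs in assemblies
#' would otherwise distort composition) and reported separately as
#' `ambiguous_fraction` of the total length.
#'
#' @param counts A [base_counts()] object with at least one unambiguous
#'   base.
#' @return An object of class `composition_profile`.
#' @export
profile_from_counts <- function(counts) {
  if (!inherits(counts, "base_counts"))
    stop("counts must be a base_counts object")
  n <- counts$n_a + counts$n_t + counts$n_g + counts$n_c
  if (n < 1)
    stop("cannot build a profile: no unambiguous bases (all characters ambiguous)")
  new_profile(counts$n_a / n, counts$n_t / n, counts$n_g / n, counts$n_c / n,
              ambiguous_fraction = counts$n_ambiguous / counts$n_total,
              n_counted = n)
}

#' Composition profile from the four base proportions
#'
#' Builds a profile from proportions alone, e.g. when reading a
#' published composition table where counts are unavailable. Values may
#' be percentages (auto-detected when any value exceeds 1.5) and are
#' renormalized to sum to exactly 1 after validation.
#'
#' @param p_a,p_t,p_g,p_c Base proportions (fractions or percentages).
#' @param n_counted Optional number of bases behind the proportions.
#' @param tol Maximum tolerated deviation of the (fraction-scale) sum
#'   from 1 before renormalization.
#' @return A `composition_profile`.
#' @export
profile_from_proportions <- function(p_a, p_t, p_g, p_c,
                                     n_counted = NA_real_, tol = 0.005) {
  p <- c(p_a, p_t, p_g, p_c)
  if (length(p) != 4L || any(!is.finite(p)) || any(p < 0))
    stop("proportions must be four finite non-negative numbers")
  if (any(p > 1.5)) p <- p / 100  # percent convention
  total <- sum(p)
  if (abs(total - 1) > tol)
    stop(sprintf("base proportions sum to %.4f, not 1 (tolerance %.3g)",
                 total, tol))
  p <- p / total
  new_profile(p[1], p[2], p[3], p[4], n_counted = n_counted)
}

#' Reverse complement of an IUPAC sequence
#'
#' Standard IUPAC complementation (A-T, G-C, R-Y, K-M, B-V, D-H; S, W
#' and N are self-complementary) followed by reversal.
#'
#' @param sequence Normalized IUPAC string.
#' @return The reverse-complemented string.
#' @export
reverse_complement <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("sequence must be a single non-empty string")
  bad <- regexpr(.invalid_iupac_regex, sequence)
  if (bad > 0L)
    stop(sprintf("invalid character '%s' at position %d",
                 substr(sequence, bad, bad), bad))
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
}

# Proportion-valued columns rounded at report time (round-half-even).
.profile_columns <- c("p_a", "p_t", "p_g", "p_c", "p_s", "p_w", "p_r", "p_y")

profile_row <- function(profile, genome_id, digits = NULL) {
  row <- data.frame(genome_id = genome_id,
                    n_counted = profile$n_counted,
                    ambiguous_fraction = profile$ambiguous_fraction,
                    stringsAsFactors = FALSE)
  for (col in .profile_columns) row[[col]] <- profile[[col]]
  if (!is.null(digits))
    for (col in c(.profile_columns, "ambiguous_fraction"))
      row[[col]] <- round(row[[col]], digits)
  row
}

#' Write composition profiles as TSV
#'
#' One row per profile with columns `genome_id`, `n_counted`,
#' `ambiguous_fraction`, and the eight proportions. Proportions are
#' rounded (round-half-even) at `digits` decimals; storage is always
#' full precision.
#'
#' @param profiles Named list of `composition_profile` objects (names are
#'   genome ids).
#' @param path Output TSV path.
#' @param digits Report rounding, default 4 decimals.
#' @return Invisibly, the data frame written.
#' @export
write_profiles <- function(profiles, path, digits = 4) {
  if (!is.list(profiles) || length(profiles) == 0L || is.null(names(profiles)))
    stop("profiles must be a non-empty named list")
  rows <- do.call(rbind, Map(profile_row, profiles, names(profiles),
                             MoreArgs = list(digits = digits)))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rows)
}
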