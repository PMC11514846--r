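#' Estimated base proportions under the independence factorization
#'
#' Treating a base's strong/weak status (S = G-or-C vs W) and its
#' purine/pyrimidine status (R = A-or-G vs Y) as statistically
#' independent, every base proportion is a product of the two marginal
#' contents:
#' \deqn{P(A) = (1-P(S))\,P(R),\quad P(T) = (1-P(S))(1-P(R)),}
#' \deqn{P(G) = P(S)\,P(R),\quad P(C) = P(S)(1-P(R)).}
#' The four products sum to 1 algebraically for any inputs in
#' \eqn{[0,1]^2}, and the resulting profile's `p_s` and `p_r` equal the
#' inputs. When `p_r = 0.5` the estimates collapse to Chargaff parity:
#' `P(A) = P(T) = (1-P(S))/2` and `P(G) = P(C) = P(S)/2`.
#'
#' @param p_s GC content in `[0,1]`.
#' @param p_r Purine content in `[0,1]`.
#' @return A `composition_profile` of estimated proportions
#'   (`n_counted` is `NA`: estimates have no underlying counts).
#' @examples
#' estimate_profile(0.3815, 0.5004) # budding-yeast-like composition
#' @export
estimate_profile <- function(p_s, p_r) {
  for (v in list(p_s = p_s, p_r = p_r))
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("p_s and p_r must be single finite numbers")
  if (p_s < 0 || p_s > 1) stop("p_s must lie in [0, 1]")
  if (p_r < 0 || p_r > 1) stop("p_r must lie in [0, 1]")
  new_profile(p_a = (1 - p_s) * p_r,
              p_t = (1 - p_s) * (1 - p_r),
              p_g = p_s * p_r,
              p_c = p_s * (1 - p_r),
              p_s = p_s, p_w = 1 - p_s, p_r = p_r, p_y = 1 - p_r)
}

#' First-law (pairing parity) deviations
#'
#' Chargaff parity within a single strand predicts P(A)=P(T) and
#' P(G)=P(C); the deviations are the absolute differences.
#'
#' @param profile A `composition_profile`.
#' @return Named numeric vector `c(delta_at=, delta_gc=)`.
#' @export
law1_deviation <- function(profile) {
  stopifnot(inherits(profile, "composition_profile"))
  c(delta_at = abs(profile$p_a - profile$p_t),
    delta_gc = abs(profile$p_g - profile$p_c))
}

#' Second-law (purine/pyrimidine balance) deviation
#'
#' Purines and pyrimidines are predicted to be equally frequent
#' (P(R)=P(Y)=0.5); the deviation is |P(R) - 0.5|.
#'
#' @param profile A `composition_profile`.
#' @return A single non-negative number.
#' @export
law2_deviation <- function(profile) {
  stopifnot(inherits(profile, "composition_profile"))
  abs(profile$p_r - 0.5)
}

#' Third-law residuals: observed minus factorization estimate
#'
#' Applies [estimate_profile()] to the profile's own GC and purine
#' contents and subtracts. Residuals sum to zero (both profiles sum
#' to 1); they vanish exactly when the counts factorize
#' (`n_g * n_t == n_a * n_c`).
#'
#' @param observed A `composition_profile`.
#' @return List with `residuals` (named signed vector over a, t, g, c),
#'   `max_abs_residual`, and the `estimated` profile.
#' @export
law3_residuals <- function(observed) {
  stopifnot(inherits(observed, "composition_profile"))
  est <- estimate_profile(observed$p_s, observed$p_r)
  res <- c(a = observed$p_a - est$p_a, t = observed$p_t - est$p_t,
           g = observed$p_g - est$p_g, c = observed$p_c - est$p_c)
  list(residuals = res, max_abs_residual = max(abs(res)), estimated = est)
}

#' 2x2 test of independence between S/W and R/Y status
#'
#' Arranges the four base counts as the contingency table
#' rows {S, W} x columns {R, Y} — cells (G, C / A, T) — and tests
#' independence. Expected cell counts are the sequence length times the
#' third-law estimates of [estimate_profile()]; they are computed from
#' integer margin products (`n_W * n_R / n` etc.), which is the same
#' quantity evaluated exactly, so the statistic is exactly 0 whenever
#' the counts factorize. The default is the Pearson chi-square without
#' continuity correction (at genome scale the Yates correction is
#' negligible); `test = "g"` gives the likelihood-ratio G-test for
#' small toy tables.
#'
#' @param counts A [base_counts()] object.
#' @param test `"chisq"` (default) or `"g"`.
#' @return List with `statistic`, `df` (always 1), `p_value`,
#'   `odds_ratio` (`(n_g*n_t)/(n_a*n_c)`, `Inf` when the denominator is
#'   0), `expected` (named expected counts), and `method`.
#' @export
independence_test <- function(counts, test = c("chisq", "g")) {
  stopifnot(inherits(counts, "base_counts"))
  test <- match.arg(test)
  n_s <- counts$n_g + counts$n_c
  n_w <- counts$n_a + counts$n_t
  n_r <- counts$n_a + counts$n_g
  n_y <- counts$n_t + counts$n_c
  n <- n_s + n_w
  if (n < 1) stop("empty table: no unambiguous bases")
  margins <- c("S (G+C)" = n_s, "W (A+T)" = n_w,
               "R (A+G)" = n_r, "Y (T+C)" = n_y)
  if (any(margins == 0))
    stop(sprintf("degenerate 2x2 table: margin %s is empty",
                 names(margins)[margins == 0][1]))
  observed <- c(a = counts$n_a, t = counts$n_t, g = counts$n_g, c = counts$n_c)
  expected <- c(a = n_w * n_r / n, t = n_w * n_y / n,
                g = n_s * n_r / n, c = n_s * n_y / n)
  statistic <- if (test == "chisq") {
    sum((observed - expected)^2 / expected)
  } else {
    pos <- observed > 0
    2 * sum(observed[pos] * log(observed[pos] / expected[pos]))
  }
  num <- counts$n_g * counts$n_t
  den <- counts$n_a * counts$n_c
  list(statistic = statistic,
       df = 1L,
       p_value = stats::pchisq(statistic, df = 1, lower.tail = FALSE),
       odds_ratio = if (den == 0) Inf else num / den,
       expected = expected,
       method = if (test == "chisq")
         "Pearson chi-square (no continuity correction)" else
         "likelihood-ratio G-test")
}

law_report_new <- function(genome_id, profile, chi2 = NA_real_,
                           chi2_p = NA_real_, odds_ratio = NA_real_,
                           counts = NULL) {
  l1 <- law1_deviation(profile)
  l3 <- law3_residuals(profile)
  structure(
    list(genome_id = genome_id,
         profile = profile,
         counts = counts,
         law1_delta_at = unname(l1["delta_at"]),
         law1_delta_gc = unname(l1["delta_gc"]),
         law2_delta = law2_deviation(profile),
         estimated_profile = l3$estimated,
         residuals = l3$residuals,
         max_abs_residual = l3$max_abs_residual,
         chi2 = chi2, chi2_df = 1L, chi2_p = chi2_p,
         odds_ratio = odds_ratio,
         outlier_score = max(l1)),
    class = "law_report"
  )
}

#' Evaluate one genome against the three composition laws
#'
#' Combines the pairing-parity deviations, the purine-balance deviation,
#' the third-law residuals and the 2x2 independence test into one
#' record. The outlier score is `max(law1_delta_at, law1_delta_gc)`:
#' known aberrant genomes show a strong disparity between P(G) and
#' P(C), and unlike the chi-square statistic the score does not grow
#' with genome size.
#'
#' @param genome_id Identifier for the report.
#' @param counts A [base_counts()] object.
#' @param test Statistic for the independence test, see
#'   [independence_test()].
#' @return An object of class `law_report`.
#' @export
evaluate_genome <- function(genome_id, counts, test = c("chisq", "g")) {
  stopifnot(inherits(counts, "base_counts"))
  profile <- profile_from_counts(counts)
  it <- independence_test(counts, test = match.arg(test))
  law_report_new(genome_id, profile, chi2 = it$statistic,
                 chi2_p = it$p_value, odds_ratio = it$odds_ratio,
                 counts = counts)
}

#' Law report from a profile without counts
#'
#' For genomes known only through their proportions (e.g. a published
#' composition table) the count-based fields (`chi2`, `chi2_p`,
#' `odds_ratio`) are flagged unavailable as `NA`.
#'
#' @param genome_id Identifier for the report.
#' @param profile A `composition_profile`.
#' @return A `law_report` with the test fields set to `NA`.
#' @export
law_report_from_profile <- function(genome_id, profile) {
  stopifnot(inherits(profile, "composition_profile"))
  law_report_new(genome_id, profile)
}

#' @export
print.law_report <- function(x, digits = 4, ...) {
  cat(sprintf("<law_report> %s\n", x$genome_id))
  cat(sprintf("  law 1 |P(A)-P(T)|=%.*f |P(G)-P(C)|=%.*f\n",
              digits, x$law1_delta_at, digits, x$law1_delta_gc))
  cat(sprintf("  law 2 |P(R)-0.5|=%.*f\n", digits, x$law2_delta))
  cat(sprintf("  law 3 max |obs-est|=%.*f  chi2=%s (p=%s)\n",
              digits, x$max_abs_residual,
              if (is.na(x$chi2)) "NA" else format(x$chi2, digits = 6),
              if (is.na(x$chi2_p)) "NA" else format(x$chi2_p, digits = 3)))
  cat(sprintf("  outlier score %.*f\n", digits, x$outlier_score))
  invisible(x)
}

law_report_row <- function(report, digits = NULL) {
  p <- report$profile
  row <- profile_row(p, report$genome_id)
  row$law1_delta_at <- report$law1_delta_at
  row$law1_delta_gc <- report$law1_delta_gc
  row$law2_delta <- report$law2_delta
  est <- report$estimated_profile
  row$est_p_a <- est$p_a; row$est_p_t <- est$p_t
  row$est_p_g <- est$p_g; row$est_p_c <- est$p_c
  row$resid_a <- report$residuals[["a"]]; row$resid_t <- report$residuals[["t"]]
  row$resid_g <- report$residuals[["g"]]; row$resid_c <- report$residuals[["c"]]
  row$max_abs_residual <- report$max_abs_residual
  row$chi2 <- report$chi2
  row$chi2_df <- report$chi2_df
  row$chi2_p <- report$chi2_p
  row$odds_ratio <- report$odds_ratio
  row$outlier_score <- report$outlier_score
  if (!is.null(report$counts)) {
    row$n_a <- report$counts$n_a; row$n_t <- report$counts$n_t
    row$n_g <- report$counts$n_g; row$n_c <- report$counts$n_c
    row$n_ambiguous <- report$counts$n_ambiguous
  } else {
    row$n_a <- NA_real_; row$n_t <- NA_real_
    row$n_g <- NA_real_; row$n_c <- NA_real_
    row$n_ambiguous <- NA_real_
  }
  if (!is.null(digits)) {
    prop_cols <- c(.profile_columns, "ambiguous_fraction",
                   "law1_delta_at", "law1_delta_gc", "law2_delta",
                   "est_p_a", "est_p_t", "est_p_g", "est_p_c",
                   "resid_a", "resid_t", "resid_g", "resid_c",
                   "max_abs_residual", "outlier_score")
    for (col in prop_cols) row[[col]] <- round(row[[col]], digits)
  }
  row
}

law_report_to_list <- function(report) {
  list(genome_id = report$genome_id,
       profile = unclass(report$profile),
       law1_delta_at = report$law1_delta_at,
       law1_delta_gc = report$law1_delta_gc,
       law2_delta = report$law2_delta,
       estimated_profile = unclass(report$estimated_profile),
       residuals = as.list(report$residuals),
       max_abs_residual = report$max_abs_residual,
       chi2 = report$chi2, chi2_df = report$chi2_df,
       chi2_p = report$chi2_p, odds_ratio = report$odds_ratio,
       outlier_score = report$outlier_score)
}

#' Serialize law reports to TSV and/or JSON
#'
#' TSV rounds proportion-valued fields to `digits` decimals
#' (round-half-even); JSON keeps full precision.
#'
#' @param reports List of `law_report` objects.
#' @param tsv,json Output paths; either may be `NULL` to skip.
#' @param digits TSV rounding, default 4.
#' @return Invisibly, the (unrounded) data frame of reports.
#' @export
write_law_reports <- function(reports, tsv = NULL, json = NULL, digits = 4) {
  if (inherits(reports, "law_report")) reports <- list(reports)
  stopifnot(length(reports) > 0,
            all(vapply(reports, inherits, logical(1), "law_report")))
  full <- do.call(rbind, lapply(reports, law_report_row))
  if (!is.null(tsv)) {
    rounded <- do.call(rbind, lapply(reports, law_report_row, digits = digits))
    write.table(rounded, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json))
    jsonlite::write_json(lapply(reports, law_report_to_list), json,
                         auto_unbox = TRUE, digits = NA, na = "null")
  invisible(full)
}
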