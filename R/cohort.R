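# Cross-genome analysis: composition matrix, regression panels, outliers.

cohort_row <- function(report) {
  law_report_row(report)
}

#' Build a cohort table from per-genome counts or profiles
#'
#' One row per genome holding its composition profile and law metrics.
#' Elements may be [base_counts()] (full reports, including the
#' independence test) or `composition_profile` objects (test fields
#' `NA`, e.g. when only published proportions are available).
#'
#' @param genomes Named list; names are unique genome ids, values
#'   `base_counts` or `composition_profile` objects.
#' @param provenance Free-text description of where the cohort came
#'   from, stored as an attribute.
#' @return A data frame of class `cohort_table`.
#' @export
build_cohort <- function(genomes, provenance = "") {
  if (!is.list(genomes) || length(genomes) == 0L)
    stop("genomes must be a non-empty named list")
  ids <- names(genomes)
  if (is.null(ids) || any(is.na(ids)) || any(!nzchar(ids)))
    stop("every genome must be named by its id")
  if (anyDuplicated(ids))
    stop(sprintf("duplicate genome id: '%s'", ids[duplicated(ids)][1]))
  rows <- vector("list", length(genomes))
  for (i in seq_along(genomes)) {
    g <- genomes[[i]]
    report <- tryCatch({
      if (inherits(g, "base_counts")) evaluate_genome(ids[i], g)
      else if (inherits(g, "composition_profile"))
        law_report_from_profile(ids[i], g)
      else stop("must be base_counts or composition_profile")
    }, error = function(e)
      stop(sprintf("genome '%s': %s", ids[i], conditionMessage(e)),
           call. = FALSE))
    rows[[i]] <- cohort_row(report)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "provenance") <- provenance
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Ordinary least squares fit for one regression panel
#'
#' Textbook OLS with vertical residuals: `slope = Sxy/Sxx`,
#' `intercept = mean(y) - slope*mean(x)`, `r_squared = 1 - SSres/SStot`.
#' When the response is constant (`SStot = 0`) the coefficient of
#' determination is undefined: it is reported as `NA` with
#' `r_squared_defined = FALSE` rather than forced to 0 or 1.
#'
#' @param x,y Numeric vectors of equal length, `n >= 2`; `x` must not be
#'   constant.
#' @param x_label,y_label Panel labels carried through to reports.
#' @return An object of class `regression_fit` with fields `slope`,
#'   `intercept`, `r_squared`, `r_squared_defined`, `n`, `x_label`,
#'   `y_label`.
#' @export
fit_regression <- function(x, y, x_label = "x", y_label = "y") {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y))
    stop("x and y must be numeric vectors of equal length")
  if (length(x) < 2L)
    stop("regression needs at least 2 points")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("x and y must be finite")
  xbar <- mean(x); ybar <- mean(y)
  sxx <- sum((x - xbar)^2)
  if (sxx == 0) stop("x is constant: slope undefined")
  slope <- sum((x - xbar) * (y - ybar)) / sxx
  intercept <- ybar - slope * xbar
  ss_res <- sum((y - (intercept + slope * x))^2)
  ss_tot <- sum((y - ybar)^2)
  structure(
    list(slope = slope, intercept = intercept,
         r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
         r_squared_defined = ss_tot > 0,
         n = length(x), x_label = x_label, y_label = y_label),
    class = "regression_fit"
  )
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("<regression_fit> %s ~ %s: slope=%.6g intercept=%.6g R2=%s (n=%d)\n",
              x$y_label, x$x_label, x$slope, x$intercept,
              if (x$r_squared_defined) sprintf("%.6g", x$r_squared)
              else "undefined", x$n))
  invisible(x)
}

#' The eight standard cross-genome regression panels
#'
#' Cohort-level diagnostics of the three laws: P(T) on P(A) and P(C) on
#' P(G) (pairing parity: slope near 1 through the origin), P(R)-P(Y)
#' on P(S) (balance: slope and intercept near 0), P(R) on P(S)
#' (independence of purine content from GC content: slope near 0,
#' intercept near 0.5), and observed-on-estimated for each base
#' (factorization quality: slope near 1, intercept near 0, R-squared
#' near 1).
#'
#' @param cohort A `cohort_table` with at least 2 genomes.
#' @return Named list of eight `regression_fit` objects.
#' @export
panel_regressions <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (nrow(cohort) < 2L)
    stop("regression panels need a cohort of at least 2 genomes")
  fits <- list(
    t_vs_a = fit_regression(cohort$p_a, cohort$p_t, "P(A)", "P(T)"),
    c_vs_g = fit_regression(cohort$p_g, cohort$p_c, "P(G)", "P(C)"),
    r_minus_y_vs_s = fit_regression(cohort$p_s, cohort$p_r - cohort$p_y,
                                    "P(S)", "P(R) - P(Y)"),
    r_vs_s = fit_regression(cohort$p_s, cohort$p_r, "P(S)", "P(R)"),
    obs_vs_est_a = fit_regression(cohort$est_p_a, cohort$p_a,
                                  "estimated P(A)", "observed P(A)"),
    obs_vs_est_t = fit_regression(cohort$est_p_t, cohort$p_t,
                                  "estimated P(T)", "observed P(T)"),
    obs_vs_est_g = fit_regression(cohort$est_p_g, cohort$p_g,
                                  "estimated P(G)", "observed P(G)"),
    obs_vs_est_c = fit_regression(cohort$est_p_c, cohort$p_c,
                                  "estimated P(C)", "observed P(C)")
  )
  fits
}

#' Rank genomes by composition-outlier score
#'
#' Sorts by `outlier_score` descending; ties are broken by genome id in
#' lexicographic order, so the ranking is deterministic.
#'
#' @param cohort A `cohort_table`.
#' @param top_k Maximum number of genomes returned (>= 1).
#' @return Data frame with columns `genome_id`, `outlier_score`.
#' @export
rank_outliers <- function(cohort, top_k = 10L) {
  stopifnot(inherits(cohort, "cohort_table"))
  top_k <- as.integer(top_k)
  if (is.na(top_k) || top_k < 1L) stop("top_k must be a positive integer")
  ord <- order(-cohort$outlier_score, cohort$genome_id, method = "radix")
  out <- data.frame(genome_id = cohort$genome_id[ord],
                    outlier_score = cohort$outlier_score[ord],
                    stringsAsFactors = FALSE)
  head(out, top_k)
}

#' Read a per-genome composition table (TSV)
#'
#' The table must have a `genome_id` column plus either the four base
#' counts (`n_a`, `n_t`, `n_g`, `n_c`, optionally `n_ambiguous`) or the
#' four base proportions (`p_a`, `p_t`, `p_g`, `p_c`). Proportions may
#' be percentages — auto-detected when any value exceeds 1.5 — and must
#' sum to 1 within 0.005 per row. With proportions only, the
#' independence-test fields of the resulting cohort are `NA`.
#'
#' @param path Path to the TSV file.
#' @return A `cohort_table`.
#' @export
read_composition_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("composition table not found: '%s'", path))
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(tab) == 0L) stop(sprintf("'%s' has no data rows", path))
  count_cols <- c("n_a", "n_t", "n_g", "n_c")
  prop_cols <- c("p_a", "p_t", "p_g", "p_c")
  have_counts <- all(count_cols %in% names(tab)) &&
    !anyNA(tab[count_cols])
  have_props <- all(prop_cols %in% names(tab))
  if (!("genome_id" %in% names(tab)) || !(have_counts || have_props)) {
    missing <- setdiff("genome_id", names(tab))
    stop(sprintf(
      "composition table '%s' is missing required columns: %s",
      path,
      paste(c(missing,
              if (!have_counts && !have_props)
                "either n_a,n_t,n_g,n_c or p_a,p_t,p_g,p_c"),
            collapse = "; ")))
  }
  ids <- as.character(tab$genome_id)
  genomes <- vector("list", nrow(tab))
  if (have_counts) {
    n_amb <- if ("n_ambiguous" %in% names(tab)) tab$n_ambiguous else
      rep(0, nrow(tab))
    for (i in seq_len(nrow(tab)))
      genomes[[i]] <- tryCatch(
        base_counts(tab$n_a[i], tab$n_t[i], tab$n_g[i], tab$n_c[i],
                    n_ambiguous = n_amb[i]),
        error = function(e)
          stop(sprintf("row %d (genome '%s'): %s", i, ids[i],
                       conditionMessage(e)), call. = FALSE))
  } else {
    # one percent-vs-fraction decision for the whole table
    vals <- as.matrix(tab[prop_cols])
    scale <- if (any(vals > 1.5, na.rm = TRUE)) 100 else 1
    n_cnt <- if ("n_counted" %in% names(tab)) tab$n_counted else
      rep(NA_real_, nrow(tab))
    for (i in seq_len(nrow(tab)))
      genomes[[i]] <- tryCatch(
        profile_from_proportions(vals[i, 1] / scale, vals[i, 2] / scale,
                                 vals[i, 3] / scale, vals[i, 4] / scale,
                                 n_counted = n_cnt[i]),
        error = function(e)
          stop(sprintf("row %d (genome '%s'): %s", i, ids[i],
                       conditionMessage(e)), call. = FALSE))
  }
  names(genomes) <- ids
  build_cohort(genomes, provenance = path)
}

#' Write a cohort table as TSV
#'
#' Proportion-valued columns are rounded to `digits` decimals; counts
#' and test statistics are written in full.
#'
#' @param cohort A `cohort_table`.
#' @param path Output TSV path.
#' @param digits Report rounding, default 4.
#' @return Invisibly, `path`.
#' @export
write_cohort_tsv <- function(cohort, path, digits = 4) {
  stopifnot(inherits(cohort, "cohort_table"))
  out <- as.data.frame(cohort)
  prop_cols <- intersect(
    c(.profile_columns, "ambiguous_fraction",
      "law1_delta_at", "law1_delta_gc", "law2_delta",
      "est_p_a", "est_p_t", "est_p_g", "est_p_c",
      "resid_a", "resid_t", "resid_g", "resid_c",
      "max_abs_residual", "outlier_score"),
    names(out))
  for (col in prop_cols) out[[col]] <- round(out[[col]], digits)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write regression panels as TSV
#'
#' @param fits Named list of `regression_fit` objects, as from
#'   [panel_regressions()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_panels_tsv <- function(fits, path) {
  stopifnot(is.list(fits), length(fits) > 0,
            all(vapply(fits, inherits, logical(1), "regression_fit")))
  out <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(panel = nm, x_label = f$x_label, y_label = f$y_label,
               slope = f$slope, intercept = f$intercept,
               r_squared = f$r_squared,
               r_squared_defined = f$r_squared_defined,
               n = f$n, stringsAsFactors = FALSE)
  }))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an outlier ranking as TSV
#'
#' @param ranked Data frame from [rank_outliers()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_outliers_tsv <- function(ranked, path) {
  stopifnot(is.data.frame(ranked),
            all(c("genome_id", "outlier_score") %in% names(ranked)))
  write.table(ranked, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
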