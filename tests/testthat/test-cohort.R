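test_that("fit_regression reproduces hand-computed OLS", {
  f <- fit_regression(c(0, 1, 2), c(0, 1, 2))
  expect_identical(f$slope, 1)
  expect_identical(f$intercept, 0)
  expect_identical(f$r_squared, 1)

  # constant response: slope 0, R-squared undefined (not 0, not 1)
  f2 <- fit_regression(c(0, 1, 2), c(1, 1, 1))
  expect_identical(f2$slope, 0)
  expect_identical(f2$intercept, 1)
  expect_false(f2$r_squared_defined)
  expect_true(is.na(f2$r_squared))

  # Sxy = 2, Sxx = 2, Syy = 8/3
  f3 <- fit_regression(c(0, 1, 2), c(0, 2, 2))
  expect_equal(f3$slope, 1, tolerance = 1e-12)
  expect_equal(f3$intercept, 1 / 3, tolerance = 1e-12)
  expect_equal(f3$r_squared, 0.75, tolerance = 1e-12)

  expect_error(fit_regression(1, 1), "at least 2")
  expect_error(fit_regression(c(2, 2, 2), c(0, 1, 2)), "constant")
})

test_that("fit_regression agrees with independent least-squares routes", {
  set.seed(33)
  for (i in 1:10) {
    n <- sample(3:20, 1)
    x <- rnorm(n); y <- 2 * x + rnorm(n)
    f <- fit_regression(x, y)
    m <- lm(y ~ x)
    expect_equal(f$slope, unname(coef(m)[2]), tolerance = 1e-10)
    expect_equal(f$intercept, unname(coef(m)[1]), tolerance = 1e-10)
    expect_equal(f$r_squared, summary(m)$r.squared, tolerance = 1e-10)
  }
  # direct numerical minimization of the residual sum of squares
  x <- c(0.1, 0.4, 0.7, 0.9); y <- c(0.2, 0.3, 0.9, 0.8)
  f <- fit_regression(x, y)
  opt <- optim(c(0, 0), function(b) sum((y - b[1] - b[2] * x)^2),
               gr = function(b) {
                 r <- y - b[1] - b[2] * x
                 c(-2 * sum(r), -2 * sum(r * x))
               }, method = "BFGS", control = list(reltol = 1e-14))
  expect_equal(f$intercept, opt$par[1], tolerance = 1e-6)
  expect_equal(f$slope, opt$par[2], tolerance = 1e-6)
})

test_that("build_cohort validates ids and computes one report per genome", {
  genomes <- list(g1 = bc(30, 30, 20, 20),
                  g2 = bc(10, 10, 40, 40),
                  g3 = bc(25, 25, 25, 25))
  cohort <- build_cohort(genomes, provenance = "synthetic trio")
  expect_s3_class(cohort, "cohort_table")
  expect_equal(nrow(cohort), 3L)
  expect_equal(cohort$genome_id, c("g1", "g2", "g3"))
  expect_equal(attr(cohort, "provenance"), "synthetic trio")
  expect_true(all(abs(cohort$p_a + cohort$p_t + cohort$p_g + cohort$p_c - 1)
                  < 1e-12))

  expect_error(build_cohort(list(a = bc(1, 1, 1, 1), a = bc(2, 2, 2, 2))),
               "duplicate genome id")
  expect_error(build_cohort(list(bad = bc(0, 0, 0, 0, amb = 3))),
               "genome 'bad'")

  single <- build_cohort(list(only = bc(5, 5, 5, 5)))
  expect_equal(nrow(single), 1L)
  expect_error(panel_regressions(single), "at least 2")
})

test_that("panels: factorizing cohort gives identity observed-vs-estimated fits", {
  # every genome's counts factorize (n_g*n_t == n_a*n_c), so the
  # third-law estimates equal the observations
  genomes <- list(g1 = bc(36, 24, 24, 16),   # s = 0.4, r = 0.6
                  g2 = bc(25, 25, 25, 25),
                  g3 = bc(9, 9, 1, 1),
                  g4 = bc(14, 56, 6, 24))    # s = 0.3, r = 0.2
  cohort <- build_cohort(genomes)
  expect_true(all(cohort$chi2 < 1e-20))
  fits <- panel_regressions(cohort)
  expect_length(fits, 8L)
  for (panel in c("obs_vs_est_a", "obs_vs_est_t", "obs_vs_est_g",
                  "obs_vs_est_c")) {
    expect_equal(fits[[panel]]$slope, 1, tolerance = 1e-9)
    expect_equal(fits[[panel]]$intercept, 0, tolerance = 1e-9)
    expect_equal(fits[[panel]]$r_squared, 1, tolerance = 1e-12)
  }
})

test_that("panels: exact designs at r = 0.5 pin the purine-vs-GC regression", {
  s_values <- c(0.2, 0.3, 0.4, 0.5, 0.6)
  genomes <- list()
  for (i in seq_along(s_values)) {
    rec <- design_sequence(design_spec(s_values[i], 0.5, 1000, seed = i,
                                       mode = "exact"))
    genomes[[sprintf("d%02d", i)]] <- count_bases(rec$sequence)
  }
  cohort <- build_cohort(genomes)
  expect_equal(cohort$p_r, rep(0.5, 5))
  f <- panel_regressions(cohort)$r_vs_s
  expect_identical(f$slope, 0)
  expect_identical(f$intercept, 0.5)
  expect_false(f$r_squared_defined)
})

test_that("panels: iid cohort under the independence model shows near-perfect fits", {
  set.seed(202)
  s_values <- runif(20, 0.2, 0.8)
  genomes <- list()
  for (i in seq_along(s_values)) {
    rec <- design_sequence(design_spec(s_values[i], 0.5, 20000, seed = 5000 + i))
    genomes[[sprintf("sim%02d", i)]] <- count_bases(rec$sequence)
  }
  cohort <- build_cohort(genomes)
  fits <- panel_regressions(cohort)
  for (panel in c("obs_vs_est_a", "obs_vs_est_t", "obs_vs_est_g",
                  "obs_vs_est_c"))
    expect_gt(fits[[panel]]$r_squared, 0.99)
  expect_lt(abs(fits$r_vs_s$slope), 0.02)
  expect_lt(abs(fits$r_vs_s$intercept - 0.5), 0.01)
})

test_that("rank_outliers sorts by score with deterministic tie-breaking", {
  cohort <- build_cohort(list(yeast = yeast_profile(),
                              aberrant = aberrant_profile()))
  ranked <- rank_outliers(cohort, top_k = 10)
  expect_equal(ranked$genome_id, c("aberrant", "yeast"))
  expect_equal(ranked$outlier_score, c(0.1486, 0.0011), tolerance = 1e-9)

  same <- build_cohort(list(b = bc(10, 10, 5, 5), a = bc(20, 20, 10, 10),
                            c = bc(2, 2, 1, 1)))
  ranked2 <- rank_outliers(same, top_k = 5)
  expect_equal(ranked2$genome_id, c("a", "b", "c")) # ties -> id order
  expect_equal(nrow(ranked2), 3L)                   # top_k clamped
  expect_equal(nrow(rank_outliers(same, top_k = 2)), 2L)
  expect_true(all(diff(ranked2$outlier_score) <= 0))
  expect_error(rank_outliers(same, top_k = 0), "positive")
})

test_that("read_composition_table handles counts, proportions, and percent", {
  f <- tempfile(fileext = ".tsv")
  write.table(data.frame(genome_id = c("g1", "g2"),
                         n_a = c(30, 9), n_t = c(10, 9),
                         n_g = c(10, 1), n_c = c(30, 1)),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  cohort <- read_composition_table(f)
  expect_equal(cohort$chi2, c(20, 0))

  f2 <- tempfile(fileext = ".tsv")
  write.table(data.frame(genome_id = c("g1", "g2"),
                         p_a = c(0.3, 0.25), p_t = c(0.3, 0.25),
                         p_g = c(0.2, 0.25), p_c = c(0.2, 0.25)),
              f2, sep = "\t", quote = FALSE, row.names = FALSE)
  cohort2 <- read_composition_table(f2)
  expect_true(all(is.na(cohort2$chi2)))
  expect_equal(cohort2$p_s, c(0.4, 0.5))

  # percentages auto-detected and rescaled
  f3 <- tempfile(fileext = ".tsv")
  write.table(data.frame(genome_id = "g1", p_a = 27.87, p_t = 27.33,
                         p_g = 14.97, p_c = 29.83),
              f3, sep = "\t", quote = FALSE, row.names = FALSE)
  cohort3 <- read_composition_table(f3)
  expect_equal(cohort3$p_g, 0.1497, tolerance = 1e-9)
})

test_that("read_composition_table rejects malformed tables by name", {
  f <- tempfile(fileext = ".tsv")
  write.table(data.frame(genome_id = "g1", p_a = 0.5), f, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(read_composition_table(f), "missing required columns")

  f2 <- tempfile(fileext = ".tsv")
  write.table(data.frame(genome_id = c("ok", "bad"),
                         p_a = c(0.25, 0.30), p_t = c(0.25, 0.30),
                         p_g = c(0.25, 0.15), p_c = c(0.25, 0.15)),
              f2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_composition_table(f2), "row 2 \\(genome 'bad'\\)")
})

test_that("cohort writers emit readable TSVs", {
  cohort <- build_cohort(list(g1 = bc(30, 30, 20, 20), g2 = bc(9, 9, 1, 1)))
  d <- tempfile(); dir.create(d)
  write_cohort_tsv(cohort, file.path(d, "cohort.tsv"))
  write_panels_tsv(panel_regressions(cohort), file.path(d, "panels.tsv"))
  write_outliers_tsv(rank_outliers(cohort), file.path(d, "outliers.tsv"))
  expect_equal(nrow(read.delim(file.path(d, "panels.tsv"))), 8L)
  back <- read.delim(file.path(d, "cohort.tsv"))
  expect_equal(back$genome_id, c("g1", "g2"))
  expect_equal(back$n_a, c(30, 9))
})
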