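# Shared fixtures: all inputs are generated in code at test time.

random_dna <- function(n, probs = c(A = 0.25, T = 0.25, G = 0.25, C = 0.25)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

bc <- function(a, t, g, c, amb = 0) base_counts(a, t, g, c, n_ambiguous = amb)

# Published genome-wide base proportions used as reference points:
# budding yeast (near-perfect law conformity) and a small bacterial
# genome with a strong G/C disparity.
yeast_profile <- function() {
  profile_from_proportions(0.3098, 0.3087, 0.1906, 0.1909)
}

aberrant_profile <- function() {
  profile_from_proportions(0.2787, 0.2733, 0.1497, 0.2983)
}

write_tmp_fasta <- function(lines, ext = ".fa") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# Textbook 2x2 chi-square from margins, independent of the package's
# expected-counts route: n * (ad - bc)^2 / product of the four margins.
margins_chi2 <- function(a, t, g, c) {
  n <- a + t + g + c
  n_s <- g + c; n_w <- a + t; n_r <- a + g; n_y <- t + c
  n * (g * t - a * c)^2 / (n_s * n_w * n_r * n_y)
}
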