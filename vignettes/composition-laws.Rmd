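---
title: "Genome composition laws: model, methods, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome composition laws: model, methods, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(basecomp)
```

## The model

`basecomp` treats a genome as a single strand of nucleotides and works
with the eight proportions P(A), P(T), P(G), P(C), P(S), P(W), P(R),
P(Y), where S = G∪C, W = A∪T = S^c, R = A∪G and Y = T∪C = R^c in the
usual set notation over the base alphabet Ω = {A, T, G, C}. Three laws
structure these quantities:

1. **Pairing parity.** Complementary base pairing in double-stranded
   DNA forces P(A) = P(T) and P(G) = P(C) across both strands; the
   same equalities hold approximately within a single strand of a
   genome-scale sequence (Chargaff's second parity rule). The package
   reports the deviations |P(A) − P(T)| and |P(G) − P(C)|.
2. **Purine–pyrimidine balance.** Parity implies
   P(R) = P(Y) = 0.5; the deviation is |P(R) − 0.5|. Across genomes,
   purine content is empirically uncorrelated with GC content, which
   the cohort module checks as a regression of P(R) on P(S) (slope
   near 0, intercept near 0.5).
3. **Independence factorization.** If a base's S/W status is
   statistically independent of its R/Y status, then every base
   proportion is a product of marginals:
   P(A) = (1−P(S))P(R), P(T) = (1−P(S))(1−P(R)), P(G) = P(S)P(R),
   P(C) = P(S)(1−P(R)). These four products sum to 1 identically on
   [0,1]², and at P(R) = 0.5 they collapse to the parity law. The
   package reports signed residuals (observed − estimated) per base
   and a 2×2 independence test (below).

```{r}
estimate_profile(0.3815, 0.5004) # yeast-like reference composition
```

The laws are genome-level statements: individual genes, windows, or
regional sequences (replication origins, GC isochores, skew segments)
deviate systematically, and the package deliberately offers no
windowed analysis.

## Counting conventions

* **Single strand, as given.** Proportions are computed on the strand
  stored in the FASTA file; no canonical-strand selection is
  attempted. The complement-strand profile is available through
  `reverse_complement()`, and the concatenation of a strand with its
  reverse complement satisfies parity *exactly*, which the tests use
  as a construction oracle.
* **Ambiguity codes.** IUPAC non-ACGT characters are excluded from the
  proportion denominator — long N runs in draft assemblies would
  otherwise dilute composition — and reported as an
  `ambiguous_fraction` of total length so users can judge assembly
  quality. How published composition tables treated ambiguous bases
  is usually unstated; this choice is documented rather than assumed
  universal.
* **Normalization.** Lowercase (soft-masked) bases are counted like
  uppercase ones, since masking marks repeats, not composition. U is
  mapped to T (with a per-record tally) so RNA genomes can be
  profiled. Gap characters `-`/`.` are stripped with a warning rather
  than rejected, so alignment exports do not hard-fail.
* **Rounding.** Proportions are stored at full double precision and
  rounded only at report time, default 4 decimals with R's
  round-half-even rule, which is consistent with conventional
  published values.

## The 2×2 independence test

The factorization is testable per genome: arrange the base counts as
the contingency table rows {S, W} × columns {R, Y} — cells (G, C /
A, T) — and compare observed counts with expected counts under
independence. The expected counts *are* the third-law estimates times
sequence length; the package computes them as integer margin products
`n_W·n_R/n` etc., which is the same quantity evaluated without
intermediate rounding, so that the statistic is exactly zero whenever
the counts factorize (`n_G·n_T = n_A·n_C`). The default statistic is
the Pearson chi-square without continuity correction — at genome-scale
n the Yates correction is negligible — with a likelihood-ratio G-test
available for small toy tables. Degenerate margins (a sequence with no
purines, say) raise an error naming the empty margin instead of
propagating NaN.

Note an asymmetry the user should keep in mind: cross-genome
regressions support independence of S and R as a between-genome
pattern, while the test applies it within one genome. Genome-scale n
makes the test extremely sensitive; tiny within-genome dependencies
(codon structure, dinucleotide avoidance) will reject it even when the
residuals are biologically negligible. The residuals and the
chi-square are therefore reported side by side.

## Outlier scoring

The outlier score is `max(|P(A)−P(T)|, |P(G)−P(C)|)`. Known aberrant
genomes are characterized by a strong disparity between P(G) and P(C),
and a proportion-scale score — unlike the chi-square statistic — does
not grow with genome size, so a large well-behaved genome cannot
outrank a small deviant one. Ranking ties are broken by genome id so
the output is deterministic. No multiple-testing machinery is applied
to the per-genome p-values by default, since the laws are descriptive
rather than hypothesis-driven; users who need cohort-wide error
control can apply `p.adjust` to the `chi2_p` column.

## Cohort regressions

`panel_regressions()` fits eight ordinary-least-squares lines: P(T) on
P(A), P(C) on P(G), P(R)−P(Y) on P(S), P(R) on P(S), and observed on
estimated for each base. OLS with vertical residuals is used even for
the symmetric pairing panels, where an errors-in-variables fit would
be defensible, because plain OLS slope/intercept/R² is the convention
these diagnostics are quoted in; this is a documented simplification.
`fit_regression()` uses the closed form slope = Sxy/Sxx and reports R²
as flagged-undefined (`NA` plus `r_squared_defined = FALSE`) when the
response is constant — any numeric stand-in (0 or 1) would be
arbitrary and misleading, and a constant *predictor* is an error.
Proportions are emitted as fractions throughout; multiply by 100 for
percentage-scale intercepts. Input composition tables may use either
convention: values are auto-detected as percentages when any exceeds
1.5, a threshold no legitimate fraction can cross and no legitimate
percentage table can stay under.

## The sequence designer

`design_sequence()` uses the factorization generatively: given targets
(s, r), the per-base probabilities are `estimate_profile(s, r)`. Two
modes:

* **iid** draws every position independently — the minimal generative
  model consistent with marginal base probabilities; it produces
  binomial sampling noise of sd `sqrt(p(1−p)/L)` per content.
* **exact** fixes the base counts by largest-remainder (Hamilton)
  apportionment of L times the probabilities — which minimizes
  rounding deviation, at most 1 count per base, hence at most 2/L per
  content — and randomizes only the order.

The seed is mandatory: a design that cannot be regenerated is useless
as a specification, so there is no silent clock seeding. The FASTA
header records targets, length, seed, mode, and PRNG
(Mersenne-Twister), and the generator restores the caller's RNG state
afterwards. `verify_design()` passes a sequence when each achieved
content is within 2/L (exact mode) or four binomial standard errors
(iid mode) of its target; four standard errors keeps the false-failure
rate per target near 6×10⁻⁵ while still catching any systematic bias.
The designer emits no dinucleotide or higher-order structure (no codon
bias, no CpG depletion): designed sequences emulate genome-scale
*composition* only, so tests passing on them demonstrate the
composition algebra, not realism of real genomes with repeat content,
ambiguity runs, or local heterogeneity.

## Numerical choices

* Proportions over unambiguous counts are exact integer ratios in
  double precision; identities (profile sums, P(S)+P(W)=1) are tested
  at 1e−12.
* Exact factorization cases give chi-square exactly 0 (integer margin
  products), but law-3 *residuals* of factorizing counts are only
  zero to rounding (two different evaluation orders of the same
  ratio), so they are asserted at 1e−12, not bitwise.
* Largest-remainder ties are broken in fixed base order A, T, G, C.
* Degenerate design targets (s or r at 0 or 1) are legal and yield
  single-letter sequences with zero tolerance; verification still
  passes since the deviation is exactly 0.

## Problem sizes in the test suite

The property and simulation tests use 1000 random sequences of length
up to ~120 for the algebraic identities, all 2401 2×2 tables with
cells ≤ 6 against a textbook chi-square, 200 iid designs of length 10⁵
for target recovery, 500 designs of length 10⁴ for the chi-square(1)
calibration of the designed-sequence statistic (mean within
[0.8, 1.2]), and a 50-genome cohort of length-10⁵ designs with GC
drawn uniformly on [0.2, 0.8] at purine content 0.5 for the regression
panels (observed-vs-estimated R² > 0.99, P(R)-on-P(S) slope ≈ 0 and
intercept ≈ 0.5). These sizes give sampling errors an order of
magnitude below every tolerance asserted while keeping the suite
around a minute; they are the package's own calibration choices. A
full published-scale cohort (tens of thousands of RefSeq genomes) is
supported by the same code paths via `cmd_cohort()` on a directory of
FASTA files or a precomputed composition TSV, but is not part of the
test suite.

## Known limitations

* No windowed/regional analysis (GC skew, isochores) — the laws do not
  apply there, by design.
* No k-mer or codon composition; the model is strictly marginal.
* OLS panels ignore errors in x; for pairing panels the slope is
  therefore attenuated very slightly toward 0 when sampling noise in
  the predictor is non-negligible (short sequences).
* The cohort regressions make no phylogenetic correction; points are
  treated as independent although related genomes are not.
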