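---
title: "Differential exosome proteomics and prognostic scoring: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential exosome proteomics and prognostic scoring: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exosig)
```

# Scope

`exosig` implements the computational stages of a label-free exosome
proteomics workflow for carboplatin resistance in canine osteosarcoma:
peptide-to-protein fold-change aggregation, a serum-cohort differential
signature with a reference-relative heatmap, detection-set logic and
odds-ratio enrichment, a linear prognosis score validated by leave-one-out
cross-validation, and the phenotype assay arithmetic (doubling time, MTS
viability, four-parameter logistic IC50, disease-free-interval cohorts).
A synthetic-data module emulates every input, so the full pipeline runs and
is tested with no external downloads. The numbered scripts under
`analysis/` drive the stages in order and write their tables under
`results/`.

# Fold changes by nested geometric medians

The fold change of protein $X$ between groups $A$ and $B$ is built in two
nested steps. For each peptide, every combination of replicate abundances
across the two groups contributes one ratio $a_i/b_j$ (only observed,
positive values pair; a pair with a missing member contributes nothing),
and the peptide's group ratio is the geometric median of those
$|A|\times|B|$ ratios. The protein's fold change is then the geometric
median of its peptide group ratios.

For positive scalars the geometric median is the median in log space: the
geometric median of a set of points minimizes the summed distance to them,
and in one dimension that minimizer is the ordinary median, applied here to
log-ratios because ratios live on a multiplicative scale. With an even
count the minimizer is any point between the two central values; `exosig`
resolves the tie as the geometric mean of the two central ratios, the
unique symmetric and continuous choice. These conventions give the
estimator three exact properties that the test suite checks against a
brute-force enumerator: antisymmetry ($FC_{AB}\cdot FC_{BA}=1$), scale
equivariance, and invariance to replicate order.

Missing or nonpositive abundances are never imputed. A peptide with no
usable replicate pair is excluded and counted; a protein observed in only
one of the two groups is a detection event, not a ratio, and is reported
with an `only_group_a` / `only_group_b` flag (and participates in the Venn
logic) rather than an infinite fold change entering downstream filters.

# Differential signature

Serum-exosome abundances are first normalized by total-sum scaling (each
sample column divided by its sum), the standard correction for per-sample
loading differences in label-free data. Per-protein two-sample t statistics
(cohort 1 minus cohort 2) with two-sided p-values then rank the features;
heatmap rows follow descending t-score. The default is the pooled-variance
Student test, matching a conventional Prism-style workflow; Welch is
available behind `var_equal = FALSE`. Raw p-values drive all displayed
thresholds, and Benjamini–Hochberg q-values are emitted alongside because a
proteome-wide scan on five-versus-five cohorts demands a multiplicity-aware
column; the q-values are an extension, not part of the displayed statistic.
Whether testing happens on normalized or raw values was an open choice;
`exosig` tests normalized values by default (mirroring the order of
operations used for the heatmap) and exposes `normalize = FALSE`.

The heatmap matrix entry for protein $p$ in sample $s$ is
$\log_2\!\big((x_{ps}+\varepsilon)/(\bar{x}_{p,\mathrm{ref}}+\varepsilon)\big)$,
where $\bar{x}_{p,\mathrm{ref}}$ is the protein's mean over the reference
cohort's columns, so a sample equal to the reference mean maps to zero. The
pseudocount $\varepsilon$ defaults to $10^{-9}$ of the matrix mean — large
enough to keep zero cells finite, nine orders of magnitude too small to
move any nonzero cell visibly.

Detection (presence) for the Venn logic counts a protein as detected in a
group when it is observed in at least one replicate; the rule is exposed
rather than hard-coded because presence filtering conventions vary between
search engines. Ortholog filtering retains proteins with strictly more than
99% amino acid similarity to their human ortholog, an exclusive boundary
(99.0% is dropped). Enrichment per gene set is the sample odds ratio of the
2×2 query-by-set table over the background (Haldane–Anscombe 0.5 correction
when a cell is empty) with a one-sided hypergeometric tail p-value — the
quantities the study's bar charts display. This is a reimplementation of
the displayed statistic, not of any particular web tool's gene-set
libraries or ranking extras.

# The prognosis score

The source study presents its outcome classifier only graphically: samples
plotted by two signed "net prediction score contribution" axes with a
straight decision boundary, and a net score where lower means better
prognosis. `exosig` formalizes the minimal model consistent with that
display, and documents it as an explicit interpretation:

* **Features**: proteins with t-test p below `p_cutoff` (default 0.05),
  optionally truncated to the `max_features` largest $|t|$.
* **Weights**: the feature's t-score, oriented so a positive weight marks a
  protein more abundant in poor responders (negatively correlated with good
  outcome).
* **Score**: abundances are standardized with training-set means and SDs;
  a sample's net score is $\sum_f w_f z_f$. The two plotted axes are the
  positive-weight and negative-weight partial sums, so
  `net = contrib_negative - contrib_positive` holds exactly.
* **Boundary**: the midpoint of the two training cohorts' mean net scores —
  data-driven, like the drawn decision line, rather than fixed at zero. A
  sample exactly on the boundary is called a poor responder, the
  conservative clinical default.

Leave-one-out validation retrains everything inside each fold —
normalization statistics, feature selection, standardization, boundary —
before scoring the held-out sample, whose own total-sum scaling uses only
its own column. A fold in which no feature passes selection counts its
sample as misclassified and flags it.

Two calibration facts are worth knowing. In the strong-separation regime
the generator emulates (a 4-fold shift on 20 of 500 proteins against a 20%
CV, about seven standard deviations per feature), leave-one-out accuracy is
100% for any seed — this is the regime reproducing the study's headline
claim, and the acceptance script recomputes it. Under the null
(no shift), accuracy over repeated simulations sits near, and in fact
slightly **below**, chance (about 0.35–0.4): this is the known
anti-learning bias of leave-one-out with data-driven feature selection —
the held-out sample's own cohort contributes one fewer training sample, so
chance-selected features place the population mean closer to the opposite
cohort's sample mean. The no-leakage test is therefore one-sided: null
accuracy must not exceed chance, which is what a fold-leakage bug would
produce. Below-chance null behavior is a property of the estimator, not a
defect, and disappears as cohorts grow.

# Phenotype assays

Doubling time follows $t = H\ln 2 / \ln(c_2/c_1)$; a count that has not
increased is an explicit non-growth error rather than a negative or complex
time. MTS absorbances are divided by the mean of the vehicle-control wells,
so controls average exactly 1.

Dose-response viability is fit with the four-parameter logistic
$v(d) = \text{lower} + (\text{upper}-\text{lower})/(1+(d/\mathrm{IC}_{50})^{h})$
by Levenberg–Marquardt least squares (`minpack.lm::nlsLM`), with the
IC50 parameterized on the log scale. The reported IC50 is the curve's
inflection (the "relative" IC50, the convention of standard curve-fitting
software); zero doses stay in the residuals, anchoring the upper asymptote,
but are excluded from any log-dose consideration. Initialization takes
upper and lower from the data's range, the IC50 start from the dose nearest
the half-range crossing, and tries hill slopes 0.5, 1 and 2, keeping the
best of the converged fits. Non-convergence or a degenerate solution
(non-decreasing curve, inverted asymptotes) is reported with
`converged = FALSE`, and an IC50 beyond the tested dose range is flagged
`ic50_in_range = FALSE` rather than suppressed — the 0–10 µM MTS ladder
genuinely cannot bracket a several-hundred-µM IC50, and fits in that regime
are extrapolations. On noise-free curves with at least six distinct doses
the fit recovers all four parameters to relative $10^{-6}$; with realistic
noise (SD 0.03, triplicate wells) the median IC50 error is about 5% when
the doses span the transition, but several-fold worse when the curve is
truncated well above its lower asymptote, which is a property of the design
rather than the optimizer (an independent optimizer returns the same
estimates on shared data).

Cohort assignment uses strict inequalities exactly as stated clinically:
disease-free interval **greater than** 300 days is a good responder,
**less than** 100 days a poor responder, everything else — including a
missing DFI — is `unclassified`, never imputed. On the ten-dog clinical
records shipped with the package this yields 4 good, 5 poor and 1
unclassified (one good-cohort dog has no printed DFI).

# The synthetic-data generators

All inputs are emulated by `sim_config()`-driven generators:

* **Abundances** are lognormal — per-protein baselines
  $\log \mu_p \sim \mathcal N(\log 10^6, 1.5^2)$, per-peptide ionization
  offsets (SD 0.5 in log space), and replicate noise with
  $\mathrm{sdlog}=\sqrt{\log(1+\mathrm{CV}^2)}$ — the standard model for
  label-free MS intensities, and the one that makes geometric-median
  aggregation natural.
* **Effects**: a fraction `frac_discriminating` of proteins (flagged in the
  returned ground truth) carries a `effect_log2` log2 shift in the
  non-reference groups / second cohort; peptides inherit their protein's
  effect exactly, so the quantifier's truth is well-defined.
* **Missingness** is missing-completely-at-random by default (simplest to
  reason about in tests); an intensity-dependent mode (logistic dropout in
  log-abundance) is available because real MS missingness is
  abundance-biased, and the analysis scripts use it to produce realistic
  presence/absence structure.
* **Design sizes**: serum cohorts default to two groups of five, the
  study's cohort size. The cell-line replicate count is not stated for the
  MS runs; the generators default to triplicate, matching the cell-culture
  design, and expose `n_per_group`.
* **Dose-response and growth** generators are exact closed forms plus
  optional truncated Gaussian noise.

What the generators deliberately do **not** emulate: peptide-level
interference or shared peptides (each peptide maps to one protein), raw
spectra and retention times, correlated protein modules, batch effects, or
heavy-tailed contamination. Passing tests on this synthetic data
demonstrates that the pipeline's arithmetic and contracts are correct under
the stated statistical model — not that the biological signatures of any
real cohort would replicate.

# Problem sizes and determinism

Everything is seeded through `sim_config(seed = ...)` or explicit seed
arguments; generators restore the caller's RNG state and are
bit-reproducible. The test suite and the acceptance script use desk-scale
sizes chosen to make the statistical assertions sharp at interactive run
times: 500–2000 proteins for calibration checks, 1000 random small
instances against the brute-force fold-change oracle, 20 simulation seeds
for the null classification sweep, 10,000 Monte-Carlo draws for enrichment
super-uniformity, and 50 replicate fits for noisy IC50 recovery.

# Known limitations

* The prognosis model is a deliberate formalization of a graphical display;
  the original feature count, score construction and validation scheme are
  not public, so agreement is at the level of behavior (perfect separation
  in a strongly separated regime), not coefficients.
* Instrument-level results (unique-protein counts, specific biomarker
  lists) depend on raw spectra and database searches and are out of scope;
  detection-set logic operates on whatever presence lists it is given.
* Single-protein tables cannot be total-sum normalized meaningfully;
  normalization assumes the usual many-protein regime.
* The enrichment test conditions on fixed margins (hypergeometric); it does
  not model inter-protein correlation, which inflates significance in real
  proteomes.
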