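---
title: "Methods: TMT EV proteomics and tau immunoassay pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TMT EV proteomics and tau immunoassay pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evtmt)
```

This vignette is the package's account of its methods: the statistical
models each stage implements, the defaults and why they were chosen, what
the synthetic-data generator does and does not emulate, and the numerical
decisions that affect reproducibility.

## Identification: decoy databases, the discriminant, FDR

Candidate PSMs are assumed to arrive from an upstream spectral search
against a **concatenated target-decoy database** in which every decoy is the
full reversal of one target sequence. Full-protein reversal (rather than
per-peptide pseudo-reversal) preserves amino-acid composition and the
length distribution of tryptic products exactly, so decoy matches are
statistically exchangeable with incorrect target matches — the premise of
decoy-counting FDR estimation. `build_decoy_db()` implements exactly this;
`tryptic_digest()` applies the standard trypsin rule (cleave C-terminal to
K/R, not before P) with configurable missed-cleavage and length bounds.
Defaults of at most 2 missed cleavages and 7–50 residues are common search
practice; they are configuration, not claims about any particular dataset.

The **combined discriminant** is two-class linear discriminant analysis
over seven PSM features: XCorr, ΔCn, precursor mass error (signed ppm,
observed minus theoretical relative to theoretical — the sign convention is
fixed here because it must be fixed somewhere), charge state, in-solution
charge, peptide length and missed cleavages. Targets are the positive
class, decoys the negative class, and the score is the signed discriminant
value centred at the class-mean midpoint. LDA is the Bayes-optimal linear
rule when both populations are Gaussian with a shared covariance, which is
exactly the structure the synthetic generator produces — making the
filter's behaviour on synthetic data analyzable rather than merely
plausible. The fit happens once on the full candidate set (one combined
filter parameter), not per-file or iteratively; a singular within-class
scatter (e.g. a constant feature) falls back to the Moore–Penrose
pseudo-inverse with a warning rather than failing.

**FDR estimation** uses the plain decoy/target ratio
`FDR(t) = D(t)/T(t)` at each score threshold, monotonized into q-values by
a running minimum from the permissive end. The plain ratio (not `(1+D)/T`,
no π₀ correction) is the most common reading of concatenated target-decoy
filtering; the calibration test quantifies its behaviour — the mean
realized false-discovery proportion at q ≤ 0.01 over 20 simulated runs of
20,000 PSMs sits near 0.010. Tied scores are processed as a block so
results cannot depend on row order. Protein-level collapse scores each
protein by its best PSM and repeats the same counting at the protein level;
best-peptide scoring is the minimal assumption where no aggregation rule is
otherwise specified.

## Parsimony inference

`assemble_parsimony()` reports the smallest set of protein groups that
explains all accepted peptides: indistinguishable accessions (identical
peptide sets) merge; strict-subset accessions are subsumed; proteins that
are the sole owner of some peptide are selected first (they belong to every
cover); the remainder is covered greedily by descending unexplained-peptide
count with lexicographic tie-breaks; and shared peptides are razor-assigned
to the selected group with most total peptides. Greedy set cover is not
guaranteed optimal, so the package ships an exhaustive minimum-cover oracle
(`min_cover_size_exhaustive()`) and the test-suite measures agreement on
200 random instances of up to 10 proteins and 25 peptides: the greedy cover
is never smaller than the optimum and matches it on ≥ 95% of instances
(typically ≈ 100% with the essential-protein step). Razor assignment is a
determinism requirement of downstream quantitation, not a biological claim;
fractional counting is a documented non-goal.

## Reporter quantitation

Reporter channels are matched to observed centroids by
nearest-within-tolerance (default 0.003 Da) against the published TMT
10-plex monoisotopic reporter masses, stored as a versioned constant; one
peak can satisfy at most one channel. The three exclusion rules are applied
with literal boundary semantics: *no MS3 block* excludes; *more than eight
missing channels* excludes 9 or 10 missing (8 missing is kept); *summed S/N
less than 100* excludes strictly below 100 (exactly 100 is kept). Protein
values are sums of channel S/N over assigned PSMs with missing channels
contributing zero — summation admits no imputation, so none is attempted.
This makes total S/N conservation an exact identity (matrix total =
included-PSM S/N total), which the tests assert with `expect_identical`.
Channel totals can optionally be used for total-sum normalization (each
column divided by its total, rescaled to the mean total); whether the
per-channel summation is a report or a normalization is ambiguous in
standard practice, so both behaviours sit behind a flag and the matrix
carries an explicit `normalized` state.

No isotope-impurity correction is applied; correction factors are
lot-specific and none are modelled. This is a documented limitation, not an
option.

## Differential analysis

Fold change is the ratio of arithmetic group means (NFL/CTRL) on the
(optionally normalized) S/N scale; a zero control mean flags the protein
undefined and excludes it from selection. Mann–Whitney p-values are exact
whenever the pooled sample is untied — the exact distribution is what makes
the following structural fact provable — and tie-corrected normal
otherwise. With 4 vs 5 samples the most extreme arrangement has two-sided
p = 2/126 ≈ 0.0159, so Bonferroni over 429 proteins cannot reach 0.05
(floor 6.81): the strict selection (FC > 1.5 or < 0.67 and adjusted
p < 0.05) is empty for any untied data of those dimensions, and the
pipeline reproduces that emptiness by construction rather than by accident.
The relaxed selection (FC > 1.2 or < 0.83, exclusive boundaries as printed)
is a fold-change-only rule; on synthetic matrices with 2-fold spikes and
~10% measurement CV it recovers ≥ 90% of spikes with ≤ 5% false positives.

Clustering is unsupervised average linkage (UPGMA) on 1 − Pearson distance
via `stats::hclust`, applied to a pre-filtered (e.g. relaxed-selected)
protein subset — the package's reading of "semi-supervised" clustering,
whose procedural meaning is otherwise undefined: the supervision enters
only through the subset choice, never the linkage. Zero-variance rows have
undefined correlation and are dropped with a warning.

Marker tallies intersect gene symbols with a bundled brain-cell-type marker
table (microglia, astrocyte, oligodendrocyte, neuron). The top-100 EV
protein list bundled for overlap counting is a synthetic stand-in
(`ev_top100_synthetic.tsv`): it exercises the Venn-counting surface without
shipping a third-party database export.

## Immunoassay calibration and correlation

Standard curves are four-parameter logistic (4PL) — the kit-standard
sigmoid — fitted by least squares with the `SSfpl` self-start on
log-concentration (fallback: Levenberg–Marquardt via minpack.lm). 4PL
rather than 5PL: no asymmetry parameter is identifiable from typical 6–8
point calibrations. Back-calculation inverts the 4PL analytically and
multiplies by the dilution factor (default 4, the matrix-effect dilution
used for EV samples); the round trip is exact to 10⁻⁶ relative error across
the calibrated range. Signals at or beyond the asymptotes are censored, not
extrapolated — an inverted logistic diverges there. Duplicate wells are
averaged per sample before back-calculation.

Correlations are Pearson product-moment with t-distribution p-values,
computed per group where the question is group-specific (EV vs total-CSF
tau) and pooled where it is not (EV t-tau vs EV p-tau181). At cohort sizes
of 10 and 8 a sample correlation is a wide-interval estimate: a population
r of 0.812 at n = 10 yields sample r anywhere in roughly (0.37, 0.95) 95%
of the time (Fisher z). The calibration tests therefore check Fisher-z
interval coverage over 200 replicates rather than demanding significance in
every draw; requiring the positive-r group to reach α = 0.01 in ≥ 90% of
replicates would be analytically impossible at these sizes (exact power
≈ 0.6).

## The synthetic-data generator

`sim_config()` / `simulate_psms()` emulate one TMT 10-plex MS3 run:

* **PSM populations.** 10,000 correct and 10,000 incorrect PSMs per run.
  The seven features are drawn from two multivariate normals with diagonal
  covariance; the incorrect population is shifted down by the configured
  effect sizes (defaults 2, 1.5, 1, 0.3, 0.3, 0.2, 0.5 standardized units,
  ≈ 2.8 SD Mahalanobis separation — strong but imperfect, so the 1% FDR
  threshold is a real cut, not a formality). Correct PSMs carry true
  peptides from the tryptic digest; their length and missed-cleavage
  features come from the digest (the record invariant
  `peptide_length = nchar(peptide)` holds on the emitted table).
* **Decoys.** Half of the incorrect PSMs hit the decoy half of the
  database (`decoy_fraction_of_incorrect = 0.5`), matching a concatenated
  search of equal halves; correct PSMs are never decoys. This is the
  setting under which the decoy count is an unbiased estimate of incorrect
  target matches, and the calibration tests measure exactly that.
* **Reporters.** Per-channel S/N is log-normal (median `snr_scale = 20`,
  `sdlog = 0.5` — positive and right-skewed, as S/N is), with independent
  Bernoulli channel dropout (5% default) and spiked proteins' NFL channels
  multiplied by the true fold change. Ground truth lives in a sidecar table
  keyed by PSM id; the analysis-visible table never carries it (a leakage
  test asserts the column sets are disjoint).
* **Protein matrices.** `simulate_quant_matrix()` generates protein × sample
  tables directly for power studies: log-normal baselines across proteins
  and ~10% per-measurement CV (`sdlog = 0.1`), the coefficient of variation
  protein-level sums inherit after aggregating reporter noise over many
  PSMs.
* **Immunoassay.** `simulate_immunoassay()` draws the four analytes from a
  chained Gaussian construction that hits the configured pairwise
  correlations exactly in population: EV t-tau anchors, EV p-tau181
  correlates with it at 0.87, and the EV-vs-CSF correlations are
  group-specific (defaults 0.812/0.627 in NFL, −0.492/−0.530 in CTRL, at
  n = 10 and 8). Concentration scales (pg/mL) are set so EV t-tau runs well
  below EV p-tau181, the counter-intuitive ordering ultrasensitive assays
  show when tau circulates as N-terminally truncated fragments; values are
  floored at 0.01 pg/mL (truncation is rare at ≥ 2.5 SD from zero, so
  target correlations are not materially distorted).

What the generator does **not** emulate: spectra (no m/z peak lists,
retention time or chromatography), co-isolation interference, isotope
impurity leakage between channels, peptide-level abundance structure
(ionization efficiency, shared-peptide quantitative ambiguity), batch or
plex effects, and assay matrix effects beyond a scalar dilution. Passing
tests therefore demonstrate that the *statistical machinery* is correct and
calibrated under its stated assumptions — not that those assumptions hold
for any particular instrument run.

## Problem sizes and determinism

The test-suite and acceptance script use 20 runs × 20,000 PSMs for FDR
calibration, 200 random instances for the parsimony oracle, 50 runs × 500
proteins for spike recovery, and 200 replicates for correlation coverage —
sizes at which Monte-Carlo error is well inside the asserted bands while a
full run stays in the tens of seconds. Every stochastic step is seeded;
identical configuration gives byte-identical tables, and the acceptance
script derives all of its seeds from its `--seed` argument.
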