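# evtmt

Quantitative proteomics and tau-immunoassay analysis of extracellular
vesicles (EVs) isolated from cerebrospinal fluid (CSF), packaged as a fully
testable pipeline. The scientific setting is biomarker discovery for
repetitive-head-injury tauopathy: EVs are isolated from the CSF of a small
exposed cohort ("NFL") and age-matched controls ("CTRL"), their protein
cargo is quantified by TMT 10-plex isobaric labeling with MS3 reporter-ion
readout, and total tau (t-tau) and tau phosphorylated at threonine 181
(p-tau181) are measured in the same samples by ultrasensitive immunoassay.

The package implements every computational stage of that study design and a
synthetic-data module that generates all inputs with known ground truth, so
each stage is verifiable end to end without access to raw instrument data.

## What the pipeline computes

**Identification.** Candidate peptide-spectrum matches (PSMs) searched
against a target database concatenated with whole-sequence reversed decoys
are screened at a 50 ppm precursor tolerance, then rescored with a
two-class linear discriminant over seven features (XCorr, ΔCn, precursor
mass accuracy in ppm, charge state, in-solution charge, peptide length,
missed cleavages):

    w = S⁻¹ (μ_target − μ_decoy),   score(x) = wᵀx − wᵀ(μ_target + μ_decoy)/2

with S the pooled within-class covariance. The false-discovery rate at a
score threshold t is estimated by decoy counting, FDR(t) = D(t)/T(t), and
monotonized into q-values; PSMs are accepted at q ≤ 0.01 and proteins
(scored by their best PSM) are collapsed at a further 1% protein-level FDR.

**Inference and quantitation.** Accepted peptides are assembled into the
smallest set of protein groups explaining them all (indistinguishable-set
merging, subset subsumption, essential-protein selection, greedy cover,
razor assignment of shared peptides). Each group is quantified by summing
reporter-channel signal-to-noise over its PSMs, after excluding PSMs with no
MS3 block, more than eight missing channels, or summed S/N below 100.

**Statistics.** Group comparisons use the exact two-sided Mann-Whitney U
test with Bonferroni adjustment; selection applies fold-change thresholds
(strict: FC > 1.5 or < 0.67 with adjusted p < 0.05; relaxed: FC > 1.2 or
< 0.83); heatmaps are ordered by average-linkage clustering on
1 − Pearson-correlation distance. Immunoassay signals are calibrated with a
four-parameter logistic curve, back-calculated with the 4× dilution
correction, and related across fluids by Pearson correlation per group.

A structural consequence worth knowing: with 4 vs 5 samples the smallest
achievable exact Mann-Whitney p is 2/126 ≈ 0.0159, so Bonferroni over 429
proteins has an adjusted-p floor of 6.81 — the strict selection is provably
empty at these dimensions, whatever the data.

## Worked example

The `analysis/` directory holds the numbered workflow drivers; run them in
order from the repository root:

```sh
Rscript analysis/01_simulate_inputs.R
Rscript analysis/02_filter_psms.R
```

Stage 1 simulates one TMT 10-plex run (300 proteins, 20,000 candidate PSMs,
three proteins spiked at 2-fold in the NFL channels) plus an 18-participant
immunoassay cohort, writing analysis-visible tables and a ground-truth
sidecar under `results/sim/`. Stage 2 prints:

```
accepted PSMs at 1% FDR: 9061
retained proteins at 1% protein FDR: 300
realized FDP among accepted PSMs (vs hidden truth): 0.0127
```

i.e. at the 1% decoy-estimated threshold the realized false-discovery
proportion, judged against the hidden truth labels, is 1.3%. Stage 3
quantifies (`conservation check: matrix total - included S/N total = 0`),
stage 4 runs the group comparison:

```
strict selection (FC>1.5 or <0.67, adj p<0.05): 0 proteins
relaxed selection (FC>1.2 or <0.83): 11 proteins
spiked proteins recovered by relaxed selection: 3 of 3
```

— the strict criterion returns nothing (the analytic floor above) while the
fold-change-only criterion recovers all three spiked proteins — and stage 5
calibrates the 4PL curve and reports the tau correlations, e.g. a pooled
EV t-tau vs EV p-tau181 correlation of r = 0.833 (n = 18) in this cohort
draw.

In code, the same identification stage is three calls:

```r
library(evtmt)
cfg <- sim_config(seed = 1)
sim <- simulate_psms(generate_protein_db(cfg), cfg)
res <- run_psm_pipeline(sim$psms, psm_q = 0.01, protein_q = 0.01)
nrow(res$accepted)            # 8666 PSMs at 1% FDR
length(res$proteins$retained) # 300 proteins at 1% protein FDR
```

## Documentation

The methods vignette (`vignettes/ev-tmt-pipeline.Rmd`) describes the models,
the synthetic-data generator and its defaults, numerical choices, and known
limitations. Every exported function carries roxygen documentation.
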