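#!/usr/bin/env Rscript
# Stage 1 — generate every input the pipeline consumes, with ground truth.
#
# Emulates one TMT 10-plex MS3 run over a CSF-EV-sized protein database
# (300 proteins, 20,000 candidate PSMs, 5 NFL vs 5 CTRL channels, 3 spiked
# proteins at 2-fold) plus the paired immunoassay cohort (10 NFL / 8 CTRL).
# Ground truth goes to a sidecar file the analysis stages never read.

suppressMessages(library(evtmt))
outdir <- "results/sim"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 20260101L, n_spiked = 3L, spike_fold_change = 2)
db <- generate_protein_db(cfg)
write_fasta_db(db, file.path(outdir, "targets.fasta"))
write_fasta_db(build_decoy_db(db), file.path(outdir, "targets_plus_decoys.fasta"))

sim <- simulate_psms(db, cfg)
write_pipeline_tsv(sim$psms, file.path(outdir, "psms.tsv"))
write_pipeline_tsv(sim$truth, file.path(outdir, "psm_truth_sidecar.tsv"))
write_pipeline_tsv(sim$design, file.path(outdir, "design.tsv"))
write_pipeline_tsv(sim$spiked, file.path(outdir, "spiked_truth_sidecar.tsv"))

imm <- simulate_immunoassay(immuno_sim_config(seed = 20260102L))
write_pipeline_tsv(imm, file.path(outdir, "immunoassay.tsv"))

cat(sprintf("proteins: %d (x2 with decoys)\n", nrow(db)))
cat(sprintf("candidate PSMs: %d (%d decoy-labelled)\n",
            nrow(sim$psms), sum(sim$psms$is_decoy)))
cat(sprintf("spiked proteins: %s at fold-change %g\n",
            paste(sim$spiked$accession, collapse = ", "),
            cfg$spike_fold_change))
cat(sprintf("immunoassay records: %d (%d NFL / %d CTRL)\n", nrow(imm),
            sum(imm$group == "NFL"), sum(imm$group == "CTRL")))
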