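#!/usr/bin/env Rscript
# Stage 3 — reporter-ion quantitation.
#
# Applies the three exclusion rules (no MS3 block, >8 missing channels,
# summed S/N < 100), assembles parsimonious protein groups from the accepted
# peptides, sums each group's reporter S/N per channel, and reports channel
# totals plus the total-sum-normalized matrix.

suppressMessages(library(evtmt))
acc <- read_pipeline_tsv("results/accepted_psms.tsv")
design <- read_pipeline_tsv("results/sim/design.tsv")

acc <- apply_quant_filter(acc)
cat("quantification filter:\n")
print(table(acc$quant_reason))

pep_map <- lapply(split(acc$accessions, acc$peptide),
                  function(a) sort(unique(a)))
inf <- assemble_parsimony(pep_map)
cat(sprintf("unique protein groups (parsimony): %d (%d accessions subsumed)\n",
            count_unique_proteins(inf), length(inf$subsumed_accessions)))

qm <- quantify_proteins(acc, inf, design)
ct <- channel_totals(qm, normalize = TRUE)
write_pipeline_tsv(qm, "results/quant_matrix_raw.tsv")
write_pipeline_tsv(ct$matrix, "results/quant_matrix_normalized.tsv")
cat("per-sample summed S/N totals:\n")
print(round(ct$totals))

snr_cols <- paste0("snr_", TMT10_CHANNELS)
included <- sum(as.matrix(acc[acc$quant_keep, snr_cols]), na.rm = TRUE)
cat(sprintf("conservation check: matrix total - included S/N total = %g\n",
            sum(qm) - included))
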