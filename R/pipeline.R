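#' Run the PSM-level identification pipeline
#'
#' Convenience wrapper chaining the mass-tolerance screen, the linear
#' discriminant fit, PSM-level FDR filtering and the protein-level FDR
#' collapse at the published 1%/1% thresholds.
#'
#' @param psms raw PSM table (e.g. `simulate_psms()$psms`).
#' @param psm_q PSM-level q-value threshold (default 0.01).
#' @param protein_q protein-level q-value threshold (default 0.01).
#' @param precursor_tol_ppm precursor screen tolerance (ppm).
#' @return list: `accepted` (accepted target PSMs with `lda_score`,
#'   `q_value`), `curve` (PSM-level `fdr_curve`), `lda` (the `lda_fit`),
#'   `proteins` (result of [protein_level_fdr()]), `accepted_protein_psms`
#'   (accepted PSMs restricted to retained proteins).
#' @export
run_psm_pipeline <- function(psms, psm_q = 0.01, protein_q = 0.01,
                             precursor_tol_ppm = 50) {
  screened <- mass_tolerance_screen(psms, precursor_tol_ppm)
  lda <- fit_lda(screened)
  curve <- estimate_fdr(lda$psms)
  accepted <- filter_psm_fdr(lda$psms, q_max = psm_q, curve = curve)
  prot <- protein_level_fdr(accepted, q_max = protein_q)
  keep <- vapply(strsplit(accepted$accessions, ";", fixed = TRUE),
                 function(a) any(a %in% prot$retained), logical(1))
  list(accepted = accepted, curve = curve, lda = lda, proteins = prot,
       accepted_protein_psms = accepted[keep, , drop = FALSE])
}

#' Write / read the pipeline's tab-delimited tables
#'
#' All pipeline tables (PSM tables, truth sidecars, designs, quantitation
#' matrices, DE tables, immunoassay records) are plain TSV with a header
#' row.
#'
#' @param x data.frame (or `quant_matrix`; written with a leading `protein`
#'   column).
#' @param path file path.
#' @return `read_pipeline_tsv` returns a data.frame; writers return `path`
#'   invisibly.
#' @export
write_pipeline_tsv <- function(x, path) {
  if (inherits(x, "quant_matrix")) {
    x <- data.frame(protein = rownames(x), as.data.frame(unclass(x)),
                    check.names = FALSE)
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pipeline_tsv
#' @export
read_pipeline_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
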