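#' Per-protein NFL/CTRL fold change
#'
#' Ratio of arithmetic group means. A zero CTRL mean yields `NA` with the
#' protein listed in the `undefined_fc` attribute; such proteins are never
#' selected downstream.
#'
#' @param m a [quant_matrix()].
#' @param design a [study_design()] whose `sample` ids match `colnames(m)`.
#' @return named numeric vector of fold changes (NFL mean / CTRL mean).
#' @export
fold_change <- function(m, design) {
  stopifnot(all(colnames(m) %in% design$sample))
  grp <- design$group[match(colnames(m), design$sample)]
  if (!all(c("NFL", "CTRL") %in% grp)) stop("both groups must be present")
  mu_n <- rowMeans(m[, grp == "NFL", drop = FALSE])
  mu_c <- rowMeans(m[, grp == "CTRL", drop = FALSE])
  fc <- ifelse(mu_c == 0, NA_real_, mu_n / mu_c)
  names(fc) <- rownames(m)
  attr(fc, "undefined_fc") <- rownames(m)[mu_c == 0]
  fc
}

#' Two-sided Mann-Whitney U test
#'
#' Exact-distribution p-value whenever the pooled sample is untied,
#' tie-corrected normal approximation (without continuity correction) in the
#' presence of ties. The U statistic counts (x > y) pairs plus half-ties.
#'
#' @param x,y numeric vectors, each with at least 1 value.
#' @return list: `U`, `p_value`, `method`.
#' @export
mann_whitney_test <- function(x, y) {
  if (length(x) < 1L || length(y) < 1L) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties
  if (all(x == x[1]) && all(y == y[1]) && x[1] == y[1]) {
    # fully degenerate: identical constant samples
    return(list(U = length(x) * length(y) / 2, p_value = 1, method = "exact"))
  }
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = FALSE, alternative = "two.sided"))
  list(U = unname(wt$statistic), p_value = min(1, wt$p.value),
       method = if (exact) "exact" else "normal_tie_corrected")
}

#' Differential-expression table
#'
#' Per-protein fold change (NFL/CTRL ratio of group means), two-sided
#' Mann-Whitney p-value, and Bonferroni adjustment over the number of tested
#' proteins.
#'
#' @param m a [quant_matrix()].
#' @param design a [study_design()].
#' @return data.frame: `protein`, `fold_change`, `p_raw`, `p_adj`,
#'   `selected_strict` (FC > 1.5 or < 0.67 AND adjusted p < 0.05),
#'   `selected_relaxed` (FC > 1.2 or < 0.83).
#' @export
de_table <- function(m, design) {
  grp <- design$group[match(colnames(m), design$sample)]
  fc <- fold_change(m, design)
  p <- vapply(seq_len(nrow(m)), function(i) {
    mann_whitney_test(m[i, grp == "NFL"], m[i, grp == "CTRL"])$p_value
  }, numeric(1))
  p_adj <- pmin(1, p * nrow(m))  # Bonferroni over tested proteins
  res <- data.frame(protein = rownames(m), fold_change = as.numeric(fc),
                    p_raw = p, p_adj = p_adj, stringsAsFactors = FALSE)
  res$selected_strict <- !is.na(res$fold_change) &
    (res$fold_change > 1.5 | res$fold_change < 0.67) & res$p_adj < 0.05
  res$selected_relaxed <- !is.na(res$fold_change) &
    (res$fold_change > 1.2 | res$fold_change < 0.83)
  res
}

#' Select differentially expressed proteins
#'
#' `strict` requires fold change > 1.5 or < 0.67 *and* Bonferroni-adjusted
#' p < 0.05; `relaxed` applies only the fold-change bounds > 1.2 or < 0.83.
#' All boundaries are exclusive.
#'
#' @param results a [de_table()] data.frame.
#' @param mode `"strict"` or `"relaxed"`.
#' @return character vector of selected protein ids.
#' @export
select_de <- function(results, mode = c("strict", "relaxed")) {
  mode <- match.arg(mode)
  col <- paste0("selected_", mode)
  results$protein[results[[col]]]
}

#' Hierarchical clustering with Pearson distance and average linkage
#'
#' Distance `1 - Pearson correlation` between rows (and between columns),
#' average-linkage (UPGMA) agglomeration. Zero-variance rows are dropped
#' with a warning (correlation undefined).
#'
#' @param m a [quant_matrix()] with at least 2 rows.
#' @param cluster_columns also cluster samples (default TRUE).
#' @return list: `row_hclust`, `col_hclust` (or NULL), `row_order`,
#'   `col_order` (leaf orders as labels), `dropped` (zero-variance rows).
#' @export
hierarchical_cluster <- function(m, cluster_columns = TRUE) {
  stopifnot(nrow(m) >= 2L)
  v <- apply(m, 1L, sd)
  dropped <- rownames(m)[v == 0]
  if (length(dropped)) {
    warning("dropping zero-variance row(s): ",
            paste(head(dropped, 5), collapse = ", "))
    m <- m[v > 0, , drop = FALSE]
  }
  if (nrow(m) < 2L) stop("fewer than 2 rows with positive variance")
  dr <- as.dist(1 - cor(t(unclass(m))))
  hr <- hclust(dr, method = "average")
  hc <- NULL
  if (cluster_columns) {
    dc <- as.dist(1 - cor(unclass(m)))
    hc <- hclust(dc, method = "average")
  }
  list(row_hclust = hr, col_hclust = hc,
       row_order = hr$labels[hr$order],
       col_order = if (is.null(hc)) colnames(m) else hc$labels[hc$order],
       dropped = dropped)
}

#' Export a dendrogram as Newick text
#'
#' @param h an `hclust` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(h, path) {
  ape::write.tree(ape::as.phylo(h), file = path)
  invisible(path)
}

#' Tally brain-cell-type markers in a protein list
#'
#' Intersects gene symbols with a marker table (cell type per gene: microglia,
#' astrocyte, oligodendrocyte, neuron). Proteins absent from the table are
#' ignored.
#'
#' @param proteins character vector of gene symbols.
#' @param marker_table data.frame with columns `gene` and `cell_type`;
#'   default is the bundled table.
#' @return list: `counts` (named integer per cell type), `members` (list of
#'   matched genes per cell type).
#' @export
marker_tally <- function(proteins, marker_table = load_marker_table()) {
  types <- sort(unique(marker_table$cell_type))
  members <- lapply(setNames(types, types), function(ct) {
    sort(intersect(proteins, marker_table$gene[marker_table$cell_type == ct]))
  })
  list(counts = vapply(members, length, integer(1)), members = members)
}

#' Bundled brain-cell-type marker table
#'
#' Marker genes for microglia, astrocytes, oligodendrocytes and neurons
#' (derived from brain cell-type expression data) shipped under
#' `inst/extdata/brain_cell_markers.tsv`.
#'
#' @return data.frame with columns `gene`, `cell_type`.
#' @export
load_marker_table <- function() {
  path <- system.file("extdata", "brain_cell_markers.tsv", package = "evtmt")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Bundled synthetic stand-in for a top-100 EV protein list
#'
#' A synthetic list of 100 gene symbols playing the role of a
#' database-derived top-100 extracellular-vesicle protein table for overlap
#' counting (`inst/extdata/ev_top100_synthetic.tsv`). Synthetic: it is not
#' the real database export.
#'
#' @return character vector of 100 gene symbols.
#' @export
load_ev_top100_synthetic <- function() {
  path <- system.file("extdata", "ev_top100_synthetic.tsv", package = "evtmt")
  utils::read.delim(path, stringsAsFactors = FALSE)$gene
}

#' Two-set Venn partition counts
#'
#' @param set_a,set_b character vectors (duplicates ignored).
#' @return named integer vector `c(only_a, shared, only_b)`.
#' @export
venn_overlap <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  c(only_a = length(setdiff(a, b)),
    shared = length(intersect(a, b)),
    only_b = length(setdiff(b, a)))
}
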