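make_design_4v5 <- function() {
  study_design(rep(c("NFL", "CTRL"), c(4, 5)))
}

test_that("fold change is the NFL/CTRL ratio of arithmetic group means", {
  design <- make_design_4v5()
  m <- quant_matrix(matrix(c(rep(2, 4), rep(1, 5),
                             rep(3, 4), rep(3, 5)), nrow = 2, byrow = TRUE,
                           dimnames = list(c("up", "flat"), design$sample)))
  fc <- fold_change(m, design)
  expect_equal(unname(fc["up"]), 2)
  expect_equal(unname(fc["flat"]), 1)
  # label swap inverts the ratio
  swapped <- design
  swapped$group <- ifelse(design$group == "NFL", "CTRL", "NFL")
  expect_equal(unname(fold_change(m, swapped)["up"]), 0.5)
  # zero CTRL mean is flagged undefined
  m0 <- quant_matrix(matrix(c(rep(2, 4), rep(0, 5)), nrow = 1,
                            dimnames = list("z", design$sample)))
  expect_true(is.na(fold_change(m0, design)["z"]))
  expect_equal(attr(fold_change(m0, design), "undefined_fc"), "z")
})

test_that("Mann-Whitney p-values are exact for small untied samples", {
  expect_equal(mann_whitney_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # complete separation 4 vs 5: two-sided exact p = 2/126
  mt <- mann_whitney_test(c(10, 11, 12, 13), c(1, 2, 3, 4, 5))
  expect_equal(mt$p_value, 2 / 126)
  expect_equal(mt$method, "exact")
  expect_error(mann_whitney_test(numeric(0), 1), "non-empty")
})

test_that("Mann-Whitney matches full enumeration on untied instances up to n = 5", {
  set.seed(19)
  for (i in 1:30) {
    m <- sample(2:5, 1); n <- sample(2:5, 1)
    v <- sample(seq_len(50), m + n)  # distinct integers: untied
    x <- v[seq_len(m)]; y <- v[-seq_len(m)]
    expect_equal(mann_whitney_test(x, y)$p_value, mw_enum_oracle(x, y),
                 tolerance = 1e-12)
  }
})

test_that("selection thresholds are exclusive and combine FC with adjusted p", {
  res <- data.frame(protein = c("a", "b", "c", "d", "e"),
                    fold_change = c(1.18, 0.5, 1.2, 1.51, 2.0),
                    p_raw = c(0.001, 0.0001, 0.001, 0.2, 0.001))
  res$p_adj <- pmin(1, res$p_raw * nrow(res))
  res$selected_strict <- (res$fold_change > 1.5 | res$fold_change < 0.67) &
    res$p_adj < 0.05
  res$selected_relaxed <- res$fold_change > 1.2 | res$fold_change < 0.83
  # boundary FC = 1.18 and FC = 1.2 exactly are never selected
  expect_false("a" %in% select_de(res, "strict"))
  expect_false("a" %in% select_de(res, "relaxed"))
  expect_false("c" %in% select_de(res, "relaxed"))
  # strong down-regulation with small adjusted p selected in both modes
  expect_true("b" %in% select_de(res, "strict"))
  expect_true("b" %in% select_de(res, "relaxed"))
  # FC above 1.5 but non-significant: relaxed only
  expect_false("d" %in% select_de(res, "strict"))
  expect_true("d" %in% select_de(res, "relaxed"))
})

test_that("de_table applies Bonferroni over tested proteins", {
  sim <- simulate_quant_matrix(n_proteins = 30, n_spiked = 0, seed = 3)
  res <- de_table(sim$matrix, sim$design)
  expect_equal(res$p_adj, pmin(1, res$p_raw * nrow(res)))
  expect_true(all(res$p_adj >= res$p_raw))
})

test_that("4 vs 5 with Bonferroni over 429 tests can never reach strict significance", {
  # minimum achievable exact two-sided p is 2/126; adjusted it is 429*2/126 > 1
  expect_gt(429 * 2 / 126, 0.05)
  sim <- simulate_quant_matrix(n_proteins = 429, n_spiked = 40,
                               fold_change = 3, n_nfl = 4, n_ctrl = 5,
                               seed = 23)
  res <- de_table(sim$matrix, sim$design)
  expect_gte(min(res$p_raw), 2 / 126 - 1e-12)
  expect_equal(min(res$p_adj), 1)  # Bonferroni caps at 1; 429 * 2/126 > 1
  expect_length(select_de(res, "strict"), 0L)
  # the fold-change-only relaxed mode still sees the spikes
  expect_gt(length(select_de(res, "relaxed")), 0L)
})

test_that("clustering uses 1 - Pearson distance with average linkage", {
  design <- make_design_4v5()
  base <- c(1, 5, 2, 8, 3, 9, 4, 7, 6)
  m <- quant_matrix(rbind(r1 = base, r2 = base, r3 = 10 - base,
                          r4 = base * 2 + rnorm(9, sd = 0.01)))
  colnames(m) <- design$sample
  cl <- hierarchical_cluster(m)
  hm <- cl$row_hclust$merge
  # identical rows merge at distance 0; a row and its negation at distance 2
  expect_equal(min(cl$row_hclust$height), 0, tolerance = 1e-12)
  expect_equal(max(cl$row_hclust$height), 2, tolerance = 0.01)
  # zero-variance rows are dropped with a warning
  mz <- quant_matrix(rbind(m, rz = rep(1, 9)))
  colnames(mz) <- design$sample
  expect_warning(cz <- hierarchical_cluster(mz), "zero-variance")
  expect_equal(cz$dropped, "rz")
  # Newick export round-trips through ape
  f <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(cl$row_hclust, f)
  expect_setequal(ape::read.tree(f)$tip.label, rownames(m))
})

test_that("average-linkage heights match a brute-force UPGMA oracle", {
  set.seed(29)
  for (i in 1:10) {
    m <- matrix(rnorm(6 * 8), nrow = 6,
                dimnames = list(paste0("r", 1:6), paste0("s", 1:8)))
    d <- as.dist(1 - cor(t(m)))
    h <- hierarchical_cluster(quant_matrix(abs(m)))  # values must be >= 0
    d2 <- as.dist(1 - cor(t(abs(m))))
    expect_equal(sort(hierarchical_cluster(quant_matrix(abs(m)))$row_hclust$height),
                 upgma_heights_oracle(d2), tolerance = 1e-10)
  }
})

test_that("marker tally counts cell-type members via set intersection", {
  tally <- marker_tally(c("S100A9", "MFGE8", "GSN", "CRABP1", "NOTINTABLE"))
  expect_gte(tally$counts[["microglia"]], 1L)
  expect_gte(tally$counts[["astrocyte"]], 1L)
  expect_equal(tally$members$microglia, "S100A9")
  expect_equal(sum(marker_tally(character(0))$counts), 0L)
  # recount oracle
  tab <- load_marker_table()
  input <- sample(c(tab$gene, paste0("X", 1:50)), 40)
  t2 <- marker_tally(input)
  for (ct in names(t2$counts)) {
    expect_equal(t2$counts[[ct]],
                 length(intersect(unique(input),
                                  tab$gene[tab$cell_type == ct])))
  }
})

test_that("venn overlap partitions two sets", {
  expect_equal(venn_overlap(letters[1:3], letters[4:7]),
               c(only_a = 3L, shared = 0L, only_b = 4L))
  expect_equal(venn_overlap(letters[1:5], letters[1:5]),
               c(only_a = 0L, shared = 5L, only_b = 0L))
  a <- sample(letters, 10); b <- sample(letters, 12)
  v <- venn_overlap(a, b)
  expect_equal(sum(v), length(union(a, b)))
})
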