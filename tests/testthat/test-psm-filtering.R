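test_that("precursor mass screen applies the 50 ppm window symmetrically", {
  p <- toy_psm_table(scores = rep(1, 6), is_decoy = rep(FALSE, 6),
                     mass_error = c(49.9, 50.1, -49.9, -50.1, 0, 50))
  kept <- mass_tolerance_screen(p)
  expect_setequal(kept$mass_error_ppm, c(49.9, -49.9, 0, 50))
  expect_identical(mass_tolerance_screen(p, 1000)$psm_id, p$psm_id)
  expect_equal(attr(kept, "product_tol_da"), 0.9)
})

test_that("discriminant reduces to the single informative feature", {
  set.seed(1)
  n <- 400
  psms <- data.frame(is_decoy = rep(c(FALSE, TRUE), each = n / 2),
                     xcorr = c(rnorm(n / 2, 3), rnorm(n / 2, 1)),
                     delta_cn = 0.3, mass_error_ppm = 1, charge_state = 2,
                     in_solution_charge = 2, peptide_length = 12,
                     missed_cleavages = 0)
  fit <- suppressWarnings(fit_lda(psms))
  expect_equal(order(fit$psms$lda_score), order(psms$xcorr))
})

test_that("label swap negates scores up to the orientation fix", {
  set.seed(2)
  n <- 200
  psms <- data.frame(is_decoy = rep(c(FALSE, TRUE), each = n / 2))
  for (f in evtmt:::PSM_FEATURES) {
    psms[[f]] <- rnorm(n, mean = ifelse(psms$is_decoy, 0, 1))
  }
  f1 <- fit_lda(psms)
  swapped <- psms; swapped$is_decoy <- !psms$is_decoy
  f2 <- fit_lda(swapped)
  # orientation guard re-points the swapped fit at its "targets" (the decoys),
  # so the two score vectors are exact negatives
  expect_equal(f2$psms$lda_score, -f1$psms$lda_score, tolerance = 1e-9)
})

test_that("discriminant separates two-Gaussian populations and matches MASS::lda direction", {
  skip_if_not_installed("MASS")
  set.seed(3)
  n <- 2000
  psms <- data.frame(is_decoy = rep(c(FALSE, TRUE), each = n / 2))
  eff <- c(2, 2, 2, 0, 0, 0, 0)
  for (i in seq_along(evtmt:::PSM_FEATURES)) {
    f <- evtmt:::PSM_FEATURES[i]
    psms[[f]] <- rnorm(n, mean = ifelse(psms$is_decoy, 0, eff[i]))
  }
  fit <- fit_lda(psms)
  sc <- fit$psms$lda_score
  pooled_sd <- sqrt(((n / 2 - 1) * var(sc[!psms$is_decoy]) +
                     (n / 2 - 1) * var(sc[psms$is_decoy])) / (n - 2))
  expect_gt(mean(sc[!psms$is_decoy]) - mean(sc[psms$is_decoy]), pooled_sd)
  # independent oracle: MASS::lda scaling is proportional to our weights
  ml <- MASS::lda(psms[, evtmt:::PSM_FEATURES], grouping = psms$is_decoy)
  ratio <- fit$weights / ml$scaling[, 1]
  ratio <- ratio[abs(ml$scaling[, 1]) > 1e-8]
  expect_lt(diff(range(ratio)) / abs(mean(ratio)), 1e-6)
  expect_error(fit_lda(psms[c(1, 2, n), ]), "at least 2")
})

test_that("FDR estimate and q-values match the forced ratio and the recount oracle", {
  # 198 targets above 2 decoys: estimate at the permissive end is 2/198
  p <- toy_psm_table(scores = c(seq(3, 4, length.out = 198), 1, 2),
                     is_decoy = rep(c(FALSE, TRUE), c(198, 2)))
  cv <- estimate_fdr(p)
  expect_equal(cv$fdr[cv$score == 1], 2 / 198)
  # zero decoys anywhere -> q identically 0
  p0 <- toy_psm_table(scores = rnorm(50), is_decoy = rep(FALSE, 50))
  expect_true(all(estimate_fdr(p0)$q_value == 0))
  expect_error(estimate_fdr(toy_psm_table(1, TRUE)), "no target")
  # brute-force recount on random 50-PSM instances, including tied scores
  set.seed(8)
  for (i in 1:10) {
    sc <- sample(round(rnorm(50), 1))  # rounding forces ties
    dec <- runif(50) < 0.4
    if (!any(!dec)) dec[1] <- FALSE
    cv <- estimate_fdr(data.frame(lda_score = sc, is_decoy = dec))
    or <- fdr_recount_oracle(sc, dec)
    expect_equal(cv$score, or$score)
    expect_equal(cv$fdr, or$fdr)
    expect_equal(cv$q_value, or$q_value)
    expect_true(all(diff(cv$q_value) >= -1e-12))  # monotone in threshold order
  }
})

test_that("PSM acceptance respects q thresholds and tie blocks", {
  p <- toy_psm_table(scores = c(5, 4, 4, 3), is_decoy = c(FALSE, TRUE, FALSE, FALSE))
  expect_setequal(filter_psm_fdr(p, q_max = 1)$psm_id,
                  p$psm_id[!p$is_decoy])
  # top score is a decoy: q_max = 0 empties the set
  p2 <- toy_psm_table(scores = c(9, 5, 4), is_decoy = c(TRUE, FALSE, FALSE))
  expect_equal(nrow(filter_psm_fdr(p2, q_max = 0)), 0L)
  # tied targets and decoy at the same score are accepted/rejected as a block
  q <- filter_psm_fdr(p, q_max = 0.5)
  expect_true(all(c("T002", "T003") %in% p$psm_id))
  tied_q <- estimate_fdr(p)$q_value[estimate_fdr(p)$score == 4]
  expect_length(tied_q, 1L)
})

test_that("empirical FDP among accepted PSMs is calibrated at 1% FDR", {
  cfg <- sim_config(seed = 13)
  sim <- simulate_psms(generate_protein_db(cfg), cfg)
  res <- run_psm_pipeline(sim$psms)
  truth <- setNames(sim$truth$is_correct, sim$truth$psm_id)
  fdp <- mean(!truth[res$accepted$psm_id])
  expect_gte(fdp, 0.002)
  expect_lte(fdp, 0.02)
})

test_that("the combined discriminant accepts at least as many true PSMs as XCorr alone", {
  cfg <- sim_config(seed = 17)
  sim <- simulate_psms(generate_protein_db(cfg), cfg)
  screened <- mass_tolerance_screen(sim$psms)
  lda <- fit_lda(screened)
  truth <- setNames(sim$truth$is_correct, sim$truth$psm_id)
  acc_lda <- filter_psm_fdr(lda$psms, 0.01, score_field = "lda_score")
  screened$xcorr_score <- screened$xcorr
  acc_x <- filter_psm_fdr(screened, 0.01, score_field = "xcorr_score")
  expect_gte(sum(truth[acc_lda$psm_id]), sum(truth[acc_x$psm_id]))
})

test_that("protein-level collapse ranks by best peptide and is monotone in q", {
  # one decoy protein outscoring 50 targets: everything at/below it has
  # fdr >= 1/50 > 0.01, so only proteins above the decoy could survive
  p <- toy_psm_table(scores = c(100, seq_len(50)),
                     is_decoy = c(TRUE, rep(FALSE, 50)))
  out <- protein_level_fdr(p, q_max = 0.01)
  expect_length(out$retained, 0L)
  # all-target input is fully retained
  pt <- toy_psm_table(scores = seq_len(20), is_decoy = rep(FALSE, 20))
  expect_length(protein_level_fdr(pt, 0.01)$retained, 20L)
  # retained set grows with q_max
  set.seed(4)
  pr <- toy_psm_table(scores = rnorm(200),
                      is_decoy = runif(200) < 0.3)
  r1 <- protein_level_fdr(pr, 0.01)$retained
  r2 <- protein_level_fdr(pr, 0.05)$retained
  r3 <- protein_level_fdr(pr, 0.5)$retained
  expect_true(all(r1 %in% r2) && all(r2 %in% r3))
})
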