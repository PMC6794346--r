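#' TMT 10-plex channel labels
#' @export
TMT10_CHANNELS <- c("126", "127N", "127C", "128N", "128C",
                    "129N", "129C", "130N", "130C", "131")

# Names of the seven discriminant features carried by every PSM record.
PSM_FEATURES <- c("xcorr", "delta_cn", "mass_error_ppm", "charge_state",
                  "in_solution_charge", "peptide_length", "missed_cleavages")

# Marginal location/scale used to turn standardized draws into
# plausible search-engine feature values. Correct population sits at
# `mean`; the incorrect population is shifted down by effect * sd.
PSM_FEATURE_BASE <- data.frame(
  feature = PSM_FEATURES,
  mean = c(2.5, 0.35, 0, 2.5, 2.5, 14, 0.4),
  sd   = c(0.6, 0.12, 6, 0.7, 0.7, 5, 0.6),
  stringsAsFactors = FALSE
)

#' Simulation configuration for the proteomics pipeline
#'
#' Bundles every knob of the synthetic PSM generator. Defaults emulate a
#' single TMT 10-plex MS3 run over a CSF-EV-sized protein database with a
#' mixed population of correct and incorrect peptide-spectrum matches that a
#' linear discriminant can separate.
#'
#' @param seed integer seed; identical seed + config gives byte-identical
#'   tables.
#' @param n_proteins number of target proteins in the synthetic database.
#' @param n_correct_psms,n_incorrect_psms sizes of the correct / incorrect
#'   PSM populations.
#' @param decoy_fraction_of_incorrect probability that an incorrect PSM hits
#'   the decoy half of the concatenated database; correct PSMs are never
#'   decoys.
#' @param feature_effect_sizes named numeric vector of length 7: standardized
#'   downward location shifts of the incorrect population, one per
#'   discriminant feature.
#' @param group_assignment character vector of length 10 mapping each TMT
#'   channel to `"NFL"` or `"CTRL"`.
#' @param n_spiked number of proteins spiked with a group effect.
#' @param spike_fold_change true NFL/CTRL fold change of spiked proteins.
#' @param missing_channel_rate independent Bernoulli missingness probability
#'   per reporter channel.
#' @param snr_scale median per-channel reporter S/N (log-normal scale
#'   parameter).
#' @param snr_sdlog log-normal sdlog of per-channel reporter noise.
#' @return list with class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_proteins = 300L,
                       n_correct_psms = 10000L,
                       n_incorrect_psms = 10000L,
                       decoy_fraction_of_incorrect = 0.5,
                       feature_effect_sizes = c(
                         xcorr = 2, delta_cn = 1.5, mass_error_ppm = 1,
                         charge_state = 0.3, in_solution_charge = 0.3,
                         peptide_length = 0.2, missed_cleavages = 0.5),
                       group_assignment = rep(c("NFL", "CTRL"), each = 5),
                       n_spiked = 0L,
                       spike_fold_change = 2,
                       missing_channel_rate = 0.05,
                       snr_scale = 20,
                       snr_sdlog = 0.5) {
  stopifnot(n_proteins >= 1, n_correct_psms >= 0, n_incorrect_psms >= 0,
            decoy_fraction_of_incorrect >= 0,
            decoy_fraction_of_incorrect <= 1,
            length(group_assignment) == 10L,
            all(group_assignment %in% c("NFL", "CTRL")),
            missing_channel_rate >= 0, missing_channel_rate < 1,
            snr_scale > 0)
  if (length(feature_effect_sizes) != 7L) {
    stop("feature_effect_sizes must have length 7 (one per discriminant feature)")
  }
  names(feature_effect_sizes) <- PSM_FEATURES
  cfg <- list(seed = as.integer(seed), n_proteins = as.integer(n_proteins),
              n_correct_psms = as.integer(n_correct_psms),
              n_incorrect_psms = as.integer(n_incorrect_psms),
              decoy_fraction_of_incorrect = decoy_fraction_of_incorrect,
              feature_effect_sizes = feature_effect_sizes,
              group_assignment = group_assignment,
              n_spiked = as.integer(n_spiked),
              spike_fold_change = spike_fold_change,
              missing_channel_rate = missing_channel_rate,
              snr_scale = snr_scale, snr_sdlog = snr_sdlog)
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a synthetic target protein database
#'
#' Draws `n_proteins` random sequences over the 20 canonical amino acids
#' (lengths 150-600, K/R enriched so tryptic digestion yields realistic
#' peptide numbers), with unique accessions `SYNP0001`, ...
#'
#' @param config a [sim_config()].
#' @return a `protein_db` of target entries.
#' @export
generate_protein_db <- function(config) {
  if (config$n_proteins < 1) stop("n_proteins must be >= 1")
  set.seed(config$seed)
  n <- config$n_proteins
  # K+R at ~11% so average fully-tryptic peptide length is ~9 residues
  w <- rep(1, 20)
  names(w) <- AA_CANONICAL
  w[c("K", "R")] <- 2.2
  w <- w / sum(w)
  lens <- sample(150:600, n, replace = TRUE)
  seqs <- vapply(lens, function(L) {
    paste(sample(AA_CANONICAL, L, replace = TRUE, prob = w), collapse = "")
  }, character(1))
  protein_db(sprintf("SYNP%04d", seq_len(n)), seqs)
}

#' Simulate a table of candidate peptide-spectrum matches
#'
#' Generates `n_correct_psms` correct and `n_incorrect_psms` incorrect PSMs.
#' The seven discriminant features are drawn from two multivariate normal
#' distributions with diagonal covariance, separated by
#' `feature_effect_sizes` (standardized units); correct PSMs map to true
#' peptides from the tryptic digest of `db`, incorrect PSMs split
#' decoy/target by `decoy_fraction_of_incorrect`. Every PSM carries a
#' 10-channel reporter block with log-normal multiplicative noise,
#' independent Bernoulli channel masking, and — for PSMs of spiked proteins —
#' NFL channels scaled by the true fold change.
#'
#' Ground truth (correctness, true protein) is returned as a separate
#' `truth` table keyed by `psm_id`, keeping the analysis-visible table blind.
#'
#' @param db a target `protein_db` (non-empty).
#' @param config a [sim_config()].
#' @param decoy_prefix decoy accession prefix.
#' @return list with elements `psms` (analysis-visible data.frame: ids,
#'   peptide, accessions, decoy flag, the seven features, reporter columns
#'   `snr_<channel>`), `truth` (psm_id, is_correct, true_accession),
#'   `spiked` (data.frame accession, fold_change), and `design` (a
#'   [study_design()]).
#' @export
simulate_psms <- function(db, config, decoy_prefix = "rev_") {
  if (nrow(db) == 0L) stop("protein database is empty")
  if (length(config$feature_effect_sizes) != 7L) {
    stop("feature_effect_sizes must have length 7")
  }
  set.seed(config$seed + 1L)
  digest <- digest_db(db, max_missed = 2L, min_len = 7L, max_len = 50L)
  if (nrow(digest) == 0L) stop("digest of database produced no peptides")
  # one parent per digest peptide row is enough for simulation draws
  nc <- config$n_correct_psms
  ni <- config$n_incorrect_psms
  n <- nc + ni
  correct <- rep(c(TRUE, FALSE), c(nc, ni))

  eff <- config$feature_effect_sizes
  feats <- matrix(rnorm(n * 7L), nrow = n)
  colnames(feats) <- PSM_FEATURES
  for (j in seq_len(7L)) {
    shift <- ifelse(correct, 0, -eff[j])
    feats[, j] <- PSM_FEATURE_BASE$mean[j] +
      PSM_FEATURE_BASE$sd[j] * (feats[, j] + shift)
  }
  feats[, "delta_cn"] <- pmax(feats[, "delta_cn"], 0)

  # peptides: correct PSMs take real digest peptides; incorrect PSMs take
  # random sequences whose length follows the simulated feature (rounded)
  idx_c <- sample.int(nrow(digest), nc, replace = TRUE)
  pep <- character(n)
  acc <- character(n)
  mc <- numeric(n)
  pep[correct] <- digest$peptide[idx_c]
  acc[correct] <- digest$accession[idx_c]
  mc[correct] <- digest$missed_cleavages[idx_c]
  feats[correct, "peptide_length"] <- nchar(pep[correct])
  feats[correct, "missed_cleavages"] <- mc[correct] +
    0.1 * rnorm(nc)  # jitter so the LDA sees a continuous feature
  if (ni > 0L) {
    len_i <- pmin(pmax(round(feats[!correct, "peptide_length"]), 7L), 50L)
    pep[!correct] <- vapply(len_i, function(L) {
      paste(sample(AA_CANONICAL, L, replace = TRUE), collapse = "")
    }, character(1))
    feats[!correct, "peptide_length"] <- len_i
    is_decoy_hit <- runif(ni) < config$decoy_fraction_of_incorrect
    acc_i <- db$accession[sample.int(nrow(db), ni, replace = TRUE)]
    acc_i[is_decoy_hit] <- paste0(decoy_prefix, acc_i[is_decoy_hit])
    acc[!correct] <- acc_i
  }
  is_decoy <- startsWith(acc, decoy_prefix)

  # spiked proteins: group effect enters through their PSMs' NFL channels
  spiked_acc <- character(0)
  if (config$n_spiked > 0L) {
    present <- unique(acc[correct])
    spiked_acc <- sort(present)[seq_len(min(config$n_spiked, length(present)))]
  }
  spiked <- data.frame(accession = spiked_acc,
                       fold_change = rep(config$spike_fold_change,
                                         length(spiked_acc)),
                       stringsAsFactors = FALSE)

  snr <- matrix(rlnorm(n * 10L, meanlog = log(config$snr_scale),
                       sdlog = config$snr_sdlog), nrow = n)
  colnames(snr) <- paste0("snr_", TMT10_CHANNELS)
  if (length(spiked_acc)) {
    nfl_cols <- which(config$group_assignment == "NFL")
    rows <- which(acc %in% spiked_acc & correct)
    snr[rows, nfl_cols] <- snr[rows, nfl_cols] * config$spike_fold_change
  }
  if (config$missing_channel_rate > 0) {
    miss <- matrix(runif(n * 10L) < config$missing_channel_rate, nrow = n)
    snr[miss] <- NA_real_
  }

  psms <- data.frame(psm_id = sprintf("PSM%06d", seq_len(n)),
                     peptide = pep, accessions = acc, is_decoy = is_decoy,
                     stringsAsFactors = FALSE)
  psms <- cbind(psms, as.data.frame(feats), as.data.frame(snr))
  # shuffle rows so truth is not recoverable from order
  ord <- sample.int(n)
  truth <- data.frame(psm_id = psms$psm_id, is_correct = correct,
                      true_accession = ifelse(correct, acc, NA_character_),
                      stringsAsFactors = FALSE)
  list(psms = psms[ord, , drop = FALSE],
       truth = truth[ord, , drop = FALSE],
       spiked = spiked,
       design = study_design(group_assignment = config$group_assignment))
}

#' Simulate a protein-level quantitation matrix with spiked fold changes
#'
#' Direct protein x sample generator for power studies of the differential
#' stage: baseline abundances are log-normal across proteins, per-sample
#' measurement noise is log-normal with coefficient of variation
#' `exp(sdlog) - 1` (~10% at the default), and spiked proteins have their
#' NFL-group columns multiplied by `fold_change`. The low default CV reflects
#' protein-level values obtained by summing reporter S/N over many PSMs.
#'
#' @param n_proteins total proteins (rows).
#' @param n_spiked number of spiked proteins (first rows, returned in
#'   `spiked`).
#' @param fold_change true NFL/CTRL ratio of spiked proteins.
#' @param n_nfl,n_ctrl group sizes (columns).
#' @param sdlog per-measurement log-normal sdlog (default 0.1).
#' @param seed integer seed.
#' @return list: `matrix` (a [quant_matrix()]), `design`, `spiked`
#'   (character vector of spiked protein ids).
#' @export
simulate_quant_matrix <- function(n_proteins = 500L, n_spiked = 20L,
                                  fold_change = 2, n_nfl = 5L, n_ctrl = 5L,
                                  sdlog = 0.1, seed = 1L) {
  stopifnot(n_spiked <= n_proteins, n_nfl >= 1, n_ctrl >= 1)
  set.seed(seed)
  groups <- rep(c("NFL", "CTRL"), c(n_nfl, n_ctrl))
  samples <- sprintf("S%02d", seq_along(groups))
  base <- rlnorm(n_proteins, meanlog = log(500), sdlog = 1)
  m <- matrix(rlnorm(n_proteins * length(groups), meanlog = 0, sdlog = sdlog),
              nrow = n_proteins) * base
  rownames(m) <- sprintf("PROT%04d", seq_len(n_proteins))
  colnames(m) <- samples
  spiked <- rownames(m)[seq_len(n_spiked)]
  if (n_spiked > 0L) {
    m[seq_len(n_spiked), groups == "NFL"] <-
      m[seq_len(n_spiked), groups == "NFL"] * fold_change
  }
  ch <- if (length(groups) <= 10L) TMT10_CHANNELS[seq_along(groups)] else
    sprintf("C%02d", seq_along(groups))
  design <- study_design(groups, channel = ch, sample = samples)
  list(matrix = quant_matrix(m, normalized = FALSE), design = design,
       spiked = spiked)
}

#' Configuration for the immunoassay simulator
#'
#' Defaults reproduce the study layout: 10 NFL and 8 CTRL participants with
#' paired EV and total-CSF t-tau / p-tau181 concentrations; EV t-tau and EV
#' p-tau181 correlate strongly in both groups, while the EV-vs-CSF
#' correlations are positive in the NFL group and null-to-negative in CTRL.
#'
#' @param seed integer seed.
#' @param n_per_group named counts, `c(NFL = ..., CTRL = ...)`.
#' @param r_ev_ttau_ptau correlation between EV t-tau and EV p-tau181
#'   (applies within each group).
#' @param r_ev_csf_ttau,r_ev_csf_ptau named per-group target correlations
#'   between the EV and total-CSF analyte.
#' @param analyte_mean,analyte_sd named concentration means/sds (pg/mL) for
#'   `ev_t_tau`, `ev_p_tau181`, `csf_t_tau`, `csf_p_tau181`.
#' @param dilution_factor assay dilution applied to EV samples (default 4).
#' @return list with class `immuno_sim_config`.
#' @export
immuno_sim_config <- function(seed = 1L,
                              n_per_group = c(NFL = 10L, CTRL = 8L),
                              r_ev_ttau_ptau = 0.87,
                              r_ev_csf_ttau = c(NFL = 0.812, CTRL = -0.492),
                              r_ev_csf_ptau = c(NFL = 0.627, CTRL = -0.530),
                              analyte_mean = c(ev_t_tau = 8, ev_p_tau181 = 45,
                                               csf_t_tau = 60,
                                               csf_p_tau181 = 35),
                              analyte_sd = c(ev_t_tau = 3, ev_p_tau181 = 16,
                                             csf_t_tau = 22,
                                             csf_p_tau181 = 12),
                              dilution_factor = 4) {
  rs <- c(r_ev_ttau_ptau, r_ev_csf_ttau, r_ev_csf_ptau)
  if (any(abs(rs) > 1)) stop("target correlations must lie in [-1, 1]")
  stopifnot(all(n_per_group >= 3), dilution_factor > 0)
  cfg <- list(seed = as.integer(seed), n_per_group = n_per_group,
              r_ev_ttau_ptau = r_ev_ttau_ptau,
              r_ev_csf_ttau = r_ev_csf_ttau, r_ev_csf_ptau = r_ev_csf_ptau,
              analyte_mean = analyte_mean, analyte_sd = analyte_sd,
              dilution_factor = dilution_factor)
  class(cfg) <- "immuno_sim_config"
  cfg
}

#' Draw a bivariate sample with a target population correlation
#'
#' Gaussian construction `y = r*x + sqrt(1-r^2)*e`; at `|r| = 1` the
#' construction is degenerate-linear, so the sample correlation equals `r`
#' exactly.
#'
#' @param n sample size.
#' @param r target population correlation in `[-1, 1]`.
#' @param x optional pre-drawn standardized x (length `n`).
#' @return matrix with columns `x`, `y` of standardized draws.
#' @export
sim_correlated_pair <- function(n, r, x = NULL) {
  if (abs(r) > 1) stop("correlation magnitude must be <= 1")
  if (is.null(x)) x <- rnorm(n)
  y <- r * x + sqrt(max(0, 1 - r^2)) * rnorm(n)
  cbind(x = x, y = y)
}

#' Simulate paired EV / CSF tau immunoassay records
#'
#' Per group, draws the four analytes from a chained Gaussian construction
#' hitting the configured pairwise correlations: EV t-tau is the anchor, EV
#' p-tau181 correlates with it at `r_ev_ttau_ptau`, total-CSF t-tau with EV
#' t-tau at the group's `r_ev_csf_ttau`, and total-CSF p-tau181 with EV
#' p-tau181 at the group's `r_ev_csf_ptau`. Standardized draws are scaled to
#' the configured concentration means/sds and truncated at a small positive
#' floor (0.01 pg/mL).
#'
#' @param config an [immuno_sim_config()].
#' @return data.frame with columns `sample_id`, `group`, `ev_t_tau`,
#'   `ev_p_tau181`, `csf_t_tau`, `csf_p_tau181`, `dilution_factor`.
#' @export
simulate_immunoassay <- function(config) {
  stopifnot(inherits(config, "immuno_sim_config"))
  set.seed(config$seed)
  groups <- names(config$n_per_group)
  out <- lapply(groups, function(g) {
    n <- config$n_per_group[[g]]
    ev_t <- rnorm(n)
    ev_p <- sim_correlated_pair(n, config$r_ev_ttau_ptau, x = ev_t)[, "y"]
    csf_t <- sim_correlated_pair(n, config$r_ev_csf_ttau[[g]], x = ev_t)[, "y"]
    csf_p <- sim_correlated_pair(n, config$r_ev_csf_ptau[[g]], x = ev_p)[, "y"]
    z <- cbind(ev_t_tau = ev_t, ev_p_tau181 = ev_p,
               csf_t_tau = csf_t, csf_p_tau181 = csf_p)
    for (a in colnames(z)) {
      z[, a] <- pmax(config$analyte_mean[[a]] + config$analyte_sd[[a]] * z[, a],
                     0.01)
    }
    data.frame(sample_id = sprintf("%s%02d", g, seq_len(n)), group = g,
               as.data.frame(z),
               dilution_factor = config$dilution_factor,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
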