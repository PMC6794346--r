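#' TMT 10-plex monoisotopic reporter ion masses
#'
#' Published monoisotopic m/z of the ten reporter ions, used to match
#' observed centroids to channels. Versioned package constant.
#'
#' @format named numeric vector (Da), names are channel labels.
#' @export
TMT10_REPORTER_MASSES <- c(
  "126"  = 126.127726, "127N" = 127.124761, "127C" = 127.131081,
  "128N" = 128.128116, "128C" = 128.134436, "129N" = 129.131471,
  "129C" = 129.137790, "130N" = 130.134825, "130C" = 130.141145,
  "131"  = 131.138180)

#' Study design: channel -> sample -> group
#'
#' @param group_assignment character vector of group labels (`"NFL"` /
#'   `"CTRL"`), one per channel.
#' @param channel channel labels (default the TMT 10-plex labels, truncated
#'   to the design size).
#' @param sample sample ids (default generated from group labels).
#' @return data.frame of class `study_design` with columns `channel`,
#'   `sample`, `group`.
#' @export
study_design <- function(group_assignment,
                         channel = TMT10_CHANNELS[seq_along(group_assignment)],
                         sample = NULL) {
  stopifnot(length(channel) == length(group_assignment),
            !anyDuplicated(channel),
            all(group_assignment %in% c("NFL", "CTRL")))
  if (is.null(sample)) {
    sample <- paste0(group_assignment, stats::ave(
      seq_along(group_assignment), group_assignment, FUN = seq_along))
  }
  stopifnot(!anyDuplicated(sample))
  d <- data.frame(channel = channel, sample = sample,
                  group = group_assignment, stringsAsFactors = FALSE)
  class(d) <- c("study_design", "data.frame")
  d
}

#' Match observed reporter centroids to TMT channels
#'
#' For each of the ten expected reporter masses, selects the closest
#' observed peak within `tol_da`; a peak may satisfy at most one channel
#' (it goes to the channel whose expected mass it is closest to). Channels
#' with no peak within tolerance are missing (`NA`).
#'
#' @param peaks data.frame with columns `mass` (Da, positive) and `snr`.
#' @param tol_da matching tolerance in Da (default 0.003).
#' @return named numeric vector of length 10 (S/N per channel, `NA` =
#'   missing) with attribute `summed_snr`.
#' @export
match_reporter_centroids <- function(peaks, tol_da = 0.003) {
  stopifnot(all(peaks$mass > 0))
  snr <- setNames(rep(NA_real_, 10L), names(TMT10_REPORTER_MASSES))
  if (nrow(peaks)) {
    # each peak belongs to its closest expected channel
    best_ch <- vapply(peaks$mass, function(m) {
      which.min(abs(TMT10_REPORTER_MASSES - m))
    }, integer(1))
    for (ch in unique(best_ch)) {
      sel <- which(best_ch == ch)
      d <- abs(peaks$mass[sel] - TMT10_REPORTER_MASSES[ch])
      if (min(d) <= tol_da) snr[ch] <- peaks$snr[sel[which.min(d)]]
    }
  }
  attr(snr, "summed_snr") <- sum(snr, na.rm = TRUE)
  snr
}

#' Reporter-block quantification filter
#'
#' A PSM is excluded from quantification iff it has no reporter block (no
#' MS3 spectrum), more than eight of its ten channels are missing, or its
#' summed signal-to-noise over present channels is strictly less than 100.
#'
#' @param snr numeric vector of 10 channel S/N values (`NA` = missing), or
#'   `NULL` for a PSM without an MS3 spectrum.
#' @param min_summed_snr summed S/N threshold (default 100; strict `<`
#'   excludes).
#' @param max_missing maximum tolerated missing channels (default 8; more
#'   than this excludes).
#' @return list: `keep` (logical), `reason` (`"kept"`, `"no_ms3"`,
#'   `"missing_gt8"`, `"low_snr"`).
#' @export
psm_quant_filter <- function(snr, min_summed_snr = 100, max_missing = 8L) {
  if (is.null(snr) || length(snr) == 0L) {
    return(list(keep = FALSE, reason = "no_ms3"))
  }
  stopifnot(length(snr) == 10L)
  n_missing <- sum(is.na(snr))
  if (n_missing > max_missing) {
    return(list(keep = FALSE, reason = "missing_gt8"))
  }
  if (sum(snr, na.rm = TRUE) < min_summed_snr) {
    return(list(keep = FALSE, reason = "low_snr"))
  }
  list(keep = TRUE, reason = "kept")
}

#' Apply the quantification filter to a PSM table
#'
#' Vectorized application of [psm_quant_filter()] to the `snr_*` columns of
#' a PSM table. A row whose reporter columns are absent or all-`NA` with an
#' `has_ms3 = FALSE` flag counts as "no MS3". Rule order matches
#' [psm_quant_filter()]: no-MS3, then missing-channel count, then summed
#' S/N.
#'
#' @param psms PSM data.frame with `snr_<channel>` columns; optional logical
#'   column `has_ms3` (default `TRUE`).
#' @inheritParams psm_quant_filter
#' @return the input with logical `quant_keep` and character `quant_reason`
#'   columns appended.
#' @export
apply_quant_filter <- function(psms, min_summed_snr = 100, max_missing = 8L) {
  snr_cols <- paste0("snr_", names(TMT10_REPORTER_MASSES))
  stopifnot(all(snr_cols %in% names(psms)))
  m <- as.matrix(psms[, snr_cols])
  no_ms3 <- if ("has_ms3" %in% names(psms)) !psms$has_ms3 else
    rep(FALSE, nrow(psms))
  n_missing <- rowSums(is.na(m))
  summed <- rowSums(m, na.rm = TRUE)
  reason <- rep("kept", nrow(psms))
  reason[summed < min_summed_snr] <- "low_snr"
  reason[n_missing > max_missing] <- "missing_gt8"
  reason[no_ms3] <- "no_ms3"
  psms$quant_keep <- reason == "kept"
  psms$quant_reason <- reason
  psms
}

#' Construct a quantitation matrix object
#'
#' @param m numeric matrix, rows = protein-group representatives, columns =
#'   sample ids; values are summed reporter S/N, non-negative.
#' @param normalized logical flag.
#' @return the matrix with class `quant_matrix` and attribute `normalized`.
#' @export
quant_matrix <- function(m, normalized = FALSE) {
  stopifnot(is.matrix(m), all(m >= 0 | is.na(m)))
  structure(m, class = c("quant_matrix", class(m)), normalized = normalized)
}

#' Protein quantitation by summed reporter S/N
#'
#' Sums each channel's S/N over the quantifiable PSMs assigned to each
#' protein group (missing channels contribute 0) and relabels columns to
#' sample ids via the study design. Groups with no quantifiable PSM keep a
#' row of zeros and are listed in the `zero_rows` attribute.
#'
#' @param psms PSM table already passed through [apply_quant_filter()]
#'   (only `quant_keep` rows are used) with `peptide` and `snr_*` columns.
#' @param inference an `inference_result` assigning peptides to groups.
#' @param design a [study_design()].
#' @return a [quant_matrix()] (rows = group representatives in inference
#'   order, columns = sample ids), attribute `zero_rows`.
#' @export
quantify_proteins <- function(psms, inference, design) {
  if (!"quant_keep" %in% names(psms)) {
    stop("run apply_quant_filter() before quantification")
  }
  use <- psms[psms$quant_keep, , drop = FALSE]
  grp <- inference$peptide_assignment[use$peptide]
  if (anyNA(grp) && nrow(use) > 0L) {
    stop("PSM peptide(s) with no protein-group assignment: ",
         paste(head(unique(use$peptide[is.na(grp)]), 3), collapse = ", "))
  }
  reps <- names(inference$protein_groups)
  snr_cols <- paste0("snr_", design$channel)
  stopifnot(all(snr_cols %in% names(use) | nrow(use) == 0L))
  m <- matrix(0, nrow = length(reps), ncol = nrow(design),
              dimnames = list(reps, design$sample))
  if (nrow(use) > 0L) {
    v <- as.matrix(use[, snr_cols, drop = FALSE])
    v[is.na(v)] <- 0
    agg <- rowsum(v, group = grp)
    m[rownames(agg), ] <- agg
  }
  zero <- reps[rowSums(m) == 0]
  out <- quant_matrix(m, normalized = FALSE)
  attr(out, "zero_rows") <- zero
  out
}

#' Per-sample channel totals and optional total-sum normalization
#'
#' Sums each reporter channel (column) across all quantified proteins.
#' With `normalize = TRUE`, each column is divided by its total and rescaled
#' to the mean total, and the matrix is flagged normalized.
#'
#' @param m a [quant_matrix()] (unnormalized).
#' @param normalize logical.
#' @return list: `totals` (named per-sample totals), `matrix` (input, or
#'   normalized copy when `normalize = TRUE`).
#' @export
channel_totals <- function(m, normalize = FALSE) {
  stopifnot(inherits(m, "quant_matrix"))
  if (isTRUE(attr(m, "normalized"))) stop("matrix is already normalized")
  totals <- colSums(m)
  if (any(totals == 0)) stop("zero-total channel: degenerate input")
  out <- m
  if (normalize) {
    scaled <- sweep(unclass(m), 2L, totals, `/`) * mean(totals)
    out <- quant_matrix(scaled, normalized = TRUE)
  }
  list(totals = totals, matrix = out)
}
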