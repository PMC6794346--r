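#' Precursor mass-tolerance screen
#'
#' Retains PSMs whose absolute precursor mass error is at most
#' `precursor_tol_ppm` (default 50 ppm, the wide-window setting used with
#' SEQUEST + linear-discriminant filtering). The product-ion tolerance
#' (default 0.9 Da) applies to fragment matching upstream of this pipeline
#' and is recorded as an attribute only.
#'
#' @param psms PSM data.frame with a `mass_error_ppm` column (signed ppm,
#'   observed minus theoretical relative to theoretical).
#' @param precursor_tol_ppm positive precursor tolerance in ppm.
#' @param product_tol_da positive product-ion tolerance in Da (metadata).
#' @return the retained rows, with attributes `precursor_tol_ppm` and
#'   `product_tol_da`.
#' @export
mass_tolerance_screen <- function(psms, precursor_tol_ppm = 50,
                                  product_tol_da = 0.9) {
  stopifnot(precursor_tol_ppm > 0, product_tol_da > 0)
  out <- psms[abs(psms$mass_error_ppm) <= precursor_tol_ppm, , drop = FALSE]
  attr(out, "precursor_tol_ppm") <- precursor_tol_ppm
  attr(out, "product_tol_da") <- product_tol_da
  out
}

#' Fit the combined linear-discriminant filter score
#'
#' Two-class linear discriminant over the seven PSM features (XCorr, deltaCn,
#' precursor mass accuracy, charge state, in-solution charge, peptide length,
#' missed cleavages) with target PSMs as the positive class and decoy PSMs as
#' the negative class. The weight vector is `S^-1 (mu_target - mu_decoy)`
#' with `S` the pooled within-class covariance; the score is the signed
#' discriminant value centred at the class-mean midpoint, oriented so higher
#' means more target-like. A singular within-class scatter falls back to the
#' Moore-Penrose pseudo-inverse with a warning.
#'
#' @param psms PSM data.frame containing the seven feature columns and
#'   `is_decoy`.
#' @param features feature column names (default the seven canonical ones).
#' @return list of class `lda_fit`: `weights` (named), `intercept`, and
#'   `psms` — the input with an `lda_score` column appended.
#' @export
fit_lda <- function(psms, features = PSM_FEATURES) {
  stopifnot(all(features %in% names(psms)))
  x <- as.matrix(psms[, features, drop = FALSE])
  if (!all(is.finite(x))) stop("non-finite feature values")
  lab <- psms$is_decoy
  if (sum(lab) < 2L || sum(!lab) < 2L) {
    stop("need at least 2 decoy and 2 target PSMs to fit the discriminant")
  }
  mu_t <- colMeans(x[!lab, , drop = FALSE])
  mu_d <- colMeans(x[lab, , drop = FALSE])
  n_t <- sum(!lab); n_d <- sum(lab)
  S <- ((n_t - 1) * cov(x[!lab, , drop = FALSE]) +
        (n_d - 1) * cov(x[lab, , drop = FALSE])) / (n_t + n_d - 2)
  w <- tryCatch(solve(S, mu_t - mu_d), error = function(e) {
    warning("singular within-class scatter; using pseudo-inverse")
    sv <- svd(S)
    pos <- sv$d > max(sv$d) * 1e-10
    (sv$v[, pos, drop = FALSE] %*%
       ((t(sv$u[, pos, drop = FALSE]) %*% (mu_t - mu_d)) / sv$d[pos]))[, 1]
  })
  names(w) <- features
  intercept <- -sum(w * (mu_t + mu_d) / 2)
  score <- drop(x %*% w) + intercept
  # orientation guard (w as constructed already points at targets)
  if (mean(score[!lab]) < mean(score[lab])) {
    w <- -w; intercept <- -intercept; score <- -score
  }
  psms$lda_score <- score
  structure(list(weights = w, intercept = intercept, psms = psms),
            class = "lda_fit")
}

#' Target-decoy FDR curve
#'
#' Sweeping the score threshold from the most to the least confident PSM,
#' the FDR estimate at each threshold is `(#decoys >= threshold) /
#' (#targets >= threshold)`; q-values are the running minimum of the
#' estimate from the permissive end, so they are monotone non-increasing in
#' score. Tied scores are processed as a block.
#'
#' @param psms data.frame with `is_decoy` and the score column.
#' @param score_field name of the score column (default `"lda_score"`).
#' @return data.frame of class `fdr_curve` with one row per distinct score:
#'   `score`, `n_targets` and `n_decoys` (cumulative counts at or above the
#'   score), `fdr`, `q_value`.
#' @export
estimate_fdr <- function(psms, score_field = "lda_score") {
  stopifnot(score_field %in% names(psms))
  if (!any(!psms$is_decoy)) stop("no target PSMs")
  s <- psms[[score_field]]
  thr <- sort(unique(s), decreasing = TRUE)
  idx <- match(s, thr)  # block index per PSM, 1 = best score
  tgt_blk <- tabulate(idx[!psms$is_decoy], nbins = length(thr))
  dec_blk <- tabulate(idx[psms$is_decoy], nbins = length(thr))
  n_t <- cumsum(tgt_blk)
  n_d <- cumsum(dec_blk)
  fdr <- ifelse(n_t > 0, n_d / n_t, Inf)
  q <- rev(cummin(rev(fdr)))
  structure(data.frame(score = thr, n_targets = n_t, n_decoys = n_d,
                       fdr = fdr, q_value = q),
            class = c("fdr_curve", "data.frame"))
}

#' Accept PSMs at a q-value threshold
#'
#' Retains target PSMs whose q-value (from [estimate_fdr()]) is at most
#' `q_max`; decoys inform the curve but are excluded from the accepted set.
#'
#' @param psms PSM data.frame with `is_decoy` and the score column.
#' @param q_max maximum q-value (default 0.01, i.e. 1% FDR).
#' @param score_field score column name.
#' @param curve optionally a precomputed [estimate_fdr()] curve.
#' @return accepted target rows with a `q_value` column appended.
#' @export
filter_psm_fdr <- function(psms, q_max = 0.01, score_field = "lda_score",
                           curve = NULL) {
  if (is.null(curve)) curve <- estimate_fdr(psms, score_field)
  q <- curve$q_value[match(psms[[score_field]], curve$score)]
  psms$q_value <- q
  psms[!psms$is_decoy & q <= q_max, , drop = FALSE]
}

#' Protein-level FDR collapse
#'
#' Scores every protein (target and decoy) by the best `lda_score` among its
#' PSMs, ranks proteins, estimates FDR by decoy counting exactly as at the
#' PSM level, and retains target proteins at `q_max`.
#'
#' PSMs mapping to several accessions contribute their score to each.
#'
#' @param psms accepted PSM data.frame (post [filter_psm_fdr()] for the
#'   published 1%/1% scheme, but any PSM table with `accessions`,
#'   `is_decoy` — or decoy-prefixed accessions — and a score column works).
#'   `accessions` may be `;`-separated.
#' @param q_max protein-level q-value threshold (default 0.01).
#' @param score_field score column name.
#' @param decoy_prefix prefix identifying decoy accessions.
#' @return list: `retained` (character vector of retained target
#'   accessions), `curve` (protein-level `fdr_curve`), `protein_scores`
#'   (data.frame accession, is_decoy, score).
#' @export
protein_level_fdr <- function(psms, q_max = 0.01, score_field = "lda_score",
                              decoy_prefix = "rev_") {
  acc <- strsplit(psms$accessions, ";", fixed = TRUE)
  reps <- lengths(acc)
  long <- data.frame(accession = unlist(acc),
                     score = rep(psms[[score_field]], reps),
                     stringsAsFactors = FALSE)
  best <- aggregate(score ~ accession, data = long, FUN = max)
  best$is_decoy <- startsWith(best$accession, decoy_prefix)
  if (nrow(best) == 0L) {
    return(list(retained = character(0), curve = NULL,
                protein_scores = best))
  }
  curve <- estimate_fdr(data.frame(is_decoy = best$is_decoy,
                                   lda_score = best$score),
                        score_field = "lda_score")
  q <- curve$q_value[match(best$score, curve$score)]
  retained <- sort(best$accession[!best$is_decoy & q <= q_max])
  list(retained = retained, curve = curve, protein_scores = best)
}
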