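#' Evaluate a four-parameter logistic calibration curve
#'
#' `signal(conc) = lower + (upper - lower) / (1 + (conc / mid)^(-slope))`
#' — monotone increasing in `conc` for `slope > 0`, with `signal(mid)` the
#' midpoint of the two asymptotes.
#'
#' @param conc concentration(s), > 0.
#' @param curve a `standard_curve` (or list with `lower`, `upper`, `mid`,
#'   `slope`).
#' @return predicted signal(s).
#' @export
curve_signal <- function(curve, conc) {
  stopifnot(all(conc > 0))
  with(curve, lower + (upper - lower) / (1 + (conc / mid)^(-slope)))
}

#' Fit a four-parameter logistic standard curve
#'
#' Least-squares 4PL fit via `nls()` with the `SSfpl` self-start on
#' log-concentration, falling back to `minpack.lm::nlsLM` with heuristic
#' starts. Requires at least 5 calibrator levels with positive
#' concentrations spanning the response range.
#'
#' @param conc calibrator concentrations (> 0).
#' @param signal measured signals (duplicate wells should be averaged first;
#'   see [average_duplicates()]).
#' @return list of class `standard_curve`: `lower`, `upper`, `mid` (midpoint
#'   concentration), `slope`, `residual_sd`, `converged`.
#' @export
fit_standard_curve <- function(conc, signal) {
  stopifnot(length(conc) == length(signal))
  if (length(unique(conc)) < 5L) stop("need at least 5 calibrator levels")
  if (any(conc <= 0)) stop("calibrator concentrations must be positive")
  if (sd(signal) == 0) stop("degenerate curve: constant signals")
  df <- data.frame(lx = log(conc), y = signal)
  fit <- tryCatch(
    nls(y ~ SSfpl(lx, A, B, xmid, scal), data = df),
    error = function(e) {
      start <- list(A = min(signal), B = max(signal),
                    xmid = mean(log(conc)), scal = 1)
      minpack.lm::nlsLM(y ~ A + (B - A) / (1 + exp((xmid - lx) / scal)),
                        data = df, start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    })
  cf <- coef(fit)
  # SSfpl: y = A + (B - A)/(1 + exp((xmid - lx)/scal));
  # in concentration space: mid = exp(xmid), slope = 1/scal
  curve <- structure(list(lower = unname(cf["A"]), upper = unname(cf["B"]),
                          mid = exp(unname(cf["xmid"])),
                          slope = 1 / unname(cf["scal"]),
                          residual_sd = sd(resid(fit)),
                          converged = fit$convInfo$isConv %||% TRUE),
                     class = "standard_curve")
  if (curve$slope < 0) {
    # canonicalize orientation: store increasing form
    curve[c("lower", "upper")] <- curve[c("upper", "lower")]
    curve$slope <- -curve$slope
  }
  if (curve$mid <= 0) stop("non-positive midpoint concentration")
  curve
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Back-calculate concentration from a standard curve
#'
#' Inverts the 4PL analytically and multiplies by the sample dilution factor
#' (assays run on 4x-diluted samples by default). Signals at or outside the
#' asymptote interval are censored (`NA` with reason), not extrapolated.
#'
#' @param curve a `standard_curve`.
#' @param signal measured signal(s).
#' @param dilution_factor dilution applied to the sample before assay
#'   (default 4); the reported concentration is in-well concentration times
#'   this factor.
#' @return data.frame: `signal`, `concentration` (pg/mL, `NA` when
#'   censored), `status` (`"ok"`, `"below_range"`, `"above_range"`).
#' @export
back_calculate <- function(curve, signal, dilution_factor = 4) {
  stopifnot(dilution_factor > 0)
  lo <- min(curve$lower, curve$upper); hi <- max(curve$lower, curve$upper)
  status <- ifelse(signal <= lo, "below_range",
                   ifelse(signal >= hi, "above_range", "ok"))
  frac <- (signal - curve$lower) / (curve$upper - curve$lower)
  conc <- ifelse(status == "ok",
                 curve$mid * (frac / (1 - frac))^(1 / curve$slope),
                 NA_real_)
  data.frame(signal = signal, concentration = conc * dilution_factor,
             status = status, stringsAsFactors = FALSE)
}

#' Average duplicate wells
#'
#' Samples are assayed in duplicate; signals are averaged per sample id
#' before back-calculation.
#'
#' @param sample_id character vector.
#' @param signal numeric vector.
#' @return data.frame `sample_id`, `signal` (means, input order of first
#'   occurrence).
#' @export
average_duplicates <- function(sample_id, signal) {
  agg <- aggregate(list(signal = signal), by = list(sample_id = sample_id),
                   FUN = mean)
  agg[match(unique(sample_id), agg$sample_id), , drop = FALSE]
}

#' Group comparison of an analyte
#'
#' Two-sided Mann-Whitney comparison of an analyte between NFL and CTRL,
#' with group medians.
#'
#' @param records immunoassay data.frame (as from [simulate_immunoassay()]).
#' @param analyte column name, e.g. `"ev_t_tau"`.
#' @return list: `p_value`, `U`, `medians` (named).
#' @export
group_compare <- function(records, analyte) {
  stopifnot(analyte %in% names(records))
  x <- records[[analyte]][records$group == "NFL"]
  y <- records[[analyte]][records$group == "CTRL"]
  mt <- mann_whitney_test(x, y)
  list(p_value = mt$p_value, U = mt$U,
       medians = c(NFL = stats::median(x), CTRL = stats::median(y)))
}

#' Pearson correlation between two analytes
#'
#' Product-moment correlation with two-sided t-distribution p-value, overall
#' or per group; pairs with any missing value are dropped and counted.
#'
#' @param records immunoassay data.frame.
#' @param analyte_x,analyte_y column names.
#' @param by_group if `TRUE`, one result per group; otherwise pooled.
#' @return data.frame: `group` (`"all"` when pooled), `n`, `r`, `p_value`,
#'   `n_dropped`.
#' @export
correlate <- function(records, analyte_x, analyte_y, by_group = FALSE) {
  stopifnot(all(c(analyte_x, analyte_y) %in% names(records)))
  one <- function(d, label) {
    ok <- is.finite(d[[analyte_x]]) & is.finite(d[[analyte_y]])
    x <- d[[analyte_x]][ok]; y <- d[[analyte_y]][ok]
    if (length(x) < 3L) stop("need at least 3 complete pairs per group")
    if (sd(x) == 0 || sd(y) == 0) stop("zero variance in a variable")
    ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
    data.frame(group = label, n = length(x), r = unname(ct$estimate),
               p_value = ct$p.value, n_dropped = sum(!ok),
               stringsAsFactors = FALSE)
  }
  if (by_group) {
    do.call(rbind, lapply(split(records, records$group), function(d) {
      one(d, d$group[1])
    }))
  } else {
    one(records, "all")
  }
}

#' Fisher-z confidence interval for a correlation
#'
#' @param r target/population correlation, `|r| < 1`.
#' @param n sample size (> 3).
#' @param level confidence level (default 0.95).
#' @return numeric length-2 vector, the interval on the r scale.
#' @export
fisher_z_ci <- function(r, n, level = 0.95) {
  stopifnot(abs(r) < 1, n > 3)
  z <- atanh(r)
  half <- qnorm(1 - (1 - level) / 2) / sqrt(n - 3)
  tanh(c(z - half, z + half))
}
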