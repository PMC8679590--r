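# Noncompartmental PK analysis.
#
# The terminal slope (lambda_z) is chosen the way the standard commercial NCA
# tools do by default: among all candidate tails of >= 3 points that start
# strictly after Tmax, fit log-linear regressions and keep the tail with the
# best adjusted R^2, breaking ties toward the tail with more points.

# linear (default) or linear-up/log-down trapezoid on one segment
.trapz_segment <- function(t1, t2, y1, y2, rule) {
  dt <- t2 - t1
  if (rule == "linuplogdown" && y2 < y1 && y1 > 0 && y2 > 0) {
    (y1 - y2) * dt / log(y1 / y2)
  } else {
    (y1 + y2) / 2 * dt
  }
}

.auc_trapz <- function(time, value, rule = "linear") {
  if (length(time) < 2L) return(0)
  sum(vapply(seq_len(length(time) - 1L), function(i) {
    .trapz_segment(time[i], time[i + 1L], value[i], value[i + 1L], rule)
  }, numeric(1)))
}

# best-adjusted-R^2 terminal tail; returns NULL when no admissible tail exists
.select_lambda_z <- function(time, value) {
  n <- length(time)
  i_tmax <- which.max(value)
  first <- i_tmax + 1L            # Tmax itself is excluded
  best <- NULL
  for (k in seq(3L, n)) {
    start <- n - k + 1L
    if (start < first) next
    idx <- start:n
    y <- value[idx]
    if (any(y <= 0)) next
    ft <- stats::lm.fit(cbind(1, time[idx]), log(y))
    slope <- ft$coefficients[2]
    if (!is.finite(slope) || slope >= 0) next
    r2 <- 1 - sum(ft$residuals^2) / sum((log(y) - mean(log(y)))^2)
    adj <- 1 - (1 - r2) * (k - 1) / (k - 2)
    # ties (within 1e-9) go to the longer tail; loop runs short->long so >= wins
    if (is.null(best) || adj >= best$adj_r2 - 1e-9) {
      best <- list(lambda_z = unname(-slope), n_tail = k, adj_r2 = unname(adj),
                   intercept = unname(ft$coefficients[1]))
    }
  }
  best
}

# AUC0-inf machinery shared by nca() and tiac_from_curve().
# Returns NULL lambda fields when the curve ends at zero (no extrapolation).
.auc_inf <- function(time, value, rule = "linear") {
  auc_last <- .auc_trapz(time, value, rule)
  aumc_last <- .auc_trapz(time, time * value, "linear")
  clast <- value[length(value)]
  tlast <- time[length(time)]
  if (clast <= 0) {
    return(list(auc_last = auc_last, auc_inf = auc_last,
                aumc_inf = aumc_last, lambda_z = NA_real_,
                n_tail = NA_integer_, adj_r2 = NA_real_, extrap_frac = 0))
  }
  tail <- .select_lambda_z(time, value)
  if (is.null(tail)) {
    md_stop("cannot fit a terminal log-linear phase (need >= 3 positive points after Tmax)",
            "mirdose_cannot_fit_terminal")
  }
  lz <- tail$lambda_z
  auc_inf <- auc_last + clast / lz
  aumc_inf <- aumc_last + clast * tlast / lz + clast / lz^2
  list(auc_last = auc_last, auc_inf = auc_inf, aumc_inf = aumc_inf,
       lambda_z = lz, n_tail = tail$n_tail, adj_r2 = tail$adj_r2,
       extrap_frac = (clast / lz) / auc_inf)
}

#' Noncompartmental pharmacokinetic analysis
#'
#' Computes Cmax/Tmax from the observed samples, AUC0-last by the trapezoid
#' rule, the terminal rate constant lambda_z by best-adjusted-R^2 log-linear
#' regression (see Details), AUC0-inf = AUC0-last + Clast/lambda_z, and the
#' derived parameters T1/2 = ln2/lambda_z, CL = dose/AUC0-inf,
#' MRT = AUMC0-inf/AUC0-inf, Vss = CL x MRT. With curves in %ID units the
#' dose is 100 %ID, so CL carries g/h (for %ID/g curves) or mL/h (for
#' %ID/mL curves) and Vss carries g or mL.
#'
#' @details Candidate tails are every run of the last k >= 3 samples that
#' starts strictly after Tmax and is everywhere positive; the tail with the
#' highest adjusted R^2 wins, ties broken toward more points. An extrapolated
#' AUC fraction above 30% raises a classed warning
#' (`mirdose_high_extrapolation`), not an error.
#'
#' @param curve a [tac()] object (or anything with `$time`/`$value`).
#' @param dose administered dose in curve-consistent units; 100 when the
#'   curve is in %ID form.
#' @param rule trapezoid rule, `"linear"` (default) or `"linuplogdown"`.
#' @return object of class `"nca_result"`: list with `cmax`, `tmax`,
#'   `auc_last`, `auc_inf`, `aumc_inf`, `lambda_z`, `t_half`, `cl`, `vss`,
#'   `mrt`, `n_tail`, `r2_adj`, `extrap_frac`.
#' @export
#' @examples
#' tm <- c(0.083, 24, 48, 96, 192)
#' cv <- tac(tm, 35 * exp(-0.0025 * tm), "pid_per_g")
#' nca(cv)
nca <- function(curve, dose = 100, rule = c("linear", "linuplogdown")) {
  rule <- match.arg(rule)
  time <- curve$time
  value <- curve$value
  if (length(time) < 3L) {
    md_stop("nca needs at least 3 samples", "mirdose_insufficient_data")
  }
  res <- .auc_inf(time, value, rule)
  if (!is.finite(res$lambda_z)) {
    md_stop("terminal phase is non-positive; cannot extrapolate",
            "mirdose_cannot_fit_terminal")
  }
  if (res$extrap_frac > 0.3) {
    md_warn(sprintf("extrapolated AUC fraction is %.1f%% (> 30%%)",
                    100 * res$extrap_frac), "mirdose_high_extrapolation")
  }
  i_max <- which.max(value)
  cl <- dose / res$auc_inf
  mrt <- res$aumc_inf / res$auc_inf
  structure(list(
    cmax = value[i_max], tmax = time[i_max],
    auc_last = res$auc_last, auc_inf = res$auc_inf, aumc_inf = res$aumc_inf,
    lambda_z = res$lambda_z, t_half = log(2) / res$lambda_z,
    cl = cl, mrt = mrt, vss = cl * mrt,
    n_tail = res$n_tail, r2_adj = res$adj_r2, extrap_frac = res$extrap_frac
  ), class = "nca_result")
}

#' @export
print.nca_result <- function(x, ...) {
  cat(sprintf(
    "<nca> Cmax %.4g @ %.3g h | AUCinf %.6g | T1/2 %.4g h | CL %.4g | Vss %.4g | MRT %.4g h (tail n=%d, adjR2=%.4f)\n",
    x$cmax, x$tmax, x$auc_inf, x$t_half, x$cl, x$vss, x$mrt, x$n_tail, x$r2_adj))
  invisible(x)
}

#' Collect NCA results into the `nca_result.csv` layout
#'
#' @param results named list of `nca_result`, names `subject.compartment`.
#' @param subject_id,compartment optional explicit label vectors.
#' @return data frame with one row per result.
#' @export
nca_result_table <- function(results, subject_id = NULL, compartment = NULL) {
  nm <- names(results)
  df <- do.call(rbind, lapply(results, function(r) {
    data.frame(cmax = r$cmax, tmax_h = r$tmax, auc = r$auc_inf,
               aumc = r$aumc_inf, lambda_z = r$lambda_z, t_half_h = r$t_half,
               cl = r$cl, vss = r$vss, mrt_h = r$mrt, n_tail = r$n_tail,
               r2_adj = r$r2_adj)
  }))
  df <- cbind(data.frame(
    subject_id = if (is.null(subject_id)) sub("\\..*$", "", nm) else subject_id,
    compartment = if (is.null(compartment)) sub("^[^.]*\\.", "", nm) else compartment),
    df)
  rownames(df) <- NULL
  df
}
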