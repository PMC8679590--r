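# Saturation-binding analysis, serum-stability normalization, and tumor
# study bookkeeping.

#' One-site saturation binding model
#'
#' y = Bmax x / (Kd + x): specific binding of a radioligand at free
#' concentration x with equilibrium dissociation constant Kd and maximal
#' binding Bmax.
#'
#' @param x free ligand concentration, nM (vectorized).
#' @param bmax maximal binding (cpm, or fmol if calibrated).
#' @param kd equilibrium dissociation constant, nM (> 0).
#' @return bound signal, same unit as `bmax`.
#' @export
one_site_binding <- function(x, bmax, kd) {
  if (kd <= 0) md_stop("kd must be > 0", "mirdose_invalid_input")
  bmax * x / (kd + x)
}

# specific binding per concentration from a binding.csv-layout data frame:
# mean total-well counts minus mean nonspecific (negative-control) counts
specific_binding <- function(df) {
  need <- c("concentration_nm", "well_type", "counts_cpm")
  if (!all(need %in% names(df))) {
    md_stop(paste0("binding data must have columns: ", paste(need, collapse = ", ")),
            "mirdose_invalid_input")
  }
  agg <- stats::aggregate(counts_cpm ~ concentration_nm + well_type, df, mean)
  tot <- agg[agg$well_type == "total", ]
  ns <- agg[agg$well_type == "nonspecific", ]
  m <- merge(tot, ns, by = "concentration_nm", suffixes = c("_tot", "_ns"),
             all.x = TRUE)
  m$counts_cpm_ns[is.na(m$counts_cpm_ns)] <- 0
  data.frame(concentration_nm = m$concentration_nm,
             bound = m$counts_cpm_tot - m$counts_cpm_ns)
}

#' Fit the one-site saturation binding model
#'
#' Nonlinear least squares of specific binding against concentration.
#' Initialization: Bmax0 = maximum observed binding; Kd0 = concentration at
#' half of Bmax0, linearly interpolated. Non-convergence is reported via the
#' `converged` flag, never as an exception.
#'
#' @param concentration_nm concentrations, nM (>= 4 distinct values), or a
#'   data frame in `binding.csv` layout (`concentration_nm`, `well_type`,
#'   `counts_cpm`, `replicate`) from which specific binding is formed as
#'   total minus negative-control counts per concentration.
#' @param bound specific binding per concentration (ignored when a data
#'   frame is supplied).
#' @param weighted if `TRUE`, weight residuals by 1/y^2; default unweighted
#'   (the common graphing-software default).
#' @return object of class `"binding_fit"`: list with `kd`, `bmax`, `rss`,
#'   `converged`, `data`.
#' @export
fit_saturation <- function(concentration_nm, bound = NULL, weighted = FALSE) {
  if (is.data.frame(concentration_nm)) {
    sp <- specific_binding(concentration_nm)
    concentration_nm <- sp$concentration_nm
    bound <- sp$bound
  }
  ord <- order(concentration_nm)
  x <- concentration_nm[ord]
  y <- bound[ord]
  if (length(unique(x)) < 4L) {
    md_stop("need >= 4 distinct concentrations", "mirdose_insufficient_data")
  }
  if (any(x <= 0)) md_stop("concentrations must be > 0", "mirdose_invalid_input")
  if (stats::sd(y) == 0) {
    # constant binding carries no concentration information: degenerate
    return(structure(list(kd = NA_real_, bmax = NA_real_, rss = NA_real_,
                          converged = FALSE,
                          data = data.frame(concentration_nm = x, bound = y)),
                     class = "binding_fit"))
  }
  bmax0 <- max(y)
  kd0 <- tryCatch(stats::approx(y, x, xout = bmax0 / 2, ties = mean)$y,
                  error = function(e) NA_real_)
  if (!is.finite(kd0) || kd0 <= 0) kd0 <- stats::median(x)
  # "port" handles the zero-residual (noiseless) case that plain Gauss-Newton
  # rejects, and lets us keep both parameters positive
  fit <- tryCatch(
    stats::nls(y ~ bmax * x / (kd + x),
               start = list(bmax = bmax0, kd = kd0),
               algorithm = "port", lower = c(bmax = 1e-12, kd = 1e-12),
               weights = if (weighted) 1 / pmax(y, 1e-12)^2 else NULL,
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(kd = NA_real_, bmax = NA_real_, rss = NA_real_,
                          converged = FALSE,
                          data = data.frame(concentration_nm = x, bound = y)),
                     class = "binding_fit"))
  }
  cf <- stats::coef(fit)
  structure(list(kd = unname(cf[["kd"]]), bmax = unname(cf[["bmax"]]),
                 rss = sum(stats::residuals(fit)^2), converged = TRUE,
                 data = data.frame(concentration_nm = x, bound = y)),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("<binding_fit> Kd = %.4g nM, Bmax = %.5g (rss %.4g)\n",
                x$kd, x$bmax, x$rss))
  } else {
    cat("<binding_fit> did not converge\n")
  }
  invisible(x)
}

#' Scatchard transform
#'
#' Returns (bound, bound/free) pairs; a pure transform, no fitting is done on
#' the transformed coordinates. For exact one-site data the transform is a
#' line of slope -1/Kd with bound-axis intercept Bmax.
#'
#' @param bound bound signal per point.
#' @param free free ligand per point (total minus bound for count data);
#'   must be > 0.
#' @return data frame with columns `bound`, `bound_over_free`.
#' @export
scatchard <- function(bound, free) {
  if (any(free <= 0)) {
    md_stop("free ligand must be > 0 for the Scatchard transform",
            "mirdose_invalid_input")
  }
  data.frame(bound = bound, bound_over_free = bound / free)
}

#' Normalize a stability time course to 100% at t = 0
#'
#' @param time_h measurement times, hours; must contain 0.
#' @param value intact-fraction signal at each time; value at t = 0 must be
#'   > 0.
#' @return percent of the t = 0 signal at each time.
#' @export
stability_normalize <- function(time_h, value) {
  i0 <- which(time_h == 0)
  if (length(i0) != 1L) {
    md_stop("exactly one t = 0 measurement required", "mirdose_invalid_input")
  }
  if (value[i0] <= 0) md_stop("t = 0 signal must be > 0", "mirdose_invalid_input")
  value / value[i0] * 100
}

#' Ellipsoid tumor volume
#'
#' volume = long diameter x (short diameter)^2 / 2, in mm^3 for mm inputs.
#'
#' @param long_mm,short_mm caliper diameters, mm; `long_mm >= short_mm > 0`.
#' @return tumor volume, mm^3.
#' @export
tumor_volume <- function(long_mm, short_mm) {
  if (any(short_mm <= 0) || any(long_mm < short_mm)) {
    md_stop("need long >= short > 0", "mirdose_invalid_input")
  }
  long_mm * short_mm^2 / 2
}

#' Humane-endpoint check for a tumor-bearing animal
#'
#' Euthanasia rules: body weight fallen by more than 20% of baseline, or
#' tumor burden above 10% of body weight. The volume-to-weight comparison
#' assumes 1 mm^3 of tumor weighs 1 mg. The weight rule is evaluated first.
#'
#' @param tumor_mm3 tumor volume, mm^3 (see [tumor_volume()]).
#' @param body_weight_g current body weight, g.
#' @param baseline_weight_g body weight at day 0, g.
#' @return one of `"continue"`, `"euthanize_weight"`, `"euthanize_tumor"`.
#' @export
endpoint_check <- function(tumor_mm3, body_weight_g, baseline_weight_g) {
  if (baseline_weight_g <= 0 || body_weight_g <= 0 || tumor_mm3 < 0) {
    md_stop("weights must be > 0 and volume >= 0", "mirdose_invalid_input")
  }
  if (body_weight_g < 0.8 * baseline_weight_g) return("euthanize_weight")
  if (tumor_mm3 > 0.10 * body_weight_g * 1000) return("euthanize_tumor") # mm3 = mg
  "continue"
}
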