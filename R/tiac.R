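# Time-integrated activity coefficients (TIACs): the integral over time of
# the fraction of administered activity residing in a source region, in
# hours. For a pure physical-decay curve normalized to 1 at t = 0 the TIAC is
# bounded by T_phys/ln2 (92.33 h for the 64 h half-life used for 90Y).

#' Humanization constants
#'
#' Reference-adult constants used to humanize a monkey blood curve: reference
#' body mass 73,700 g and reference blood volume 5,300 mL (adult male
#' defaults of the standard internal-dosimetry phantom), and the 64 h
#' half-life used for 90Y.
#'
#' @param monkey_body_mass_g monkey body mass in grams.
#' @param reference_body_mass_g,reference_blood_volume_ml,y90_half_life_h
#'   reference-adult constants; override only with documented cause.
#' @return object of class `"humanization_params"`.
#' @export
humanization_params <- function(monkey_body_mass_g,
                                reference_body_mass_g = 73700,
                                reference_blood_volume_ml = 5300,
                                y90_half_life_h = 64) {
  vals <- c(monkey_body_mass_g, reference_body_mass_g,
            reference_blood_volume_ml, y90_half_life_h)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    md_stop("all humanization parameters must be > 0", "mirdose_invalid_input")
  }
  structure(list(monkey_body_mass_g = monkey_body_mass_g,
                 reference_body_mass_g = reference_body_mass_g,
                 reference_blood_volume_ml = reference_blood_volume_ml,
                 y90_half_life_h = y90_half_life_h),
            class = "humanization_params")
}

#' Impose 90Y physical decay on a biological retention curve
#'
#' Decay-corrected FIA = FIA x 0.5^(t / half-life). Imaging with a co-counted
#' calibration source yields biological retention; the therapy nuclide's
#' physical decay (64 h for 90Y) is imposed before integration.
#'
#' @param curve `tac` in `fia` or `fia_per_ml` units.
#' @param half_life_h physical half-life in hours (default 64, the value used
#'   for 90Y).
#' @return `tac` with decayed values.
#' @export
apply_y90_decay <- function(curve, half_life_h = 64) {
  stopifnot(is_tac(curve))
  if (!curve$unit %in% c("fia", "fia_per_ml")) {
    md_stop("decay is applied to FIA curves; convert %ID with pid_to_fia()",
            "mirdose_invalid_input")
  }
  tac_update(curve, curve$value * 0.5^(curve$time / half_life_h))
}

#' Convert a %ID (or %ID/mL) curve to FIA units
#'
#' FIA = %ID / 100.
#' @param curve `tac` in `pid`, `pid_per_ml`, or `pid_per_g` units.
#' @return `tac` in `fia` (or `fia_per_ml`) units.
#' @export
pid_to_fia <- function(curve) {
  stopifnot(is_tac(curve))
  unit <- switch(curve$unit,
                 pid = "fia", pid_per_ml = "fia_per_ml", pid_per_g = "fia_per_ml",
                 md_stop("curve is already in FIA units", "mirdose_invalid_input"))
  tac_update(curve, curve$value / 100, unit = unit)
}

#' Humanize and scale a decay-corrected monkey blood FIA/mL curve
#'
#' Humanized FIA/mL = decay-corrected FIA/mL x monkey body mass / reference
#' body mass; humanized max FIA = peak humanized FIA/mL x reference blood
#' volume; scaled FIA/mL = humanized FIA/mL / humanized max FIA. By
#' construction the scaled curve's peak equals 1/reference blood volume per
#' mL, i.e. the scaled curve integrates to a TIAC per unit (max-normalized)
#' administered activity.
#'
#' @param curve decay-corrected `tac` in `fia_per_ml` units.
#' @param params a [humanization_params()].
#' @return scaled `tac` (`fia_per_ml`).
#' @export
humanize_fia <- function(curve, params) {
  stopifnot(is_tac(curve), inherits(params, "humanization_params"))
  if (curve$unit != "fia_per_ml") {
    md_stop("humanize_fia requires an FIA/mL curve", "mirdose_invalid_input")
  }
  humanized <- curve$value * params$monkey_body_mass_g / params$reference_body_mass_g
  max_fia <- max(humanized) * params$reference_blood_volume_ml
  if (!is.finite(max_fia) || max_fia <= 0) {
    md_stop("curve peak is not positive; cannot scale", "mirdose_degenerate_curve")
  }
  tac_update(curve, humanized / max_fia)
}

#' Time-integrated activity coefficient of a curve
#'
#' AUC0-inf of an FIA curve versus time: trapezoid to the last sample plus
#' Clast/lambda_z tail extrapolation, in hours (or h/mL for FIA/mL input).
#' Physical decay must already be imposed on the curve.
#'
#' @param curve `tac` in `fia` or `fia_per_ml` units, >= 3 samples (an
#'   all-zero curve returns 0).
#' @param rule trapezoid rule as in [nca()].
#' @return the TIAC in hours (h/mL for concentration input).
#' @export
tiac_from_curve <- function(curve, rule = "linear") {
  stopifnot(is_tac(curve))
  if (!curve$unit %in% c("fia", "fia_per_ml")) {
    md_stop("tiac_from_curve requires FIA units", "mirdose_invalid_input")
  }
  if (all(curve$value == 0)) return(0)
  if (length(curve$time) < 3L) {
    md_stop("tiac_from_curve needs at least 3 samples", "mirdose_insufficient_data")
  }
  .auc_inf(curve$time, curve$value, rule)$auc_inf
}

#' Red-marrow parameters for the blood-based method
#'
#' @param reference_red_marrow_mass_g reference adult red-marrow mass
#'   (default 1,120 g).
#' @param rmecff red-marrow extracellular fluid fraction (default 0.19).
#' @param hct hematocrit (default 0.47).
#' @return object of class `"red_marrow_params"`.
#' @export
red_marrow_params <- function(reference_red_marrow_mass_g = 1120,
                              rmecff = 0.19, hct = 0.47) {
  if (reference_red_marrow_mass_g <= 0) {
    md_stop("marrow mass must be > 0", "mirdose_invalid_input")
  }
  if (rmecff <= 0 || rmecff >= 1) md_stop("rmecff must be in (0,1)", "mirdose_invalid_input")
  if (hct <= 0 || hct >= 1) md_stop("hct must be in (0,1)", "mirdose_invalid_input")
  structure(list(reference_red_marrow_mass_g = reference_red_marrow_mass_g,
                 rmecff = rmecff, hct = hct), class = "red_marrow_params")
}

#' Blood-based red-marrow TIAC
#'
#' T_red marrow = T_blood/mL x marrow mass x RMECFF / (1 - HCT). With the
#' default constants (1,120 g, 0.19, 0.47) the multiplier is 401.51 mL.
#'
#' @param t_blood_per_ml blood TIAC per mL (h/mL), >= 0.
#' @param params a [red_marrow_params()].
#' @return red-marrow TIAC in hours.
#' @export
red_marrow_tiac <- function(t_blood_per_ml, params = red_marrow_params()) {
  stopifnot(inherits(params, "red_marrow_params"))
  if (any(t_blood_per_ml < 0)) md_stop("blood TIAC must be >= 0", "mirdose_invalid_input")
  t_blood_per_ml * params$reference_red_marrow_mass_g * params$rmecff /
    (1 - params$hct)
}

#' Construct a set of source-region TIACs
#'
#' @param ... named TIAC values in hours (e.g. `red_marrow = 4.1`,
#'   `liver = 9.0`, `whole_body = 57`). All must be >= 0.
#' @param remainder if `NULL` and `whole_body` plus at least one organ are
#'   present, computed with [remainder_tiac()].
#' @return named numeric vector of class `"tiac_set"`.
#' @export
tiac_set <- function(..., remainder = NULL) {
  x <- c(...)
  if (is.null(names(x)) || any(names(x) == "")) {
    md_stop("all TIACs must be named", "mirdose_invalid_input")
  }
  if (any(x < 0)) md_stop("TIACs must be >= 0", "mirdose_invalid_input")
  x <- structure(x, class = "tiac_set")
  if (is.null(remainder) && "whole_body" %in% names(x) &&
      !"remainder" %in% names(x)) {
    remainder <- remainder_tiac(x)
  }
  if (!is.null(remainder)) {
    x <- structure(c(unclass(x), remainder = unname(remainder)), class = "tiac_set")
  }
  x
}

.remainder_organs <- c("heart_contents", "liver", "lungs", "spleen")

#' Remainder-of-body TIAC
#'
#' whole body minus the sum of the imaged source organs (heart contents,
#' liver, lungs, spleen). The blood-derived red marrow TIAC is *not*
#' subtracted: marrow activity is already inside the measured whole body and
#' no double-counting correction is attempted.
#'
#' @param tiacs a [tiac_set()] (or named vector) containing `whole_body`.
#' @return remainder TIAC in hours; errors (`mirdose_inconsistent_tiacs`) if
#'   the organs integrate to more than the whole body.
#' @export
remainder_tiac <- function(tiacs) {
  if (!"whole_body" %in% names(tiacs)) {
    md_stop("whole_body TIAC required to form the remainder", "mirdose_invalid_input")
  }
  organs <- intersect(names(tiacs), .remainder_organs)
  rem <- unname(tiacs[["whole_body"]] - sum(unlist(tiacs[organs])))
  if (rem < 0) {
    md_stop(sprintf("organ TIACs exceed whole body by %.4g h", -rem),
            "mirdose_inconsistent_tiacs")
  }
  rem
}

#' @export
print.tiac_set <- function(x, ...) {
  cat("<tiac_set> (h)\n")
  print(round(unclass(x), 4))
  invisible(x)
}
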