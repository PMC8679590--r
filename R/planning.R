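# Dose planning: dose-limiting organ, maximum administrable activity, and
# interspecies antibody/activity dose conversion.

#' Organ absorbed-dose limits
#'
#' Defaults: 3,000 mGy for red marrow and 20,000 mGy for any other organ.
#'
#' @param red_marrow_mgy red-marrow limit, mGy.
#' @param other_organ_mgy generic limit for every other organ, mGy.
#' @param overrides named numeric vector of per-organ overrides, mGy.
#' @return object of class `"dose_limits"`.
#' @export
dose_limits <- function(red_marrow_mgy = 3000, other_organ_mgy = 20000,
                        overrides = NULL) {
  if (red_marrow_mgy <= 0 || other_organ_mgy <= 0 || any(overrides <= 0)) {
    md_stop("dose limits must be > 0", "mirdose_invalid_input")
  }
  structure(list(red_marrow_mgy = red_marrow_mgy,
                 other_organ_mgy = other_organ_mgy,
                 overrides = overrides), class = "dose_limits")
}

limit_for_organ <- function(organ, limits) {
  if (!is.null(limits$overrides) && organ %in% names(limits$overrides)) {
    return(limits$overrides[[organ]])
  }
  if (organ == "red_marrow") limits$red_marrow_mgy else limits$other_organ_mgy
}

#' Maximum administrable activity and dose-limiting organ
#'
#' For every organ in the dose table the maximum administrable activity is
#' limit(organ) / dose(organ); the dose-limiting organ is the argmin and the
#' reported maximum activity is its value rounded half-up to integer MBq.
#' Organs with `NA` or zero dose are skipped with a warning; organs named in
#' `exclude` keep their per-organ row but do not compete for the limiting
#' role.
#'
#' @param dose_table a [dose_table()] (columns `organ`, `mgy_per_mbq`).
#' @param limits a [dose_limits()].
#' @param exclude organs excluded from the limiting-organ search (e.g.
#'   `c("total_body", "osteogenic_cells")`); default none — with the standard
#'   limits those rows never bind anyway.
#' @param therapeutic_mbq optional therapeutic activity; adds a
#'   [safety_margin()] assessment to the result.
#' @return object of class `"planning_result"`: list with `limiting_organ`,
#'   `max_activity_mbq` (integer-rounded), `table` (organ, dose, limit,
#'   max_mbq, limiting), and optionally `safety`.
#' @export
max_activity <- function(dose_table, limits = dose_limits(),
                         exclude = character(0), therapeutic_mbq = NULL) {
  if (nrow(dose_table) == 0L) md_stop("dose table is empty", "mirdose_invalid_input")
  d <- dose_table$mgy_per_mbq
  skip <- is.na(d) | d <= 0
  if (any(skip)) {
    md_warn(paste0("organ(s) skipped (zero or missing dose): ",
                   paste(dose_table$organ[skip], collapse = ", ")),
            "mirdose_zero_dose")
  }
  organ <- dose_table$organ[!skip]
  d <- d[!skip]
  if (length(d) == 0L) md_stop("no usable dose entries", "mirdose_invalid_input")
  lim <- vapply(organ, limit_for_organ, numeric(1), limits = limits)
  max_raw <- lim / d
  eligible <- !(organ %in% exclude)
  if (!any(eligible)) md_stop("all organs excluded", "mirdose_invalid_input")
  i <- which(eligible)[which.min(max_raw[eligible])]
  tab <- data.frame(organ = organ, mgy_per_mbq = d, limit_mgy = lim,
                    max_mbq = round_half_up(max_raw),
                    limiting = seq_along(organ) == i,
                    stringsAsFactors = FALSE)
  res <- list(limiting_organ = unname(organ[i]),
              max_activity_mbq = unname(round_half_up(max_raw[i])),
              table = tab)
  if (!is.null(therapeutic_mbq)) {
    res$safety <- safety_margin(res$max_activity_mbq, therapeutic_mbq)
  }
  structure(res, class = "planning_result")
}

#' @export
print.planning_result <- function(x, ...) {
  cat(sprintf("<planning> limiting organ: %s; max activity: %d MBq/human\n",
              x$limiting_organ, as.integer(x$max_activity_mbq)))
  print(x$table, row.names = FALSE)
  if (!is.null(x$safety)) {
    cat(sprintf("safety margin vs therapeutic: %.3f (%s)\n", x$safety$ratio,
                if (x$safety$adequate) "adequate" else "INADEQUATE"))
  }
  invisible(x)
}

#' Interspecies scaling constants
#'
#' km factors (body-weight-to-body-surface-area divisors, mg/kg x km =
#' mg/m^2): mouse 3, cynomolgus monkey 12, human 37; reference weights 25 g
#' (mouse) and 60 kg (human); human body surface area 1.89 m^2 (reference
#' adult male, ~73.7 kg / 175 cm) used for activity extrapolation. The
#' 60 kg / km = 37 pairing and the 1.89 m^2 BSA are distinct conventions and
#' are each used only where the corresponding conversion uses them.
#'
#' @param km named numeric vector of km factors.
#' @param reference_weight_kg named numeric vector of reference body weights.
#' @param human_bsa_m2 human body surface area for activity extrapolation.
#' @return object of class `"species_params"`.
#' @export
species_params <- function(km = c(mouse = 3, cynomolgus = 12, human = 37),
                           reference_weight_kg = c(mouse = 0.025, human = 60),
                           human_bsa_m2 = 1.89) {
  if (any(km <= 0) || any(reference_weight_kg <= 0) || human_bsa_m2 <= 0) {
    md_stop("species constants must be > 0", "mirdose_invalid_input")
  }
  structure(list(km = km, reference_weight_kg = reference_weight_kg,
                 human_bsa_m2 = human_bsa_m2), class = "species_params")
}

.km_for <- function(species, params) {
  if (!species %in% names(params$km)) {
    md_stop(sprintf("unknown species '%s' (have: %s)", species,
                    paste(names(params$km), collapse = ", ")),
            "mirdose_config_error")
  }
  params$km[[species]]
}

#' Convert an antibody dose from mg/kg to mg/m^2
#'
#' mg/m^2 = mg/kg x km(species).
#' @param dose_mg_per_kg dose in mg per kg body weight (>= 0, vectorized).
#' @param species species name present in `params$km`.
#' @param params a [species_params()].
#' @return dose in mg/m^2.
#' @export
#' @examples
#' mg_per_kg_to_mg_per_m2(0.4, "cynomolgus") # 4.8
mg_per_kg_to_mg_per_m2 <- function(dose_mg_per_kg, species,
                                   params = species_params()) {
  if (any(dose_mg_per_kg < 0)) md_stop("dose must be >= 0", "mirdose_invalid_input")
  dose_mg_per_kg * .km_for(species, params)
}

#' Convert an antibody dose from mg/m^2 to mg/kg
#'
#' mg/kg = mg/m^2 / km(species). Exact inverse of
#' [mg_per_kg_to_mg_per_m2()].
#' @inheritParams mg_per_kg_to_mg_per_m2
#' @param dose_mg_per_m2 dose in mg per m^2 (>= 0, vectorized).
#' @return dose in mg/kg.
#' @export
#' @examples
#' round(mg_per_m2_to_mg_per_kg(4.8, "human"), 2) # 0.13
mg_per_m2_to_mg_per_kg <- function(dose_mg_per_m2, species,
                                   params = species_params()) {
  if (any(dose_mg_per_m2 < 0)) md_stop("dose must be >= 0", "mirdose_invalid_input")
  dose_mg_per_m2 / .km_for(species, params)
}

#' Convert a BSA dose to a per-animal mouse dose
#'
#' ug/animal = mg/m^2 / km(mouse) x reference mouse weight (kg) x 1000.
#' @param dose_mg_per_m2 dose in mg/m^2 (>= 0, vectorized).
#' @param params a [species_params()].
#' @return dose in micrograms per (25 g reference) mouse.
#' @export
#' @examples
#' mg_per_m2_to_mouse_ug_per_animal(4.8) # 40
mg_per_m2_to_mouse_ug_per_animal <- function(dose_mg_per_m2,
                                             params = species_params()) {
  if (any(dose_mg_per_m2 < 0)) md_stop("dose must be >= 0", "mirdose_invalid_input")
  dose_mg_per_m2 / .km_for("mouse", params) *
    params$reference_weight_kg[["mouse"]] * 1000
}

#' Extrapolate a per-mouse administered activity to the human scale
#'
#' MBq/m^2 = (MBq/animal / reference mouse weight kg) x km(mouse);
#' MBq/human = MBq/m^2 x human BSA. Reported values are rounded half-up to
#' integer MBq; unrounded values are kept in the result.
#'
#' @param mbq_per_animal administered activity per mouse, MBq (>= 0).
#' @param params a [species_params()].
#' @return list with `mbq_per_m2`, `mbq_per_human` (integer-rounded) and
#'   `raw` (both unrounded).
#' @export
#' @examples
#' mouse_activity_to_human(7.4) # 888 MBq/m2, 1678 MBq/human
mouse_activity_to_human <- function(mbq_per_animal, params = species_params()) {
  if (any(mbq_per_animal < 0)) md_stop("activity must be >= 0", "mirdose_invalid_input")
  per_m2 <- mbq_per_animal / params$reference_weight_kg[["mouse"]] *
    .km_for("mouse", params)
  per_human <- per_m2 * params$human_bsa_m2
  list(mbq_per_m2 = round_half_up(per_m2),
       mbq_per_human = round_half_up(per_human),
       raw = c(mbq_per_m2 = per_m2, mbq_per_human = per_human))
}

#' Safety margin of a planned activity
#'
#' @param max_activity_mbq maximum administrable activity, MBq.
#' @param therapeutic_mbq required therapeutic activity, MBq (> 0).
#' @param threshold ratio below which the margin is flagged inadequate
#'   (default 1.0).
#' @return list with `ratio` and logical `adequate`.
#' @export
safety_margin <- function(max_activity_mbq, therapeutic_mbq, threshold = 1.0) {
  if (therapeutic_mbq <= 0) {
    md_stop("therapeutic activity must be > 0", "mirdose_invalid_input")
  }
  ratio <- max_activity_mbq / therapeutic_mbq
  list(ratio = ratio, adequate = ratio >= threshold)
}
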