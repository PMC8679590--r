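# Packaged fixtures: the study's printed summary tables and default JSON
# configs, shipped so every table-derived check runs offline.

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "mirdose")
  if (p == "") md_stop(sprintf("fixture '%s' not found", file),
                       "mirdose_config_error")
  p
}

#' Read a packaged fixture table
#'
#' Available fixtures from the published FF-21101 preclinical program:
#' `serum_stability` (percent intact conjugate in human serum over 96 h),
#' `mouse_pk` (normal-mouse blood NCA parameters), `monkey_pk` (cynomolgus
#' blood NCA parameters per antibody dose), `human_dose` (projected human
#' organ doses, mGy/MBq, per antibody dose), `antibody_dose` (interspecies
#' antibody-dose correspondence on a body-surface-area basis), `planning`
#' (dose-limiting organ and maximum activity per antibody dose).
#'
#' @param name fixture name.
#' @return data frame.
#' @export
ff21101_fixture <- function(name = c("serum_stability", "mouse_pk", "monkey_pk",
                                     "human_dose", "antibody_dose", "planning")) {
  name <- match.arg(name)
  file <- switch(name,
                 serum_stability = "serum_stability.csv",
                 mouse_pk = "mouse_pk.csv",
                 monkey_pk = "monkey_pk.csv",
                 human_dose = "human_dose_mgy_per_mbq.csv",
                 antibody_dose = "antibody_dose_bsa.csv",
                 planning = "planning_reference.csv")
  utils::read.csv(fixture_path(file), stringsAsFactors = FALSE)
}

#' Packaged human dose table at one antibody dose
#'
#' The published organ-dose column (mGy/MBq) at a given monkey antibody dose,
#' as a [dose_table()] ready for [max_activity()]. These values come from a
#' full phantom photon/beta dosimetry code and serve as *planning inputs*;
#' the simplified pure-beta engine in this package does not reproduce them.
#'
#' @param antibody_dose_mg_per_kg one of 0.04, 0.4, 4.
#' @return a [dose_table()].
#' @export
ff21101_dose_table <- function(antibody_dose_mg_per_kg = 0.04) {
  df <- ff21101_fixture("human_dose")
  sub <- df[df$antibody_dose_mg_per_kg == antibody_dose_mg_per_kg, ]
  if (nrow(sub) == 0L) {
    md_stop("antibody dose must be one of 0.04, 0.4, 4 mg/kg",
            "mirdose_invalid_input")
  }
  dose_table(sub$organ, sub$mgy_per_mbq,
             label = paste0(antibody_dose_mg_per_kg, " mg/kg"))
}

#' Load a phantom, nuclide, limits, or species config from JSON
#'
#' JSON layouts match the packaged defaults in `inst/extdata`
#' (`phantom_adult_male.json`, `nuclide_y90.json`, `dose_limits.json`,
#' `species_km.json`).
#'
#' @param path JSON file path.
#' @param what one of `"phantom"`, `"nuclide"`, `"limits"`, `"species"`.
#' @return the corresponding parameter object.
#' @export
read_config <- function(path, what = c("phantom", "nuclide", "limits", "species")) {
  what <- match.arg(what)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  switch(what,
    phantom = phantom(unlist(x$organ_masses_g), x$total_body_mass_g,
                      name = if (is.null(x$name)) "custom" else x$name),
    nuclide = nuclide(x$name, x$half_life_h, x$mean_energy_mev),
    limits = dose_limits(x$red_marrow_mgy, x$other_organ_mgy,
                         overrides = if (!is.null(x$overrides)) unlist(x$overrides)),
    species = species_params(unlist(x$km), unlist(x$reference_weight_kg),
                             x$human_bsa_m2))
}
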