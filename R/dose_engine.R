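# Simplified MIRD absorbed-dose engine for a pure beta emitter.
#
# For beta particles the range is millimetric, so the self-absorbed fraction
# is taken as 1 and cross-organ dose as 0; the remainder of body irradiates
# every organ uniformly at Delta x TIAC / total body mass. Bremsstrahlung and
# photon cross-dose are deliberately neglected, so outputs of this engine are
# order-of-magnitude comparable to, but not a reproduction of, a full
# phantom Monte Carlo code.

# Delta: energy emitted per unit time-integrated activity, J/(MBq h)
.delta_j_per_mbq_h <- function(nuclide) {
  nuclide$mean_energy_mev * 1.602e-13 * 3.6e9
}

#' Define a nuclide
#'
#' @param name label.
#' @param half_life_h physical half-life, hours.
#' @param mean_energy_mev mean beta energy emitted per decay, MeV.
#' @return object of class `"nuclide"`.
#' @export
nuclide <- function(name, half_life_h, mean_energy_mev) {
  if (half_life_h <= 0 || mean_energy_mev < 0) {
    md_stop("half-life must be > 0 and mean energy >= 0", "mirdose_invalid_input")
  }
  structure(list(name = name, half_life_h = half_life_h,
                 mean_energy_mev = mean_energy_mev), class = "nuclide")
}

#' Yttrium-90 defaults
#'
#' Half-life 64 h (the value used throughout the dose projections here) and
#' mean beta energy 0.9337 MeV per decay from standard decay data.
#' @return a [nuclide()].
#' @export
y90 <- function() nuclide("90Y", half_life_h = 64, mean_energy_mev = 0.9337)

#' Reference phantom
#'
#' @param organ_masses_g named numeric vector of target-organ masses in grams.
#' @param total_body_mass_g total body mass in grams (default 73,700,
#'   reference adult male).
#' @param name label.
#' @return object of class `"phantom"`.
#' @export
phantom <- function(organ_masses_g, total_body_mass_g = 73700,
                    name = "custom") {
  if (any(organ_masses_g <= 0) || total_body_mass_g <= 0) {
    md_stop("all masses must be > 0", "mirdose_invalid_input")
  }
  if (sum(organ_masses_g) >= total_body_mass_g) {
    md_stop("organ masses must sum to less than total body mass",
            "mirdose_invalid_input")
  }
  structure(list(organ_masses_g = organ_masses_g,
                 total_body_mass_g = total_body_mass_g, name = name),
            class = "phantom")
}

#' Reference adult male phantom masses
#'
#' Target-organ masses (g) of the hermaphrodite/adult-male mathematical
#' phantom family used by the standard internal-dosimetry codes: heart wall
#' 316, liver 1,910, lungs 1,000, spleen 183, red marrow 1,120; total body
#' 73,700 g. Editable: pass a modified copy to [absorbed_dose()].
#'
#' @return a [phantom()].
#' @export
adult_male_phantom <- function() {
  phantom(c(heart_wall = 316, liver = 1910, lungs = 1000,
            spleen = 183, red_marrow = 1120),
          total_body_mass_g = 73700, name = "adult_male")
}

#' Self-dose S value for a pure beta emitter
#'
#' S = Delta / m with absorbed fraction 1, where Delta = mean beta energy
#' (MeV) x 1.602e-13 J/MeV x 3.6e9 decays/(MBq h). Returned in
#' mGy/(MBq h).
#'
#' @param nuclide a [nuclide()].
#' @param mass_g target (= source) region mass in grams.
#' @return S value, mGy per MBq h.
#' @export
#' @examples
#' self_dose_s_value(y90(), 1000) # 0.5385
self_dose_s_value <- function(nuclide, mass_g) {
  stopifnot(inherits(nuclide, "nuclide"))
  if (any(!is.finite(mass_g)) || any(mass_g <= 0)) {
    md_stop("mass must be > 0", "mirdose_invalid_input")
  }
  # J/(MBq h) / kg = Gy/(MBq h); x1000 -> mGy
  .delta_j_per_mbq_h(nuclide) / (mass_g / 1000) * 1000
}

#' Absorbed dose table from a TIAC set
#'
#' D(target) = TIAC(target as source) x S_self(target) + TIAC(remainder) x
#' Delta / total body mass (uniform remainder irradiation). The
#' `heart_contents` source deposits its self-dose in the `heart_wall` target
#' via `source_target_map`. Total body dose is the mass-weighted mean dose,
#' Delta x sum(all source TIACs) / total body mass. Osteogenic cells require
#' a skeletal dosimetry model and are reported as `NA` (not computed).
#'
#' @param tiacs a [tiac_set()]; entries other than `whole_body` and
#'   `remainder` are treated as source organs.
#' @param phantom a [phantom()] covering every mapped target organ.
#' @param nuclide a [nuclide()]; default [y90()].
#' @param source_target_map named character vector mapping source-region
#'   names to phantom target names.
#' @return data frame of class `"dose_table"` with columns `organ`,
#'   `mgy_per_mbq`.
#' @export
absorbed_dose <- function(tiacs, phantom = adult_male_phantom(),
                          nuclide = y90(),
                          source_target_map = c(heart_contents = "heart_wall")) {
  stopifnot(inherits(phantom, "phantom"), inherits(nuclide, "nuclide"))
  src <- setdiff(names(tiacs), c("whole_body", "remainder"))
  delta <- .delta_j_per_mbq_h(nuclide)
  rem <- if ("remainder" %in% names(tiacs)) tiacs[["remainder"]] else 0
  uniform <- rem * delta / (phantom$total_body_mass_g / 1000) * 1000 # mGy/MBq
  targets <- vapply(src, function(s) {
    if (s %in% names(source_target_map)) source_target_map[[s]] else s
  }, character(1))
  missing <- setdiff(targets, names(phantom$organ_masses_g))
  if (length(missing)) {
    md_stop(paste0("phantom has no mass for target organ(s): ",
                   paste(missing, collapse = ", ")), "mirdose_config_error")
  }
  doses <- vapply(seq_along(src), function(i) {
    tiacs[[src[i]]] * self_dose_s_value(nuclide, phantom$organ_masses_g[[targets[i]]])
  }, numeric(1)) + uniform
  total_body <- (sum(unlist(tiacs[src])) + rem) * delta /
    (phantom$total_body_mass_g / 1000) * 1000
  df <- data.frame(organ = c(targets, "total_body", "osteogenic_cells"),
                   mgy_per_mbq = c(doses, total_body, NA_real_),
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  class(df) <- c("dose_table", "data.frame")
  df
}

#' Construct a dose table directly
#'
#' @param organ character vector of target organs.
#' @param mgy_per_mbq absorbed dose per unit administered activity, mGy/MBq.
#' @param label optional antibody-dose label carried as an attribute.
#' @return data frame of class `"dose_table"`.
#' @export
dose_table <- function(organ, mgy_per_mbq, label = NULL) {
  if (any(mgy_per_mbq < 0, na.rm = TRUE)) {
    md_stop("doses must be >= 0", "mirdose_invalid_input")
  }
  df <- data.frame(organ = organ, mgy_per_mbq = mgy_per_mbq,
                   stringsAsFactors = FALSE)
  class(df) <- c("dose_table", "data.frame")
  attr(df, "antibody_dose_label") <- label
  df
}
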