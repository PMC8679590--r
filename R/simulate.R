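# Synthetic-data generators. Every generator has an analytic model with a
# machine-readable truth record, so every pipeline stage can be tested both
# noiselessly (tight tolerance) and under a realistic noise model
# (statistical tolerance over seeds).
#
# Noise model: Poisson on raw counts, multiplicative lognormal on continuous
# measurements — the standard behavior of counting instruments.

#' Noise specification for the generators
#'
#' @param counting `"none"` (noiseless, exactly invertible) or `"poisson"`
#'   (counts drawn Poisson at their expectation).
#' @param measurement_cv coefficient of variation of multiplicative lognormal
#'   noise applied to continuous measurements (0 disables).
#' @param background_cpp_mean mean background counts per pixel used by the
#'   planar projector.
#' @return object of class `"noise_spec"`.
#' @export
noise_spec <- function(counting = c("none", "poisson"), measurement_cv = 0,
                       background_cpp_mean = 5) {
  counting <- match.arg(counting)
  if (measurement_cv < 0 || background_cpp_mean < 0) {
    md_stop("noise parameters must be >= 0", "mirdose_invalid_input")
  }
  structure(list(counting = counting, measurement_cv = measurement_cv,
                 background_cpp_mean = background_cpp_mean),
            class = "noise_spec")
}

# lognormal multiplicative noise with cv on the natural scale
.lognoise <- function(x, cv) {
  if (cv <= 0) return(x)
  sdlog <- sqrt(log(1 + cv^2))
  x * stats::rlnorm(length(x), meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Subject specification for kinetic simulation
#'
#' Blood kinetics are biexponential in FIA/mL: A e^(-alpha t) + B e^(-beta t)
#' with alpha > beta > 0. Each organ follows a rise-and-washout shape
#' f (e^(-kw t) - e^(-ku t)) in FIA, and the whole body clears
#' monoexponentially (wb0 e^(-k t)).
#'
#' @param species `"mouse"` or `"monkey"`.
#' @param body_weight_kg body weight, kg.
#' @param blood list with `A`, `alpha`, `B`, `beta` (FIA/mL and 1/h).
#' @param organs named list; each entry a list with uptake fraction `f`,
#'   uptake rate `ku` (1/h), washout rate `kw` (1/h), with `ku > kw`.
#' @param whole_body list with `wb0` (FIA at t = 0) and clearance `k` (1/h);
#'   may be `NULL` for blood-only subjects.
#' @return object of class `"subject_spec"`.
#' @export
subject_spec <- function(species = c("monkey", "mouse"), body_weight_kg,
                         blood, organs = list(), whole_body = NULL) {
  species <- match.arg(species)
  with(blood, {
    if (A < 0 || B < 0 || !(alpha > beta) || beta <= 0) {
      md_stop("blood params need A,B >= 0 and alpha > beta > 0",
              "mirdose_invalid_input")
    }
  })
  if (length(organs)) {
    fs <- vapply(organs, `[[`, numeric(1), "f")
    if (any(fs < 0) || sum(fs) > 1) {
      md_stop("organ uptake fractions must be >= 0 and sum to <= 1",
              "mirdose_invalid_input")
    }
  }
  structure(list(species = species, body_weight_kg = body_weight_kg,
                 blood = blood, organs = organs, whole_body = whole_body),
            class = "subject_spec")
}

#' Default mouse subject
#'
#' Biexponential blood kinetics calibrated so the 5-minute sample is about
#' 35.3 %ID/g (the observed peak for an intact radiolabeled IgG in mice)
#' with a terminal biological half-life of ~260 h.
#' @return a [subject_spec()].
#' @export
default_mouse_spec <- function() {
  subject_spec("mouse", body_weight_kg = 0.025,
               blood = list(A = 0.103, alpha = 1.2, B = 0.26, beta = log(2) / 260))
}

#' Default monkey subject
#'
#' Calibrated so that (noiselessly) the whole body holds ~75 %ID at 3 h
#' falling to ~55 %ID at 168 h, blood peaks near 0.5 %ID/mL, and heart /
#' liver / spleen / lungs sit at roughly 8 / 11 / 3 / 5 %ID at 3 h — the
#' typical slow-clearing IgG picture in a ~3 kg cynomolgus monkey. These are
#' plausibility calibrations of the generator, not estimates of any real
#' animal's kinetics.
#' @return a [subject_spec()].
#' @export
default_monkey_spec <- function() {
  subject_spec("monkey", body_weight_kg = 3.0,
    blood = list(A = 0.0012, alpha = 2.5, B = 0.0040, beta = log(2) / 147),
    organs = list(
      heart  = list(f = 0.082, ku = 2.0, kw = 0.006),
      liver  = list(f = 0.125, ku = 0.8, kw = 0.0025),
      spleen = list(f = 0.033, ku = 0.8, kw = 0.002),
      lungs  = list(f = 0.055, ku = 1.5, kw = 0.006)),
    whole_body = list(wb0 = 0.754, k = 0.00188))
}

# analytic model evaluations ------------------------------------------------

.blood_fia_per_ml <- function(spec, t) {
  with(spec$blood, A * exp(-alpha * t) + B * exp(-beta * t))
}

.organ_fia <- function(org, t) {
  with(org, f * (exp(-kw * t) - exp(-ku * t)))
}

.wb_fia <- function(spec, t) {
  with(spec$whole_body, wb0 * exp(-k * t))
}

# exact integral of c1*exp(-r t) terms over [t0, Inf), with extra decay rate
# lam added to every rate (lam = ln2/64 imposes 90Y physical decay)
.int_exp <- function(coefs, rates, t0, lam = 0) {
  sum(coefs * exp(-(rates + lam) * t0) / (rates + lam))
}

#' Simulate a blood time-activity curve
#'
#' @param spec a [subject_spec()].
#' @param times sampling times, h. Defaults: the dense early-plus-late
#'   venipuncture schedule for monkeys, the 5 min-192 h necropsy schedule for
#'   mice.
#' @param noise a [noise_spec()]; only `measurement_cv` applies here.
#' @return list with `curve` (a `tac`; %ID/mL for monkey, %ID/g for mouse)
#'   and `truth` (analytic `auc_pid_h` over [0, Inf), terminal `t_half_h`,
#'   and the model parameters).
#' @export
gen_blood_curve <- function(spec, times = NULL, noise = noise_spec()) {
  if (is.null(times)) {
    times <- if (spec$species == "monkey") {
      c(0.17, 0.5, 1, 3, 6, 24, 48, 72, 96, 144, 168, 216)
    } else {
      c(5 / 60, 24, 48, 96, 192)
    }
  }
  fia_ml <- .blood_fia_per_ml(spec, times)
  value <- .lognoise(fia_ml * 100, noise$measurement_cv)
  unit <- if (spec$species == "monkey") "pid_per_ml" else "pid_per_g"
  truth <- list(
    auc_pid_h = 100 * with(spec$blood, A / alpha + B / beta),
    t_half_h = log(2) / spec$blood$beta,
    params = spec$blood)
  list(curve = tac(times, value, unit = unit,
                   subject_id = paste0(spec$species, "1"), compartment = "blood"),
       truth = truth)
}

#' Simulate organ and whole-body %ID curves
#'
#' Organ curves follow the rise-and-washout model; the whole body clears
#' monoexponentially. The truth record carries the analytic TIAC of every
#' region under imposed 90Y decay, integrated over `[min(times), Inf)` — the
#' same support the numerical pipeline sees — plus the remainder
#' (whole body minus organs).
#'
#' @param spec a [subject_spec()] with organs and a whole-body model.
#' @param times imaging times, h (default the 3-168 h imaging schedule).
#' @param noise a [noise_spec()]; `measurement_cv` applies.
#' @param y90_half_life_h half-life used in the truth TIACs (64 h).
#' @return list with `curves` (named list of `tac`, unit `pid`, including
#'   `whole_body`) and `truth` (list `tiac_h` per region with imposed decay).
#' @export
gen_organ_curves <- function(spec, times = c(3, 6, 24, 48, 72, 96, 144, 168),
                             noise = noise_spec(), y90_half_life_h = 64) {
  if (is.null(spec$whole_body) || !length(spec$organs)) {
    md_stop("spec needs organs and a whole_body model", "mirdose_invalid_input")
  }
  lam <- log(2) / y90_half_life_h
  t0 <- min(times)
  subject <- paste0(spec$species, "1")
  curves <- lapply(names(spec$organs), function(nm) {
    v <- 100 * .organ_fia(spec$organs[[nm]], times)
    tac(times, .lognoise(v, noise$measurement_cv), unit = "pid",
        subject_id = subject, compartment = nm)
  })
  names(curves) <- names(spec$organs)
  wb <- 100 * .wb_fia(spec, times)
  curves$whole_body <- tac(times, .lognoise(wb, noise$measurement_cv),
                           unit = "pid", subject_id = subject,
                           compartment = "whole_body")
  tiac <- vapply(spec$organs, function(o) {
    .int_exp(c(o$f, -o$f), c(o$kw, o$ku), t0, lam)
  }, numeric(1))
  tiac_wb <- .int_exp(spec$whole_body$wb0, spec$whole_body$k, t0, lam)
  truth <- list(tiac_h = c(as.list(tiac),
                           list(whole_body = tiac_wb,
                                remainder = tiac_wb - sum(tiac))),
                decay_from_h = t0, y90_half_life_h = y90_half_life_h)
  list(curves = curves, truth = truth)
}

#' Project %ID curves into a two-view planar ROI count table
#'
#' Exact inverse of [conjugate_percent_id()] in noiseless mode: each organ's
#' true image-domain net count is %ID/100 x administered count; anterior and
#' posterior views get (1 + asym) and (1 - asym) times the true net so their
#' arithmetic mean is exact; corner-background CPP is added to whole-body and
#' calibration ROIs and body-background CPP to organ ROIs. Under
#' `counting = "poisson"` every ROI count is drawn Poisson at its
#' expectation.
#'
#' @param curves named list of `tac` in `pid` units, containing
#'   `whole_body`.
#' @param calibration_ratio calibration-source / administered activity ratio
#'   (the `std_ratio` the quantifier must be given).
#' @param noise a [noise_spec()]; `background_cpp_mean` sets the corner CPP
#'   (body background is 1.6x that).
#' @param administered_count image-domain counts corresponding to 100 %ID.
#' @param view_asym anterior/posterior asymmetry fraction.
#' @param roi_sizes_px named sizes; defaults provided for the standard
#'   regions.
#' @return data frame in `planar_rois.csv` layout.
#' @export
gen_planar_study <- function(curves, calibration_ratio = 1e-3,
                             noise = noise_spec(), administered_count = 5e6,
                             view_asym = 0.1, roi_sizes_px = NULL) {
  if (!"whole_body" %in% names(curves)) {
    md_stop("curves must include whole_body", "mirdose_invalid_input")
  }
  sizes <- c(whole_body = 20000, calibration_source = 100, heart = 600,
             liver = 1500, spleen = 300, lungs = 900)
  if (!is.null(roi_sizes_px)) sizes[names(roi_sizes_px)] <- roi_sizes_px
  organs <- names(curves)
  for (o in setdiff(organs, names(sizes))) sizes[o] <- 500
  times <- curves[[1]]$time
  subject <- curves[[1]]$subject_id
  bg_cpp <- noise$background_cpp_mean
  body_cpp <- 1.6 * noise$background_cpp_mean
  rows <- list()
  add <- function(tp, vw, lb, count, size) {
    rows[[length(rows) + 1L]] <<- data.frame(
      subject_id = subject, time_h = tp, view = vw, roi_label = lb,
      count = count, size_px = size, stringsAsFactors = FALSE)
  }
  maybe_pois <- function(x) {
    if (noise$counting == "poisson") stats::rpois(length(x), x) else x
  }
  for (tp in times) {
    for (vw in c("anterior", "posterior")) {
      fac <- if (vw == "anterior") 1 + view_asym else 1 - view_asym
      for (i in seq_len(4)) {
        add(tp, vw, "background_corner", maybe_pois(bg_cpp * 2500), 2500)
      }
      for (i in seq_len(8)) {
        add(tp, vw, "body_background", maybe_pois(body_cpp * 100), 100)
      }
      cal_net <- calibration_ratio * administered_count * fac
      add(tp, vw, "calibration_source",
          maybe_pois(cal_net + bg_cpp * sizes[["calibration_source"]]),
          sizes[["calibration_source"]])
      for (o in organs) {
        pid <- curves[[o]]$value[curves[[o]]$time == tp]
        net <- pid / 100 * administered_count * fac
        cpp <- if (o == "whole_body") bg_cpp else body_cpp
        add(tp, vw, o, maybe_pois(net + cpp * sizes[[o]]), sizes[[o]])
      }
    }
  }
  do.call(rbind, rows)
}

#' Simulate a saturation binding assay
#'
#' Concentrations form an `n_steps`-point geometric series (2-fold serial
#' dilution by default) from `top_nm` downward. Total-well counts are
#' specific binding (one-site model) plus a linear nonspecific component;
#' negative-control wells carry the nonspecific component only.
#'
#' @param kd,bmax ground-truth dissociation constant (nM) and maximal
#'   binding (cpm). Defaults: Kd 1.083 nM, Bmax 5,000 cpm.
#' @param top_nm top concentration of the dilution series, nM.
#' @param n_steps,dilution series length and dilution factor.
#' @param noise_cv lognormal CV applied to every well count (0 = noiseless).
#' @param ns_cpm_per_nm slope of the linear nonspecific component.
#' @param replicates wells per type per concentration.
#' @return list with `data` (binding.csv layout: `concentration_nm`,
#'   `well_type`, `counts_cpm`, `replicate`) and `truth` (`kd`, `bmax`).
#' @export
gen_binding_assay <- function(kd = 1.083, bmax = 5000, top_nm = 20,
                              n_steps = 8, dilution = 2, noise_cv = 0,
                              ns_cpm_per_nm = 25, replicates = 2) {
  conc <- top_nm / dilution^(seq_len(n_steps) - 1)
  spec <- one_site_binding(conc, bmax, kd)
  ns <- ns_cpm_per_nm * conc
  rows <- lapply(seq_len(replicates), function(r) {
    rbind(
      data.frame(concentration_nm = conc, well_type = "total",
                 counts_cpm = .lognoise(spec + ns, noise_cv), replicate = r),
      data.frame(concentration_nm = conc, well_type = "nonspecific",
                 counts_cpm = .lognoise(ns, noise_cv), replicate = r))
  })
  list(data = do.call(rbind, rows), truth = list(kd = kd, bmax = bmax))
}

#' Simulate a xenograft tumor study
#'
#' Tumor volumes follow V(t) = V0 [(1 - effect) e^(g t) + effect e^(-d t)]:
#' untreated growth at rate `g`, with a treated fraction `effect` that
#' regresses at rate `d`. `effect = 1` regresses monotonically (no regrowth);
#' `effect = 0` is a control. Volumes get lognormal measurement noise; body
#' weights stay near baseline.
#'
#' @param groups named list; each entry a list with `effect` (0-1) and `n`
#'   (animals). Default: PBS control and a fully effective treatment, n = 6.
#' @param v0_mm3 mean tumor volume at day 0 (default 200 mm^3).
#' @param growth_per_day exponential growth rate of untreated tumor, 1/day.
#' @param regress_per_day regression rate of treated tumor, 1/day.
#' @param days measurement days (twice weekly to day 74 by default).
#' @param baseline_weight_g mean body weight at day 0.
#' @param noise_cv lognormal CV on volumes and weights.
#' @return list with `data` (tumor_log.csv layout: `animal_id`, `group`,
#'   `day`, `long_mm`, `short_mm`, `body_weight_g`) and `truth`.
#' @export
gen_tumor_study <- function(groups = list(control = list(effect = 0, n = 6),
                                          treated = list(effect = 1, n = 6)),
                            v0_mm3 = 200, growth_per_day = 0.07,
                            regress_per_day = 0.1,
                            days = seq(0, 74, by = 3.5),
                            baseline_weight_g = 25, noise_cv = 0.05) {
  rows <- list()
  for (g in names(groups)) {
    eff <- groups[[g]]$effect
    for (a in seq_len(groups[[g]]$n)) {
      v0 <- .lognoise(v0_mm3, noise_cv)
      v <- v0 * ((1 - eff) * exp(growth_per_day * days) +
                   eff * exp(-regress_per_day * days))
      v <- .lognoise(v, noise_cv)
      # caliper split: long = 2x short-equivalent sphere -> L = (4V)^(1/3) etc.
      short <- (v)^(1/3)
      long <- 2 * v / short^2
      bw <- .lognoise(rep(baseline_weight_g, length(days)), noise_cv / 2)
      rows[[length(rows) + 1L]] <- data.frame(
        animal_id = sprintf("%s_%d", g, a), group = g, day = days,
        long_mm = long, short_mm = short, body_weight_g = bw,
        stringsAsFactors = FALSE)
    }
  }
  list(data = do.call(rbind, rows),
       truth = list(v0_mm3 = v0_mm3, growth_per_day = growth_per_day,
                    effects = vapply(groups, `[[`, numeric(1), "effect")))
}

#' Simulate gamma-counter records for a blood curve
#'
#' Inverse of the counting-standard arithmetic: sample counts =
#' %ID/amount-unit / 100 x administered activity x amount.
#'
#' @param curve blood `tac` in %ID/mL or %ID/g units.
#' @param std the study [counting_standard()].
#' @param amount sample volume (mL) or mass (g) per sample.
#' @param noise a [noise_spec()]; `"poisson"` draws integer counts.
#' @return data frame in `gamma_counts.csv` layout.
#' @export
gen_gamma_counts <- function(curve, std, amount = 0.5, noise = noise_spec()) {
  stopifnot(is_tac(curve))
  aa <- administered_activity(std)
  counts <- curve$value / 100 * aa * amount
  if (noise$counting == "poisson") counts <- stats::rpois(length(counts), counts)
  data.frame(subject_id = curve$subject_id, compartment = curve$compartment,
             time_h = curve$time, counts_cpm = counts, amount = amount,
             amount_unit = if (curve$unit == "pid_per_g") "g" else "mL",
             stringsAsFactors = FALSE)
}
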