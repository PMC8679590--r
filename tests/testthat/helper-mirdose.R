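# shared helpers and generators for the test suite

expect_rel <- function(actual, expected, tol) {
  expect_lt(max(abs(actual / expected - 1)), tol)
}

# dense mono-exponential curve over n_halves terminal half-lives
monoexp_tac <- function(c0 = 10, lambda = log(2) / 64, n_halves = 5,
                        dt = 1, unit = "fia") {
  tm <- seq(0, n_halves * log(2) / lambda, by = dt)
  tac(tm, c0 * exp(-lambda * tm), unit = unit)
}

biexp_tac <- function(A, alpha, B, beta, times, unit = "pid_per_ml") {
  tac(times, A * exp(-alpha * times) + B * exp(-beta * times), unit = unit)
}

std_simple <- function() counting_standard(2e5, 1, dilution_factor = 1000,
                                           administered_volume = 2)

# standard noiseless monkey bundle used by several files
monkey_bundle <- function(noise = noise_spec(), ratio = 1e-3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  spec <- default_monkey_spec()
  organs <- gen_organ_curves(spec, noise = noise)
  blood <- gen_blood_curve(spec, noise = noise)
  std <- std_simple()
  list(spec = spec, organs = organs, blood = blood, std = std, ratio = ratio,
       rois = gen_planar_study(organs$curves, calibration_ratio = ratio,
                               noise = noise),
       gamma = gen_gamma_counts(blood$curve, std, noise = noise))
}
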