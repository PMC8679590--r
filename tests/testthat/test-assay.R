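test_that("one-site model: half-saturation, asymptote, worked value", {
  expect_equal(one_site_binding(1.083, 100, 1.083), 50)
  expect_equal(one_site_binding(1e9, 100, 1.083), 100, tolerance = 1e-6)
  expect_equal(one_site_binding(1, 100, 1.083), 48.01, tolerance = 1e-3)
  expect_equal(one_site_binding(0, 100, 1.083), 0)
  expect_error(one_site_binding(1, 100, 0), class = "mirdose_invalid_input")
})

test_that("noiseless synthetic assay recovers Kd/Bmax to 1e-6 relative", {
  ba <- gen_binding_assay(kd = 1.083, bmax = 5000, noise_cv = 0)
  fit <- fit_saturation(ba$data)
  expect_true(fit$converged)
  expect_rel(fit$kd, 1.083, 1e-6)
  expect_rel(fit$bmax, 5000, 1e-6)
  # 90Y conjugate value as truth
  ba2 <- gen_binding_assay(kd = 1.367, bmax = 4200, noise_cv = 0)
  fit2 <- fit_saturation(ba2$data)
  expect_rel(fit2$kd, 1.367, 1e-6)
})

test_that("median Kd error < 10% at 5% noise over 20 seeds", {
  set.seed(55)
  errs <- replicate(20, {
    ba <- gen_binding_assay(kd = 1.083, bmax = 5000, noise_cv = 0.05)
    fit <- fit_saturation(ba$data)
    if (fit$converged) abs(fit$kd / 1.083 - 1) else Inf
  })
  expect_lt(median(errs), 0.10)
})

test_that("fit is scale-equivariant and flags degenerate data", {
  ba <- gen_binding_assay(kd = 2, bmax = 1000, noise_cv = 0)
  sp <- mirdose:::specific_binding(ba$data)
  f1 <- fit_saturation(sp$concentration_nm, sp$bound)
  f2 <- fit_saturation(sp$concentration_nm, sp$bound * 7)
  expect_rel(f2$bmax, 7 * f1$bmax, 1e-6)
  expect_rel(f2$kd, f1$kd, 1e-6)
  flat <- fit_saturation(c(1, 2, 4, 8, 16), rep(100, 5))
  expect_false(flat$converged)
  expect_true(is.na(flat$kd))
})

test_that("Scatchard transform of exact one-site data is a -1/Kd line", {
  kd <- 1.083; bmax <- 5000
  x <- 20 / 2^(0:7)
  bound <- one_site_binding(x, bmax, kd)
  sc <- scatchard(bound, free = x)
  fit <- lm(bound_over_free ~ bound, sc)
  expect_rel(coef(fit)[["bound"]], -1 / kd, 1e-9)
  # bound-axis intercept (where bound/free = 0) equals Bmax
  expect_rel(-coef(fit)[["(Intercept)"]] / coef(fit)[["bound"]], bmax, 1e-9)
  # lm warns about the (intended) essentially perfect fit
  expect_gt(suppressWarnings(summary(fit)$r.squared), 1 - 1e-12)
  expect_error(scatchard(1, 0), class = "mirdose_invalid_input")
})

test_that("stability normalization anchors t = 0 at 100%", {
  expect_equal(stability_normalize(c(0, 3, 24), c(8000, 7752, 7576))[1], 100)
  expect_equal(stability_normalize(c(0, 96), c(10, 5)), c(100, 50))
  # already-normalized packaged series passes through unchanged
  tab <- ff21101_fixture("serum_stability")
  y90 <- tab[tab$agent == "y90_ff21101", ]
  out <- stability_normalize(c(0, y90$time_h), c(100, y90$mean_pct))
  expect_equal(out[-1], y90$mean_pct)
  expect_equal(out[2], 96.9)
  expect_error(stability_normalize(c(3, 24), c(1, 2)),
               class = "mirdose_invalid_input")
})

test_that("tumor volume and humane endpoints", {
  expect_equal(tumor_volume(20, 10), 1000)
  expect_equal(tumor_volume(10, 10), 500)          # sphere-like L = S = r
  expect_equal(tumor_volume(12.4, 5.6), 194.4, tolerance = 1e-3)
  expect_error(tumor_volume(5, 10), class = "mirdose_invalid_input")
  expect_equal(endpoint_check(2600, 25, 25), "euthanize_tumor")  # 2600 mg > 2500 mg
  expect_equal(endpoint_check(100, 19.7, 25), "euthanize_weight") # 79% of baseline
  expect_equal(endpoint_check(2400, 25, 25), "continue")
  # monotone: growing tumor never flips euthanize -> continue
  vols <- seq(2000, 3000, by = 100)
  states <- vapply(vols, endpoint_check, "", body_weight_g = 25,
                   baseline_weight_g = 25)
  first <- match("euthanize_tumor", states)
  expect_true(all(states[first:length(states)] == "euthanize_tumor"))
})
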