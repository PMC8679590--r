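test_that("pure-beta self S value: hand value, inverse mass, zero energy", {
  # Delta (J per MBq h) over 1 kg, in mGy: 0.9337 x 1.602e-13 x 3.6e9 x 1000
  expect_equal(self_dose_s_value(y90(), 1000),
               0.9337 * 1.602e-13 * 3.6e9 * 1000, tolerance = 1e-12)  # 0.5385
  expect_equal(self_dose_s_value(y90(), 500), 2 * self_dose_s_value(y90(), 1000))
  expect_equal(self_dose_s_value(nuclide("x", 10, 0), 100), 0)
  expect_error(self_dose_s_value(y90(), 0), class = "mirdose_invalid_input")
})

test_that("spleen worked example lands at the expected order of magnitude", {
  d <- absorbed_dose(tiac_set(spleen = 4.0))
  ds <- d$mgy_per_mbq[d$organ == "spleen"]
  expect_equal(ds, 4.0 * 0.5384835 * 1000 / 183, tolerance = 1e-4)  # 11.77
  # same order as the published 12.0 mGy/MBq at the lowest antibody dose;
  # agreement is not claimed (no bremsstrahlung / photon cross-dose)
  expect_gt(ds, 12.0 / 2); expect_lt(ds, 12.0 * 2)
})

test_that("dose is linear in TIAC and additive over sources", {
  base <- tiac_set(liver = 3, spleen = 2, red_marrow = 1, remainder = 10)
  d1 <- absorbed_dose(base)
  doubled <- tiac_set(liver = 6, spleen = 2, red_marrow = 1, remainder = 10)
  d2 <- absorbed_dose(doubled)
  liver1 <- d1$mgy_per_mbq[d1$organ == "liver"]
  liver2 <- d2$mgy_per_mbq[d2$organ == "liver"]
  uniform <- 10 * self_dose_s_value(y90(), 73700)
  expect_equal(liver2 - uniform, 2 * (liver1 - uniform), tolerance = 1e-12)
  # only liver changed
  expect_equal(d1$mgy_per_mbq[d1$organ == "spleen"],
               d2$mgy_per_mbq[d2$organ == "spleen"])
  # all-zero TIACs give all-zero doses
  d0 <- absorbed_dose(tiac_set(liver = 0, spleen = 0, remainder = 0))
  expect_true(all(d0$mgy_per_mbq == 0, na.rm = TRUE))
})

test_that("remainder-only source irradiates every organ uniformly", {
  d <- absorbed_dose(tiac_set(liver = 0, spleen = 0, lungs = 0,
                              red_marrow = 0, remainder = 20))
  organs <- d$mgy_per_mbq[!d$organ %in% c("total_body", "osteogenic_cells")]
  expect_true(all(abs(organs - organs[1]) < 1e-12))
  expect_equal(organs[1], 20 * self_dose_s_value(y90(), 73700))
})

test_that("total-body dose is the mass-weighted mean and below the max", {
  ts <- tiac_set(heart_contents = 4.7, liver = 9.1, lungs = 3.2, spleen = 2.5,
                 red_marrow = 4.1, remainder = 38)
  d <- absorbed_dose(ts)
  tb <- d$mgy_per_mbq[d$organ == "total_body"]
  expect_gte(tb, 0)
  expect_lte(tb, max(d$mgy_per_mbq, na.rm = TRUE))
  # mass-weighted identity: sum TIAC * Delta / M
  expect_equal(tb, sum(ts) * self_dose_s_value(y90(), 73700), tolerance = 1e-12)
  # heart_contents deposits in heart_wall; osteogenic cells not computed
  expect_true("heart_wall" %in% d$organ)
  expect_true(is.na(d$mgy_per_mbq[d$organ == "osteogenic_cells"]))
})

test_that("missing phantom mass is a config error", {
  expect_error(absorbed_dose(tiac_set(kidneys = 1)), class = "mirdose_config_error")
  expect_error(phantom(c(liver = 80000)), class = "mirdose_invalid_input")
})

test_that("configs load from packaged JSON", {
  ph <- read_config(system.file("extdata", "phantom_adult_male.json",
                                package = "mirdose"), "phantom")
  expect_equal(ph$organ_masses_g[["spleen"]], 183)
  nk <- read_config(system.file("extdata", "nuclide_y90.json",
                                package = "mirdose"), "nuclide")
  expect_equal(nk$half_life_h, 64)
  lim <- read_config(system.file("extdata", "dose_limits.json",
                                 package = "mirdose"), "limits")
  expect_equal(lim$red_marrow_mgy, 3000)
  sp <- read_config(system.file("extdata", "species_km.json",
                                package = "mirdose"), "species")
  expect_equal(sp$km[["human"]], 37)
})
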