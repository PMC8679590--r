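test_that("90Y decay imposition is pointwise 0.5^(t/64)", {
  cv <- tac(c(0, 64, 128), c(0.8, 0.8, 1.0), "fia")
  d <- apply_y90_decay(cv)
  expect_equal(d$value, c(0.8, 0.4, 0.25))
  expect_error(apply_y90_decay(tac(1, 5, "pid")), class = "mirdose_invalid_input")
})

test_that("humanize_fia forces the 1/5300 peak contract", {
  hp <- humanization_params(monkey_body_mass_g = 3000)
  for (scale in c(1, 17, 0.002)) {
    cv <- tac(c(0.2, 24, 96), scale * c(0.005, 0.003, 0.001), "fia_per_ml")
    sc <- humanize_fia(cv, hp)
    expect_equal(max(sc$value), 1 / 5300, tolerance = 1e-15)
  }
  # monkey mass = reference mass and unit peak: humanized equals input shape
  hp2 <- humanization_params(monkey_body_mass_g = 73700)
  cv <- tac(c(0, 24), c(1 / 5300, 0.5 / 5300), "fia_per_ml")
  expect_equal(humanize_fia(cv, hp2)$value, cv$value, tolerance = 1e-15)
  expect_error(humanize_fia(tac(1, 0, "fia_per_ml"), hp),
               class = "mirdose_degenerate_curve")
})

test_that("hand-computed humanization chain matches to 1e-12", {
  # 3-sample toy curve, worked independently with plain arithmetic
  t <- c(0, 32, 64); pid_ml <- c(0.5, 0.4, 0.3); mass <- 2900
  fia <- pid_ml / 100
  dec <- fia * 0.5^(t / 64)
  hum <- dec * mass / 73700
  expected <- hum / (max(hum) * 5300)
  got <- humanize_fia(apply_y90_decay(pid_to_fia(tac(t, pid_ml, "pid_per_ml"))),
                      humanization_params(mass))
  expect_equal(got$value, expected, tolerance = 1e-12)
})

test_that("TIAC of pure physical decay approaches 64/ln2 and respects the bound", {
  tm <- c(0, 1, seq(8, 480, by = 8))
  cv <- tac(tm, 0.5^(tm / 64), "fia")
  ti <- tiac_from_curve(cv)
  expect_rel(ti, 64 / log(2), 0.01)
  expect_equal(tiac_from_curve(tac(1:5, rep(0, 5), "fia")), 0)
  # property: any max-normalized decay-imposed curve integrates below the bound
  set.seed(7)
  for (i in 1:20) {
    kb <- runif(1, 0.001, 0.05)   # biological clearance on top of decay
    v <- exp(-kb * tm) * 0.5^(tm / 64)
    ti_i <- tiac_from_curve(tac(tm, v / max(v), "fia"))
    expect_lt(ti_i, 64 / log(2) * 1.01)
  }
})

test_that("synthetic organ curves integrate to their analytic TIACs within 2%", {
  og <- gen_organ_curves(default_monkey_spec())
  for (nm in names(og$curves)) {
    f <- apply_y90_decay(pid_to_fia(og$curves[[nm]]))
    expect_rel(tiac_from_curve(f), og$truth$tiac_h[[nm]], 0.02)
  }
})

test_that("blood-based red-marrow TIAC uses the printed constants", {
  expect_equal(red_marrow_tiac(0), 0)
  expect_equal(red_marrow_tiac(1e-3), 0.40151, tolerance = 1e-5)
  expect_equal(red_marrow_tiac(2e-3), 2 * red_marrow_tiac(1e-3))  # linearity
  expect_error(red_marrow_params(hct = 1), class = "mirdose_invalid_input")
  expect_error(red_marrow_tiac(-1), class = "mirdose_invalid_input")
})

test_that("remainder is whole body minus the four imaged organs", {
  ts <- tiac_set(heart_contents = 5, liver = 9, lungs = 3, spleen = 3,
                 red_marrow = 4, whole_body = 50)
  expect_equal(ts[["remainder"]], 30)   # red marrow not subtracted
  expect_error(remainder_tiac(c(heart_contents = 40, liver = 20, whole_body = 50)),
               class = "mirdose_inconsistent_tiacs")
  expect_error(remainder_tiac(c(liver = 1)), class = "mirdose_invalid_input")
  expect_error(tiac_set(liver = -1), class = "mirdose_invalid_input")
})

test_that("end-to-end remainder matches the generator's non-organ integral", {
  og <- gen_organ_curves(default_monkey_spec())
  vals <- vapply(og$curves, function(cv) {
    tiac_from_curve(apply_y90_decay(pid_to_fia(cv)))
  }, numeric(1))
  names(vals)[names(vals) == "heart"] <- "heart_contents"
  ts <- do.call(tiac_set, as.list(vals))
  expect_rel(ts[["remainder"]], og$truth$tiac_h$remainder, 0.02)
})
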