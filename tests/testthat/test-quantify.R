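test_that("administered activity follows the counting-standard arithmetic", {
  expect_equal(administered_activity(counting_standard(1000, 1, 100, 2)), 200000)
  expect_equal(administered_activity(counting_standard(5000, 0.5, 50, 1.5)), 750000)
  # identity: no dilution, administered volume equal to counted volume
  expect_equal(administered_activity(counting_standard(1234, 2, 1, 2)), 1234)
  expect_error(counting_standard(1000, 0, 10, 1), class = "mirdose_invalid_input")
  expect_error(counting_standard(-5, 1, 10, 1), class = "mirdose_invalid_input")
})

test_that("percent_id_per_ml is the definitional ratio and is linear", {
  std <- counting_standard(1000, 1, 100, 2)   # administered = 200,000 cpm
  expect_equal(percent_id_per_ml(2000, 1, std), 1.0)  # 1% of dose in 1 mL
  expect_equal(percent_id_per_ml(0, 1, std), 0)
  # linear in counts, inversely linear in administered activity
  expect_equal(percent_id_per_ml(c(1000, 3000), 1, std),
               c(0.5, 1.5))
  std2 <- counting_standard(2000, 1, 100, 2)  # doubled administered activity
  expect_equal(percent_id_per_ml(2000, 1, std2),
               percent_id_per_ml(2000, 1, std) / 2)
  expect_error(percent_id_per_ml(100, 0, std), class = "mirdose_invalid_input")
})

test_that("noiseless mouse blood generator round-trips through %ID/g", {
  spec <- default_mouse_spec()
  blood <- gen_blood_curve(spec)   # noiseless
  std <- std_simple()
  gc <- gen_gamma_counts(blood$curve, std, amount = 0.3)
  rec <- gamma_counts_to_tac(gc, list(mouse1 = std))[[1]]
  expect_equal(rec$unit, "pid_per_g")
  expect_equal(rec$value, blood$curve$value, tolerance = 1e-12)
  # 5-min sample sits at the calibrated ~35.3 %ID/g peak
  expect_equal(blood$curve$value[1], 35.3, tolerance = 0.01)
})

test_that("background CPP pools counts over pixels (partition invariance)", {
  rois <- data.frame(roi_label = "background_corner",
                     count = c(500), size_px = c(100))
  expect_equal(background_cpp(rois, "background_corner"), 5)
  two <- data.frame(roi_label = "background_corner",
                    count = c(100, 300), size_px = c(50, 50))
  expect_equal(background_cpp(two, "background_corner"), 4)  # 400/100 pooled
  # partition invariance: any split of the same pixels gives the same CPP
  set.seed(42)
  for (i in 1:10) {
    counts <- rpois(6, 50)
    px <- sample(10:60, 6)
    merged <- data.frame(roi_label = "b", count = sum(counts), size_px = sum(px))
    split6 <- data.frame(roi_label = "b", count = counts, size_px = px)
    expect_equal(background_cpp(split6, "b"), background_cpp(merged, "b"))
  }
  zero <- data.frame(roi_label = "b", count = c(0, 0), size_px = c(10, 20))
  expect_equal(background_cpp(zero, "b"), 0)
  expect_error(background_cpp(zero, "missing"),
               class = "mirdose_missing_background")
})

test_that("net ROI counts keep negatives but warn", {
  expect_equal(net_roi_count(1000, 100, 5), 500)
  expect_equal(net_roi_count(400, 100, 0), 400)  # cpp 0 is the identity
  expect_warning(out <- net_roi_count(400, 100, 5),
                 class = "mirdose_negative_net")
  expect_equal(out, -100)
  expect_error(net_roi_count(400, 100, -1), class = "mirdose_invalid_input")
})

test_that("conjugate-view quantification inverts the noiseless projector", {
  b <- monkey_bundle()
  rec <- conjugate_percent_id(b$rois, b$ratio)
  for (nm in names(b$organs$curves)) {
    expect_rel(rec[[nm]]$value, b$organs$curves[[nm]]$value, 1e-9)
  }
  # organ %ID never exceeds whole-body %ID in the noiseless world
  wb <- rec$whole_body$value
  for (nm in setdiff(names(rec), "whole_body")) {
    expect_true(all(rec[[nm]]$value <= wb + 1e-9))
  }
})

test_that("conjugate-view errors are specific", {
  b <- monkey_bundle()
  broken <- b$rois[!(b$rois$time_h == 6 & b$rois$view == "posterior"), ]
  expect_error(conjugate_percent_id(broken, b$ratio),
               class = "mirdose_incomplete_timepoint")
  nocal <- b$rois[b$rois$roi_label != "calibration_source", ]
  expect_error(conjugate_percent_id(nocal, b$ratio),
               class = "mirdose_missing_calibration")
  expect_error(conjugate_percent_id(b$rois, 0), class = "mirdose_invalid_input")
})

test_that("trivial conjugate case: equal views, unit ratio", {
  rois <- do.call(rbind, lapply(c("anterior", "posterior"), function(vw) {
    data.frame(subject_id = "s", time_h = c(3, 3, 3, 3, 3),
               view = vw,
               roi_label = c("background_corner", "body_background",
                             "calibration_source", "whole_body", "liver"),
               count = c(0, 0, 2000, 1500, 300),
               size_px = c(100, 100, 10, 100, 10))
  }))
  rec <- conjugate_percent_id(rois, 1)
  expect_equal(rec$liver$value, 300 / 2000 * 100)
  expect_equal(rec$whole_body$value, 75)
})

test_that("scaled %ID/mL follows the blood-volume normalization", {
  cv <- tac(c(0.17, 24, 48), c(0.5, 0.3, 0.2), "pid_per_ml")
  sc <- scaled_percent_id(cv, body_weight_kg = 3)
  # max %ID = 0.5 * 3 * 65 = 97.5; peak scaled = 0.5/97.5*100
  expect_equal(max(sc$value), 0.5 / 97.5 * 100, tolerance = 1e-12)
  expect_equal(sc$value[1], 0.5128, tolerance = 1e-4)
  # scale invariance
  sc2 <- scaled_percent_id(tac_update <- tac(cv$time, cv$value * 2, "pid_per_ml"), 3)
  expect_equal(sc2$value, sc$value)
  expect_error(scaled_percent_id(tac(1, 0, "pid_per_ml"), 3),
               class = "mirdose_degenerate_curve")
  expect_error(scaled_percent_id(tac(1, 1, "pid"), 3),
               class = "mirdose_invalid_input")
})

test_that("tac validation and CSV round trip", {
  expect_error(tac(c(1, 1), c(1, 2), "pid"), class = "mirdose_invalid_input")
  expect_error(tac(c(-1, 1), c(1, 2), "pid"), class = "mirdose_invalid_input")
  expect_warning(tac(1:3, c(1, -1, 2), "pid"), class = "mirdose_negative_value")
  p <- withr::local_tempfile(fileext = ".csv")
  cur <- list(tac(1:3, c(3, 2, 1), "pid", "s1", "liver"),
              tac(c(0.5, 2), c(9, 4), "pid_per_ml", "s1", "blood"))
  write_tac(cur, p)
  back <- read_tac(p)
  expect_equal(back$s1.liver$value, c(3, 2, 1))
  expect_equal(back$s1.blood$unit, "pid_per_ml")
})
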