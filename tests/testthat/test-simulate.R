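test_that("generators are deterministic under a fixed seed", {
  set.seed(123)
  a <- gen_planar_study(gen_organ_curves(default_monkey_spec(),
                                         noise = noise_spec("poisson"))$curves,
                        noise = noise_spec("poisson"))
  set.seed(123)
  b <- gen_planar_study(gen_organ_curves(default_monkey_spec(),
                                         noise = noise_spec("poisson"))$curves,
                        noise = noise_spec("poisson"))
  expect_identical(a, b)
})

test_that("noiseless blood generator matches its analytic truth", {
  bl <- gen_blood_curve(default_mouse_spec())
  r <- suppressWarnings(nca(bl$curve))
  expect_rel(r$auc_inf, bl$truth$auc_pid_h, 0.02)
  expect_rel(r$t_half, bl$truth$t_half_h, 0.02)
})

test_that("default monkey calibration sits inside the stated bands", {
  og <- gen_organ_curves(default_monkey_spec())
  at <- function(nm, t) og$curves[[nm]]$value[og$curves[[nm]]$time == t]
  expect_gt(at("liver", 3), 10); expect_lt(at("liver", 3), 12)
  expect_gt(at("heart", 3), 7);  expect_lt(at("heart", 3), 9)
  expect_gt(at("spleen", 3), 1); expect_lt(at("spleen", 3), 5)
  expect_gt(at("lungs", 3), 4);  expect_lt(at("lungs", 3), 6)
  expect_gt(at("whole_body", 3), 70); expect_lt(at("whole_body", 3), 80)
  expect_gt(at("whole_body", 168), 50); expect_lt(at("whole_body", 168), 60)
  # organ sum never exceeds the whole body
  organs <- Reduce(`+`, lapply(og$curves[names(og$curves) != "whole_body"],
                               `[[`, "value"))
  expect_true(all(organs <= og$curves$whole_body$value))
})

test_that("Poisson planar noise shrinks like 1/sqrt(administered counts)", {
  set.seed(99)
  spec <- default_monkey_spec()
  curves <- gen_organ_curves(spec)$curves
  rel_err <- function(adm, n = 8) {
    replicate(n, {
      rois <- gen_planar_study(curves, noise = noise_spec("poisson"),
                               administered_count = adm)
      rec <- suppressWarnings(conjugate_percent_id(rois, 1e-3))
      mean(abs(rec$liver$value / curves$liver$value - 1))
    })
  }
  lo <- mean(rel_err(2e5))
  hi <- mean(rel_err(2e7))
  # 100x the counts -> ~10x smaller relative error; allow generous slack
  expect_lt(hi, lo / 3)
})

test_that("binding assay generator: exact geometric series and truth defaults", {
  ba <- gen_binding_assay()
  conc <- sort(unique(ba$data$concentration_nm), decreasing = TRUE)
  expect_equal(length(conc), 8)
  expect_equal(conc, 20 / 2^(0:7))
  expect_equal(ba$truth$kd, 1.083)
})

test_that("tumor generator: control triggers the endpoint, treated never does", {
  set.seed(5)
  ts <- gen_tumor_study(noise_cv = 0)
  d <- ts$data
  d$vol <- tumor_volume(d$long_mm, d$short_mm)
  ctrl <- d[d$group == "control", ]
  state <- mapply(endpoint_check, ctrl$vol, ctrl$body_weight_g,
                  MoreArgs = list(baseline_weight_g = 25))
  expect_true("euthanize_tumor" %in% state)   # exponential growth hits 10% bw
  trt <- d[d$group == "treated", ]
  expect_true(all(diff(trt$vol[trt$animal_id == "treated_1"]) <= 0))
})

test_that("planar projector puts only background in zero-activity organs", {
  curves <- gen_organ_curves(default_monkey_spec())$curves
  curves$cold <- tac(curves[[1]]$time, rep(0, length(curves[[1]]$time)),
                     "pid", compartment = "cold")
  rois <- gen_planar_study(curves)
  cold <- rois[rois$roi_label == "cold", ]
  expect_equal(cold$count, 1.6 * 5 * cold$size_px)  # body-background only
  rec <- conjugate_percent_id(rois, 1e-3)
  expect_equal(rec$cold$value, rep(0, length(curves$cold$time)))
})
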