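test_that("rectification is element-wise absolute value and idempotent", {
  expect_equal(rectify(c(-1, 2, -3)), c(1, 2, 3))
  expect_equal(rectify(rep(0, 5)), rep(0, 5))
  x <- rnorm(100)
  expect_equal(rectify(rectify(x)), rectify(x))
  expect_error(rectify(numeric(0)), "empty")
})

test_that("window_area reproduces closed forms and errors on out-of-trace windows", {
  # constant 1 mV over a 10 ms window -> 10 mV.ms, at two sampling rates
  expect_equal(window_area(rep(1, 401), 1000, 201, c(-10, 0)), 10)
  expect_equal(window_area(rep(1, 801), 2000, 401, c(20, 30)), 10)
  expect_equal(window_area(rep(0, 401), 1000, 201, c(0, 50)), 0)
  # triangular pulse, peak 2 mV, base 10 ms: trapezoid gives the exact 10
  tri <- c(rep(0, 5), seq(0, 2, by = 0.4), seq(1.6, 0, by = -0.4), rep(0, 5))
  expect_equal(window_area(tri, 1000, 6, c(0, 10)), 10)
  # area is linear in amplitude
  expect_equal(window_area(3 * tri, 1000, 6, c(0, 10)), 30)
  expect_error(window_area(rep(1, 100), 1000, 50, c(-200, 0)),
               "window start \\(-200")
  expect_error(window_area(rep(1, 100), 1000, 50, c(0, 500)),
               "window end \\(500")
})

test_that("window_area tracks a rectangle-sum oracle within 1% on random traces", {
  # the two rules differ only in the half-weighted endpoints, so the gap
  # shrinks with the sample count; 1000 window samples keep it well under 1%
  withr::with_seed(42, {
    for (i in 1:100) {
      x <- rnorm(1500, sd = runif(1, 0.1, 2))
      a <- window_area(x, 5000, 1200, c(-200, 0))
      b <- rect_area_oracle(x, 5000, 1200, c(-200, 0))
      expect_lt(abs(a - b) / b, 0.01)
    }
  })
})

test_that("normalized MEP is the area ratio, scale-invariant, and guards zero baselines", {
  tr <- flat_trace(pre_mv = 0.05, mep_mv = 0.125)
  # pre area = 0.05 * 100 ms = 5; mep area = 0.125 * 40 = 5 -> but windows:
  expect_equal(
    normalized_mep(tr, 1000, 201, mep_window = c(20, 60), pre_window = c(-110, -10)),
    (0.125 * 40) / (0.05 * 100)
  )
  # identical windows give exactly 1
  expect_equal(normalized_mep(tr, 1000, 201, c(-60, -20), c(-60, -20)), 1)
  # multiplying the trace leaves the ratio unchanged
  for (c_ in c(0.1, 3, 1000)) {
    expect_equal(normalized_mep(c_ * tr, 1000, 201, c(20, 60), c(-110, -10)),
                 normalized_mep(tr, 1000, 201, c(20, 60), c(-110, -10)))
  }
  # zero pre-trigger baseline -> flagged invalid, not a division blow-up
  expect_warning(
    out <- normalized_mep(flat_trace(0, 1), 1000, 201, c(20, 60), c(-110, -10)),
    "invalid")
  expect_true(is.na(out))
})

test_that("block means average per-trial ratios and ignore trial order", {
  mk <- function(mep_mv, trial) {
    trial_row(flat_trace(0.05, mep_mv), intensity = 120, trial = trial)
  }
  # ratios 1, 2, 3 (mep areas 5, 10, 15 over pre area 5... via mep_mv)
  trials <- dplyr::bind_rows(mk(0.125, 1L), mk(0.25, 2L), mk(0.375, 3L))
  pts <- block_points(trials)
  expect_equal(nrow(pts), 1L)
  expect_equal(pts$response, 2)
  expect_equal(pts$n_trials, 3L)
  # permutation invariance
  pts2 <- block_points(trials[c(3, 1, 2), ])
  expect_equal(pts2$response, pts$response)
  # single trial -> that trial's ratio
  expect_equal(block_points(mk(0.25, 1L))$response, 2)
  # all trials invalid in a block -> error
  bad <- trial_row(flat_trace(0, 1), intensity = 110)
  expect_error(suppressWarnings(block_points(bad)), "all trials invalid")
})

test_that("motor threshold is the lowest intensity meeting the response criterion", {
  mk <- function(intensity, mep_mv) {
    trial_row(flat_trace(0.05, mep_mv), intensity = intensity)
  }
  # responses appear from 120 upward (mep area > pre area + 0.1)
  trials <- dplyr::bind_rows(
    mk(100, 0), mk(110, 0.05), mk(120, 0.2), mk(130, 0.4))
  expect_equal(estimate_motor_threshold(trials), 120)
  # criterion 0 with every trial suprathreshold -> lowest grid intensity
  all_on <- dplyr::bind_rows(mk(100, 0.2), mk(110, 0.3), mk(120, 0.4))
  expect_equal(estimate_motor_threshold(all_on, criterion = 0), 100)
  # all subthreshold -> error advising a wider grid
  off <- dplyr::bind_rows(mk(100, 0), mk(110, 0))
  expect_error(estimate_motor_threshold(off), "widen the intensity grid")
  expect_error(estimate_motor_threshold(mk(100, 1)), ">= 2 intensities")
})

test_that("estimated threshold brackets the generator's true threshold", {
  # the linear-above-threshold response is exactly 0 at 100 %MT, so the
  # lowest criterion-positive grid point is the next one above it; slopes
  # steep enough that one 10 %MT step clears the default criterion
  cfg <- gen_config(n_subjects = 3, seed = 23, emg_noise_sd = 0,
                    slope_scale = 0.2, slope_jitter_sd = 0)
  st <- generate_cohort(cfg)[1, ]
  ses <- generate_emg_session(st, cfg)
  one <- dplyr::filter(ses, hemisphere == "lesioned", leg == "paretic")
  expect_equal(estimate_motor_threshold(one), 110)
})
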