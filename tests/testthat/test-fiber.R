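test_that("breakpoint extraction recovers constructed bilinear traces", {
  t <- seq(0, 1, 0.005)
  y <- pmin(3 * t, 1.8 + 0.5 * (t - 0.6))    # break at t = 0.6, F = 1.8
  bp <- extract_critical_force(tibble::tibble(time_s = t, force_pN = y),
                               c(0, 1))
  expect_identical(bp$flag, "ok")
  expect_equal(bp$F_c, 1.8, tolerance = 0.01)
  expect_equal(bp$breakpoint_time, 0.6, tolerance = 0.01)
  # single-slope trace: no breakpoint
  lin <- extract_critical_force(tibble::tibble(time_s = t, force_pN = 2 * t),
                                c(0, 1))
  expect_identical(lin$flag, "undefined")
  expect_true(is.na(lin$F_c))
})

test_that("breakpoint recovery tolerates 5% noise (median error <= 5%)", {
  set.seed(7)
  t <- seq(0, 1, 0.005)
  clean <- pmin(3 * t, 1.8 + 0.5 * (t - 0.6))
  err <- replicate(100, {
    y <- clean * (1 + rnorm(length(t), 0, 0.05))
    bp <- extract_critical_force(tibble::tibble(time_s = t, force_pN = y),
                                 c(0, 1))
    abs(bp$F_c - 1.8) / 1.8
  })
  expect_lte(median(err, na.rm = TRUE), 0.05)
})

test_that("rise-rate estimator recovers a known exponential", {
  set.seed(3)
  t <- seq(0, 1, 1e-3)
  y <- 50 * (1 - exp(-10 * t)) + rnorm(length(t), 0, 2)
  fit <- crossbridge:::fit_exponential_rise(t, y)
  expect_equal(fit$rate, 10, tolerance = 0.1)
})

test_that("isometric runs produce steady force and zero ramp gives no F_c", {
  p <- fast_params()
  iso <- isometric_force(p, duration = 0.8, n_runs = 2, seed = 5,
                         filament_length = 1.5)
  expect_gt(iso$force_pN, 0)
  expect_gt(iso$rise_rate_s, 0)
  sr0 <- stretch_response(p, protocol_ramp(speed = 0, t_start = 0.4,
                                           t_end = 0.55),
                          n_runs = 2, seed = 6, filament_length = 1.5)
  expect_identical(sr0$flag, "undefined")
  expect_true(is.na(sr0$F_c))
  expect_equal(sr0$isometric_force_pN,
               mean(sr0$trace$force_pN[sr0$trace$time_s > 0.4]),
               tolerance = 0.35)
})

test_that("a stretch ramp produces a fast rise, then a slower phase", {
  # dense ensemble: the stretch response needs a realistic supply of
  # re-attaching heads during the ramp
  p <- default_parameters()
  sr <- stretch_response(p, protocol_ramp(2500, 0.8, 0.95), n_runs = 4,
                         seed = 8, filament_length = 1)
  # the fast phase drives force clearly above the isometric level
  ramp <- sr$trace$force_pN[sr$trace$time_s >= 0.8 &
                            sr$trace$time_s <= 0.95]
  expect_gt(max(ramp), 1.15 * sr$isometric_force_pN)
  # and the stretched ensemble keeps bearing force through the ramp
  expect_gt(mean(ramp), 0.85 * sr$isometric_force_pN)
  # the breakpoint, when defined, lies inside the ramp window
  if (sr$flag == "ok") {
    expect_gte(sr$breakpoint_time, 0.8)
    expect_lte(sr$breakpoint_time, 0.95)
    expect_gte(sr$F_c, 0.95 * sr$isometric_force_pN)
  }
})

test_that("raising [Pi] depresses force more than velocity", {
  p <- fast_params()
  tab <- force_and_velocity_vs_pi(p, pi_series = c(0.5, 8), n_runs = 2,
                                  seed = 9, filament_length = 1.5,
                                  duration = 0.15)
  expect_equal(tab$force_fraction[1], 1)
  expect_lt(tab$force_fraction[2], tab$velocity_fraction[2])
})
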