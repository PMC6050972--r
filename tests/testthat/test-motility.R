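test_that("velocity-length tables have the expected shape and plateau", {
  p <- fast_params()
  vl <- velocity_vs_length(p, c(1, 5, 10), n_runs = 2, seed = 1,
                           duration = 0.15)
  expect_equal(nrow(vl), 3)
  expect_true(all(vl$mean_velocity_um_s >= 0))
  expect_true(all(vl$se_um_s > 0))
  # approximately length-independent above ~5 um
  expect_lt(abs(vl$mean_velocity_um_s[3] / vl$mean_velocity_um_s[2] - 1),
            0.25)
  # short filaments are slower (propelled by few motors at a time)
  expect_lt(vl$mean_velocity_um_s[1], vl$mean_velocity_um_s[3])
  expect_error(velocity_vs_length(p, c(-1, 5)), "lengths")
})

test_that("fractional velocity vs blebbistatin is self-normalized and monotone", {
  p <- fast_params()
  fb <- fractional_velocity_vs_bleb(p, "reduce_kPplus",
                                    bleb_series = c(0, 2, 30),
                                    filament_length = 5, n_runs = 2,
                                    seed = 2, duration = 0.15)
  expect_equal(fb$fraction[fb$bleb_uM == 0], 1)
  # monotone non-increasing within SE
  expect_true(all(diff(fb$fraction) < 3 * fb$se_fraction[-1]))
  # saturating blebbistatin: velocity plateaus above zero
  expect_gt(fb$fraction[fb$bleb_uM == 30], 0)
  expect_error(fractional_velocity_vs_bleb(p, bleb_series = c(1, 5)),
               "include")
})

test_that("duty-ratio fitting recovers a generated curve and flags plateaus", {
  # self-consistency on a curve generated from the fitted law
  N <- c(5, 10, 20, 40, 80, 160)
  f_true <- 0.05
  v <- 10 * (1 - (1 - f_true)^N)
  tab <- tibble::tibble(filament_length_um = N / 12,
                        mean_velocity_um_s = v)
  fit <- fit_duty_ratio(tab, density = 12)
  expect_equal(fit$f, f_true, tolerance = 1e-6)
  expect_identical(fit$flag, "ok")
  # plateau-only data cannot constrain the duty ratio
  tabp <- tibble::tibble(filament_length_um = c(5, 10, 15, 20),
                         mean_velocity_um_s = rep(10, 4))
  expect_identical(fit_duty_ratio(tabp, density = 12)$flag,
                   "non_identifiable")
})

test_that("velocity vs MgATP vanishes at zero ATP and fits a hyperbola", {
  p <- fast_params()
  # without ATP there is no detachment pathway from rigor: no sliding
  tr <- simulate_ensemble(init_ensemble(2, set_parameters(p, MgATP = 1e-4),
                                        seed = 3),
                          duration = 0.1)
  v0 <- measure_velocity(tr)$velocity_um_s
  tr1 <- simulate_ensemble(init_ensemble(2, p, seed = 3), duration = 0.1)
  v1 <- measure_velocity(tr1)$velocity_um_s
  expect_lt(v0, 0.25 * v1)
})
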