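test_that("ensemble initialization is reproducible and counts motors", {
  p <- fast_params()
  ens <- init_ensemble(1, p, seed = 7)
  expect_equal(length(ens$anchors), round(p$density * 1))
  expect_true(all(is.na(ens$cst)))
  ens2 <- init_ensemble(1, p, seed = 7)
  expect_identical(ens, ens2)
  expect_error(init_ensemble(0.01, p, seed = 1), "minimum length")
  # three sites per repeat triple the candidate target sites
  expect_equal(init_ensemble(1, p, seed = 1)$spacing * 3,
               init_ensemble(1, set_parameters(p, sites_per_repeat = 1),
                             seed = 1)$spacing)
})

test_that("simulation is deterministic under a fixed seed", {
  p <- fast_params()
  ens <- init_ensemble(2, p, seed = 3)
  set.seed(11); tr1 <- simulate_ensemble(ens, duration = 0.05)
  set.seed(11); tr2 <- simulate_ensemble(ens, duration = 0.05)
  expect_identical(as.data.frame(tr1), as.data.frame(tr2))
})

test_that("clamped filaments never move; detached ensembles exert no force", {
  p <- fast_params()
  ens <- init_ensemble(2, p, seed = 5)
  tr <- simulate_ensemble(ens, protocol_isometric(), duration = 0.05)
  expect_equal(unique(tr$position_nm), 0)
  # an ensemble that can never attach exerts no force and does not move
  p0 <- set_parameters(p, k_w = 0)
  tr0 <- simulate_ensemble(init_ensemble(2, p0, seed = 5),
                           protocol_unloaded(), duration = 0.02)
  expect_equal(unique(tr0$force_pN), 0)
  expect_equal(unique(tr0$position_nm), 0)
})

test_that("force balance is exact after every recorded event", {
  p <- fast_params()
  ens <- init_ensemble(2, p, seed = 9)
  for (load in c(0, 15)) {
    tr <- simulate_ensemble(ens, protocol_isotonic(load), duration = 0.05)
    fin <- attr(tr, "final_ensemble")
    att <- !is.na(fin$cst)
    st <- state_table(p)
    mech <- st$mech[fin$state]
    fb <- att & mech == 2L
    if (any(fb)) {
      x <- fin$cst[fb] + fin$z
      tension <- sum(p$kappa * (x - st$x_min[fin$state[fb]]))
      expect_equal(tension, load, tolerance = 1e-6)
    }
  }
})

test_that("the sampler picks competing reactions with the right frequency", {
  # one motor placed in AM'D_H: two escape routes, the strain-gated
  # forward transition to AMD and the power-stroke reversal to AM*D_L
  p <- fast_params()
  ens <- init_ensemble(1 / 30, p, seed = 2)   # a single motor
  ens$state[1] <- match("AM'D_H", crossbridge:::state_names())
  ens$cst[1] <- 5
  sc <- build_scheme(p)
  k_fwd <- rate(sc, "AM'D_H", "AMD", x = 5)
  k_bwd <- rate(sc, "AM'D_H", "AM*D_L", x = 5)
  p_fwd <- k_fwd / (k_fwd + k_bwd)
  n <- 2000
  set.seed(99)
  hits <- vapply(seq_len(n), function(i) {
    out <- step_ensemble(ens, protocol_isometric(), n_events = 1)
    out$state[1]
  }, integer(1))
  amd <- match("AMD", crossbridge:::state_names())
  phat <- mean(hits == amd)
  expect_lt(abs(phat - p_fwd), 3 * sqrt(p_fwd * (1 - p_fwd) / n))
})

test_that("an ensemble with no possible event is reported as absorbing", {
  p <- set_parameters(fast_params(), k_w = 0, k_plus3 = 0, k_basal = 0,
                      dG_ATP = 30)
  ens <- init_ensemble(1, p, seed = 1)
  expect_error(step_ensemble(ens, n_events = 1), "absorbing")
})

test_that("velocity measurement recovers known slopes", {
  tr <- tibble::tibble(time_s = seq(0, 1, 1e-3),
                       position_nm = -5000 * seq(0, 1, 1e-3))
  class(tr) <- c("xb_trace", class(tr))
  v <- measure_velocity(tr)
  expect_equal(v$velocity_um_s, 5, tolerance = 1e-10)
  # white noise around a known slope: recovered within the bootstrap CI
  # in at least 90% of replicates
  set.seed(1)
  ok <- replicate(100, {
    t <- seq(0, 1, 1e-3)
    trn <- tibble::tibble(time_s = t,
                          position_nm = -3000 * t + rnorm(length(t), 0, 20))
    vn <- measure_velocity(trn)
    abs(vn$velocity_um_s - 3) < 2.6 * vn$se_um_s
  })
  expect_gte(mean(ok), 0.9)
  expect_error(measure_velocity(tr, discard = 2), "discard")
})

test_that("strain-free reduced scheme matches the ODE solver within 3 SE", {
  p <- strain_free_params()
  # one motor with exactly one reachable site: the engine then realizes
  # the same Markov chain as the solution-mode generator
  ens <- init_ensemble(1/30, p, seed = 4)
  ens$anchors <- 500
  ens$phase <- (500 + p$x_pre) %% ens$spacing  # one site at x = x_pre
  # at K_w [A] = 1 the solution-mode actin shift vanishes and both
  # descriptions share every free-energy difference
  a_eq <- 1 / p$K_w
  tr <- simulate_ensemble(ens, protocol_isometric(), duration = 60,
                          record_dt = 5e-3)
  occ_sim <- trace_occupancy(tr, discard = 2)
  occ_ode <- steady_state(p, a_eq)$probability
  d <- tr[tr$time_s >= 2, grep("^n_", names(tr))]
  for (i in seq_along(occ_ode)) {
    if (occ_ode[i] < 0.02) next
    se <- max(blocked_se(d[[i]]), 1e-3)
    expect_lt(abs(occ_sim[i] - occ_ode[i]), 3 * se)
  }
})
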