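test_that("state table satisfies the structural invariants", {
  st <- state_table(default_parameters())
  expect_equal(nrow(st), 15)
  expect_equal(sum(st$state == "AM"), 1)        # exactly one rigor state
  expect_equal(sum(st$state == "M*T"), 1)       # exactly one ATP state
  expect_identical(st$attached, grepl("^A", st$state))
  expect_true(all(grepl("_bleb$", st$state[st$bleb_bound])))
  expect_false(any(st$state[st$bleb_bound] %in% c("AM", "M*T", "AMD")))
  # AM*DP and AM*D_L share their minimum; the power stroke shifts the
  # AM'D_H minimum relative to AM*D_L
  expect_equal(st$x_min[st$state == "AM*DP"], st$x_min[st$state == "AM*D_L"])
  expect_lt(st$x_min[st$state == "AM'D_H"], st$x_min[st$state == "AM*D_L"])
})

test_that("scheme topology reduces to the base model without blebbistatin", {
  sc <- build_scheme(default_parameters())
  tab <- scheme_table(sc)
  expect_equal(nrow(tab), 17)
  # with [bleb] = 0 every transition into the bleb branch carries rate 0
  r <- transition_rates(sc, x = 5)
  expect_equal(r$forward[r$to == "M**DP_bleb"], 0)
  # blebbistatin on: binding is rapid-equilibrium, release one-way
  scb <- build_scheme(set_parameters(default_parameters(), bleb = 2))
  rb <- transition_rates(scb, x = 5)
  expect_gt(rb$forward[rb$to == "M**DP_bleb"], 0)
  expect_true(is.na(rb$backward[rb$from == "AM'D_H_bleb"]))
})

test_that("detailed balance holds to 1e-9 at every strain on [-15, 15]", {
  for (pars in list(default_parameters(),
                    set_parameters(default_parameters(), bleb = 2, Pi = 2),
                    set_parameters(apply_hypothesis(default_parameters(),
                                                    "reduce_kPplus"),
                                   bleb = 5))) {
    sc <- build_scheme(pars)
    tr <- sc$trans
    for (x in seq(-15, 15, length.out = 50)) {
      rates <- transition_rates(sc, x)
      for (i in which(tr$rev)) {
        dG <- free_energy(sc, tr$to[i], x) - free_energy(sc, tr$from[i], x)
        ratio <- rates$forward[i] / rates$backward[i]
        if (!is.finite(ratio) || rates$forward[i] == 0) next
        expect_equal(ratio, exp(-dG), tolerance = 1e-9)
      }
    }
  }
})

test_that("rates follow the literature constants and functional forms", {
  p <- apply_hypothesis(default_parameters(), "reduce_kPplus")
  sc <- build_scheme(set_parameters(p, bleb = 1), mode = "ensemble")
  # bleb-bound k_P+ transition at the pre-stroke minimum: 1.5 s^-1
  expect_equal(rate(sc, "AM*'DP_bleb", "AM*DP_bleb", x = p$x_pre), 1.5)
  # control amplitude at the minimum: 1000 s^-1
  expect_equal(rate(sc, "AM*'DP", "AM*DP", x = p$x_pre), 1000)
  # hydrolysis is strain-independent (detached states carry no strain)
  expect_equal(rate(sc, "M*T", "M**DP", x = -8), rate(sc, "M*T", "M**DP", x = 8))
  # attachment rate far beyond the capture window is below 1% of its peak
  peak <- rate(sc, "AM**DP", "AM*'DP", x = p$x_pre + p$x_on_shift)
  expect_lt(rate(sc, "AM**DP", "AM*'DP", x = 25), 0.01 * peak)
  # errors: NaN strain and unknown transitions
  expect_error(rate(sc, "AM", "M*T", x = NaN), "finite")
  expect_error(rate(sc, "AM", "AM*DP"), "unknown transition")
})

test_that("parabolic profiles are force-consistent", {
  p <- default_parameters()
  sc <- build_scheme(p)
  x <- seq(-10, 12, length.out = 45)
  h <- 1e-5
  for (s in c("AM*'DP", "AM*D_L", "AM'D_H", "AM")) {
    num <- -(free_energy(sc, s, x + h) - free_energy(sc, s, x - h)) /
      (2 * h) * p$kT     # pN
    xm <- sc$states$x_min[sc$states$state == s]
    expect_equal(num, p$kappa * (xm - x), tolerance = 1e-5)
  }
})
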