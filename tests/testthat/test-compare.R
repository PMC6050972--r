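test_that("SSE scoring matches hand-computed values", {
  model <- tibble::tibble(bleb_uM = c(0, 5, 10), observable = "velocity",
                          value = c(1, 0.6, 0.4))
  ref <- tibble::tibble(bleb_uM = c(0, 5, 10), observable = "velocity",
                        value = c(1, 0.5, 0.5))
  expect_equal(sse_score(model, ref), 0.02)
  expect_equal(sse_score(model, model), 0)
  # linear interpolation onto the reference grid
  ref2 <- tibble::tibble(bleb_uM = 2.5, observable = "velocity", value = 0.8)
  expect_equal(sse_score(model, ref2), 0)
  other <- tibble::tibble(bleb_uM = 1, observable = "F_c", value = 1)
  expect_error(sse_score(model, other), "shared")
})

test_that("reference CSVs round-trip through the reader", {
  ref <- tibble::tibble(bleb_uM = c(0, 5), observable = "velocity",
                        value = c(1, 0.5))
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(ref, f, row.names = FALSE)
  expect_equal(as.data.frame(read_reference_csv(f)), as.data.frame(ref))
  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(x = 1), bad, row.names = FALSE)
  expect_error(read_reference_csv(bad), "columns")
})

test_that("an observable suite is normalized to the zero-bleb control", {
  p <- fast_params()
  suite <- build_suite(p, "reduce_kPplus", bleb_series = c(0, 30), seed = 3,
                       observables = "velocity", n_runs = 2,
                       filament_length = 4, duration_velocity = 0.15,
                       atpase = TRUE)
  fr <- suite$fractions
  expect_equal(fr$value[fr$bleb_uM == 0], 1)
  expect_lt(fr$value[fr$bleb_uM == 30], 1)
  # saturating-blebbistatin ATPase discriminators come along
  expect_gt(suite$atpase$V_max, 0)
  expect_gt(suite$atpase$K_ATPase, 0)
})

test_that("debug-identity perturbation sets reproduce the baseline", {
  p <- fast_params()
  ref <- tibble::tibble(bleb_uM = c(0, 10),
                        observable = "velocity", value = c(1, 0.4))
  scr <- perturbation_screen(p, ref, n_sets = 1, seed = 5,
                             hypotheses = c("reduce_kPplus", "reduce_kon"),
                             bleb_series = c(0, 10),
                             observables = "velocity",
                             n_runs = 1, filament_length = 3,
                             debug_identity = TRUE)
  expect_true(all(unlist(scr$multipliers) == 1))
  expect_true(scr$plausible)
  expect_true(is.finite(scr$sse_reduce_kPplus))
})
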