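test_that("default parameters validate and carry the literature constants", {
  p <- default_parameters()
  expect_s3_class(p, "xb_params")
  expect_equal(p$k_Pplus, 1000)
  expect_equal(p$K_bind, 1)
  expect_equal(p$K_3, 13)
  expect_equal(p$dG_on, 0.7)
  expect_equal(p$d_repeat, 36)
  # 5C regime is slower and colder
  p5 <- default_parameters("5C")
  expect_lt(p5$k_plus3, p$k_plus3)
  expect_lt(p5$kT, p$kT)
  expect_identical(p5$temperature_regime, "5C")
})

test_that("parameter validation rejects broken configurations", {
  p <- default_parameters()
  expect_error(set_parameters(p, kappa = -1), "kappa")
  expect_error(set_parameters(p, K_3 = 0), "equilibrium")
  expect_error(set_parameters(p, MgATP = -0.1), "concentration")
  expect_error(set_parameters(p, nonsense = 1), "unknown")
  expect_error(set_parameters(p, sites_per_repeat = 2), "sites_per_repeat")
  # free-energy budget: reversible-path drop must not exceed dG_ATP
  expect_error(set_parameters(p, G_AM = -40), "budget")
})

test_that("apply_hypothesis modifies exactly the intended block", {
  p <- default_parameters()
  p_none <- apply_hypothesis(p, "none")
  expect_identical(unclass(p_none)[names(p)], unclass(p)[names(p)])
  pk <- apply_hypothesis(p, "reduce_kPplus")
  expect_equal(pk$k_Pplus_bleb, 1.5)
  expect_equal(pk$k_Pplus, 1000)
  same <- setdiff(names(p), c("k_Pplus_bleb", "lambda_P_bleb"))
  expect_identical(unclass(pk)[same], unclass(p)[same])
  pon <- apply_hypothesis(p, "reduce_kon")
  expect_equal(pon$dG_on, -4)
  # the implemented coupling multiplies the k_on amplitude by
  # exp(dG_on - dG_on_ref)
  fac <- crossbridge:::kon_amplitude(set_parameters(pon, kon_scope = "global")) /
    crossbridge:::kon_amplitude(p)
  expect_equal(fac, exp(-4 - 0.7), tolerance = 1e-12)
  pps <- apply_hypothesis(p, "inhibit_power_stroke", power_stroke_factor = 0.2)
  expect_equal(pps$power_stroke_factor, 0.2)
  expect_error(apply_hypothesis(p, "no_such_mechanism"))
})

test_that("effective hydrolysis equilibrium follows K_3 (1 + K_bind [bleb])", {
  p <- default_parameters()
  expect_equal(effective_hydrolysis_equilibrium(p), p$K_3)
  expect_equal(effective_hydrolysis_equilibrium(
    set_parameters(p, K_3 = 13, bleb = 10, K_bind = 1)), 143)
  # monotone increasing in [bleb], no change in K_3 itself
  k <- vapply(c(0, 1, 10, 100), function(b)
    effective_hydrolysis_equilibrium(set_parameters(p, bleb = b)), numeric(1))
  expect_true(all(diff(k) > 0))
})

test_that("parameter tables round-trip through TSV and JSON", {
  p <- default_parameters()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  save_parameters(p, tsv)
  save_parameters(p, js)
  expect_equal(param_hash(load_parameters(tsv)), param_hash(p))
  expect_equal(param_hash(load_parameters(js)), param_hash(p))
  # unknown names and unit mismatches are rejected
  tab <- parameter_table(p)
  tab$name[1] <- "bogus_rate"
  bad <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab, bad, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_parameters(bad), "unknown parameter")
  tab <- parameter_table(p)
  tab$unit[tab$name == "kappa"] <- "N/m"
  write.table(tab, bad, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_parameters(bad), "unit mismatch")
})

test_that("shipped parameter files load to valid sets", {
  files <- list.files(system.file("extdata", package = "crossbridge"),
                      pattern = "^params_.*\\.tsv$", full.names = TRUE)
  expect_gte(length(files), 4)
  for (f in files) {
    p <- load_parameters(f)
    expect_s3_class(validate_parameters(p), "xb_params")
  }
  ctrl <- load_parameters(file.path(dirname(files[1]), "params_control.tsv"))
  expect_equal(ctrl$k_Pplus, 1000)
})
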