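# Pseudo-experimental data generators: noisy observations with the
# statistical structure of motility-assay and fiber measurements, built
# around simulated means so that every estimator and the hypothesis
# comparison are testable without any external data.  Every generator
# attaches a truth manifest (parameters, hypothesis, seed); recovery tests
# compare estimates to the manifest, never to hard-coded numbers.

#' Noise model for the generators
#'
#' Relative (multiplicative) Gaussian noise; experimental confidence
#' intervals in motility/fiber data scale roughly with the mean, which a
#' relative model captures.
#'
#' @param rel_sd Relative standard deviation (default 0.05).
#' @param length_range Log-uniform filament-length range, um.
#' @param n_replicates Observations per condition.
#' @return A noise-model list.
#' @export
noise_model <- function(rel_sd = 0.05, length_range = c(0.5, 20),
                        n_replicates = 3) {
  stopifnot(rel_sd >= 0, all(length_range > 0))
  list(rel_sd = rel_sd, length_range = length_range,
       n_replicates = n_replicates)
}

add_rel_noise <- function(x, rel_sd) {
  if (rel_sd == 0) return(x)
  x * (1 + rnorm(length(x), 0, rel_sd))
}

#' Generate a noisy velocity-vs-length data set
#'
#' Simulated mean velocities at log-spaced filament lengths under the truth
#' parameters/hypothesis, with relative Gaussian noise per observation.
#'
#' @param truth_params Control \code{xb_params} of the truth.
#' @param hypothesis Truth hypothesis (\code{\link{apply_hypothesis}}).
#' @param noise A \code{\link{noise_model}}.
#' @param seed Seed.
#' @param bleb Blebbistatin concentration of the generated condition, uM.
#' @param n_lengths Number of distinct lengths.
#' @param n_runs_mean Stochastic runs behind each simulated mean.
#' @param duration Simulated time per run, s.
#' @return A tibble (filament_length_um, observed_velocity_um_s,
#'   true_mean_um_s); attribute \code{truth} carries the manifest.
#' @export
gen_velocity_length_data <- function(truth_params,
                                     hypothesis = "reduce_kPplus",
                                     noise = noise_model(), seed = 1,
                                     bleb = 0, n_lengths = 6,
                                     n_runs_mean = 3, duration = 0.4) {
  set.seed(seed)
  lengths <- sort(exp(runif(n_lengths, log(noise$length_range[1]),
                            log(noise$length_range[2]))))
  p <- set_parameters(apply_hypothesis(truth_params, hypothesis),
                      bleb = bleb)
  means <- velocity_vs_length(p, lengths, n_runs = n_runs_mean,
                              seed = seed + 1L, duration = duration)
  out <- tidyr::uncount(
    dplyr::select(means, "filament_length_um",
                  true_mean_um_s = "mean_velocity_um_s"),
    noise$n_replicates)
  out$observed_velocity_um_s <- add_rel_noise(out$true_mean_um_s,
                                              noise$rel_sd)
  attr(out, "truth") <- run_manifest(p, "gen_velocity_length", seed,
                                     hypothesis = hypothesis, bleb = bleb,
                                     rel_sd = noise$rel_sd)
  out
}

#' Generate a synthetic concentration-response reference
#'
#' Noisy fractional observables (velocity/force) across a blebbistatin
#' series under the truth hypothesis, in the reference format expected by
#' \code{\link{sse_score}} and \code{\link{perturbation_screen}}.
#'
#' @inheritParams gen_velocity_length_data
#' @param bleb_series Concentrations, uM (0 included).
#' @param observables Subset of \code{c("velocity", "force", "F_c")}.
#' @param ... Problem-size arguments forwarded to \code{\link{build_suite}}.
#' @param file Optional CSV path to also write the reference to.
#' @return Reference tibble (bleb_uM, observable, value) with attribute
#'   \code{truth}.
#' @export
gen_concentration_response <- function(truth_params,
                                       hypothesis = "reduce_kPplus",
                                       bleb_series = c(0, 1, 2, 5, 10),
                                       noise = noise_model(), seed = 1,
                                       observables = c("velocity", "force"),
                                       ..., file = NULL) {
  suite <- build_suite(truth_params, hypothesis, bleb_series,
                       seed = seed + 1L, observables = observables,
                       atpase = FALSE, ...)
  set.seed(seed)
  out <- dplyr::mutate(
    dplyr::select(suite$fractions, "bleb_uM", "observable", "value"),
    value = add_rel_noise(.data$value, noise$rel_sd))
  # the zero-blebbistatin rows are normalization anchors: fraction 1 + noise
  attr(out, "truth") <- run_manifest(truth_params,
                                     "gen_concentration_response", seed,
                                     hypothesis = hypothesis,
                                     bleb_series = bleb_series,
                                     rel_sd = noise$rel_sd)
  if (!is.null(file)) {
    utils::write.csv(out, file, row.names = FALSE)
  }
  out
}

#' Generate a noisy force trace with a stretch ramp
#'
#' @inheritParams gen_velocity_length_data
#' @param protocol A \code{\link{protocol_ramp}}.
#' @param filament_length Ensemble size, um.
#' @param n_runs Runs averaged behind the clean trace.
#' @return A tibble (time_s, clamp_position_nm, force_pN, true_force_pN)
#'   with attribute \code{truth}.
#' @export
gen_force_trace <- function(truth_params, protocol = protocol_ramp(),
                            noise = noise_model(), seed = 1,
                            filament_length = 2, n_runs = 2) {
  sr <- stretch_response(truth_params, protocol, n_runs = n_runs,
                         seed = seed + 1L,
                         filament_length = filament_length)
  set.seed(seed)
  out <- tibble::tibble(
    time_s = sr$trace$time_s,
    clamp_position_nm = sr$trace$position_nm,
    true_force_pN = sr$trace$force_pN,
    force_pN = add_rel_noise(sr$trace$force_pN, noise$rel_sd))
  attr(out, "truth") <- run_manifest(truth_params, protocol, seed,
                                     rel_sd = noise$rel_sd,
                                     F_c_true = sr$F_c,
                                     isometric_true = sr$isometric_force_pN)
  out
}
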