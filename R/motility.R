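# In vitro motility pipeline: velocity vs filament length, velocity vs
# [MgATP] with K_M^v fits, blebbistatin concentration-response of velocity,
# and duty-ratio estimation from velocity-length tables.

one_velocity_run <- function(params, length_um, seed, duration, record_dt) {
  ens <- init_ensemble(length_um, params, seed = seed)
  tr <- simulate_ensemble(ens, protocol_unloaded(), duration = duration,
                          record_dt = record_dt)
  measure_velocity(tr)
}

replicate_velocity <- function(params, length_um, n_runs, seed, duration,
                               record_dt = 1e-3) {
  runs <- purrr::map(seq_len(n_runs), function(r)
    one_velocity_run(params, length_um, seed + 7919L * r, duration,
                     record_dt))
  v <- vapply(runs, function(x) x$velocity_um_s, numeric(1))
  tibble::tibble(mean_velocity_um_s = mean(v),
                 se_um_s = if (n_runs > 1) sd(v) / sqrt(n_runs)
                           else runs[[1]]$se_um_s,
                 n_runs = n_runs)
}

#' Simulated velocity vs filament length
#'
#' Unloaded-sliding velocity of filaments of different lengths, the in
#' vitro motility analogue of velocity-vs-length plots.  Velocity is
#' approximately length-independent above a few um and drops for the
#' shortest filaments, which are propelled by only a few motors at a time.
#'
#' @param params An \code{xb_params} object.
#' @param lengths Filament lengths, um.
#' @param n_runs Replicate stochastic runs per length.
#' @param seed Base seed; run seeds are derived deterministically.
#' @param duration Simulated time per run, s.
#' @return A \code{VelocityTable}: tibble with columns
#'   \code{filament_length_um}, \code{mean_velocity_um_s}, \code{se_um_s},
#'   \code{n_runs}, \code{seed}.
#' @export
velocity_vs_length <- function(params, lengths = c(1, 2, 5, 10, 20),
                               n_runs = 5, seed = 1, duration = 0.5) {
  if (any(lengths <= 0)) stop("lengths must be > 0")
  out <- purrr::map_dfr(lengths, function(L) {
    dplyr::mutate(
      replicate_velocity(params, L, n_runs, seed + round(1000 * L),
                         duration),
      filament_length_um = L, seed = seed, .before = 1)
  })
  attr(out, "manifest") <- run_manifest(params, "velocity_vs_length", seed,
                                        lengths = lengths, n_runs = n_runs,
                                        duration = duration)
  attr(out, "density") <- params$density
  class(out) <- c("xb_velocity_table", class(out))
  out
}

#' Simulated velocity vs [MgATP] with a Michaelis-Menten fit
#'
#' Long (20 um by default) filaments; returns the velocity table together
#' with a hyperbolic fit giving the maximal velocity and the MgATP
#' concentration for half-maximal velocity (K_M^v).
#'
#' @inheritParams velocity_vs_length
#' @param atp_series MgATP concentrations, mM, spanning both sides of the
#'   expected K_M^v.
#' @param filament_length Filament length, um.
#' @return A list with \code{table} (VelocityTable with \code{MgATP_mM}
#'   column) and \code{fit} (a \code{\link{fit_hyperbola}} object).
#' @export
velocity_vs_atp <- function(params,
                            atp_series = c(0.01, 0.02, 0.05, 0.1, 0.25,
                                           0.5, 1, 5),
                            filament_length = 20, n_runs = 5, seed = 1,
                            duration = 0.5) {
  tab <- purrr::map_dfr(seq_along(atp_series), function(i) {
    p <- set_parameters(params, MgATP = atp_series[i])
    dplyr::mutate(
      replicate_velocity(p, filament_length, n_runs, seed + 131L * i,
                         duration),
      MgATP_mM = atp_series[i], seed = seed, .before = 1)
  })
  fit <- fit_hyperbola(tab$MgATP_mM, tab$mean_velocity_um_s)
  attr(tab, "manifest") <- run_manifest(params, "velocity_vs_atp", seed,
                                        atp_series = atp_series,
                                        filament_length = filament_length,
                                        n_runs = n_runs, duration = duration)
  list(table = tab, fit = fit)
}

#' Fractional velocity vs blebbistatin concentration
#'
#' Concentration-response of unloaded sliding velocity under a given
#' blebbistatin mechanism hypothesis, normalized to the zero-blebbistatin
#' reference run of the same series.
#'
#' @inheritParams velocity_vs_length
#' @param hypothesis Passed to \code{\link{apply_hypothesis}}.
#' @param bleb_series Blebbistatin concentrations, uM; must include 0.
#' @param filament_length Filament length, um.
#' @return A tibble with columns \code{bleb_uM}, \code{velocity_um_s},
#'   \code{fraction}, \code{se_fraction}, \code{n_runs}.
#' @export
fractional_velocity_vs_bleb <- function(params, hypothesis = "reduce_kPplus",
                                        bleb_series = c(0, 0.5, 1, 2, 5, 10),
                                        filament_length = 10, n_runs = 5,
                                        seed = 1, duration = 0.5) {
  if (!any(bleb_series == 0))
    stop("bleb_series must include the 0 reference")
  hp <- apply_hypothesis(params, hypothesis)
  tab <- purrr::map_dfr(seq_along(bleb_series), function(i) {
    p <- set_parameters(hp, bleb = bleb_series[i])
    attr(p, "hypothesis") <- hypothesis
    dplyr::mutate(
      replicate_velocity(p, filament_length, n_runs, seed + 277L * i,
                         duration),
      bleb_uM = bleb_series[i], .before = 1)
  })
  ref <- tab$mean_velocity_um_s[tab$bleb_uM == 0][1]
  if (!is.finite(ref) || ref <= 0) stop("reference (bleb = 0) run failed")
  out <- dplyr::mutate(
    dplyr::rename(tab, velocity_um_s = "mean_velocity_um_s"),
    fraction = .data$velocity_um_s / ref,
    se_fraction = .data$se_um_s / ref)
  attr(out, "manifest") <- run_manifest(hp, "fractional_velocity_vs_bleb",
                                        seed, bleb_series = bleb_series,
                                        hypothesis = hypothesis,
                                        n_runs = n_runs)
  class(out) <- c("xb_velocity_table", class(out))
  out
}

#' Duty ratio from a velocity-vs-length table
#'
#' Least-squares fit of \eqn{v(N) = v_{max} (1 - (1 - f)^N)} where N is the
#' number of heads within reach of the filament (motor density times
#' length); f estimates the duty ratio.
#'
#' @param velocity_table Output of \code{\link{velocity_vs_length}}.
#' @param density Motor density, heads/um; defaults to the density recorded
#'   on the table by \code{\link{velocity_vs_length}}.
#' @return A list with \code{f}, \code{v_max}, \code{se_f}, \code{flag}
#'   (\code{"ok"} or \code{"non_identifiable"} when all velocities sit on
#'   the plateau).
#' @export
fit_duty_ratio <- function(velocity_table, density = NULL) {
  tab <- velocity_table
  if (is.null(density))
    density <- attr(velocity_table, "density") %||% 12
  if (nrow(tab) < 4) stop("need velocities at >= 4 motor counts")
  dat <- data.frame(N = density * tab$filament_length_um,
                    v = tab$mean_velocity_um_s)
  # plateau-only data cannot constrain f
  rel_drop <- (max(dat$v) - min(dat$v)) / max(dat$v)
  flag <- "ok"
  fit <- try(minpack.lm::nlsLM(
    v ~ vmax * (1 - (1 - f)^N), data = dat,
    start = list(vmax = max(dat$v), f = 0.05),
    lower = c(1e-9, 1e-6), upper = c(Inf, 1),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error"))
    return(list(f = NA_real_, v_max = NA_real_, se_f = NA_real_,
                flag = "non_identifiable"))
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit)))["f"], error = function(e) NA_real_)
  if (rel_drop < 0.02 || (is.finite(se) && se > est["f"] * 5))
    flag <- "non_identifiable"
  list(f = unname(est["f"]), v_max = unname(est["vmax"]),
       se_f = unname(se), flag = flag)
}

#' @export
autoplot.xb_velocity_table <- function(object, ...) {
  xcol <- intersect(c("filament_length_um", "MgATP_mM", "bleb_uM"),
                    names(object))[1]
  ycol <- intersect(c("mean_velocity_um_s", "velocity_um_s"),
                    names(object))[1]
  ggplot2::ggplot(object, ggplot2::aes(x = .data[[xcol]],
                                       y = .data[[ycol]])) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data[[ycol]] - .data$se_um_s,
      ymax = .data[[ycol]] + .data$se_um_s)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = xcol, y = "velocity (um/s)") +
    ggplot2::theme_minimal()
}
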