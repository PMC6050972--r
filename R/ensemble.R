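# Motor ensembles and the event-driven stochastic simulator: N motors with
# fixed anchor positions interact with the target sites of a rigid actin
# filament (36-nm half-repeat, 1 or 3 sites per repeat).  After every event
# that changes the force-bearing set, the filament position is re-solved in
# closed form (linear elasticity); attached strains shift by exactly the
# common filament displacement.

#' Initialize a motor ensemble
#'
#' Motors are placed uniformly at random along the filament (positions
#' incommensurate with the site lattice via a random lattice phase), all
#' detached in the M*T state.  Reproducible under a fixed seed.
#'
#' @param filament_length Filament length, um.
#' @param params An \code{xb_params} object.
#' @param seed Integer seed (sets R's RNG).
#' @return An object of class \code{xb_ensemble}.
#' @export
init_ensemble <- function(filament_length, params, seed = NULL) {
  if (filament_length <= 0) stop("filament_length must be > 0")
  p <- validate_parameters(params)
  n <- round(p$density * filament_length)
  if (n < 1)
    stop("zero motors: filament shorter than the minimum length ",
         signif(1 / p$density, 3), " um at density ", p$density, " heads/um")
  if (!is.null(seed)) set.seed(seed)
  L_nm <- filament_length * 1000
  spacing <- p$d_repeat / p$sites_per_repeat
  structure(list(
    anchors = sort(runif(n, 0, L_nm)),
    state = rep(1L, n),                    # M*T, 1-based
    cst = rep(NA_real_, n),
    z = 0,
    phase = runif(1, 0, spacing),
    spacing = spacing,
    filament_length = filament_length,
    params = p,
    seed = seed
  ), class = "xb_ensemble")
}

#' @export
print.xb_ensemble <- function(x, ...) {
  cat("<xb_ensemble>", length(x$anchors), "motors on a",
      x$filament_length, "um filament;",
      sum(!is.na(x$cst)), "attached; z =", signif(x$z, 4), "nm\n")
  invisible(x)
}

# site-capture window in x for weak binding / attachment
capture_window <- function(p) {
  centre <- p$x_pre + p$x_on_shift
  c(centre - p$capture_range, centre + p$capture_range)
}

protocol_code <- function(protocol) {
  switch(protocol$type,
         unloaded_sliding = list(mode = 0L, load = 0),
         isotonic = list(mode = 0L, load = protocol$load),
         isometric = list(mode = 1L, load = 0),
         ramp = list(mode = 2L, load = 0),
         stop("unknown protocol type: ", protocol$type))
}

#' Simulation protocols
#'
#' Constructors for the supported mechanical protocols: unloaded sliding
#' (force balance at zero external load), isotonic loading, isometric
#' (filament clamped) and a clamp ramp (stretch when \code{speed} > 0)
#' moving at \code{speed} nm/s between \code{t_start} and \code{t_end}.
#'
#' @param load External load, pN (resisting shortening).
#' @param speed Ramp speed, nm per s (per half-sarcomere in fiber use).
#' @param t_start,t_end Ramp window, s.
#' @return A protocol list understood by \code{\link{simulate_ensemble}}.
#' @export
protocol_unloaded <- function() list(type = "unloaded_sliding")

#' @rdname protocol_unloaded
#' @export
protocol_isotonic <- function(load) list(type = "isotonic", load = load)

#' @rdname protocol_unloaded
#' @export
protocol_isometric <- function() list(type = "isometric")

#' @rdname protocol_unloaded
#' @export
protocol_ramp <- function(speed = 2500, t_start = 4.8, t_end = 4.95)
  list(type = "ramp", speed = speed, t_start = t_start, t_end = t_end)

#' Run the Gillespie simulation of a motor ensemble
#'
#' Event-driven stochastic simulation: one reaction is sampled per step with
#' probability proportional to its propensity, waiting times are exponential
#' in the total propensity, and the filament position is re-solved for force
#' balance after every event that changes the force-bearing set.
#'
#' @param ensemble An \code{xb_ensemble}.
#' @param protocol A protocol from \code{\link{protocol_unloaded}} and
#'   friends.
#' @param duration Simulated time, s.
#' @param record_dt Trace sampling interval, s.
#' @param update_dt Clamp-position update interval during ramps, s.
#' @param max_events Abort threshold; exceeding it raises an error with
#'   guidance to raise rate caps/tolerances.
#' @return A tibble (class \code{xb_trace}) with columns \code{time_s},
#'   \code{position_nm}, \code{force_pN}, \code{atp_turnovers} and one
#'   occupancy-count column \code{n_<state>} per state; attributes carry the
#'   final ensemble and a run manifest.
#' @examples
#' \donttest{
#' ens <- init_ensemble(2, default_parameters(), seed = 1)
#' tr <- simulate_ensemble(ens, protocol_unloaded(), duration = 0.05)
#' measure_velocity(tr)
#' }
#' @export
simulate_ensemble <- function(ensemble, protocol = protocol_unloaded(),
                              duration = 1, record_dt = 1e-3,
                              update_dt = 2e-4, max_events = 1e8) {
  stopifnot(inherits(ensemble, "xb_ensemble"))
  p <- ensemble$params
  scheme <- build_scheme(p, mode = "ensemble")
  cs <- compile_scheme(scheme)
  pc <- protocol_code(protocol)
  win <- capture_window(p)
  res <- xb_simulate_cpp(
    cs$states, cs$trans, cs$kT, cs$kappa, cs$cap, cs$lambda_cut,
    ensemble$anchors, ensemble$state - 1L, ensemble$cst, ensemble$z,
    ensemble$spacing, ensemble$phase, win[1], win[2],
    pc$mode, pc$load,
    if (pc$mode == 2L) protocol$speed else 0,
    if (pc$mode == 2L) protocol$t_start else 0,
    if (pc$mode == 2L) protocol$t_end else 0,
    duration, record_dt, update_dt, max_events, 0L, 0L)
  if (res$exploded)
    stop("event-rate explosion (> ", format(max_events, scientific = TRUE),
         " events projected); raise rate caps/tolerances or shorten the run")
  counts <- res$counts
  colnames(counts) <- paste0("n_", safe_state_names())
  out <- tibble::as_tibble(as.data.frame(counts))
  out <- dplyr::bind_cols(
    tibble::tibble(time_s = res$time, position_nm = res$position,
                   force_pN = res$force, atp_turnovers = res$atp),
    out)
  final <- ensemble
  final$state <- res$final_state + 1L
  final$cst <- res$final_cst
  final$z <- res$final_z
  attr(out, "final_ensemble") <- final
  attr(out, "n_events") <- res$n_events
  attr(out, "absorbed") <- res$absorbed
  attr(out, "manifest") <- run_manifest(p, protocol, ensemble$seed,
                                        duration = duration,
                                        n_motors = length(ensemble$anchors))
  class(out) <- c("xb_trace", class(out))
  out
}

#' Advance an ensemble by a fixed number of Gillespie events
#'
#' Mainly for inspection and statistical tests of the sampler; returns the
#' updated ensemble after \code{n_events} reactions (mechanically
#' re-equilibrated after each).
#'
#' @param ensemble An \code{xb_ensemble}.
#' @param protocol Mechanical protocol.
#' @param n_events Number of reactions to apply.
#' @return The updated \code{xb_ensemble}; attribute \code{elapsed_s} holds
#'   the simulated time span.
#' @export
step_ensemble <- function(ensemble, protocol = protocol_unloaded(),
                          n_events = 1) {
  p <- ensemble$params
  scheme <- build_scheme(p, mode = "ensemble")
  cs <- compile_scheme(scheme)
  pc <- protocol_code(protocol)
  win <- capture_window(p)
  res <- xb_simulate_cpp(
    cs$states, cs$trans, cs$kT, cs$kappa, cs$cap, cs$lambda_cut,
    ensemble$anchors, ensemble$state - 1L, ensemble$cst, ensemble$z,
    ensemble$spacing, ensemble$phase, win[1], win[2],
    pc$mode, pc$load,
    if (pc$mode == 2L) protocol$speed else 0,
    if (pc$mode == 2L) protocol$t_start else 0,
    if (pc$mode == 2L) protocol$t_end else 0,
    1e9, 1e9, 2e-4, 1e9, 0L, as.integer(n_events))
  if (res$n_events < n_events)
    stop("absorbing state: no attached motors and no possible attachment")
  out <- ensemble
  out$state <- res$final_state + 1L
  out$cst <- res$final_cst
  out$z <- res$final_z
  attr(out, "elapsed_s") <- res$final_t
  out
}

#' Sliding velocity from a trace
#'
#' Least-squares slope of filament position vs time after discarding the
#' initial transient; sliding in the shortening direction is reported
#' positive.  The standard error comes from a moving-block bootstrap over
#' time blocks.
#'
#' @param trace An \code{xb_trace}.
#' @param discard Transient to discard, s (default the first 20 percent).
#' @param n_blocks Number of time blocks for the bootstrap.
#' @param n_boot Bootstrap resamples.
#' @return A tibble with \code{velocity_um_s} and \code{se_um_s}.
#' @export
measure_velocity <- function(trace, discard = NULL, n_blocks = 10,
                             n_boot = 200) {
  t_all <- trace$time_s
  if (is.null(discard)) discard <- 0.2 * max(t_all)
  if (max(t_all) <= discard) stop("duration must exceed the discard window")
  keep <- trace[t_all >= discard, ]
  if (nrow(keep) < 10)
    stop("insufficient data: fewer than 10 samples after the discard window")
  slope <- function(d) -coef(lm(position_nm ~ time_s, data = d))[2] / 1000
  v <- unname(slope(keep))
  blocks <- split(seq_len(nrow(keep)),
                  cut(seq_len(nrow(keep)), n_blocks, labels = FALSE))
  bslopes <- vapply(blocks, function(ix) {
    d <- keep[ix, ]
    if (length(unique(d$time_s)) < 2) return(NA_real_)
    unname(slope(d))
  }, numeric(1))
  bslopes <- bslopes[is.finite(bslopes)]
  boot <- replicate(n_boot, mean(sample(bslopes, replace = TRUE)))
  tibble::tibble(velocity_um_s = v, se_um_s = sd(boot))
}

#' @export
autoplot.xb_trace <- function(object, ...) {
  d <- tidyr::pivot_longer(
    dplyr::select(object, "time_s", "position_nm", "force_pN"),
    -"time_s", names_to = "quantity")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}
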