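# Half-sarcomere protocols: one motor ensemble working against a clamp
# (no series compliance, no titin parallel element).  Isometric force and
# its rate of rise, stretch ramps with critical-force extraction, the
# force-velocity relationship, and the [Pi] dependence of force/velocity.

#' Isometric force and its rate of rise
#'
#' Clamped-filament runs from the fully detached state.  Steady force is
#' the time-average after the transient; the rise rate is the rate constant
#' of a single-exponential fit to the force-redevelopment phase of the
#' run-averaged trace.
#'
#' @param params An \code{xb_params} object.
#' @param duration Simulated time per run, s.
#' @param n_runs Replicates.
#' @param seed Base seed.
#' @param filament_length Ensemble size as filament length, um (half-
#'   sarcomere abstraction; forces are reported per ensemble).
#' @param record_dt Trace sampling interval, s.
#' @return A tibble with \code{force_pN}, \code{se_pN}, \code{rise_rate_s},
#'   \code{n_runs}, plus attribute \code{traces}.
#' @export
isometric_force <- function(params, duration = 1.5, n_runs = 3, seed = 1,
                            filament_length = 2, record_dt = 1e-3) {
  traces <- purrr::map(seq_len(n_runs), function(r) {
    ens <- init_ensemble(filament_length, params, seed = seed + 7919L * r)
    simulate_ensemble(ens, protocol_isometric(), duration = duration,
                      record_dt = record_dt)
  })
  tail_means <- vapply(traces, function(tr)
    mean(tr$force_pN[tr$time_s >= 0.5 * duration]), numeric(1))
  favg <- rowMeans(sapply(traces, function(tr) tr$force_pN))
  tavg <- traces[[1]]$time_s
  rise <- tryCatch(fit_exponential_rise(tavg, favg),
                   error = function(e) list(rate = NA_real_))
  # stationarity check on the averaged tail
  tail_ix <- tavg >= 0.5 * duration
  tr_fit <- lm(favg[tail_ix] ~ tavg[tail_ix])
  trend <- coef(summary(tr_fit))[2, ]
  if (is.finite(trend["t value"]) && abs(trend["t value"]) > 2 &&
      abs(trend["Estimate"]) * duration * 0.5 >
        0.1 * max(mean(tail_means), 1e-9))
    warning("non-stationary force tail (trend > 2 SE)")
  out <- tibble::tibble(
    force_pN = mean(tail_means),
    se_pN = if (n_runs > 1) sd(tail_means) / sqrt(n_runs) else NA_real_,
    rise_rate_s = rise$rate,
    n_runs = n_runs)
  attr(out, "traces") <- traces
  attr(out, "manifest") <- run_manifest(params, "isometric", seed,
                                        duration = duration,
                                        filament_length = filament_length)
  out
}

#' Critical force from a stretch trace
#'
#' Two-segment continuous piecewise-linear least-squares fit over the ramp
#' window (grid search over the breakpoint, then local refinement); the
#' critical force F_c is the fitted force at the breakpoint, the analogue
#' of the crossing-lines construction on experimental records.
#'
#' @param force_trace A tibble with columns \code{time_s} and
#'   \code{force_pN} (an \code{xb_trace} works).
#' @param ramp_window Numeric length-2: start and end of the ramp, s.
#' @return A list with \code{F_c}, \code{breakpoint_time}, \code{slopes}
#'   (pre/post), \code{flag} (\code{"ok"} or \code{"undefined"} when no
#'   breakpoint is detectable or it sits at the window edge).
#' @examples
#' tr <- tibble::tibble(time_s = seq(0, 1, 0.01),
#'                      force_pN = pmin(2 * seq(0, 1, 0.01), 0.8 +
#'                                      0.4 * seq(0, 1, 0.01)))
#' extract_critical_force(tr, c(0, 1))$F_c   # 1.5
#' @export
extract_critical_force <- function(force_trace, ramp_window) {
  d <- force_trace[force_trace$time_s >= ramp_window[1] &
                   force_trace$time_s <= ramp_window[2], ]
  if (nrow(d) < 8) stop("trace must cover the ramp window (>= 8 samples)")
  t <- d$time_s; y <- d$force_pN
  rss_at <- function(tb) {
    h <- pmax(t - tb, 0)
    sum(stats::residuals(lm(y ~ t + h))^2)
  }
  span <- range(t)
  # the fast (elastic) phase can occupy a small leading fraction of the
  # ramp, so the breakpoint grid starts close to the window edge
  grid <- seq(span[1] + 0.02 * diff(span), span[2] - 0.05 * diff(span),
              length.out = 60)
  rss <- vapply(grid, rss_at, numeric(1))
  tb0 <- grid[which.min(rss)]
  opt <- optimize(rss_at, interval = c(max(span[1], tb0 - diff(span) / 20),
                                       min(span[2], tb0 + diff(span) / 20)))
  tb <- opt$minimum
  fit <- lm(y ~ t + h, data = data.frame(t = t, h = pmax(t - tb, 0), y = y))
  cf <- coef(fit)
  rss1 <- sum(stats::residuals(lm(y ~ t))^2)
  rss2 <- sum(stats::residuals(fit)^2)
  improvement <- if (rss1 > 1e-12) 1 - rss2 / rss1 else 0
  edge <- (tb - span[1]) < 0.015 * diff(span) ||
          (span[2] - tb) < 0.04 * diff(span)
  flag <- if (edge || improvement < 0.05 || !is.finite(cf[3])) "undefined"
          else "ok"
  Fc <- unname(cf[1] + cf[2] * tb)
  list(F_c = if (flag == "ok") Fc else NA_real_,
       breakpoint_time = if (flag == "ok") tb else NA_real_,
       slopes = c(pre = unname(cf[2]), post = unname(cf[2] + cf[3])),
       flag = flag)
}

#' Stretch response of an active half-sarcomere
#'
#' Isometric contraction followed by a clamp ramp (default 2500 nm per
#' half-sarcomere per s between 4.8 and 4.95 s).  The force response shows
#' a fast elastic rise and a subsequent slower rise; the transition force
#' (critical force F_c) is extracted by the piecewise-linear fit.
#'
#' @inheritParams isometric_force
#' @param protocol A \code{\link{protocol_ramp}}.
#' @return A list of class \code{xb_stretch}: run-averaged \code{trace},
#'   \code{isometric_force_pN} (pre-ramp), \code{F_c}, \code{enhancement}
#'   (F_c minus isometric force), \code{breakpoint_time}, \code{flag}.
#' @export
stretch_response <- function(params, protocol = protocol_ramp(),
                             n_runs = 3, seed = 1, filament_length = 2,
                             record_dt = 5e-4) {
  if (protocol$t_end <= protocol$t_start) stop("t_end must exceed t_start")
  duration <- protocol$t_end + 0.3 * (protocol$t_end - protocol$t_start)
  traces <- purrr::map(seq_len(n_runs), function(r) {
    ens <- init_ensemble(filament_length, params, seed = seed + 7919L * r)
    simulate_ensemble(ens, protocol, duration = duration,
                      record_dt = record_dt)
  })
  favg <- rowMeans(sapply(traces, function(tr) tr$force_pN))
  trace <- tibble::tibble(time_s = traces[[1]]$time_s,
                          position_nm = traces[[1]]$position_nm,
                          force_pN = favg)
  pre <- trace$force_pN[trace$time_s >= 0.6 * protocol$t_start &
                        trace$time_s < protocol$t_start]
  iso <- mean(pre)
  if (protocol$speed <= 0) {
    return(structure(list(trace = trace, isometric_force_pN = iso,
                          F_c = NA_real_, enhancement = NA_real_,
                          breakpoint_time = NA_real_, flag = "undefined"),
                     class = "xb_stretch"))
  }
  bp <- extract_critical_force(trace,
                               c(protocol$t_start, protocol$t_end))
  structure(list(trace = trace, isometric_force_pN = iso,
                 F_c = bp$F_c,
                 enhancement = bp$F_c - iso,
                 breakpoint_time = bp$breakpoint_time,
                 flag = bp$flag,
                 manifest = run_manifest(params, protocol, seed,
                                         n_runs = n_runs,
                                         filament_length = filament_length)),
            class = "xb_stretch")
}

#' @export
print.xb_stretch <- function(x, ...) {
  cat("<xb_stretch> isometric", signif(x$isometric_force_pN, 4), "pN; F_c",
      signif(x$F_c, 4), "pN (", x$flag, ")\n")
  invisible(x)
}

#' @export
autoplot.xb_stretch <- function(object, ...) {
  g <- ggplot2::ggplot(object$trace,
                       ggplot2::aes(x = .data$time_s, y = .data$force_pN)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "force (pN)") +
    ggplot2::theme_minimal()
  if (is.finite(object$F_c))
    g <- g + ggplot2::geom_hline(yintercept = object$F_c,
                                 linetype = "dashed", colour = "red")
  g
}

#' Force-velocity relationship
#'
#' Isotonic runs across a series of loads; velocity is monotone
#' non-increasing with load (within SE), intercepting the velocity axis at
#' the unloaded sliding velocity and the load axis near the isometric
#' force.
#'
#' @inheritParams isometric_force
#' @param loads External loads, pN (per ensemble).  Default: 8 levels from
#'   0 to just above the isotonic stall force.  Under load clamp the
#'   ensemble yields at a stall force below the length-clamped plateau
#'   force (detachment of over-strained bridges cascades once the load is
#'   shared by too few heads), so the stall is located by probing rather
#'   than taken from \code{\link{isometric_force}}.
#' @param duration Simulated time per run, s.
#' @return A tibble with \code{load_pN}, \code{velocity_um_s},
#'   \code{se_um_s}.
#' @export
force_velocity_curve <- function(params, loads = NULL, n_runs = 3, seed = 1,
                                 filament_length = 2, duration = 0.4) {
  if (is.null(loads)) {
    iso <- isometric_force(params, duration = 1, n_runs = 2, seed = seed,
                           filament_length = filament_length)
    stall <- isotonic_stall_force(params, iso$force_pN, seed = seed,
                                  filament_length = filament_length,
                                  duration = duration)
    loads <- seq(0, 1.05 * stall, length.out = 8)
  }
  out <- purrr::map_dfr(seq_along(loads), function(i) {
    vs <- purrr::map_dfr(seq_len(n_runs), function(r) {
      ens <- init_ensemble(filament_length, params,
                          seed = seed + 977L * i + 7919L * r)
      tr <- simulate_ensemble(ens, protocol_isotonic(loads[i]),
                              duration = duration)
      measure_velocity(tr)
    })
    tibble::tibble(load_pN = loads[i],
                   velocity_um_s = mean(vs$velocity_um_s),
                   se_um_s = if (n_runs > 1)
                     sd(vs$velocity_um_s) / sqrt(n_runs)
                   else vs$se_um_s[1])
  })
  attr(out, "manifest") <- run_manifest(params, "force_velocity", seed,
                                        loads = loads, n_runs = n_runs)
  out
}

# locate the isotonic stall load by coarse probing + linear interpolation
# of the sign change of velocity
isotonic_stall_force <- function(params, f_max, seed = 1,
                                 filament_length = 2, duration = 0.3) {
  probe <- function(load) {
    ens <- init_ensemble(filament_length, params,
                         seed = seed + round(load) + 37L)
    tr <- simulate_ensemble(ens, protocol_isotonic(load),
                            duration = duration)
    measure_velocity(tr)$velocity_um_s
  }
  fr <- seq(0.1, 1, by = 0.15) * f_max
  v <- vapply(fr, probe, numeric(1))
  neg <- which(v <= 0)
  if (length(neg) == 0) return(f_max)
  i <- neg[1]
  if (i == 1) return(fr[1])
  # linear interpolation of the zero crossing
  fr[i - 1] + (fr[i] - fr[i - 1]) * v[i - 1] / (v[i - 1] - v[i])
}

#' Isometric force and sliding velocity vs [Pi]
#'
#' Raising inorganic phosphate depresses isometric force substantially more
#' (fractionally) than unloaded sliding velocity, because Pi rebinding
#' reverses force-generating attachments while velocity is detachment-
#' limited.
#'
#' @inheritParams isometric_force
#' @param pi_series Phosphate concentrations, mM; must include the lowest
#'   reference value.
#' @param duration Simulated time per velocity run, s.
#' @return A tibble with \code{Pi_mM}, \code{force_pN}, \code{velocity_um_s}
#'   and their fractions relative to the first row.
#' @export
force_and_velocity_vs_pi <- function(params, pi_series = c(0.5, 2, 5, 10),
                                     n_runs = 3, seed = 1,
                                     filament_length = 2, duration = 0.4) {
  out <- purrr::map_dfr(seq_along(pi_series), function(i) {
    p <- set_parameters(params, Pi = pi_series[i])
    iso <- isometric_force(p, duration = 1, n_runs = n_runs,
                           seed = seed + 13L * i,
                           filament_length = filament_length)
    vel <- replicate_velocity(p, 10, n_runs, seed + 29L * i, duration)
    tibble::tibble(Pi_mM = pi_series[i], force_pN = iso$force_pN,
                   velocity_um_s = vel$mean_velocity_um_s)
  })
  dplyr::mutate(out,
                force_fraction = .data$force_pN / .data$force_pN[1],
                velocity_fraction = .data$velocity_um_s /
                  .data$velocity_um_s[1])
}
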