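# Hypothesis comparison: assemble the normalized observable suite
# (fractional velocity, isometric force and critical force across a
# blebbistatin series, plus the saturating-blebbistatin ATPase
# Michaelis-Menten constants), score against reference data by sum of
# squared errors, and run the +/-25 percent parameter-perturbation screen.

#' Observable suite for one blebbistatin hypothesis
#'
#' All observables are computed from the same parameter set and normalized
#' to the zero-blebbistatin control (fractions equal 1 at bleb = 0 by
#' construction of the velocity/force references).
#'
#' @param params Control \code{xb_params}.
#' @param hypothesis Passed to \code{\link{apply_hypothesis}}.
#' @param bleb_series Blebbistatin concentrations, uM; must include 0.
#' @param seed Base seed.
#' @param observables Which fractional observables to simulate: subset of
#'   \code{c("velocity", "force", "F_c")}.
#' @param n_runs,filament_length,duration_velocity,duration_force Problem
#'   sizes for the stochastic runs.
#' @param stretch_protocol Ramp protocol used for F_c (a compressed
#'   pre-stretch window keeps suites affordable; the ramp speed is the
#'   standard 2500 nm/s).
#' @param atpase Also compute saturating-blebbistatin ATPase V_max and
#'   K_ATPase (solution mode, deterministic).
#' @return An object of class \code{xb_suite}: list with \code{fractions}
#'   (tibble bleb_uM x observable), \code{atpase} (hyperbolic fit summary or
#'   NULL), \code{hypothesis}, \code{param_hash}, \code{partial} flag.
#' @export
build_suite <- function(params, hypothesis = "reduce_kPplus",
                        bleb_series = c(0, 1, 2, 5, 10), seed = 1,
                        observables = c("velocity", "force"),
                        n_runs = 3, filament_length = 5,
                        duration_velocity = 0.4, duration_force = 1,
                        stretch_protocol = protocol_ramp(2500, 1.2, 1.35),
                        atpase = TRUE) {
  if (!any(bleb_series == 0)) stop("bleb_series must include 0")
  observables <- match.arg(observables, c("velocity", "force", "F_c"),
                           several.ok = TRUE)
  hp <- apply_hypothesis(params, hypothesis)
  partial <- FALSE
  rows <- list()
  safe <- function(expr) tryCatch(expr, error = function(e) {
    partial <<- TRUE; NA_real_
  })
  for (obs in observables) {
    vals <- ses <- numeric(length(bleb_series))
    for (i in seq_along(bleb_series)) {
      p <- set_parameters(hp, bleb = bleb_series[i])
      if (obs == "velocity") {
        r <- safe(replicate_velocity(p, filament_length, n_runs,
                                     seed + 101L * i, duration_velocity))
        vals[i] <- if (is.list(r)) r$mean_velocity_um_s else r
        ses[i] <- if (is.list(r)) r$se_um_s else NA_real_
      } else if (obs == "force") {
        r <- safe(isometric_force(p, duration = duration_force,
                                  n_runs = n_runs, seed = seed + 211L * i,
                                  filament_length = filament_length / 2))
        vals[i] <- if (is.list(r)) r$force_pN else r
        ses[i] <- if (is.list(r)) r$se_pN else NA_real_
      } else {
        r <- safe(stretch_response(p, stretch_protocol, n_runs = n_runs,
                                   seed = seed + 307L * i,
                                   filament_length = filament_length / 2))
        vals[i] <- if (inherits(r, "xb_stretch")) r$F_c else r
        ses[i] <- NA_real_
      }
    }
    ref <- vals[bleb_series == 0][1]
    rows[[obs]] <- tibble::tibble(
      bleb_uM = bleb_series, observable = obs,
      value = vals / ref, se = ses / ref)
  }
  atp <- NULL
  if (atpase) {
    p_sat <- set_parameters(hp, bleb = 100)
    fit <- tryCatch({
      cv <- atpase_curve(p_sat)
      suppressWarnings(fit_hyperbola(cv$actin_mM, cv$atpase_per_s))
    }, error = function(e) { partial <<- TRUE; NULL })
    if (!is.null(fit))
      atp <- tibble::tibble(V_max = fit$V_max, K_ATPase = fit$K)
  }
  structure(list(fractions = dplyr::bind_rows(rows), atpase = atp,
                 hypothesis = hypothesis, param_hash = param_hash(params),
                 seed = seed, partial = partial),
            class = "xb_suite")
}

#' @export
print.xb_suite <- function(x, ...) {
  cat("<xb_suite> hypothesis:", x$hypothesis,
      if (x$partial) "(partial)" else "", "\n")
  print(tidyr::pivot_wider(x$fractions[, 1:3], names_from = "observable",
                           values_from = "value"))
  if (!is.null(x$atpase))
    cat("saturating-bleb ATPase: V_max =", signif(x$atpase$V_max, 3),
        "s^-1, K_ATPase =", signif(x$atpase$K_ATPase, 3), "mM\n")
  invisible(x)
}

#' Sum of squared errors of a suite against reference data
#'
#' Observables are pre-normalized to control = 1; reference tables on a
#' different concentration grid are interpolated linearly per observable.
#'
#' @param suite An \code{xb_suite} (or its \code{fractions} tibble).
#' @param reference A tibble with columns \code{bleb_uM},
#'   \code{observable}, \code{value} (e.g. from
#'   \code{\link{gen_concentration_response}} or a user-supplied CSV read
#'   with \code{read_reference_csv}).
#' @return Scalar SSE.
#' @examples
#' model <- tibble::tibble(bleb_uM = c(0, 5, 10), observable = "velocity",
#'                         value = c(1, 0.6, 0.4))
#' ref <- tibble::tibble(bleb_uM = c(0, 5, 10), observable = "velocity",
#'                       value = c(1, 0.5, 0.5))
#' sse_score(model, ref)   # 0.02
#' @export
sse_score <- function(suite, reference) {
  frac <- if (inherits(suite, "xb_suite")) suite$fractions else suite
  obs <- intersect(unique(frac$observable), unique(reference$observable))
  if (length(obs) == 0) stop("no shared observables between suite and reference")
  total <- 0
  n_used <- 0
  for (o in obs) {
    m <- frac[frac$observable == o & is.finite(frac$value), ]
    r <- reference[reference$observable == o, ]
    lo <- max(min(m$bleb_uM), min(r$bleb_uM))
    hi <- min(max(m$bleb_uM), max(r$bleb_uM))
    keep <- r$bleb_uM >= lo & r$bleb_uM <= hi
    if (!any(keep)) stop("empty concentration overlap for ", o)
    pred <- stats::approx(m$bleb_uM, m$value, xout = r$bleb_uM[keep])$y
    total <- total + sum((pred - r$value[keep])^2)
    n_used <- n_used + sum(keep)
  }
  if (n_used == 0) stop("empty overlap between suite and reference")
  total
}

#' Read a reference concentration-response CSV
#'
#' @param path CSV with columns bleb_uM, observable, value.
#' @return A tibble usable as \code{reference} in \code{\link{sse_score}}.
#' @export
read_reference_csv <- function(path) {
  d <- tibble::as_tibble(utils::read.csv(path))
  need <- c("bleb_uM", "observable", "value")
  if (!all(need %in% names(d)))
    stop("reference CSV must have columns: ", paste(need, collapse = ", "))
  d
}

# force-velocity plausibility gate: unloaded velocity and isometric force
# of the perturbed control within +/-30 percent of baseline, and velocity
# non-increasing with load (allowing SE-level violations)
fv_plausible <- function(params, baseline_v0, baseline_f0, seed,
                         tol = 0.30, filament_length = 2) {
  iso <- tryCatch(isometric_force(params, duration = 1, n_runs = 2,
                                  seed = seed,
                                  filament_length = filament_length),
                  error = function(e) NULL)
  if (is.null(iso)) return(FALSE)
  vel <- tryCatch(replicate_velocity(params, 5, 2, seed + 1L, 0.35),
                  error = function(e) NULL)
  if (is.null(vel)) return(FALSE)
  ok_v <- abs(vel$mean_velocity_um_s / baseline_v0 - 1) <= tol
  ok_f <- abs(iso$force_pN / baseline_f0 - 1) <= tol
  isTRUE(ok_v && ok_f)
}

#' +/-25 percent parameter-perturbation robustness screen
#'
#' Each perturbable parameter is independently multiplied by 0.75 or 1.25
#' (chosen at random per set).  Sets whose perturbed control model still
#' gives a reasonable force-velocity behaviour (unloaded velocity and
#' isometric force within 30 percent of baseline) pass the plausibility
#' gate; for those, the SSE of each hypothesis against the reference data
#' is computed and the hypothesis ranking recorded.
#'
#' @param params Control \code{xb_params}.
#' @param reference Reference table as in \code{\link{sse_score}}.
#' @param n_sets Number of perturbation sets.
#' @param seed Base seed.
#' @param hypotheses Hypotheses to rank.
#' @param bleb_series Concentrations for the per-set suites.
#' @param observables Observables entering the per-set SSE.
#' @param n_runs,filament_length Problem sizes per suite.
#' @param perturb Names of the perturbed parameters.
#' @param debug_identity If TRUE all multipliers are 1 (baseline check).
#' @return A tibble, one row per set: multipliers (list-column),
#'   \code{plausible}, one SSE column per hypothesis, \code{ranking_holds}
#'   (first hypothesis strictly better than the second), \code{failed}.
#' @export
perturbation_screen <- function(params, reference, n_sets = 6, seed = 1,
                                hypotheses = c("reduce_kPplus",
                                               "reduce_kon"),
                                bleb_series = c(0, 2, 10),
                                observables = c("velocity", "force"),
                                n_runs = 2, filament_length = 4,
                                perturb = c("k_plus3", "K_3", "K_w",
                                            "k_on_amp", "k_D0", "lambda_D",
                                            "k_ADP", "k_T", "kappa", "K_P"),
                                debug_identity = FALSE) {
  if (n_sets < 1) stop("n_sets must be >= 1")
  set.seed(seed)
  base_iso <- isometric_force(params, duration = 1, n_runs = 2, seed = seed,
                              filament_length = 2)
  base_vel <- replicate_velocity(params, 5, 2, seed + 5L, 0.35)
  rows <- purrr::map_dfr(seq_len(n_sets), function(s) {
    mult <- if (debug_identity) rep(1, length(perturb)) else
      sample(c(0.75, 1.25), length(perturb), replace = TRUE)
    names(mult) <- perturb
    p_s <- tryCatch({
      repl <- as.list(unlist(params[perturb]) * mult)
      validate_parameters(modifyList(unclass(params), repl))
    }, error = function(e) NULL)
    if (is.null(p_s))
      return(tibble::tibble(set = s, multipliers = list(mult),
                            plausible = FALSE, failed = TRUE))
    plaus <- if (debug_identity) TRUE else
      fv_plausible(p_s, base_vel$mean_velocity_um_s, base_iso$force_pN,
                   seed = seed + 1000L * s,
                   filament_length = filament_length / 2)
    sses <- rep(NA_real_, length(hypotheses))
    names(sses) <- hypotheses
    failed <- FALSE
    if (plaus) {
      for (h in hypotheses) {
        sses[h] <- tryCatch(
          sse_score(build_suite(p_s, h, bleb_series,
                                seed = seed + 1000L * s,
                                observables = observables,
                                n_runs = n_runs,
                                filament_length = filament_length,
                                atpase = FALSE),
                    reference),
          error = function(e) { failed <<- TRUE; NA_real_ })
      }
    }
    out <- tibble::tibble(set = s, multipliers = list(mult),
                          plausible = plaus, failed = failed)
    for (h in hypotheses) out[[paste0("sse_", h)]] <- sses[h]
    out$ranking_holds <- if (plaus && !failed && length(hypotheses) >= 2)
      sses[1] < sses[2] else NA
    out
  })
  attr(rows, "manifest") <- run_manifest(params, "perturbation_screen",
                                         seed, n_sets = n_sets,
                                         hypotheses = hypotheses)
  rows
}
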