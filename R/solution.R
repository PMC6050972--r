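# Solution (strain-free) kinetics: the spatially uniform case used for
# actin-activated ATPase predictions.  Each state is taken at its own
# free-energy minimum (the lever and spring relax instantly when nothing
# constrains the filament), so every transition proceeds minimum-to-minimum:
# forward rate = rate function evaluated at the reactant's minimum,
# backward rate closed by detailed balance against the level difference.

solution_rate_pairs <- function(scheme) {
  st <- scheme$states
  tr <- scheme$trans
  p <- scheme$params
  lcap <- log(p$rate_cap)
  f <- b <- numeric(nrow(tr))
  for (i in seq_len(nrow(tr))) {
    A <- tr$A[i]
    if (A <= 0) next
    from <- tr$from_id[i]; to <- tr$to_id[i]
    dG <- st$G[to] - st$G[from]
    x_eval <- if (st$mech[from] == MECH_FB) st$x_min[from]
              else if (st$mech[to] == MECH_FB) st$x_min[to] else 0
    lf <- log(A) + switch(tr$form[i],
      0,                                                   # const
      0,                          # bell: x-integrated amplitude = peak
      -x_eval / tr$p1[i],                                  # exp
      -dG / 2,                                             # symmetric
      0,                                                   # attach
      -(min(x_eval, tr$p2[i]) - tr$p2[i]) / tr$p1[i],      # floored promotion
      abs(x_eval - tr$p2[i]) / tr$p1[i],                   # V-shaped promotion
      -dG)                                                 # late-barrier stroke
    lb <- lf + dG
    if (tr$rev[i]) {
      m <- max(lf, lb)
      if (m > lcap) { lf <- lf - (m - lcap); lb <- lb - (m - lcap) }
      f[i] <- exp(lf); b[i] <- exp(lb)
    } else {
      f[i] <- exp(min(lf, lcap))
    }
  }
  list(f = f, b = b)
}

solution_generator <- function(params) {
  scheme <- build_scheme(params, mode = "solution")
  pr <- solution_rate_pairs(scheme)
  n <- nrow(scheme$states)
  Q <- matrix(0, n, n, dimnames = list(scheme$states$state,
                                       scheme$states$state))
  tr <- scheme$trans
  for (i in seq_len(nrow(tr))) {
    Q[tr$from_id[i], tr$to_id[i]] <- Q[tr$from_id[i], tr$to_id[i]] + pr$f[i]
    if (tr$rev[i])
      Q[tr$to_id[i], tr$from_id[i]] <- Q[tr$to_id[i], tr$from_id[i]] + pr$b[i]
  }
  list(Q = Q, scheme = scheme, pairs = pr)
}

reachable_states <- function(Q, start = 1L) {
  n <- nrow(Q)
  seen <- rep(FALSE, n)
  seen[start] <- TRUE
  frontier <- start
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (i in frontier) {
      hit <- which(Q[i, ] > 0 & !seen)
      seen[hit] <- TRUE
      nxt <- c(nxt, hit)
    }
    frontier <- nxt
  }
  which(seen)
}

#' Steady-state state probabilities (solution mode)
#'
#' Solves the state-probability balance of the strain-free scheme at a given
#' actin concentration, by direct linear algebra on the rate matrix
#' (null-space solve restricted to the reachable states), optionally
#' cross-checked by stiff ODE integration.
#'
#' @param params An \code{xb_params} object.
#' @param actin_conc Actin concentration, mM.
#' @param method \code{"linear"} (null-space solve, default) or \code{"ode"}
#'   (stiff integration with \pkg{deSolve} to 100 / slowest rate).
#' @return A tibble (class \code{xb_occupancy}) with columns \code{state}
#'   and \code{probability}; attribute \code{max_dpdt} carries the largest
#'   absolute time-derivative at the solution.
#' @export
steady_state <- function(params, actin_conc = params$actin,
                         method = c("linear", "ode")) {
  method <- match.arg(method)
  if (actin_conc < 0) stop("actin_conc must be >= 0")
  p <- set_parameters(params, actin = actin_conc)
  gen <- solution_generator(p)
  Q <- gen$Q
  n <- nrow(Q)
  keep <- reachable_states(Q)
  Qr <- Q[keep, keep, drop = FALSE]
  nr <- nrow(Qr)
  G <- Qr; diag(G) <- diag(G) - rowSums(Qr)
  prob <- rep(0, n)
  if (method == "linear") {
    M <- t(G)
    M[nr, ] <- 1
    rhs <- c(rep(0, nr - 1), 1)
    sol <- tryCatch(solve(M, rhs), error = function(e)
      stop("steady state not identifiable: ", conditionMessage(e)))
    sol[abs(sol) < 1e-15] <- 0
  } else {
    pos <- Qr[Qr > 0]
    t_end <- min(1e4, 100 / max(min(pos), 1e-3))
    f <- function(t, y, parms) list(as.numeric(t(G) %*% y))
    y0 <- c(1, rep(0, nr - 1))
    out <- deSolve::lsoda(y0, c(0, t_end), f, NULL,
                          rtol = 1e-10, atol = 1e-12)
    sol <- as.numeric(out[nrow(out), -1])
  }
  dpdt <- as.numeric(t(G) %*% sol)
  if (max(abs(dpdt)) > 1e-6)
    stop("steady state did not converge: max |dp/dt| = ",
         signif(max(abs(dpdt)), 3))
  prob[keep] <- sol / sum(sol)
  out <- tibble::tibble(state = rownames(Q), probability = prob)
  attr(out, "max_dpdt") <- max(abs(dpdt))
  attr(out, "generator") <- gen
  class(out) <- c("xb_occupancy", class(out))
  out
}

# net steady-state flux through each transition row, plus pooled fluxes
# through the serial cuts of the cycle (base + blebbistatin branch pooled)
solution_fluxes <- function(gen, prob) {
  tr <- gen$scheme$trans
  pr <- gen$pairs
  net <- pr$f * prob[tr$from_id] - pr$b * prob[tr$to_id]
  cuts <- list(
    hydrolysis = "M*T->M**DP",
    attach = c("M**DP->AM**DP", "M**DP_bleb->AM**DP_bleb", "M**DP->M*T"),
    k_on = c("AM**DP->AM*'DP", "AM**DP_bleb->AM*'DP_bleb", "M**DP->M*T"),
    k_Pplus = c("AM*'DP->AM*DP", "AM*'DP_bleb->AM*DP_bleb", "M**DP->M*T"),
    pi_release = c("AM*DP->AM*D_L", "AM*DP_bleb->AM*D_L_bleb", "M**DP->M*T"),
    power_stroke = c("AM*D_L->AM'D_H", "AM*D_L_bleb->AM'D_H_bleb",
                     "M**DP->M*T"),
    adp_gate = c("AM'D_H->AMD", "M**DP->M*T"),
    adp_release = c("AMD->AM", "M**DP->M*T"),
    atp_detach = c("AM->M*T", "M**DP->M*T")
  )
  key <- paste0(tr$from, "->", tr$to)
  cut_flux <- vapply(cuts, function(k) sum(net[match(k, key)]), numeric(1))
  list(net = tibble::tibble(from = tr$from, to = tr$to, flux = net),
       cuts = cut_flux)
}

#' Actin-activated ATPase rate
#'
#' Steady-state ATP turnover per myosin head: the net flux through the
#' hydrolysis step, which at steady state equals the net flux through every
#' serial cut of the cycle (checked to 1 percent; a larger mismatch raises
#' an internal-consistency error).
#'
#' @inheritParams steady_state
#' @param check_flux Verify flux conservation across all cycle cuts.
#' @return ATPase rate, s\eqn{^{-1}} per head.
#' @export
atpase_rate <- function(params, actin_conc = params$actin,
                        check_flux = TRUE) {
  occ <- steady_state(params, actin_conc)
  gen <- attr(occ, "generator")
  fl <- solution_fluxes(gen, occ$probability)
  v <- fl$cuts[["hydrolysis"]]
  if (check_flux) {
    spread <- max(abs(fl$cuts - v))
    if (spread > 0.01 * max(abs(v), 1e-12))
      stop("internal-consistency error: cycle fluxes differ by ",
           signif(spread, 3), " s^-1 (ATPase = ", signif(v, 3), ")")
  }
  v
}

#' Simulated ATPase vs actin concentration
#'
#' @param params An \code{xb_params} object.
#' @param actin_series Actin concentrations, mM (default 10 log-spaced
#'   points over 0.05-5 mM).
#' @return A tibble with columns \code{actin_mM}, \code{atpase_per_s}.
#' @examples
#' \donttest{
#' curve <- atpase_curve(default_parameters())
#' fit_hyperbola(curve$actin_mM, curve$atpase_per_s)
#' }
#' @export
atpase_curve <- function(params,
                         actin_series = 10^seq(log10(0.05), log10(5),
                                               length.out = 10)) {
  tibble::tibble(
    actin_mM = actin_series,
    atpase_per_s = vapply(actin_series, function(a)
      atpase_rate(params, a), numeric(1))
  )
}
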