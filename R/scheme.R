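# State space and strain-dependent transition rates of the extended
# cross-bridge scheme.  Only forward rate forms are parameterized; every
# backward rate of a reversible pair is closed by detailed balance against
# the free-energy profiles, so k_f(x)/k_b(x) = exp(-dG(x)/kBT) holds exactly
# at every strain x.  Where the larger member of a pair would exceed the
# rate cap, both members are scaled by the same factor (the ratio - and
# with it detailed balance - is preserved).

# mechanical classes
MECH_DETACHED <- 0L  # no strain coordinate
MECH_WEAK     <- 1L  # bound to a site, strain tracked, no force borne
MECH_FB       <- 2L  # force-bearing: parabolic free energy, stiffness kappa

# rate functional forms
FORM_CONST <- 1L  # A
FORM_BELL  <- 2L  # A exp(-(x - p1)^2 / (2 p2^2))
FORM_EXP   <- 3L  # A exp(-x / p1)
FORM_SYM   <- 4L  # A exp(-dG(x)/2)  (symmetric Kramers split)
FORM_ATTACH <- 5L # as FORM_CONST, but applied per reachable actin site
FORM_EXPFLOOR <- 6L # A exp(-(min(x, p2) - p2)/p1): A above p2, promoted below
FORM_VEXP <- 7L     # A exp(|x - p2|/p1): strain-promoted on both sides
FORM_REVCONST <- 8L # forward A exp(-dG(x)), backward A (late barrier)

# syntactic column aliases for the trace tibble
safe_state_names <- function() {
  c("MT", "MDP", "AMDPw", "AMpDP", "AMsDP", "AMDL", "AMDH", "AMD", "AM",
    "MDP_bleb", "AMDPw_bleb", "AMpDP_bleb", "AMsDP_bleb", "AMDL_bleb",
    "AMDH_bleb")
}

state_names <- function() {
  c("M*T", "M**DP", "AM**DP", "AM*'DP", "AM*DP", "AM*D_L", "AM'D_H",
    "AMD", "AM",
    "M**DP_bleb", "AM**DP_bleb", "AM*'DP_bleb", "AM*DP_bleb",
    "AM*D_L_bleb", "AM'D_H_bleb")
}

#' Motor state table
#'
#' One row per state of the extended scheme: nine blebbistatin-free states
#' (exactly one rigor state AM and one ATP-detached state M*T) plus the six
#' blebbistatin-bound copies reachable between rapid-equilibrium binding to
#' M**DP and irreversible release from AM'D_H_bleb.
#'
#' @param params An \code{xb_params} object (affects free-energy levels).
#' @param mode \code{"ensemble"} (per-site weak binding) or
#'   \code{"solution"} (weak binding scaled by actin concentration).
#' @return A tibble with columns \code{state}, \code{attached},
#'   \code{bleb_bound}, \code{mech} (mechanical class), \code{G} (free-energy
#'   level at the minimum, \eqn{k_BT}, including ligand chemical-potential
#'   shifts at the set concentrations) and \code{x_min} (nm, force-bearing
#'   states only).
#' @export
state_table <- function(params, mode = c("ensemble", "solution")) {
  mode <- match.arg(mode)
  p <- params
  nm <- state_names()
  # ligand chemical-potential shifts: Pi rebinding (post-release states),
  # actin binding (all attached states, solution mode: the weak ->
  # stereospecific step is unimolecular and must not depend on [actin]),
  # blebbistatin binding (bleb branch)
  pi_shift <- if (p$Pi > 0) log(p$K_P * p$Pi) else 0
  att_shift <- if (mode == "solution" && p$actin > 0)
    -log(p$K_w * p$actin) else 0
  G_w <- -log(p$K_3) + p$dG_w + att_shift
  bleb_shift <- if (p$bleb > 0) -log(p$K_bind * p$bleb) else 0
  ps_shift <- -log(p$power_stroke_factor)  # raises bleb post-stroke level
  G <- c(0, -log(p$K_3), G_w, p$G_AMpDP + att_shift,
         p$G_AMsDP + att_shift,
         p$G_AMDL + pi_shift + att_shift,
         p$G_AMDH + pi_shift + att_shift,
         p$G_AMD + pi_shift + att_shift,
         p$G_AM + pi_shift + att_shift,
         -log(p$K_3) + bleb_shift, G_w + bleb_shift,
         p$G_AMpDP + att_shift + bleb_shift,
         p$G_AMsDP + att_shift + bleb_shift,
         p$G_AMDL + pi_shift + att_shift + bleb_shift,
         p$G_AMDH + pi_shift + att_shift + bleb_shift + ps_shift)
  mech <- c(MECH_DETACHED, MECH_DETACHED, MECH_WEAK, MECH_FB, MECH_FB,
            MECH_FB, MECH_FB, MECH_FB, MECH_FB,
            MECH_DETACHED, MECH_WEAK, MECH_FB, MECH_FB, MECH_FB, MECH_FB)
  x_min <- c(NA, NA, NA, p$x_pre, p$x_pre, p$x_pre, p$x_DH, 0, 0,
             NA, NA, p$x_pre, p$x_pre, p$x_pre, p$x_DH)
  tibble::tibble(
    state = nm,
    attached = grepl("^A", nm),
    bleb_bound = grepl("_bleb$", nm),
    mech = mech, G = G, x_min = x_min
  )
}

#' Free energy of a state at strain x
#'
#' Parabolic profiles \eqn{G(x) = G_{min} + \kappa (x - x_{min})^2 / (2 k_BT)}
#' for force-bearing states; flat levels for detached and non-stereospecific
#' weakly bound states.
#'
#' @param scheme An \code{xb_scheme} (from \code{\link{build_scheme}}).
#' @param state State name (see \code{\link{state_table}}).
#' @param x Strain, nm (vectorized).
#' @return Free energy in \eqn{k_BT}.
#' @export
free_energy <- function(scheme, state, x) {
  st <- scheme$states
  i <- match(state, st$state)
  if (is.na(i)) stop("unknown state name: ", state)
  g <- st$G[i]
  if (st$mech[i] == MECH_FB)
    g <- g + 0.5 * scheme$params$kappa * (x - st$x_min[i])^2 / scheme$params$kT
  else
    g <- rep(g, length(x))
  g
}

kon_amplitude <- function(p, branch = c("base", "bleb")) {
  branch <- match.arg(branch)
  dg <- if (branch == "bleb" || p$kon_scope == "global") p$dG_on else p$dG_on_ref
  p$k_on_amp * exp(dg - p$dG_on_ref)
}

#' Build the transition scheme
#'
#' Assembles the full transition table of the extended cross-bridge cycle:
#' hydrolysis (M*T to M**DP), rapid-equilibrium weak binding, the
#' strain-dependent attachment step k_on(x) into the stereospecific
#' pre-power-stroke state AM*'DP, the k_P+ transition into the phosphate
#' release state AM*DP, rapid-equilibrium Pi release (backward rate
#' proportional to [Pi]), the power stroke (AM*D_L to AM'D_H), the
#' strain-gated AM'D_H to AMD transition, one-way ADP release and
#' ATP-induced detachment, plus the blebbistatin branch: rapid-equilibrium
#' binding to M**DP (association constant K_bind) with a copy of the
#' attached cascade and irreversible blebbistatin dissociation from
#' AM'D_H_bleb.
#'
#' @inheritParams state_table
#' @return An object of class \code{xb_scheme}: list with \code{states}
#'   (state table), \code{trans} (transition tibble with forward rate form
#'   and reversibility flag), \code{params}, \code{mode}.
#' @examples
#' sc <- build_scheme(default_parameters())
#' scheme_table(sc)
#' @export
build_scheme <- function(params, mode = c("ensemble", "solution")) {
  mode <- match.arg(mode)
  p <- validate_parameters(params)
  s <- state_names()
  id <- function(nm) match(nm, s)
  attach_form <- if (mode == "ensemble") FORM_ATTACH else FORM_CONST
  attach_A <- if (mode == "ensemble") p$k_w else {
    if (p$actin > 0) p$k_w else 0
  }
  bleb_on <- p$k_bfast * p$K_bind * p$bleb
  cut_on <- p$x_pre + p$x_on_shift + p$capture_range
  tr <- tibble::tribble(
    ~from, ~to, ~form, ~A, ~p1, ~p2, ~p3, ~rev,
    "M*T", "M**DP", FORM_CONST, p$k_plus3, 0, 0, 1e9, TRUE,
    "M**DP", "AM**DP", attach_form, attach_A, 0, 0, 1e9, attach_A > 0,
    "AM**DP", "AM*'DP", FORM_BELL, kon_amplitude(p, "base"),
      p$x_pre + p$x_on_shift, p$sigma_on, cut_on, TRUE,
    "AM*'DP", "AM*DP", FORM_VEXP, p$k_Pplus, p$lambda_P, p$x_pre, 1e9, TRUE,
    "AM*DP", "AM*D_L", FORM_CONST, p$k_Pi, 0, 0, 1e9, p$Pi > 0,
    "AM*D_L", "AM'D_H", FORM_REVCONST, p$k_HL, 0, 0, 1e9, TRUE,
    "AM'D_H", "AMD", FORM_EXP, p$k_D0, p$lambda_D, 0, 1e9, TRUE,
    "AMD", "AM", FORM_CONST, p$k_ADP, 0, 0, 1e9, FALSE,
    "AM", "M*T", FORM_CONST, p$k_T * p$MgATP, 0, 0, 1e9, FALSE,
    "M**DP", "M*T", FORM_CONST, p$k_basal, 0, 0, 1e9, FALSE,
    "M**DP", "M**DP_bleb", FORM_CONST, bleb_on, 0, 0, 1e9, bleb_on > 0,
    "M**DP_bleb", "AM**DP_bleb", attach_form, attach_A, 0, 0, 1e9, attach_A > 0,
    "AM**DP_bleb", "AM*'DP_bleb", FORM_BELL, kon_amplitude(p, "bleb"),
      p$x_pre + p$x_on_shift, p$sigma_on, cut_on, TRUE,
    "AM*'DP_bleb", "AM*DP_bleb", FORM_VEXP, p$k_Pplus_bleb,
      p$lambda_P_bleb, p$x_pre, 1e9, TRUE,
    "AM*DP_bleb", "AM*D_L_bleb", FORM_CONST, p$k_Pi, 0, 0, 1e9, p$Pi > 0,
    "AM*D_L_bleb", "AM'D_H_bleb", FORM_REVCONST, p$k_HL, 0, 0, 1e9, TRUE,
    "AM'D_H_bleb", "AM'D_H", FORM_CONST, p$k_brel, 0, 0, 1e9, FALSE
  )
  if (any(tr$A < 0)) stop("configuration error: negative rate amplitude")
  tr$from_id <- id(tr$from)
  tr$to_id <- id(tr$to)
  structure(list(states = state_table(p, mode), trans = tr,
                 params = p, mode = mode),
            class = "xb_scheme")
}

#' @export
print.xb_scheme <- function(x, ...) {
  cat("<xb_scheme>", nrow(x$states), "states,", nrow(x$trans),
      "transitions, mode =", x$mode, "\n")
  invisible(x)
}

# numeric matrices handed to the C++ rate evaluator / engine
compile_scheme <- function(scheme) {
  st <- scheme$states
  tr <- scheme$trans
  list(
    states = cbind(mech = st$mech, G = st$G,
                   x_min = ifelse(is.na(st$x_min), 0, st$x_min)),
    trans = cbind(from = tr$from_id - 1L, to = tr$to_id - 1L,
                  form = tr$form, A = tr$A, p1 = tr$p1, p2 = tr$p2,
                  rev = as.numeric(tr$rev), p3 = tr$p3),
    kT = scheme$params$kT, kappa = scheme$params$kappa,
    cap = scheme$params$rate_cap, lambda_cut = scheme$params$lambda_cut
  )
}

#' Transition rates at a given strain
#'
#' Evaluates every forward and detailed-balance-closed backward rate of the
#' scheme at strain \code{x}, with the pair-preserving rate cap applied.
#' This is the same evaluator the stochastic engine uses.
#'
#' @param scheme An \code{xb_scheme}.
#' @param x Strain, nm (finite scalar).
#' @return A tibble with columns \code{from}, \code{to}, \code{forward},
#'   \code{backward} (s\eqn{^{-1}}; backward is \code{NA} for one-way
#'   transitions).
#' @export
transition_rates <- function(scheme, x) {
  if (length(x) != 1 || !is.finite(x)) stop("x must be a finite scalar")
  cs <- compile_scheme(scheme)
  m <- xb_pair_rates_cpp(cs$states, cs$trans, cs$kT, cs$kappa, cs$cap, x,
                         cs$lambda_cut)
  tibble::tibble(from = scheme$trans$from, to = scheme$trans$to,
                 forward = m[, 1],
                 backward = ifelse(scheme$trans$rev, m[, 2], NA_real_))
}

#' Rate of one transition at strain x
#'
#' @param scheme An \code{xb_scheme}.
#' @param from,to State names of the (directed) transition; the backward
#'   member of a reversible pair is requested by swapping the two names.
#' @param x Strain, nm; ignored (rates are x-independent) for transitions
#'   between detached states.
#' @return Rate in s\eqn{^{-1}}.
#' @examples
#' sc <- build_scheme(apply_hypothesis(default_parameters(), "reduce_kPplus"),
#'                    mode = "solution")
#' rate(sc, "AM*'DP_bleb", "AM*DP_bleb", x = 0)   # 1.5
#' @export
rate <- function(scheme, from, to, x = 0) {
  if (is.na(x) || !is.finite(x)) stop("x must be finite")
  tab <- transition_rates(scheme, x)
  i <- which(tab$from == from & tab$to == to)
  if (length(i) == 1) return(tab$forward[i])
  j <- which(tab$from == to & tab$to == from)
  if (length(j) == 1 && !is.na(tab$backward[j])) return(tab$backward[j])
  stop("unknown transition: ", from, " -> ", to)
}

#' Human-readable transition-table dump
#'
#' @param scheme An \code{xb_scheme}.
#' @return A tibble (state_from, state_to, rate_expression, reversible) for
#'   audit of the scheme.
#' @export
scheme_table <- function(scheme) {
  tr <- scheme$trans
  expr <- vapply(seq_len(nrow(tr)), function(i) {
    A <- signif(tr$A[i], 4)
    switch(tr$form[i],
      paste0(A, " s^-1"),
      paste0(A, " * exp(-(x - ", tr$p1[i], ")^2 / (2 * ", tr$p2[i], "^2))"),
      paste0(A, " * exp(-x / ", tr$p1[i], ")"),
      paste0(A, " * exp(-dG(x) / 2)"),
      paste0(A, " s^-1 per reachable site"),
      paste0(A, " * exp(-(min(x, ", tr$p2[i], ") - ", tr$p2[i], ") / ",
             tr$p1[i], ")"),
      paste0(A, " * exp(|x - ", tr$p2[i], "| / ", tr$p1[i], ")"),
      paste0(A, " * exp(-dG(x))  [backward ", A, "]"))
  }, character(1))
  tibble::tibble(state_from = tr$from, state_to = tr$to,
                 rate_expression = expr, reversible = tr$rev)
}

#' Validate a model configuration
#'
#' Runs the always-available consistency suite on a parameter set: detailed
#' balance of every reversible transition across a strain grid (relative
#' tolerance 1e-9), steady-state convergence of the solution-mode solver,
#' and flux conservation through every cycle cut.
#'
#' @param params An \code{xb_params} object.
#' @param x_grid Strain grid, nm.
#' @return \code{TRUE} (invisibly) if all checks pass; otherwise an error
#'   describing the first violated property.
#' @export
validate_model <- function(params, x_grid = seq(-15, 15, length.out = 25)) {
  p <- validate_parameters(params)
  sc <- build_scheme(set_parameters(p, bleb = max(p$bleb, 1)))
  for (x in x_grid) {
    r <- transition_rates(sc, x)
    for (i in which(sc$trans$rev)) {
      if (r$forward[i] == 0) next
      dG <- free_energy(sc, sc$trans$to[i], x) -
        free_energy(sc, sc$trans$from[i], x)
      if (abs(r$forward[i] / r$backward[i] / exp(-dG) - 1) > 1e-9)
        stop("detailed balance violated for ", sc$trans$from[i], " <-> ",
             sc$trans$to[i], " at x = ", signif(x, 3))
    }
  }
  atpase_rate(p, 1, check_flux = TRUE)  # convergence + flux conservation
  invisible(TRUE)
}
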