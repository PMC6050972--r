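# Model parameters: the full set of rate amplitudes, equilibrium constants,
# free-energy geometry and concentrations defining one variant of the
# extended cross-bridge scheme (two serial pre-power-stroke/phosphate-release
# states plus blebbistatin-bound state copies).
#
# Values flagged source = "literature" are established literature values
# (k_P+ = 1000 / 1.5 s^-1, dG_on = 0.7 / -4 k_BT, K_bind = 1 uM^-1,
# K_3 ~ 13, d = 36 nm, [MgATP] = 1 mM).  The remaining entries are the
# package's baseline parameterization, calibrated once against the
# published control and saturating-blebbistatin observables (see the
# methods vignette); their source column reads "assumed".

PARAM_INFO <- tibble::tribble(
  ~name,              ~unit,        ~source,
  "k_plus3",          "1/s",        "assumed",
  "K_3",              "1",          "literature",
  "K_w",              "1/mM",       "assumed",
  "k_w",              "1/s",        "assumed",
  "dG_w",             "kBT",        "assumed",
  "k_on_amp",         "1/s",        "assumed",
  "sigma_on",         "nm",         "assumed",
  "x_on_shift",       "nm",         "assumed",
  "capture_range",    "nm",         "assumed",
  "lambda_cut",       "nm",         "assumed",
  "dG_on",            "kBT",        "literature",
  "dG_on_ref",        "kBT",        "literature",
  "k_Pplus",          "1/s",        "literature",
  "lambda_P",         "nm",         "assumed",
  "lambda_P_bleb",    "nm",         "assumed",
  "k_Pplus_bleb",     "1/s",        "literature",
  "k_Pi",             "1/s",        "assumed",
  "K_P",              "1/mM",       "assumed",
  "k_HL",             "1/s",        "assumed",
  "k_D0",             "1/s",        "assumed",
  "lambda_D",         "nm",         "assumed",
  "k_ADP",            "1/s",        "assumed",
  "k_T",              "1/(mM s)",   "assumed",
  "k_basal",          "1/s",        "assumed",
  "k_bfast",          "1/s",        "assumed",
  "K_bind",           "1/uM",       "literature",
  "k_brel",           "1/s",        "assumed",
  "power_stroke_factor", "1",       "assumed",
  "kT",               "pN nm",      "assumed",
  "kappa",            "pN/nm",      "assumed",
  "x_pre",            "nm",         "assumed",
  "x_DH",             "nm",         "assumed",
  "G_AMpDP",          "kBT",        "assumed",
  "G_AMsDP",          "kBT",        "assumed",
  "G_AMDL",           "kBT",        "assumed",
  "G_AMDH",           "kBT",        "assumed",
  "G_AMD",            "kBT",        "assumed",
  "G_AM",             "kBT",        "assumed",
  "dG_ATP",           "kBT",        "assumed",
  "rate_cap",         "1/s",        "assumed",
  "MgATP",            "mM",         "literature",
  "Pi",               "mM",         "assumed",
  "actin",            "mM",         "assumed",
  "bleb",             "uM",         "literature",
  "d_repeat",         "nm",         "literature",
  "sites_per_repeat", "1",          "literature",
  "density",          "heads/um",   "assumed",
  "temperature_regime", "",         "literature",
  "kon_scope",        "",           "assumed"
)

#' Default model parameters
#'
#' Builds the baseline parameter set of the extended actomyosin cross-bridge
#' model.  Literature values (the forward rate of the pre-power-stroke
#' to phosphate-release transition \code{k_Pplus} = 1000 s\eqn{^{-1}} in the
#' absence of blebbistatin and 1.5 s\eqn{^{-1}} for blebbistatin-bound heads,
#' the attachment free-energy offset \code{dG_on} = 0.7 \eqn{k_BT},
#' blebbistatin affinity \code{K_bind} = 1 \eqn{\mu M^{-1}}, hydrolysis
#' equilibrium \code{K_3} = 13, actin half-repeat 36 nm, [MgATP] = 1 mM)
#' are used verbatim; the remaining rate amplitudes and free-energy
#' geometry are the package's calibrated baseline (see the methods
#' vignette).
#'
#' @param regime Temperature regime, \code{"25-30C"} (motility/solution
#'   conditions) or \code{"5C"} (skinned-fiber conditions; slower rate
#'   amplitudes, lower thermal energy).
#' @return An object of class \code{xb_params}: a named list of parameters.
#' @examples
#' p <- default_parameters()
#' p$k_Pplus
#' @export
default_parameters <- function(regime = c("25-30C", "5C")) {
  regime <- match.arg(regime)
  p <- list(
    # biochemical amplitudes / equilibria
    k_plus3   = 175,     # ATP hydrolysis M*T -> M**DP
    K_3       = 13,      # hydrolysis equilibrium constant
    K_w       = 0.082,     # weak-binding association constant (solution), 1/mM
    k_w       = 4000,    # weak attach rate per reachable site (ensemble)
    dG_w      = -2.45,      # per-site weak-binding free energy (ensemble), kBT
    k_on_amp  = 239,     # amplitude of the attachment rate function k_on(x)
    sigma_on  = 100,     # width of the attachment bell, nm
    x_on_shift = 3.5,      # bell-center offset above the AM*'DP minimum, nm
    capture_range = 3,  # half-width of the site-capture window, nm
    lambda_cut = 0.4,    # taper e-fold distance above the capture window, nm
    dG_on     = 0.7,     # attachment activation offset, kBT (control 0.7)
    dG_on_ref = 0.7,     # reference value giving multiplier 1
    k_Pplus   = 1000,    # AM*'DP -> AM*DP amplitude at x = x_pre, control
    lambda_P  = 0.65,    # e-fold distance of the k_P+(x) strain promotion, nm
    lambda_P_bleb = 0.65, # same, for blebbistatin-bound heads
    k_Pplus_bleb = 1000, # same transition for blebbistatin-bound heads
    k_Pi      = 2e4,     # rapid-equilibrium Pi release attempt rate
    K_P       = 0.3,     # phosphate affinity, 1/mM (rebinding ~ K_P*[Pi])
    k_HL      = 160,     # power-stroke reversal attempt rate (late barrier)
    k_D0      = 4000,     # strain-gated AM'D_H -> AMD amplitude
    lambda_D  = 2,     # e-fold distance of the strain gate, nm
    k_ADP     = 5000,     # ADP release AMD -> AM (one-way, [MgADP] = 0)
    k_T       = 26000,    # ATP-induced detachment, 1/(mM s)
    k_basal   = 0.05,    # basal (actin-independent) turnover leak
    k_bfast   = 1e4,     # blebbistatin rapid-equilibrium attempt rate
    K_bind    = 1,       # blebbistatin association constant, 1/uM
    k_brel    = 500,     # irreversible bleb release from AM'D_H_bleb
    power_stroke_factor = 1,  # multiplies K_LH of bleb-bound heads
    # free-energy geometry (levels in kBT at reference concentrations;
    # parabolic minima positions in nm; shared linear elasticity kappa)
    kT     = 4.14,   # thermal energy, pN nm
    kappa  = 2.0,    # cross-bridge stiffness, pN/nm
    x_pre  = 7,      # pre-power-stroke minimum, nm
    x_DH   = 2,    # AM'D_H minimum (second substep to 0 at ADP release), nm
    G_AMpDP = -7,  # AM*'DP minimum level
    G_AMsDP = -7.05,  # AM*DP minimum level
    G_AMDL  = -7.1,  # AM*D_L minimum level (at 1 mM Pi reference)
    G_AMDH  = -23.1, # AM'D_H minimum level
    G_AMD   = -23.6,   # AMD minimum level
    G_AM    = -24.1,   # rigor minimum level
    dG_ATP  = 25,    # free energy of MgATP hydrolysis, kBT/cycle
    rate_cap = 1e5,  # cap on the larger member of each reversible pair
    # concentrations
    MgATP = 1,    # mM
    Pi    = 0.5,  # mM (contaminating phosphate)
    actin = 0,    # mM, solution mode only
    bleb  = 0,    # uM
    # geometry
    d_repeat = 36,        # actin half-repeat, nm
    sites_per_repeat = 3, # myosin-binding target sites per half-repeat
    density = 80,         # motor surface density, heads per um of filament
    temperature_regime = regime,
    kon_scope = "bleb_only"  # where a dG_on change applies: "global"/"bleb_only"
  )
  if (regime == "5C") {
    # slower biochemistry at 5 C; strain-gated mechanical steps less affected
    p$kT <- 3.84
    p$k_plus3 <- p$k_plus3 / 8
    p$k_on_amp <- p$k_on_amp / 8
    p$k_Pplus <- p$k_Pplus / 4
    p$k_Pplus_bleb <- p$k_Pplus_bleb / 4
    p$k_D0 <- p$k_D0 / 4
    p$k_ADP <- p$k_ADP / 4
    p$k_T <- p$k_T / 4
    p$k_basal <- p$k_basal / 8
  }
  validate_parameters(structure(p, class = "xb_params"))
}

#' Validate a parameter set
#'
#' Checks positivity of amplitudes and equilibrium constants, non-negativity
#' of concentrations, and thermodynamic consistency: the free-energy drop
#' over one full cycle must equal \code{dG_ATP}, with a non-negative drop
#' left over for the one-way steps (ADP release and ATP-induced detachment).
#'
#' @param p An \code{xb_params} object (or plain named list).
#' @return The validated object, invisibly classed as \code{xb_params}.
#' @export
validate_parameters <- function(p) {
  need <- PARAM_INFO$name
  missing <- setdiff(need, names(p))
  if (length(missing) > 0)
    stop("missing parameters: ", paste(missing, collapse = ", "))
  unknown <- setdiff(names(p), need)
  if (length(unknown) > 0)
    stop("unknown parameters: ", paste(unknown, collapse = ", "))
  rates <- c("k_plus3", "k_w", "k_on_amp", "k_Pplus", "k_Pplus_bleb", "k_Pi",
             "k_HL", "k_D0", "k_ADP", "k_T", "k_basal", "k_bfast", "k_brel")
  for (nm in rates)
    if (!is.finite(p[[nm]]) || p[[nm]] < 0)
      stop("rate amplitude must be >= 0: ", nm)
  eqc <- c("K_3", "K_w", "K_P", "K_bind", "power_stroke_factor")
  for (nm in eqc)
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0)
      stop("equilibrium constant must be > 0: ", nm)
  conc <- c("MgATP", "Pi", "actin", "bleb")
  for (nm in conc)
    if (!is.finite(p[[nm]]) || p[[nm]] < 0)
      stop("concentration must be >= 0: ", nm)
  for (nm in c("kappa", "kT", "sigma_on", "lambda_D", "density",
               "d_repeat", "rate_cap"))
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0)
      stop("parameter must be > 0: ", nm)
  if (!p$sites_per_repeat %in% c(1, 3))
    stop("sites_per_repeat must be 1 or 3")
  if (!p$temperature_regime %in% c("25-30C", "5C"))
    stop("temperature_regime must be '25-30C' or '5C'")
  if (!p$kon_scope %in% c("global", "bleb_only"))
    stop("kon_scope must be 'global' or 'bleb_only'")
  # cycle free-energy budget: reversible path M*T -> ... -> AM at reference
  # concentrations; the remainder dG_ATP + G_AM is spent on the one-way steps
  if (p$G_AM >= 0) stop("G_AM must be below the detached M*T level (0)")
  irrev_drop <- p$dG_ATP + p$G_AM
  if (irrev_drop < -1e-9)
    stop("free-energy budget violated: the drop over the reversible path (",
         signif(-p$G_AM, 4), " kBT) exceeds dG_ATP (", p$dG_ATP, " kBT)")
  steps <- diff(c(0, -log(p$K_3), p$G_AMpDP, p$G_AMsDP, p$G_AMDL,
                  p$G_AMDH, p$G_AMD, p$G_AM))
  if (any(steps[c(4:7)] > 0))
    stop("free-energy levels of the attached cascade must be non-increasing ",
         "from AM*DP onward")
  invisible(structure(p, class = "xb_params"))
}

#' @export
print.xb_params <- function(x, ...) {
  cat("<xb_params> extended cross-bridge model parameters\n")
  cat("  regime:", x$temperature_regime,
      " [MgATP] =", x$MgATP, "mM, [Pi] =", x$Pi, "mM, [bleb] =", x$bleb,
      "uM\n")
  cat("  k_Pplus =", x$k_Pplus, "/ bleb", x$k_Pplus_bleb, "s^-1;",
      "dG_on =", x$dG_on, "kBT; K_bind =", x$K_bind, "uM^-1\n")
  cat("  hash:", param_hash(x), "\n")
  invisible(x)
}

#' Modify a parameter set
#'
#' @param p An \code{xb_params} object.
#' @param ... Named parameter replacements.
#' @return The modified, re-validated \code{xb_params}.
#' @export
set_parameters <- function(p, ...) {
  repl <- list(...)
  if (length(repl) == 0) return(p)
  bad <- setdiff(names(repl), names(p))
  if (length(bad) > 0) stop("unknown parameters: ", paste(bad, collapse = ", "))
  validate_parameters(modifyList(unclass(p), repl))
}

#' Apply a blebbistatin mechanism hypothesis to a parameter set
#'
#' The three candidate mechanisms for blebbistatin action, each modifying a
#' single parameter block: \code{reduce_kPplus} slows the transition from the
#' pre-power-stroke state AM*'DP to the phosphate-release state AM*DP for
#' blebbistatin-bound heads (1000 to 1.5 s\eqn{^{-1}}); \code{reduce_kon}
#' lowers the attachment offset \code{dG_on} from 0.7 to \eqn{-4\,k_BT}
#' (reducing the amplitude of k_on(x) about 110-fold); and
#' \code{inhibit_power_stroke} scales the power-stroke equilibrium of
#' bleb-bound heads by \code{power_stroke_factor}.
#'
#' @param p An \code{xb_params} object.
#' @param hypothesis One of \code{"none"}, \code{"reduce_kPplus"},
#'   \code{"reduce_kon"}, \code{"inhibit_power_stroke"},
#'   \code{"reduce_kPplus_plus_power_stroke"}.
#' @param k_Pplus_bleb Blebbistatin-bound forward rate for
#'   \code{reduce_kPplus}, s\eqn{^{-1}}.
#' @param dG_on Attachment offset under \code{reduce_kon}, \eqn{k_BT}.
#' @param power_stroke_factor Multiplier on the bleb-bound power-stroke
#'   equilibrium constant for \code{inhibit_power_stroke}.
#' @param kon_scope Whether the \code{dG_on} change applies to all heads
#'   (\code{"global"}, the saturating-blebbistatin presentation) or only to
#'   blebbistatin-bound heads (\code{"bleb_only"}).
#' @return A new \code{xb_params}.
#' @examples
#' p <- apply_hypothesis(default_parameters(), "reduce_kPplus")
#' p$k_Pplus_bleb
#' @export
apply_hypothesis <- function(p,
                             hypothesis = c("none", "reduce_kPplus",
                                            "reduce_kon",
                                            "inhibit_power_stroke",
                                            "reduce_kPplus_plus_power_stroke"),
                             k_Pplus_bleb = 1.5,
                             dG_on = -4,
                             power_stroke_factor = 0.1,
                             kon_scope = p$kon_scope) {
  hypothesis <- match.arg(hypothesis)
  out <- switch(hypothesis,
    none = p,
    reduce_kPplus = set_parameters(p, k_Pplus_bleb = k_Pplus_bleb,
                                   lambda_P_bleb = 1e9),
    reduce_kon = set_parameters(p, dG_on = dG_on, kon_scope = kon_scope),
    inhibit_power_stroke =
      set_parameters(p, power_stroke_factor = power_stroke_factor),
    reduce_kPplus_plus_power_stroke =
      set_parameters(p, k_Pplus_bleb = k_Pplus_bleb, lambda_P_bleb = 1e9,
                     power_stroke_factor = power_stroke_factor)
  )
  attr(out, "hypothesis") <- hypothesis
  out
}

#' Effective hydrolysis equilibrium constant
#'
#' Equilibrium constant between M*T and the pooled (M**DP + M**DP_bleb)
#' states.  Rapid-equilibrium blebbistatin binding to M**DP enlarges the
#' pool without any change in \code{K_3}:
#' \eqn{K_{eff} = K_3 (1 + K_{bind} [bleb])}.
#'
#' @param p An \code{xb_params} object.
#' @return Dimensionless equilibrium constant.
#' @examples
#' effective_hydrolysis_equilibrium(default_parameters())            # ~ 13
#' effective_hydrolysis_equilibrium(set_parameters(default_parameters(),
#'                                                 bleb = 10))       # 143
#' @export
effective_hydrolysis_equilibrium <- function(p) {
  p$K_3 * (1 + p$K_bind * p$bleb)
}

#' Parameter table (one row per named parameter)
#'
#' @param p An \code{xb_params} object.
#' @return A tibble with columns name, value, unit, source.
#' @export
parameter_table <- function(p) {
  vals <- vapply(PARAM_INFO$name, function(nm) {
    v <- p[[nm]]
    if (is.character(v)) v else as.character(v)
  }, character(1))
  dplyr::mutate(PARAM_INFO, value = unname(vals), .after = "name")
}

#' Read / write parameter tables
#'
#' Parameter sets are stored either as TSV (columns name, value, unit,
#' source) or as JSON.  Unknown names are rejected; units are checked
#' against the package's unit registry.
#'
#' @param path File path; format inferred from the extension
#'   (\code{.tsv}/\code{.txt} or \code{.json}).
#' @return \code{load_parameters}: an \code{xb_params} object.
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    tab <- tibble::tibble(name = names(raw),
                          value = as.character(unlist(raw)))
  } else {
    tab <- tibble::as_tibble(read.delim(path, sep = "\t",
                                        colClasses = "character"))
  }
  unknown <- setdiff(tab$name, PARAM_INFO$name)
  if (length(unknown) > 0)
    stop("unknown parameter names: ", paste(unknown, collapse = ", "))
  if ("unit" %in% names(tab)) {
    ref <- setNames(PARAM_INFO$unit, PARAM_INFO$name)
    bad <- tab$name[tab$unit != ref[tab$name]]
    if (length(bad) > 0)
      stop("unit mismatch for: ", paste(bad, collapse = ", "))
  }
  chr <- c("temperature_regime", "kon_scope")
  p <- lapply(setNames(tab$value, tab$name), identity)
  p[!names(p) %in% chr] <- lapply(p[!names(p) %in% chr], as.numeric)
  validate_parameters(p)
}

#' @rdname load_parameters
#' @param p An \code{xb_params} object to write.
#' @export
save_parameters <- function(p, path) {
  p <- validate_parameters(p)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(unclass(p), path, auto_unbox = TRUE, digits = NA)
  } else {
    write.table(parameter_table(p), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

#' Deterministic short hash of a parameter set (for run manifests)
#'
#' @param p An \code{xb_params} object.
#' @return An 8-hex-digit character scalar.
#' @export
param_hash <- function(p) {
  s <- paste(names(p), vapply(p, function(v)
    if (is.character(v)) v else sprintf("%.12g", v), character(1)),
    collapse = ";")
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 131 + code) %% 2147483647
  sprintf("%08x", h)
}
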