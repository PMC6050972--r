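---
title: "A mechanokinetic model of the actomyosin cross-bridge cycle and of blebbistatin action"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A mechanokinetic model of the actomyosin cross-bridge cycle and of blebbistatin action}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(crossbridge)
```

## The model

`crossbridge` implements a strain-dependent kinetic model of the
interaction between myosin II motor fragments and a rigid actin filament.
Nine biochemical states describe one ATP turnover: the detached states
M\*T (ATP bound) and M\*\*DP (products bound, after hydrolysis with
equilibrium constant `K_3`), a non-stereospecific weakly bound state
AM\*\*DP, a stereospecific but weakly bound pre-power-stroke state AM\*'DP,
a phosphate-release state AM\*DP from which Pi leaves in rapid equilibrium,
the pre- and post-power-stroke strongly bound states AM\*D_L and AM'D_H
(the lever-arm swing between them is the Huxley–Simmons transition), the
ADP state AMD and the rigor state AM.  Blebbistatin binds in rapid
equilibrium (association constant `K_bind` = 1 per µM) to M\*\*DP, rides
through a copy of the attached cascade, and dissociates irreversibly from
AM'D_H.

Every attached, force-bearing state has a parabolic free-energy profile
`G(x) = G_min + kappa (x - x_min)^2 / (2 kBT)` with a common stiffness
`kappa` (2 pN/nm); `x` is the distance from the nearest actin target site
to the motor's reference point, zero at the rigor minimum, increasing with
stretch.  The AM\*'DP, AM\*DP and AM\*D_L minima coincide (`x_pre` = 7 nm;
Pi release does not move the lever), the AM'D_H minimum sits at `x_DH` =
2 nm and the AMD/AM minima at 0, so the working stroke is 5 nm with a 2-nm
second substep at the ADP-release gate.  The non-stereospecific weak state
is treated as mechanically silent (flat free energy, no force): a
force-bearing non-stereospecific state would re-introduce a frictional
weak-binding drag mechanism that the motility data argue against.

Only forward rate functions are parameterized.  Every reversible backward
rate is closed by detailed balance, `k_f(x)/k_b(x) = exp(-dG(x)/kBT)`,
evaluated per strain; where the larger member of a pair would exceed the
rate cap (`rate_cap` = 1e5 per s) both members are scaled by the same
factor, so the ratio — and with it detailed balance — is preserved exactly
at every strain, including far from the minima where raw backward rates
overflow.

The strain-dependent rate functions are:

* `k_on(x)` — attachment from AM\*\*DP into AM\*'DP.  A bell with width
  `sigma_on` centred `x_on_shift` above the pre-stroke minimum; the
  default width (100 nm) makes it effectively flat inside the
  site-capture window, and a steep steric taper (`lambda_cut` = 0.4 nm)
  sets it to zero beyond the upper edge of the window: stereospecific
  docking is geometrically impossible once the site has been pulled past
  the motor's reach.  Detailed balance then shapes where attachments
  commit (near and above the minimum) and guarantees rapid escape of
  negatively strained pre-stroke heads during sliding, while heads pulled
  above the window during stretch can no longer detach backward and hold
  force until the strongly strain-promoted forward path releases them —
  the forcible-detachment behaviour that produces the critical force.
* `k_P+(x)` — the AM\*'DP to AM\*DP transition, amplitude `k_Pplus` =
  1000 per s at the pre-stroke minimum, strain-promoted on both sides
  with e-fold distance `lambda_P` (0.65 nm).  The V-shaped promotion
  keeps the pre-power-stroke state transient (well below 1% of attached
  heads during sliding, about 1% under a length clamp), consistent with
  it being undetectable under control conditions.
* the power stroke — modelled with a late transition barrier: the
  backward (reverse-stroke) rate is the constant attempt frequency
  `k_HL` (160 per s) and the forward rate follows from detailed balance
  (capped).  Forward strokes are effectively instantaneous wherever they
  are downhill; the slow reversal lets stretched post-stroke heads hold
  strain for tens of milliseconds, giving the fast elastic phase of the
  stretch response.
* `k_D(x)` — the strain-gated AM'D_H to AMD transition,
  `k_D0 exp(-x / lambda_D)`: slow under positive strain (post-stroke
  heads hold isometric force), fast once a head is dragged past its
  minimum during shortening.

ADP release proper (AMD to AM) and ATP-induced detachment
(AM to M\*T, second-order in [MgATP]) are one-way because [MgADP] = 0 in
all protocols, and blebbistatin release from AM'D_H is one-way following
the rapid-equilibrium treatment of binding.  The free-energy drop along
the cycle equals `dG_ATP`, with the residual assigned to the one-way
steps; the validator enforces a non-negative residual.

## Blebbistatin hypotheses

`apply_hypothesis()` switches between candidate mechanisms:

* `reduce_kPplus` — the favoured mechanism: for blebbistatin-bound heads
  the `k_P+` amplitude drops from 1000 to 1.5 per s (about 650-fold) and
  the strain promotion is flattened: the drug-trapped pre-power-stroke
  state is insensitive to strain.  This single change reproduces the
  reduction of ATPase `V_max`, sliding velocity, isometric force,
  `K_ATPase` and `K_M^v`, and the length-independence of the velocity
  reduction.
* `reduce_kon` — the competing mechanism: the attachment offset `dG_on`
  drops from 0.7 to −4 kBT, multiplying the `k_on` amplitude by
  `exp(dG_on − 0.7)` (about 110-fold down; both directions scale
  together, i.e. a pure activation-energy change).  The `kon_scope`
  flag chooses whether the change applies to all heads (`"global"`, the
  presentation used for the saturating-blebbistatin ATPase panels) or
  only to blebbistatin-bound heads (`"bleb_only"`, the default, which is
  what a binding-mediated mechanism implies at sub-saturating
  concentrations).
* `inhibit_power_stroke` — scales the power-stroke equilibrium of
  bleb-bound heads by `power_stroke_factor` (their post-stroke level is
  raised by −log of the factor); also available combined with
  `reduce_kPplus`.

## Parameterization

The literature constants are used verbatim: `k_Pplus` 1000 / 1.5 per s,
`dG_on` 0.7 / −4 kBT, `K_bind` 1 per µM, `K_3` 13, the 36-nm actin
half-repeat with one or three target sites, [MgATP] = 1 mM, and the
stretch protocol (2500 nm per half-sarcomere per s between 4.8 and
4.95 s).  The remaining amplitudes and the free-energy geometry are this
package's own baseline: they were calibrated once against the published
control and saturating-blebbistatin Michaelis–Menten constants of the
actin-activated ATPase (`V_max` 84.2 / 1.57 / 1.98 per s, `K_ATPase`
0.386 / 0.355 / 1.09 mM) and the simulated motility kinetics (`V_max`
10.1 / 5.22 µm/s, `K_M^v` 0.062 / 0.031 mM), and are not revisited.  The
joint fit has a structural residual: with all six ATPase constants
weighted equally the best attainable parameterization leaves deviations
of up to about 9% (control `V_max` fits about 8% low, `K_ATPase` about
8% high, and the reduced-`k_on` pair carries 6–8%).  The acceptance
tests therefore assert a 15% band on the fitted constants — the
documented calibration residual plus fitting noise — together with the
structural orderings that do not depend on calibration at all (the
direction of the `K_ATPase` shift under the two hypotheses, flux
conservation, and the ~50-fold ATPase reduction).  The source column of
`parameter_table()` distinguishes literature (`literature`) from calibrated
(`assumed`) entries, and the shipped TSVs under `inst/extdata/` carry the
control, hypothesis and 5 °C variants.

The 5 °C regime (`default_parameters("5C")`) scales the biochemical
amplitudes down (about 8-fold for hydrolysis, attachment and basal
turnover, 4-fold for the detachment path) and lowers `kT`; the values are
data in the parameter table, not code, and are stated as assumptions —
no low-temperature measurements are fitted.

## Solution (ATPase) reduction

For solution kinetics the strain coordinate is integrated out: every
state sits at its own free-energy minimum, transitions proceed
minimum-to-minimum (forward rate functions evaluated at the reactant
minimum; the attachment bell contributes its peak), and actin binding
enters as a chemical-potential shift `-log(K_w [actin])` applied to all
actin-bound states, so only the binding step itself depends on [actin]
and the weak-to-stereospecific isomerization does not.  Steady states are
solved by a null-space linear solve restricted to the reachable states,
cross-checked against stiff ODE integration (`deSolve::lsoda`), and the
net flux must agree across every serial cut of the cycle to 1% (an
internal-consistency error otherwise).  ATPase curves use 10 log-spaced
actin concentrations between 0.05 and 5 mM; Michaelis–Menten fits are
unweighted least squares with confidence intervals from the parameter
covariance.

## The stochastic engine

Ensembles are simulated with the exact (direct) Gillespie algorithm:
per-motor propensities from the same rate evaluator the R side exposes,
exponential waiting times, and closed-form re-solution of the rigid
filament's position after every event that changes the force-bearing set
(`z = (F_ext/kappa + sum(x_min - c_i)) / n` over attached force-bearing
heads; no viscous drag, no Brownian filament dynamics).  Motors are
placed uniformly at random (the lattice phase makes anchor positions
incommensurate with the 36/12-nm site spacing), weak binding is a
rapid pre-equilibrium per reachable site inside the capture window, and
clamp ramps advance the filament in 0.2-ms steps between events.  The
default motor density (80 heads per µm of filament) represents the dense
HMM lawns of the motility assay; the velocity–length plateau and its
approach around 2–5 µm emerge from it.  Traces are sampled at 1 ms (0.5
ms for stretch protocols) and record position, force, per-state
occupancy counts and cumulative ATP turnover.

Two engine-level behaviours deserve comment.  First, under load clamp the
ensemble yields at a stall force below the length-clamped plateau force:
once the load concentrates on few heads, over-strained bridges cascade
off.  `force_velocity_curve()` therefore locates the isotonic stall by
probing before laying out its load series.  Second, the isometric force
of a length-clamped ensemble is carried mostly by post-stroke heads held
by the strain-gated ADP transition; the rate of rise of force comes from
a single-exponential fit to the run-averaged redevelopment phase.

## Synthetic data and hypothesis comparison

The generators in `gen_velocity_length_data()`,
`gen_concentration_response()` and `gen_force_trace()` add relative
Gaussian noise (default 5%, matching the way experimental confidence
intervals scale with the mean) to simulated means and attach a truth
manifest (parameters, hypothesis, seed).  They emulate the statistical
structure of motility and fiber measurements — not video-tracking
artifacts, filament path curvature, ionic-strength series or
regulatory-light-chain effects, so passing recovery tests says nothing
about those aspects of real data.

`build_suite()` assembles fractional velocity, isometric force and
critical force across a blebbistatin series plus the
saturating-blebbistatin ATPase constants; `sse_score()` sums squared
errors against a reference table (linear interpolation onto the reference
grid); `perturbation_screen()` redraws every perturbable parameter at
0.75 or 1.25 times its baseline, gates each set on a plausible
force–velocity behaviour (unloaded velocity and isometric force within
30% of baseline — the gate is deliberately simple and its threshold is
configurable), and reports whether the SSE ranking of the hypotheses
survives.  Raw SSE is used deliberately; no information criteria.

## Numerical choices and problem sizes

Tolerances: detailed balance is exact by construction and verified to
1e-9; steady states must satisfy |dp/dt| < 1e-8; flux conservation to
1%; force balance is a closed-form solve (1e-6 pN in tests).  Breakpoint
extraction uses a 60-point grid plus golden-section refinement, flags
fits whose breakpoint sits at the window edge or improves the RSS by
less than 5% over a single line, and reports the force at the fitted
intersection.  The test-suite and acceptance runs use scaled-down
problem sizes chosen to keep every stochastic estimate's Monte-Carlo
error well inside the asserted bands: filaments of 1–20 µm, 2–5
replicate runs, 0.12–0.25 s of simulated sliding per run, 1-s isometric
runs, and compressed stretch protocols (1.0–1.15 s window at the full
2500 nm/s ramp speed) whose pre-ramp phase is long enough to reach the
isometric steady state.  The full experimental protocol (ramp between 4.8
and 4.95 s) is the default of `protocol_ramp()`.

## Known limitations

* Linear cross-bridge elasticity throughout; the simulated `K_M^v` is
  accordingly at the low end, a known consequence of that assumption.
* No titin/parallel elasticity, no series compliance, no sarcomere
  populations, no Ca²⁺ kinetics: the slow stretch phase reflects
  cross-bridge treadmilling only.
* No ionic-strength dependence of the rate constants, no
  methylcellulose/diffusion effects, no filament bending.
* The isotonic stall force sits below the length-clamped plateau force
  (yielding instability of load control with discrete heads); published
  fiber forces are length-clamped and comparisons are made on
  normalized observables.
* The ±25% perturbation screen perturbs rate amplitudes, equilibrium
  constants and the stiffness; it does not explore the free-energy
  minima positions, which are strongly linked to the force–velocity
  shape.
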