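# crossbridge

Mechanokinetic simulation of the force-generating cycle between myosin II
and actin, built to dissect how the small-molecule inhibitor blebbistatin
perturbs that cycle.

## The science

Muscle contraction is driven by cyclic interactions of myosin motor
domains with actin, fuelled by ATP turnover.  A long-standing question is
how phosphate (Pi) release relates to the force-generating lever-arm swing
(the power stroke).  This package implements a strain-dependent
(mechanokinetic) cross-bridge model in which attachment proceeds through a
non-stereospecific weak state (AM\*\*DP), a stereospecific but weakly
bound pre-power-stroke state (AM\*'DP) and a phosphate-release state
(AM\*DP) before the stroke (AM\*D_L → AM'D_H), ADP release and
ATP-induced detachment.  Attached states carry parabolic free-energy
profiles G(x) = G_min + κ(x − x_min)²/2 over the strain coordinate x, and
every reversible rate pair obeys detailed balance,
k_f(x)/k_b(x) = exp(−ΔG(x)/k_BT).

Blebbistatin enters by rapid-equilibrium binding (K_bind = 1 µM⁻¹) to
M\*\*DP and rides through a copy of the attached cascade.  Competing
hypotheses for its mechanism are implemented as single parameter changes:

* `reduce_kPplus` — the transition from the pre-power-stroke state to the
  phosphate-release state slows from 1000 to 1.5 s⁻¹ for drug-bound heads
  (the mechanism favoured by the data);
* `reduce_kon` — the weak-to-stereospecific attachment step slows about
  110-fold (ΔG_on 0.7 → −4 k_BT);
* `inhibit_power_stroke` — the power-stroke equilibrium of drug-bound
  heads is scaled down.

The package computes, from one parameter set: actin-activated ATPase
curves with Michaelis–Menten fits (deterministic steady-state solver), in
vitro motility (Gillespie simulation of motor ensembles propelling a
rigid filament: velocity vs filament length, vs [MgATP], vs
[blebbistatin]), half-sarcomere protocols (isometric force and its rate
of rise, stretch ramps with critical-force extraction, force–velocity
and [Pi] dependence), pseudo-experimental data generators, and a
sum-of-squared-errors comparison that ranks the hypotheses against
reference data, including a ±25% parameter-perturbation robustness
screen.

## Worked example

```r
library(crossbridge)
p <- default_parameters()

# actin-activated ATPase, control vs saturating blebbistatin
curve <- atpase_curve(p)
fit_hyperbola(curve$actin_mM, curve$atpase_per_s)
#> Hyperbolic fit y = V_max x / (K + x)
#>   V_max = 80.23  (95% CI 80.21 - 80.25)
#>   K     = 0.3929  (95% CI 0.3925 - 0.3933)

bleb <- set_parameters(apply_hypothesis(p, "reduce_kPplus"), bleb = 100)
curve_b <- atpase_curve(bleb)
fit_hyperbola(curve_b$actin_mM, curve_b$atpase_per_s)
#>   V_max = 1.547   (about a 50-fold inhibition)

# the effective M*T <-> M**DP equilibrium grows with blebbistatin binding
effective_hydrolysis_equilibrium(set_parameters(p, bleb = 10))
#> [1] 143

# unloaded sliding of a 5-um filament in the motility assay
ens <- init_ensemble(5, p, seed = 1)
tr <- simulate_ensemble(ens, protocol_unloaded(), duration = 0.2)
measure_velocity(tr)
#> # A tibble: 1 x 2
#>   velocity_um_s se_um_s
#>           <dbl>   <dbl>
#> 1          8.57   0.202
```

The ATPase fit says actin activates myosin ATP turnover to a maximum of
~80 turnovers per head per second with half-activation near 0.4 mM actin;
saturating blebbistatin collapses the maximal rate ~50-fold under the
favoured mechanism while slightly *decreasing* K_ATPase — the signature
that separates it from an attachment-rate mechanism, which would raise
K_ATPase.  The motility run shows the same model propelling a filament at
~9–10 µm/s at 1 mM MgATP.

`autoplot()` methods exist for traces, fits, velocity tables and stretch
results; `tidy()`/`glance()` work on hyperbolic fits.

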