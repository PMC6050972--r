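# Shared fixtures: small, fast parameter sets and utilities.  All
# simulated inputs are generated here at test time; nothing is read from
# disk.

# default parameters with a sparser ensemble for cheap stochastic runs
fast_params <- function(...) {
  set_parameters(default_parameters(), density = 30, ...)
}

# a strain-free reduced scheme: every rate function flattened so that the
# ensemble engine and the solution-mode solver describe the same Markov
# chain (used for the Gillespie <-> ODE equivalence oracle)
strain_free_params <- function(...) {
  set_parameters(default_parameters(),
                 kappa = 1e-9,        # no elastic energy: flat parabolas
                 sigma_on = 1e6,      # flat attachment rate
                 x_on_shift = 0,
                 capture_range = 5.9, # guarantees exactly one reachable site
                 lambda_cut = 1e9,    # no steric taper
                 lambda_P = 1e9, lambda_P_bleb = 1e9,  # constant k_P+
                 lambda_D = 1e9,      # constant ADP gate
                 density = 30,
                 ...)
}

# time-averaged occupancy fractions from a trace (count columns)
trace_occupancy <- function(trace, discard = 0.2 * max(trace$time_s)) {
  d <- trace[trace$time_s >= discard, grep("^n_", names(trace))]
  cm <- colMeans(d)
  cm / sum(cm)
}

# mean +/- blocked SE of a per-sample statistic
blocked_se <- function(x, n_blocks = 10) {
  blocks <- split(x, cut(seq_along(x), n_blocks, labels = FALSE))
  m <- vapply(blocks, mean, numeric(1))
  sd(m) / sqrt(length(m))
}
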