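# Shared fixtures: the documented central circuit values and an independent
# straight-line-formula evaluation of the circuit used as the forward-model
# oracle (composed directly from the element formulas, no package internals).

default_truth <- function() {
  circuit_params(r_ce = 2000, q_ce = 2e-3, alpha_ce = 0.9,
                 r_electrolyte = 120, r_barrier = 900, c_barrier = 5e-7)
}

oracle_circuit_z <- function(p, f) {
  w <- 2 * pi * f
  z_q <- 1 / (p$q_ce * (1i * w)^p$alpha_ce)
  z_ce <- (p$r_ce * z_q) / (p$r_ce + z_q)
  z_c <- 1 / (1i * w * p$c_barrier)
  z_b <- (p$r_barrier * z_c) / (p$r_barrier + z_c)
  z_ce + p$r_electrolyte + z_b
}

derive_seeds_vec <- function(n, master) {
  withr::with_seed(master, sample.int(.Machine$integer.max - 1L, n))
}

# Random device truths are draws from the generator's own device
# population (the study conditions): central circuit values with 10%
# log-normal jitter.
random_truth <- function() {
  baseline_parameters("barrier", seed = NULL, jitter_cv = 0.10)
}
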