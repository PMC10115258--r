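# Shared fixtures, built lazily and cached for the whole test run.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# A 300-s wheel session (20 x 15-s trials) whose ground-truth phases are
# reused by the spike-train tests.
wheel_session_300s <- function() {
  fixture("wheel300", function() {
    gen_session(synth_config(n_trials_per_context = 20), "pre", seed = 5,
                contexts = "wheel")
  })
}

wheel_truth_300s <- function() {
  s <- wheel_session_300s()
  list(phase_slow = s$ground_truth$phase_slow,
       phase_theta = s$ground_truth$phase_theta)
}

# Configs for single-purpose spike simulations: one rhythm, no bursting.
mod_config <- function(kappa_slow, rate = 10, kappa_theta = 0) {
  synth_config(kappa_slow_int = kappa_slow, kappa_theta_int = kappa_theta,
               base_rate_int = rate)
}
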