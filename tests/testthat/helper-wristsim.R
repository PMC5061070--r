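# Shared fixtures: plants are built in code, never stored.

quiet_plant <- function(orientation = "downward", ...) {
  # noise-free plant for deterministic checks
  wrist_plant(plant_config(orientation = orientation,
                           angle_noise_sd = 0, force_noise_sd = 0, ...))
}

noisy_plant <- function(orientation = "downward", ...) {
  wrist_plant(plant_config(orientation = orientation, ...))
}

# short custom trajectory for cheap closed-loop tests
short_spec <- function(amp_fe = 10, amp_rud = 0, n_cycles = 2) {
  trajectory_spec("CUSTOM", amp_fe = amp_fe, amp_rud = amp_rud,
                  n_cycles = n_cycles)
}

# a muscle table with slightly perturbed arms (valid signs) for
# property tests
perturbed_muscles <- function(rng, scale = 0.15) {
  m <- wrist_muscles()
  m$r_fe_mm <- m$r_fe_mm * (1 + scale * rng$rnorm(6))
  m$r_rud_mm <- m$r_rud_mm * (1 + scale * rng$rnorm(6))
  m$pcsa_cm2 <- m$pcsa_cm2 * exp(scale * rng$rnorm(6))
  m
}
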