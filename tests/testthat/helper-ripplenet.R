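# shared defaults and a lazily cached reference simulation

default_dp <- dimensionless_params()
default_pp <- physical_params()

.cache <- new.env(parent = emptyenv())

# one sparse-synchrony reference run shared by several metric tests
get_ref_sim <- function() {
  if (is.null(.cache$ref_sim)) {
    .cache$ref_sim <- simulate_network(
      physical_params(N = 1000),
      constant_drive(0.55, 1050, units = "nA"), seed = 42)
  }
  .cache$ref_sim
}

# step-by-step R re-implementation of the Euler-Maruyama network update,
# consuming the same RNG stream as the C++ core (uniform init, one
# standard-normal draw per unit per step)
r_reference_sim <- function(dp, I_E, n_steps, dt, seed) {
  set.seed(seed)
  N <- dp$N
  v <- runif(N, dp$V_R, dp$V_T)
  a <- dt / dp$tau_m
  noise_sd <- sqrt(2 * dp$D * dt / dp$tau_m)
  delay_steps <- as.integer(round(dp$delta / dt))
  counts <- integer(n_steps)
  for (t in seq_len(n_steps)) {
    xi <- rnorm(N)
    inh <- if (t > delay_steps) dp$K / N * counts[t - delay_steps] else 0
    v <- v + a * (I_E[t] - v) + noise_sd * xi - inh
    fired <- v >= dp$V_T
    counts[t] <- sum(fired)
    v[fired] <- dp$V_R
  }
  counts
}
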