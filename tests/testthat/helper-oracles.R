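# Independent oracles used across tests.

# Deterministic grid integration of the exact leaving-rate posterior:
# likelihood k^n * exp(-k * sum_t), inverse-Gamma(a, b) prior. Returns
# normalised moments. Written directly from the densities, independent of
# the package's sampler.
grid_posterior_moments <- function(n, sum_t, a = 2, b = 1,
                                   k_max = NULL, grid_n = 50000L) {
  if (is.null(k_max)) k_max <- 5 * max(n / sum_t, 1)
  k <- seq(k_max / grid_n, k_max, length.out = grid_n)
  log_dens <- n * log(k) - k * sum_t + (-a - 1) * log(k) - b / k
  w <- exp(log_dens - max(log_dens))
  w <- w / sum(w)
  m1 <- sum(w * k)
  m2 <- sum(w * k^2)
  list(mean = m1, sd = sqrt(m2 - m1^2), grid = k, weights = w)
}

# A small standard experiment config used in several tests.
quick_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(k_loop = 0.3, k_unloop = 0.25, k_cut = 0.2,
         rmsd_unlooped = 250, rmsd_looped = 160, noise_sd = 15,
         frame_interval = 1, baseline_duration = 10,
         observation_duration = 60, seed = seed),
    list(...)
  )
  do.call(sim_config, args)
}

default_call_config <- function(...) {
  state_call_config(unlooped_level = 250, looped_level = 160, ...)
}
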