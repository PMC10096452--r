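# Independent oracles and shared scenario builders for the test suite.

# Bisection on the mass-balance residual f(x) = K (Ht - x)(Gt - x) - x,
# independent of the closed-form quadratic used by the package.
bisect_complex <- function(K, ht, gt, iter = 200L) {
  if (K == 0 || ht == 0 || gt == 0) return(0)
  f <- function(x) K * (ht - x) * (gt - x) - x
  lo <- 0
  hi <- min(ht, gt)
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# guest grid used throughout: constant host, titrant up to 30 equivalents
canonical_guests <- function(n = 12) seq(0, 3e-4, length.out = n)

static_scenario <- function(seed, K_true = 3000, eps_guest = 1000,
                            noise_rel_F = 0.01, noise_rel_A = 0.002) {
  simulation_scenario(K_true = K_true, host_total = 1e-5,
                      guest_grid = canonical_guests(),
                      eps_guest = eps_guest,
                      noise_rel_F = noise_rel_F, noise_rel_A = noise_rel_A,
                      seed = seed)
}

null_scenario <- function(seed, eps_guest = 1000,
                          noise_rel_F = 0.01, noise_rel_A = 0.002) {
  static_scenario(seed, K_true = 0, eps_guest = eps_guest,
                  noise_rel_F = noise_rel_F, noise_rel_A = noise_rel_A)
}

single_exp_decay <- function(seed, tau = 5, channels = 1024L) {
  simulate_decay(decay_scenario(1, tau, channels = channels,
                                channel_width = 0.05, seed = seed))
}
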