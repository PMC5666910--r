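# Shared fixtures and independent oracles used across the suite.

# random binary label pilot on n images of v voxels
random_pilot <- function(n = 3, v = 12, p = 0.4, with_h = FALSE, seed = 1) {
  set.seed(seed)
  draw <- function() lapply(seq_len(n), function(k) rbinom(v, 1, p))
  pilot_dataset(draw(), draw(), draw(), if (with_h) draw() else NULL)
}

# independent McNemar paired-proportion sample size (normal quantiles):
# number of paired samples to detect a difference `delta` in correct
# classification with discordance probability `psi`
mcnemar_sample_size <- function(psi, delta, alpha = 0.05, beta = 0.20) {
  (qnorm(1 - alpha / 2) * sqrt(psi) +
     qnorm(1 - beta) * sqrt(psi - delta^2))^2 / delta^2
}

# brute-force rectangle probability P(Z1 > a, Z2 > b) for correlated
# standard normals by nested 1-D quadrature (independent of pbinorm)
upper_rect_prob <- function(a, b, rho) {
  integrate(function(z) {
    pnorm((b - rho * z) / sqrt(1 - rho^2), lower.tail = FALSE) * dnorm(z)
  }, lower = a, upper = Inf, rel.tol = 1e-10)$value
}

# ordinal (-1,0,1) Pearson correlation implied by a latent normal
# correlation, via brute-force integration (oracle for the calibration)
ordinal_corr_oracle <- function(latent, pm1, p1) {
  t1 <- qnorm(pm1); t2 <- qnorm(1 - p1)
  P11 <- upper_rect_prob(t2, t2, latent)
  Pmm <- upper_rect_prob(-t1, -t1, latent)   # symmetry: P(Z<=t1, Z<=t1)
  # P(Z1 > t2, Z2 <= t1) = P(Z1 > t2) - P(Z1 > t2, Z2 > t1)
  P1m <- pnorm(t2, lower.tail = FALSE) - upper_rect_prob(t2, t1, latent)
  exy <- P11 + Pmm - 2 * P1m
  d <- p1 - pm1
  (exy - d^2) / ((p1 + pm1) - d^2)
}

# standard baseline simulation configuration (6x6 lattice, omega = 128,
# sigma_rho = 0.7, psi = 0.15)
baseline_config <- function(delta = 0.03, n_images, n_reps, seed) {
  psi <- 0.15
  simulation_config(build_spatial_model(c(6, 6), 0.7),
                    p_vec = c((psi + delta) / 2, 1 - psi, (psi - delta) / 2),
                    omega = 128, n_images = n_images, n_reps = n_reps,
                    seed = seed)
}
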