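test_that("pooled probability and disagreement estimators are grand means", {
  p <- pilot_dataset(a = list(c(1, 0), c(1, 1)), b = list(c(0, 0), c(1, 1)),
                     l = list(c(1, 1), c(0, 0)))
  expect_equal(estimate_foreground_prob(p, "A"), 0.75)
  expect_equal(estimate_psi(p), 0.25)
  zeros <- pilot_dataset(a = c(0, 0), b = c(0, 0), l = c(0, 0))
  expect_equal(estimate_foreground_prob(zeros, "A"), 0)
  expect_equal(estimate_psi(zeros), 0)
  expect_error(estimate_foreground_prob(p, "H"), "not present")

  p2 <- pilot_dataset(a = c(1, 1, 0, 0), b = c(1, 0, 0, 0), l = c(1, 1, 1, 1))
  expect_equal(estimate_psi(p2), 0.25)
  p3 <- pilot_dataset(a = c(1, 1, 0), b = c(0, 1, 0), l = c(1, 1, 1))
  expect_equal(estimate_delta(p3), 1 / 3)
})

test_that("error covariance matches the pooled-voxel formula", {
  p <- pilot_dataset(a = c(1, 0), b = c(0, 0), l = c(1, 0), h = c(0, 0))
  expect_equal(estimate_error_covariance(p), 0.5)
  # L = H everywhere: zero covariance
  q <- random_pilot(n = 3, v = 20, seed = 3)
  q2 <- pilot_dataset(q$a, q$b, q$l, q$l)
  expect_equal(estimate_error_covariance(q2), 0)
  expect_error(estimate_error_covariance(q), "requires")
  # independent fields: covariance shrinks towards zero
  set.seed(8)
  big <- pilot_dataset(a = list(rbinom(20000, 1, 0.3)),
                       b = list(rbinom(20000, 1, 0.3)),
                       l = list(rbinom(20000, 1, 0.25)),
                       h = list(rbinom(20000, 1, 0.25)))
  expect_lt(abs(estimate_error_covariance(big)), 3 * sqrt(0.42 * 0.375) / sqrt(20000))
})

test_that("per-image variance and its conservative bound behave correctly", {
  p <- pilot_dataset(a = list(c(1, 0, 0, 0), c(1, 1, 0, 0), c(1, 1, 1, 0)),
                     b = list(rep(0, 4), rep(0, 4), rep(0, 4)),
                     l = list(rep(1, 4), rep(1, 4), rep(1, 4)))
  # d_bar = (0.25, 0.5, 0.75); rescale to the documented example via identity
  ev <- estimate_variance(p, config = estimation_config(seed = 1))
  expect_equal(ev$sigma2_hat, var(c(0.25, 0.5, 0.75)))
  expect_equal(var(c(0.01, 0.02, 0.03)), 1e-4)  # hand value used in docs
  # constant differences: zero variance and zero bound
  cst <- pilot_dataset(a = list(c(1, 1), c(1, 1)), b = list(c(0, 0), c(0, 0)),
                       l = list(c(1, 1), c(1, 1)))
  evc <- estimate_variance(cst)
  expect_equal(evc$sigma2_hat, 0)
  expect_equal(evc$sigma2_upper, 0)
  expect_error(estimate_variance(pilot_dataset(a = 1, b = 0, l = 1)),
               "at least 2")
})

test_that("conservative variance bound attains its nominal coverage", {
  set.seed(2024)
  true_var <- 4e-4
  reps <- 400
  hits <- 0
  for (r in seq_len(reps)) {
    x <- rnorm(10, 0.03, sqrt(true_var))
    ub <- variance_upper_bound(x, gamma = 80, boot_outer = 300,
                               boot_inner = 100, seed = r)
    if (ub >= true_var) hits <- hits + 1
  }
  coverage <- hits / reps
  se <- sqrt(0.8 * 0.2 / reps)
  expect_gte(coverage, 0.8 - 3 * se)
})

test_that("design factor estimate inverts the Dirichlet variance relation", {
  expect_equal(estimate_design_factor(0.134, 0.0402, 0.00231),
               0.00231 / (0.134 - 0.0402^2))
  expect_equal(estimate_design_factor(0.134, 0.0402, 0.00231), 0.017449,
               tolerance = 1e-4)
  expect_equal(estimate_design_factor(0.2, 0.1, 0.2 - 0.01), 1)
  expect_equal(estimate_design_factor(0.2, 0.1, 0), 0)
  expect_warning(f <- estimate_design_factor(0.2, 0.1, 0.5), "clipping")
  expect_equal(f, 1)
  expect_error(estimate_design_factor(0.01, 0.2, 0.001), "exceed")
})

test_that("variance, design factor and rho_bar round-trip exactly", {
  set.seed(5)
  for (i in 1:10) {
    psi <- runif(1, 0.05, 0.4); delta <- runif(1, 0, 0.5) * sqrt(psi)
    omega <- runif(1, 1, 300); rho <- runif(1, 0, 1)
    s2 <- variance_dirichlet(psi, delta, omega = omega, rho_bar = rho)
    f <- estimate_design_factor(psi, delta, s2)
    expect_equal(f, design_factor(omega, rho), tolerance = 1e-12)
    expect_equal(estimate_rho_bar(s2, psi, delta, omega), rho,
                 tolerance = 1e-12)
  }
  # boundary cases of the rho_bar inverse
  expect_equal(estimate_rho_bar((0.11 - 0.01^2) / 11, 0.11, 0.01, 10), 0,
               tolerance = 1e-10)
  expect_equal(estimate_rho_bar(0.11 - 1e-4, 0.11, 0.01, 10), 1,
               tolerance = 1e-10)
})

test_that("estimators are invariant to image and voxel ordering", {
  p <- random_pilot(n = 4, v = 30, with_h = TRUE, seed = 21)
  perm_img <- sample(4)
  set.seed(99); perm_vox <- lapply(1:4, function(k) sample(30))
  q <- pilot_dataset(
    a = lapply(seq_along(perm_img), function(k) p$a[[perm_img[k]]][perm_vox[[k]]]),
    b = lapply(seq_along(perm_img), function(k) p$b[[perm_img[k]]][perm_vox[[k]]]),
    l = lapply(seq_along(perm_img), function(k) p$l[[perm_img[k]]][perm_vox[[k]]]),
    h = lapply(seq_along(perm_img), function(k) p$h[[perm_img[k]]][perm_vox[[k]]]))
  expect_equal(estimate_psi(p), estimate_psi(q))
  expect_equal(estimate_delta(p), estimate_delta(q))
  expect_equal(estimate_foreground_prob(p, "A"), estimate_foreground_prob(q, "A"))
  expect_equal(estimate_error_covariance(p), estimate_error_covariance(q))
  expect_equal(estimate_variance(p)$sigma2_hat, estimate_variance(q)$sigma2_hat)
})

test_that("Dirichlet-multinomial precision fit matches a beta-binomial oracle", {
  set.seed(17)
  o <- sample_image_prior(c(0.3, 0.7, 0), 20, 40)
  counts <- t(vapply(seq_len(40), function(k)
    drop(rmultinom(1, 50, c(o[k, 1], 1 - o[k, 1]))), numeric(2)))
  fit <- fit_dm_precision(counts)
  # independent oracle: 1-D likelihood maximisation of the beta-binomial
  # with the mean fixed at the pooled proportion
  p <- sum(counts[, 1]) / sum(counts)
  m <- rowSums(counts)
  nll <- function(lw) {
    w <- exp(lw)
    -sum(lgamma(w) - lgamma(m + w) +
           lgamma(counts[, 1] + w * p) - lgamma(w * p) +
           lgamma(counts[, 2] + w * (1 - p)) - lgamma(w * (1 - p)))
  }
  opt <- optimize(nll, c(log(1e-3), log(1e7)), tol = 1e-10)
  expect_equal(fit$omega_hat, exp(opt$minimum), tolerance = 1e-4)
})

test_that("precision fit flags data without inter-image variability", {
  counts <- matrix(rep(c(30, 60, 10), 8), ncol = 3, byrow = TRUE)
  fit <- fit_dm_precision(counts)
  expect_true(fit$capped)
  expect_equal(fit$omega_hat, 1e9)
  # absent category: reduced-dimension fit with warning
  set.seed(3)
  o <- sample_image_prior(c(0.3, 0.7, 0), 50, 30)
  c2 <- t(vapply(seq_len(30), function(k)
    drop(rmultinom(1, 40, o[k, ])), numeric(3)))
  expect_warning(fit2 <- fit_dm_precision(c2), "absent")
  expect_gt(fit2$omega_hat, 1)
})

test_that("precision recovery on independent-voxel pilots is well-behaved", {
  # 100 images of 400 independent voxels: enough information for a tight
  # estimate (with few voxels per image the likelihood is nearly flat in
  # omega and no estimator can recover it precisely)
  set.seed(12)
  o <- sample_image_prior(c(0.09, 0.85, 0.06), 128, 100)
  counts <- t(vapply(seq_len(100), function(k)
    drop(rmultinom(1, 400, o[k, ])), numeric(3)))
  fit <- fit_dm_precision(counts)
  expect_lt(abs(fit$omega_hat - 128) / 128, 0.4)
})

test_that("estimate_all orchestrates the full workflow and its errors", {
  sp <- build_spatial_model(c(6, 6), 0.7)
  cfg <- simulation_config(sp, c(0.09, 0.85, 0.06), 128, n_images = 25,
                           seed = 10)
  pilot <- simulate_pilot(cfg)
  est <- estimate_all(pilot, config = estimation_config(boot_outer = 200,
                                                        boot_inner = 100),
                      sigma_rho = 0.7)
  expect_s3_class(est, "pilot_estimates")
  expect_true(abs(est$psi_hat - 0.15) < 0.08)
  expect_true(est$sigma2_upper >= est$sigma2_hat)
  expect_true(is.finite(est$f_hat) && est$f_hat > 0 && est$f_hat <= 1)

  # identical algorithms: psi = delta = 0, no design factor
  same <- pilot_dataset(pilot$a, pilot$a, pilot$l)
  est2 <- estimate_all(same, fit_precision = FALSE,
                       config = estimation_config(boot_outer = 100,
                                                  boot_inner = 100))
  expect_equal(est2$psi_hat, 0)
  expect_true(any(grepl("design factor", est2$warnings)))

  # requesting the MDD adjustment without H is an error
  expect_error(estimate_all(pilot, delta_mdd_H = 0.05), "no high-quality")
})

test_that("sparse lattice thinning respects the native grid", {
  idx <- segpower:::sparse_indices(36, c(6, 6), 3)
  expect_equal(idx, c(1L, 4L, 19L, 22L))   # rows/cols {1, 4} of a 6x6 grid
  expect_equal(segpower:::sparse_indices(10, NULL, 4), c(1L, 5L, 9L))
})
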