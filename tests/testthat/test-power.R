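test_that("moment-based variance follows the model formula", {
  expect_equal(variance_moments(0.15, 0.03, 0.05, 0.001),
               0.05 * 0.1491 + 0.95 * 0.001)   # 0.0084055
  expect_equal(variance_moments(0.2, 0.1, 1, 0.5), 0.2 - 0.01)
  expect_equal(variance_moments(0.2, 0.1, 0, 0), 0)
  expect_error(variance_moments(0.01, 0.2, 0.5, 0), "psi")
})

test_that("Dirichlet variance reproduces the case-study values", {
  f <- estimate_design_factor(0.134, 0.0402, 0.00231)
  expect_equal(signif(variance_dirichlet(0.134, 0, f = f), 3), 0.00234)
  expect_equal(signif(variance_dirichlet(0.134, 0.05, f = f), 3), 0.00229)
  expect_equal(variance_dirichlet(0.3, 0.1, f = 1), 0.3 - 0.01)
  expect_equal(variance_dirichlet(0.3, 0.1, omega = 128, rho_bar = 0.05),
               (1 + 128 * 0.05) / 129 * 0.29)
  expect_error(variance_dirichlet(0.3, 0.1, f = 1.2), "design factor")
})

test_that("solver reproduces the normal-quantile closed form", {
  d <- study_design(delta_mdd = 0.05, use_normal = TRUE)
  r <- solve_sample_size(variance_spec(0.02, 0.02), d)
  expect_equal(r$n_continuous,
               (qnorm(0.975) + qnorm(0.8))^2 * 0.02 / 0.0025,
               tolerance = 1e-12)
  expect_equal(r$n_continuous, 62.79, tolerance = 1e-3)
})

test_that("solver scaling and degenerate inputs behave as contracted", {
  v <- variance_spec(0.01, 0.01)
  n1 <- solve_sample_size(v, study_design(delta_mdd = 0.04))$n_continuous
  n2 <- solve_sample_size(v, study_design(delta_mdd = 0.08))$n_continuous
  expect_lt(n2, n1 / 3.5)  # ~ quarter, asymptotically exact
  # sign of delta_mdd is irrelevant
  n3 <- solve_sample_size(v, study_design(delta_mdd = -0.04))$n_continuous
  expect_equal(n1, n3)
  expect_error(solve_sample_size(variance_spec(0, 0),
                                 study_design(delta_mdd = 0.05)),
               "degenerate")
  expect_error(solve_sample_size(v, study_design(delta_mdd = 0)), "nonzero")
})

test_that("Dirichlet-path sample sizes reproduce the published grid cells", {
  expect_equal(sample_size_dirichlet(0.11, study_design(delta_mdd = 0.02),
                                     f = 0.05)$n, 110L)
  expect_equal(sample_size_dirichlet(0.20, study_design(delta_mdd = 0.05),
                                     f = 0.10)$n, 65L)
  expect_equal(sample_size_dirichlet(0.15, study_design(delta_mdd = 0.10),
                                     f = 0.10)$n, 14L)
  expect_equal(sample_size_dirichlet(0.05, study_design(delta_mdd = 0.05),
                                     f = 0.05)$n, 10L)
  expect_error(sample_size_dirichlet(0.0001, study_design(delta_mdd = 0.05),
                                     f = 0.05), "psi")
})

test_that("moment and Dirichlet paths agree through the moment identity", {
  # sigma2_{O1-O-1} = (psi - delta^2)/(omega + 1) makes the two paths equal
  set.seed(7)
  for (i in 1:10) {
    psi <- runif(1, 0.05, 0.4)
    dmdd <- min(runif(1, 0.2, 0.8) * sqrt(psi), 0.9 * psi)  # |delta| <= psi
    omega <- runif(1, 2, 500)
    rho_bar <- runif(1, 0.01, 0.9)
    m <- population_model(p1 = (psi + dmdd) / 2, p0 = 1 - psi,
                          pm1 = (psi - dmdd) / 2,
                          omega = omega, rho_bar = rho_bar,
                          sigma2_null = psi / (omega + 1),
                          sigma2_alt = (psi - dmdd^2) / (omega + 1))
    des <- study_design(delta_mdd = dmdd)
    n_mom <- sample_size_moments(m, des)$n_continuous
    n_dir <- sample_size_dirichlet(psi, des, omega = omega,
                                   rho_bar = rho_bar)$n_continuous
    expect_equal(n_mom, n_dir, tolerance = 1e-9)
  }
})

test_that("independent voxels with no image variability hit the McNemar limit", {
  # rho_bar = 1/v and sigma2 = 0: n * v equals the McNemar paired-proportion
  # sample size (normal quantiles; independently coded oracle)
  for (psi in c(0.05, 0.15, 0.30)) {
    for (dmdd in c(0.02, 0.05, 0.10)) {
      if (psi <= dmdd) next   # need |delta| <= psi for a valid p-vector
      for (v in c(50, 200)) {
        m <- population_model(p1 = (psi + dmdd) / 2, p0 = 1 - psi,
                              pm1 = (psi - dmdd) / 2,
                              rho_bar = 1 / v,
                              sigma2_null = 0, sigma2_alt = 0)
        des <- study_design(delta_mdd = dmdd, use_normal = TRUE)
        n <- sample_size_moments(m, des)$n_continuous
        expect_equal(n * v, mcnemar_sample_size(psi, dmdd),
                     tolerance = 1 / (n * v))
      }
    }
  }
})

test_that("sample size is monotone in psi, f and |delta_mdd|", {
  n_of <- function(psi, dmdd, f)
    sample_size_dirichlet(psi, study_design(delta_mdd = dmdd),
                          f = f)$n_continuous
  expect_true(n_of(0.10, 0.05, 0.05) < n_of(0.20, 0.05, 0.05))
  expect_true(n_of(0.15, 0.05, 0.02) < n_of(0.15, 0.05, 0.08))
  expect_true(n_of(0.15, 0.08, 0.05) < n_of(0.15, 0.04, 0.05))
})

test_that("power at the solved n meets the target and inverts the fixed point", {
  for (dmdd in c(0.03, 0.06)) {
    des <- study_design(delta_mdd = dmdd)
    r <- sample_size_dirichlet(0.15, des, f = 0.05)
    expect_gte(r$power_at_n, 0.8 - 1e-9)
    v <- variance_spec(variance_dirichlet(0.15, 0, f = 0.05),
                       variance_dirichlet(0.15, dmdd, f = 0.05))
    # at the continuous solution the power equals the target exactly
    expect_equal(power_at_n(r$n_continuous, des, variances = v), 0.8,
                 tolerance = 1e-6)
  }
  expect_error(power_at_n(2, study_design(delta_mdd = 0.05),
                          variances = variance_spec(0.01, 0.01)), "n >= 3")
})

test_that("power_at_n matches a Monte Carlo t-test simulation", {
  # normal per-image differences, sd sqrt(0.02), delta = 0.05, n = 63
  des <- study_design(delta_mdd = 0.05)
  pred <- power_at_n(63, des, variances = variance_spec(0.02, 0.02))
  set.seed(31)
  reps <- 20000
  hits <- sum(replicate(reps, {
    x <- rnorm(63, mean = 0.05, sd = sqrt(0.02))
    paired_t_test(x)$significant
  }))
  emp <- hits / reps
  se <- sqrt(emp * (1 - emp) / reps)
  expect_lt(abs(emp - pred), 3 * se + 0.005)
  expect_equal(pred, 0.80, tolerance = 0.02)
})

test_that("the reference grid matches the published table within one image", {
  g <- sample_size_grid()
  expect_equal(nrow(g), 27L)
  published <- rbind(
    c(0.02, 0.020, 6, 21, 41), c(0.02, 0.110, 24, 110, 218),
    c(0.02, 0.200, 41, 198, 394),
    c(0.05, 0.050, 3, 10, 17), c(0.05, 0.125, 6, 21, 41),
    c(0.05, 0.200, 8, 33, 65),
    c(0.10, 0.100, 3, 6, 10), c(0.10, 0.150, 3, 8, 14),
    c(0.10, 0.200, 3, 10, 17))
  for (r in seq_len(nrow(published))) {
    for (j in 1:3) {
      f <- c(0.01, 0.05, 0.10)[j]
      cell <- g$n[g$delta_mdd == published[r, 1] &
                    g$psi == published[r, 2] & g$f == f]
      expect_lte(abs(cell - published[r, j + 2]), 1)
    }
  }
  # monotone within each block: in f and in psi
  for (d in unique(g$delta_mdd)) {
    blk <- g[g$delta_mdd == d, ]
    for (psi in unique(blk$psi))
      expect_false(is.unsorted(blk$n[blk$psi == psi][order(c(0.01, 0.05, 0.1))]))
    for (f in unique(blk$f))
      expect_false(is.unsorted(blk$n[blk$f == f][order(unique(blk$psi))]))
  }
  # small-sample flagging convention
  expect_true(all(g$flagged == (g$n < 9)))
})
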