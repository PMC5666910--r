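## Sample-size and power calculations for paired comparisons of two
## segmentation algorithms analysed with a paired t-test on per-image
## accuracy differences.

#' Design factor from Dirichlet precision and average voxel correlation
#'
#' `f = (1 + omega * rho_bar) / (omega + 1)`, the multiplier by which
#' intra-image inter-voxel correlation (`rho_bar`) and inter-image
#' variability (Dirichlet precision `omega`) inflate the variance of the
#' per-image accuracy difference relative to `psi - delta^2`. Analogous to
#' the design effect in cluster-randomized trials: each image is one cluster
#' of correlated voxel samples. `f` ranges from `1/v` (independent voxels,
#' homogeneous images as `omega` grows with `rho_bar = 1/v`) to 1.
#'
#' @param omega Dirichlet precision (> 0, possibly `Inf`).
#' @param rho_bar Average inter-voxel correlation, in `[0, 1]`.
#' @return The design factor, in (0, 1].
#' @export
design_factor <- function(omega, rho_bar) {
  if (!(omega > 0)) stop("omega must be positive")
  if (rho_bar < 0 || rho_bar > 1) stop("rho_bar must lie in [0, 1]")
  if (is.infinite(omega)) return(max(rho_bar, .Machine$double.xmin))
  (1 + omega * rho_bar) / (omega + 1)
}

#' Variance of the per-image accuracy difference (moment form)
#'
#' For any per-image prior on the marginal difference probabilities,
#' the variance of the per-image mean difference is
#' `rho_bar * (psi - delta^2) + (1 - rho_bar) * sigma2_O1mOm1`, where
#' `sigma2_O1mOm1` is the variance of `O1 - O(-1)` under the prior.
#'
#' @param psi Disagreement probability, `psi >= delta^2` required.
#' @param delta Accuracy difference at which to evaluate the variance.
#' @param rho_bar Average inter-voxel correlation, in `[0, 1]`.
#' @param sigma2_O1mOm1 Prior variance of `O1 - O(-1)` (>= 0).
#' @return The variance of the per-image accuracy difference.
#' @examples
#' variance_moments(0.15, 0.03, 0.05, 0.001)  # 0.0084055
#' @export
variance_moments <- function(psi, delta, rho_bar, sigma2_O1mOm1) {
  if (psi < delta^2)
    stop("invalid parameters: psi must be at least delta^2")
  if (sigma2_O1mOm1 < 0) stop("sigma2_O1mOm1 must be non-negative")
  if (rho_bar < 0 || rho_bar > 1) stop("rho_bar must lie in [0, 1]")
  rho_bar * (psi - delta^2) + (1 - rho_bar) * sigma2_O1mOm1
}

#' Variance of the per-image accuracy difference (Dirichlet prior)
#'
#' Under a Dirichlet per-image prior the variance reduces to
#' `f * (psi - delta^2)` with design factor
#' `f = (1 + omega * rho_bar) / (omega + 1)`.
#'
#' @param psi Disagreement probability; `psi >= delta^2` required.
#' @param delta Accuracy difference at which to evaluate the variance.
#' @param f Design factor in (0, 1]. Alternatively supply `omega` and
#'   `rho_bar` and `f` is formed internally.
#' @param omega,rho_bar Dirichlet precision and average voxel correlation,
#'   used when `f` is not given.
#' @return The variance of the per-image accuracy difference.
#' @examples
#' f <- 0.00231 / (0.134 - 0.0402^2)
#' variance_dirichlet(0.134, 0,    f = f)  # ~0.00234
#' variance_dirichlet(0.134, 0.05, f = f)  # ~0.00229
#' @export
variance_dirichlet <- function(psi, delta, f = NULL, omega = NULL,
                               rho_bar = NULL) {
  if (is.null(f)) {
    if (is.null(omega) || is.null(rho_bar))
      stop("supply either f or both omega and rho_bar")
    f <- design_factor(omega, rho_bar)
  }
  if (!(f > 0 && f <= 1)) stop("design factor f must lie in (0, 1]")
  if (psi < delta^2) stop("invalid parameters: psi must be at least delta^2")
  f * (psi - delta^2)
}

## internal: two- and one-tailed critical values at (possibly continuous) df
crit_values <- function(alpha, beta, df, use_normal) {
  if (use_normal || is.infinite(df))
    c(qnorm(1 - alpha / 2), qnorm(1 - beta))
  else
    c(qt(1 - alpha / 2, df), qt(1 - beta, df))
}

#' Solve the generic sample size formula
#'
#' Solves `n = (t_{alpha/2} * sigma_0 + t_{beta} * sigma_alt)^2 / delta_mdd^2`
#' where the two- and one-tailed critical values are taken from the
#' t-distribution with `n - 1` degrees of freedom, creating a circular
#' dependence on `n`. The solver starts from the normal-quantile closed form
#' and applies a damped fixed-point iteration on the continuous `n`
#' (degrees of freedom floored at 2) until the update falls below the
#' design's tolerance. The reported headline `n` is the ceiling of the
#' converged continuous solution (conservative); `n_continuous` is exposed
#' for boundary analysis.
#'
#' @param variances A [variance_spec()] (or anything with `sigma2_null` and
#'   `sigma2_alt` fields).
#' @param design A [study_design()] with nonzero `delta_mdd`.
#' @return An object of class `"sample_size_result"`: list with
#'   `n_continuous`, `n`, `t_alpha2`, `t_beta1`, `power_at_n`, and
#'   `small_sample` (`TRUE` when `n < 10`, where the t-test is sensitive to
#'   violations of its assumptions).
#' @examples
#' d <- study_design(delta_mdd = 0.05, use_normal = TRUE)
#' solve_sample_size(variance_spec(0.02, 0.02), d)$n_continuous  # 62.79
#' @export
solve_sample_size <- function(variances, design) {
  s0 <- sqrt(variances$sigma2_null)
  salt <- sqrt(variances$sigma2_alt)
  if (s0 == 0 && salt == 0)
    stop("degenerate input: both variances are zero")
  dmdd <- abs(design$delta_mdd)
  if (dmdd == 0) stop("delta_mdd must be nonzero to solve for a sample size")
  g <- function(n) {
    q <- crit_values(design$alpha, design$beta, max(n - 1, 2),
                     design$use_normal)
    (q[1] * s0 + q[2] * salt)^2 / dmdd^2
  }
  q0 <- crit_values(design$alpha, design$beta, Inf, TRUE)
  n <- (q0[1] * s0 + q0[2] * salt)^2 / dmdd^2
  if (!design$use_normal) {
    converged <- FALSE
    for (i in seq_len(design$max_iter)) {
      n_new <- (g(n) + n) / 2          # damped fixed point
      if (abs(n_new - n) < design$tol) { n <- n_new; converged <- TRUE; break }
      n <- n_new
    }
    if (!converged)
      stop("sample size iteration failed to converge after ",
           design$max_iter, " iterations")
  }
  n_int <- as.integer(ceiling(n - 1e-9))
  n_int <- max(n_int, 3L)
  q <- crit_values(design$alpha, design$beta, max(n - 1, 2), design$use_normal)
  structure(
    list(n_continuous = n, n = n_int,
         t_alpha2 = q[1], t_beta1 = q[2],
         power_at_n = power_at_n(n_int, design, variances = variances),
         small_sample = n_int < 10L),
    class = "sample_size_result")
}

#' @export
print.sample_size_result <- function(x, ...) {
  cat(sprintf("Required sample size: n = %d images (continuous %.3f)\n",
              x$n, x$n_continuous))
  cat(sprintf("  critical values t_alpha{2} = %.4f, t_beta{1} = %.4f\n",
              x$t_alpha2, x$t_beta1))
  cat(sprintf("  achieved power at n: %.4f\n", x$power_at_n))
  if (isTRUE(x$small_sample))
    cat("  note: n < 10; the t-test may be sensitive to assumption",
        "violations at such small sample sizes\n")
  invisible(x)
}

#' Sample size from the moment-based variance model
#'
#' Builds the null and alternative variances via [variance_moments()] (at
#' `delta = 0` and `delta = delta_mdd`) and solves the generic formula.
#'
#' @param model A [population_model()] whose `rho_bar`, `sigma2_null` and
#'   `sigma2_alt` fields are set (the `psi` field supplies the disagreement
#'   probability).
#' @param design A [study_design()].
#' @return A `"sample_size_result"`, see [solve_sample_size()].
#' @export
sample_size_moments <- function(model, design) {
  if (is.null(model$sigma2_null) || is.null(model$sigma2_alt))
    stop("model must carry sigma2_null and sigma2_alt for the moment-based path")
  v0 <- variance_moments(model$psi, 0, model$rho_bar, model$sigma2_null)
  va <- variance_moments(model$psi, design$delta_mdd, model$rho_bar,
                         model$sigma2_alt)
  solve_sample_size(variance_spec(v0, va), design)
}

#' Sample size under the Dirichlet prior (design factor form)
#'
#' Solves `n = f * (t_{alpha/2} * sqrt(psi / delta_mdd^2) +
#' t_{beta} * sqrt(psi / delta_mdd^2 - 1))^2`, the Dirichlet-prior special
#' case of the generic formula, by the same fixed-point scheme. The quantity
#' `psi / delta_mdd^2` is the idealized efficiency: the sample size is
#' roughly proportional to it, modulated by the design factor.
#'
#' @param psi Disagreement probability; must satisfy `psi >= delta_mdd^2`.
#' @param design A [study_design()].
#' @param f Design factor in (0, 1]; alternatively supply `omega` and
#'   `rho_bar`.
#' @param omega,rho_bar Used to form `f` when it is not given.
#' @return A `"sample_size_result"`, see [solve_sample_size()].
#' @examples
#' sample_size_dirichlet(psi = 0.11, study_design(delta_mdd = 0.02),
#'                       f = 0.05)$n  # 110
#' @export
sample_size_dirichlet <- function(psi, design, f = NULL, omega = NULL,
                                  rho_bar = NULL) {
  if (is.null(f)) f <- design_factor(omega, rho_bar)
  if (!(f > 0 && f <= 1)) stop("design factor f must lie in (0, 1]")
  if (psi < design$delta_mdd^2)
    stop("psi must be at least delta_mdd^2 (idealized efficiency >= 1)")
  v0 <- variance_dirichlet(psi, 0, f = f)
  va <- variance_dirichlet(psi, design$delta_mdd, f = f)
  solve_sample_size(variance_spec(v0, va), design)
}

#' Achieved power at a given sample size
#'
#' Inverts the generic sample size relation for the one-tailed critical
#' value: `t_beta1 = (|delta_mdd| * sqrt(n) - t_{alpha/2} * sigma_0) /
#' sigma_alt`, and returns `P(T_{n-1} <= t_beta1)`.
#'
#' @param n Integer sample size, `n >= 3`.
#' @param design A [study_design()].
#' @param variances A [variance_spec()]; alternatively supply `psi` with `f`
#'   (or `omega` and `rho_bar`) for the Dirichlet-prior variances.
#' @param psi,f,omega,rho_bar Dirichlet-path parameterization, used when
#'   `variances` is `NULL`.
#' @return The power, in (0, 1).
#' @export
power_at_n <- function(n, design, variances = NULL, psi = NULL, f = NULL,
                       omega = NULL, rho_bar = NULL) {
  if (n < 3) stop("power_at_n requires n >= 3")
  if (is.null(variances)) {
    if (is.null(psi)) stop("supply either variances or psi with f/omega")
    if (is.null(f)) f <- design_factor(omega, rho_bar)
    variances <- variance_spec(variance_dirichlet(psi, 0, f = f),
                               variance_dirichlet(psi, design$delta_mdd, f = f))
  }
  s0 <- sqrt(variances$sigma2_null)
  salt <- sqrt(variances$sigma2_alt)
  if (salt == 0) stop("sigma2_alt must be positive to evaluate power")
  df <- n - 1
  ta <- if (design$use_normal) qnorm(1 - design$alpha / 2) else
    qt(1 - design$alpha / 2, df)
  tb <- (abs(design$delta_mdd) * sqrt(n) - ta * s0) / salt
  if (design$use_normal) pnorm(tb) else pt(tb, df)
}

#' Sample size reference grid
#'
#' Tabulates the Dirichlet-prior sample size over a grid of minimum
#' detectable differences, disagreement probabilities and design factors.
#' The default grid spans small (2%), medium (5%) and large (10%)
#' detectable differences; for each, disagreement ranges from the minimal
#' possible (`psi = delta_mdd`) through a midpoint to large disagreement
#' (`psi = 20%`); and design factors 0.01, 0.05 and 0.1 represent low to
#' high correlation. Cells with `n` below `small_n_threshold` are flagged:
#' such studies are highly sensitive to t-test assumption violations.
#'
#' @param delta_mdd Vector of minimum detectable differences.
#' @param psi_levels Named list mapping each `delta_mdd` (as character) to
#'   its vector of `psi` levels; the default reproduces the standard grid.
#' @param f Vector of design factors.
#' @param alpha,beta Error rates.
#' @param small_n_threshold Flag cells with `n` below this value (default 9).
#' @return A data frame with columns `delta_mdd`, `psi`, `f`,
#'   `idealized_efficiency`, `n_continuous`, `n`, `flagged`.
#' @export
sample_size_grid <- function(delta_mdd = c(0.02, 0.05, 0.10),
                             psi_levels = NULL,
                             f = c(0.01, 0.05, 0.10),
                             alpha = 0.05, beta = 0.20,
                             small_n_threshold = 9) {
  if (is.null(psi_levels)) {
    psi_levels <- lapply(delta_mdd, function(d) {
      hi <- 0.20
      c(d, (d + hi * 1.05) / 2, hi)  # minimal, midpoint, large disagreement
    })
    ## canonical midpoints for the standard grid
    std <- list("0.02" = c(0.02, 0.11, 0.20),
                "0.05" = c(0.05, 0.125, 0.20),
                "0.1"  = c(0.10, 0.15, 0.20))
    psi_levels <- lapply(delta_mdd, function(d) {
      key <- as.character(d)
      if (!is.null(std[[key]])) std[[key]] else
        c(d, (d + 0.20) / 2, 0.20)
    })
  }
  rows <- list()
  for (i in seq_along(delta_mdd)) {
    d <- delta_mdd[i]
    for (psi in psi_levels[[i]]) {
      for (fd in f) {
        res <- sample_size_dirichlet(psi, study_design(alpha, beta, d), f = fd)
        rows[[length(rows) + 1L]] <- data.frame(
          delta_mdd = d, psi = psi, f = fd,
          idealized_efficiency = psi / d^2,
          n_continuous = res$n_continuous, n = res$n,
          flagged = res$n < small_n_threshold)
      }
    }
  }
  do.call(rbind, rows)
}
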