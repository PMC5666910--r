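## Plug-in estimation of all model parameters from a pilot dataset:
## grand-mean probabilities, pooled covariance, per-image variance with a
## calibrated double-bootstrap upper bound, design factor, and the
## Dirichlet-multinomial precision from sparsely spaced voxels.

#' Estimation settings
#'
#' @param gamma Confidence level (in percent) for the conservative upper
#'   bound on the per-image variance. Using the upper end of a confidence
#'   interval rather than the point estimate guards against underpowered
#'   studies caused by the skew of small-sample variance estimates.
#' @param boot_outer,boot_inner Replicate counts for the double (calibrated)
#'   bootstrap; both must be at least 100.
#' @param sparse_spacing Voxel spacing used when thinning the grid for the
#'   Dirichlet precision estimator; voxels this far apart are treated as
#'   uncorrelated. `NULL` picks the default: the smallest integer `x` with
#'   `exp(-x / sigma_rho^2) < 0.01` when `sigma_rho` is known, else 5.
#' @param seed Random seed for the bootstrap; required for reproducibility.
#' @param omega_cap Cap on the estimated Dirichlet precision; estimates at
#'   the cap are flagged as "no detectable inter-image variability".
#' @return An object of class `"estimation_config"`.
#' @export
estimation_config <- function(gamma = 80, boot_outer = 1000L,
                              boot_inner = 200L, sparse_spacing = NULL,
                              seed = 1L, omega_cap = 1e9) {
  if (!(gamma > 0 && gamma < 100)) stop("gamma must lie in (0, 100)")
  if (boot_outer < 100L || boot_inner < 100L)
    stop("bootstrap replicate counts must be at least 100")
  if (!is.null(sparse_spacing) && sparse_spacing < 1)
    stop("sparse_spacing must be at least 1")
  structure(list(gamma = gamma, boot_outer = as.integer(boot_outer),
                 boot_inner = as.integer(boot_inner),
                 sparse_spacing = sparse_spacing,
                 seed = seed, omega_cap = omega_cap),
            class = "estimation_config")
}

#' Pooled foreground probability of one segmentation source
#'
#' Grand mean of the binary labels over all voxels of all pilot images,
#' `p_hat(x) = sum(x_{k,i}) / (n' * v)`.
#'
#' @param pilot A [pilot_dataset()].
#' @param source One of `"A"`, `"B"`, `"L"`, `"H"`.
#' @return The estimated foreground probability.
#' @export
estimate_foreground_prob <- function(pilot, source = c("A", "B", "L", "H")) {
  source <- match.arg(source)
  labels <- switch(source, A = pilot$a, B = pilot$b, L = pilot$l, H = pilot$h)
  if (is.null(labels))
    stop("source ", source, " is not present in this pilot dataset")
  x <- unlist(labels)
  if (length(x) == 0L) stop("empty label input")
  mean(x)
}

#' Covariance between algorithm differences and reference standard errors
#'
#' Pooled-voxel sample covariance between `A - B` and `L - H`, with the
#' `n' * v - 1` denominator:
#' `sum((a - b - p_hat(a) + p_hat(b)) * (l - h - p_hat(l) + p_hat(h))) /
#' (n' * v - 1)`. All voxels are pooled as if independent.
#'
#' @param pilot A [pilot_dataset()] that includes H.
#' @return The estimated covariance.
#' @export
estimate_error_covariance <- function(pilot) {
  if (is.null(pilot$h))
    stop("estimating cov(A - B, L - H) requires the high-quality reference H")
  x <- unlist(pilot$a) - unlist(pilot$b)
  y <- unlist(pilot$l) - unlist(pilot$h)
  sum((x - mean(x)) * (y - mean(y))) / (length(x) - 1)
}

#' Pooled disagreement probability between the two algorithms
#'
#' `psi_hat = sum(|a_{k,i} - b_{k,i}|) / (n' * v)`.
#'
#' @param pilot A [pilot_dataset()].
#' @return The estimated disagreement probability.
#' @export
estimate_psi <- function(pilot) {
  mean(abs(unlist(pilot$a) - unlist(pilot$b)))
}

#' Pooled accuracy difference between the two algorithms
#'
#' `delta_hat = sum(|b - ref| - |a - ref|) / (n' * v)`, the grand mean of
#' the per-voxel accuracy differences. With equal voxel counts this equals
#' the mean of the per-image means; with unequal counts the pooled grand
#' mean is used.
#'
#' @param pilot A [pilot_dataset()].
#' @param reference `"L"` (default) or `"H"`.
#' @return The estimated accuracy difference.
#' @export
estimate_delta <- function(pilot, reference = c("L", "H")) {
  d <- voxel_differences(pilot, reference)
  mean(unlist(d$d))
}

#' Upper confidence bound on a variance by double bootstrap
#'
#' Calibrated (double) percentile bootstrap upper bound for the variance of
#' the values in `x`. The outer bootstrap resamples `x` and records the
#' variance of each resample; for each outer resample an inner bootstrap
#' estimates the quantile level whose percentile bound would have covered
#' the original variance, and the nominal level is calibrated so that the
#' achieved coverage matches `gamma`. The returned bound is the calibrated
#' quantile of the outer bootstrap distribution.
#'
#' @param x Numeric vector (e.g. per-image accuracy differences), length >= 2.
#' @param gamma Confidence level in percent.
#' @param boot_outer,boot_inner Replicate counts.
#' @param seed Random seed.
#' @return The upper bound on `var(x)`.
#' @export
variance_upper_bound <- function(x, gamma = 80, boot_outer = 1000L,
                                 boot_inner = 200L, seed = 1L) {
  n <- length(x)
  if (n < 2L) stop("need at least 2 values")
  v_hat <- var(x)
  if (v_hat == 0) return(0)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  col_var <- function(m) (colSums(m^2) - colSums(m)^2 / n) / (n - 1)
  outer_mat <- matrix(x[sample.int(n, n * boot_outer, replace = TRUE)], n)
  v_outer <- col_var(outer_mat)
  ## calibration: for each outer resample, the inner quantile level at which
  ## the percentile upper bound just covers the original estimate
  u <- numeric(boot_outer)
  for (b in seq_len(boot_outer)) {
    xb <- outer_mat[, b]
    inner <- matrix(xb[sample.int(n, n * boot_inner, replace = TRUE)], n)
    u[b] <- mean(col_var(inner) < v_hat)
  }
  ## calibrated level: the gamma-quantile of the coverage roots
  lambda <- unname(quantile(u, gamma / 100, type = 6))
  lambda <- min(max(lambda, 0.5), 1 - 1 / boot_outer)
  unname(quantile(v_outer, lambda, type = 6))
}

#' Variance of per-image accuracy differences with a conservative bound
#'
#' Point estimate: unbiased sample variance of the per-image means,
#' `sum((d_bar_k - delta_hat)^2) / (n' - 1)` where `delta_hat` is the mean
#' of the `d_bar_k`. The conservative value is the upper end of a `gamma`%
#' confidence interval computed by [variance_upper_bound()].
#'
#' @param pilot A [pilot_dataset()] with at least 2 images.
#' @param reference `"L"` (default) or `"H"`.
#' @param config An [estimation_config()].
#' @return List with `sigma2_hat` and `sigma2_upper`.
#' @export
estimate_variance <- function(pilot, reference = c("L", "H"),
                              config = estimation_config()) {
  if (pilot$n_images < 2L)
    stop("variance estimation requires at least 2 pilot images")
  d_bar <- voxel_differences(pilot, reference)$d_bar
  list(sigma2_hat = var(d_bar),
       sigma2_upper = variance_upper_bound(
         d_bar, gamma = config$gamma, boot_outer = config$boot_outer,
         boot_inner = config$boot_inner, seed = config$seed))
}

#' Design factor estimate from pilot summary statistics
#'
#' `f_hat = sigma2_hat / (psi_hat - delta_hat^2)`, inverting the
#' Dirichlet-prior variance relation. Values above 1 are clipped to 1 with a
#' warning (the variance cannot exceed `psi - delta^2` under the model).
#'
#' @param psi_hat,delta_hat,sigma2_hat Pilot estimates.
#' @return The estimated design factor.
#' @examples
#' estimate_design_factor(0.134, 0.0402, 0.00231)  # 0.01745
#' @export
estimate_design_factor <- function(psi_hat, delta_hat, sigma2_hat) {
  denom <- psi_hat - delta_hat^2
  if (denom <= 0)
    stop("psi_hat must exceed delta_hat^2 to estimate a design factor")
  f <- sigma2_hat / denom
  if (f > 1) {
    warning("estimated design factor exceeds 1; clipping to 1")
    f <- 1
  }
  f
}

#' Average inter-voxel correlation from the Dirichlet variance relation
#'
#' `rho_bar_hat = (sigma2_hat * (omega_hat + 1) - (psi_hat - delta_hat^2)) /
#' ((psi_hat - delta_hat^2) * omega_hat)`, the algebraic inverse of the
#' Dirichlet-prior variance given an independently estimated precision.
#' Results outside `[0, 1]` are clipped with a warning.
#'
#' @param sigma2_hat,psi_hat,delta_hat,omega_hat Pilot estimates.
#' @return The estimated average correlation, in `[0, 1]`.
#' @export
estimate_rho_bar <- function(sigma2_hat, psi_hat, delta_hat, omega_hat) {
  if (!(omega_hat > 0)) stop("omega_hat must be positive")
  denom <- psi_hat - delta_hat^2
  if (denom <= 0) stop("psi_hat must exceed delta_hat^2")
  if (is.infinite(omega_hat)) return(min(max(sigma2_hat / denom, 0), 1))
  rho <- (sigma2_hat * (omega_hat + 1) - denom) / (denom * omega_hat)
  if (rho < 0 || rho > 1) {
    warning("estimated rho_bar ", format(rho, digits = 4),
            " outside [0, 1]; clipping")
    rho <- min(max(rho, 0), 1)
  }
  rho
}

## internal: thin a pilot image to voxels spaced `x` apart on its native
## grid (every x-th index along each grid axis); falls back to the
## flattened order when no grid shape is recorded.
sparse_indices <- function(v, grid_shape, spacing) {
  if (is.null(grid_shape)) return(seq(1L, v, by = spacing))
  axes <- lapply(grid_shape, function(d) seq(1L, d, by = spacing))
  grid <- as.matrix(expand.grid(axes))
  mult <- cumprod(c(1L, grid_shape[-length(grid_shape)]))
  as.integer(1L + (grid - 1L) %*% mult)
}

#' Dirichlet-multinomial precision from sparsely spaced voxels
#'
#' Counts the per-voxel accuracy differences over a thinned voxel lattice
#' (spacing chosen so residual spatial correlation is negligible), treats
#' the per-image counts of `D in {1, 0, -1}` as Dirichlet-multinomial, and
#' estimates the precision `omega` by fixed-point maximum likelihood with
#' the mean vector fixed at the pooled proportions. Categories absent from
#' every image are dropped (reduced-dimension fit) with a warning. When the
#' images show no more variability than multinomial sampling, the estimate
#' diverges; it is then capped at `config$omega_cap` and flagged.
#'
#' @param pilot A [pilot_dataset()] with at least 2 images.
#' @param reference `"L"` (default) or `"H"`.
#' @param config An [estimation_config()]; `sparse_spacing` sets the lattice
#'   spacing (default 5 when unknown).
#' @param sigma_rho Optional spatial correlation scale; when given, the
#'   default spacing is the smallest integer with
#'   `exp(-x / sigma_rho^2) < 0.01`.
#' @return List with `omega_hat`, `counts` (images x categories), `capped`.
#' @export
estimate_dirichlet_precision <- function(pilot, reference = c("L", "H"),
                                         config = estimation_config(),
                                         sigma_rho = NULL) {
  if (pilot$n_images < 2L)
    stop("precision estimation requires at least 2 pilot images")
  spacing <- config$sparse_spacing
  if (is.null(spacing)) {
    spacing <- if (!is.null(sigma_rho) && sigma_rho > 0)
      max(1L, as.integer(ceiling(sigma_rho^2 * log(100)))) else 5L
  }
  d <- voxel_differences(pilot, reference)$d
  counts <- t(vapply(seq_along(d), function(k) {
    idx <- sparse_indices(length(d[[k]]), pilot$grid_shape, spacing)
    dk <- d[[k]][idx]
    c(sum(dk == 1L), sum(dk == 0L), sum(dk == -1L))
  }, numeric(3)))
  colnames(counts) <- c("1", "0", "-1")
  fit <- fit_dm_precision(counts, cap = config$omega_cap)
  c(fit, list(counts = counts, spacing = spacing))
}

#' Maximum likelihood Dirichlet-multinomial precision
#'
#' Maximises the Dirichlet-multinomial likelihood over the precision
#' `omega` with the mean vector fixed at the pooled category proportions.
#' The score function in `log(omega)`,
#' `sum_kj p_j (psi(c_kj + omega p_j) - psi(omega p_j)) -
#' sum_k (psi(m_k + omega) - psi(omega))` (digamma `psi`), is monotone
#' decreasing through the maximum, so the MLE is located by safeguarded
#' iterative root finding to relative tolerance `tol`. When the images are
#' no more variable than multinomial sampling allows the score stays
#' positive for every finite `omega`; the likelihood then increases towards
#' `omega = Inf` and the estimate is reported at `cap` with the
#' "no detectable inter-image variability" flag.
#'
#' @param counts Matrix of per-image category counts (images x categories).
#' @param tol Relative convergence tolerance on `omega`.
#' @param cap Upper cap standing in for an infinite precision estimate.
#' @return List with `omega_hat`, `p` (fixed mean), `capped`.
#' @export
fit_dm_precision <- function(counts, tol = 1e-8, cap = 1e9) {
  counts <- as.matrix(counts)
  keep <- colSums(counts) > 0
  if (!all(keep)) {
    warning("categories absent from all images; fitting reduced ",
            sum(keep), "-category model")
    counts <- counts[, keep, drop = FALSE]
  }
  if (ncol(counts) < 2L)
    stop("need at least 2 observed categories to estimate a precision")
  m <- rowSums(counts)
  if (any(m == 0)) stop("images with zero sampled voxels")
  p <- colSums(counts) / sum(counts)
  ## score = d/d omega of the DM log-likelihood with fixed mean p
  score <- function(omega) {
    ap <- omega * p
    sum(t(p * (t(digamma(sweep(counts, 2, ap, "+"))) - digamma(ap)))) -
      sum(digamma(m + omega) - digamma(omega))
  }
  lo <- 1e-4
  if (score(lo) <= 0)   # maximum at (or below) the lower bound
    return(list(omega_hat = lo, p = p, capped = FALSE))
  hi <- 1
  while (score(hi) > 0 && hi < cap) hi <- hi * 8
  if (hi >= cap && score(cap) > -1e-12)
    return(list(omega_hat = cap, p = p, capped = TRUE))
  root <- uniroot(score, lower = hi / 8, upper = min(hi, cap),
                  tol = tol * hi / 8)$root
  ## precisions this large are numerically indistinguishable from "no
  ## inter-image variability": the score is within rounding error of zero
  capped <- root >= cap / 100
  list(omega_hat = if (capped) cap else root, p = p, capped = capped)
}

#' Estimate all model parameters from a pilot dataset
#'
#' Orchestrates the full estimation workflow: foreground probabilities,
#' error covariance and adjusted MDD (when `delta_mdd_H` and H are given),
#' disagreement, accuracy difference, per-image variance with its
#' conservative bound, the design factor, and — when requested — the
#' Dirichlet precision from sparse voxels and the implied average
#' correlation.
#'
#' @param pilot A [pilot_dataset()] with reference L (and H when
#'   `delta_mdd_H` is supplied).
#' @param delta_mdd_H Optional MDD specified against the high-quality
#'   reference standard; requires H in the pilot.
#' @param config An [estimation_config()].
#' @param sigma_rho Optional spatial correlation scale forwarded to
#'   [estimate_dirichlet_precision()].
#' @param fit_precision Whether to fit the Dirichlet precision (and hence
#'   `rho_bar`); requires at least 2 images.
#' @return An object of class `"pilot_estimates"`.
#' @export
estimate_all <- function(pilot, delta_mdd_H = NULL,
                         config = estimation_config(), sigma_rho = NULL,
                         fit_precision = TRUE) {
  stopifnot(inherits(pilot, "pilot_dataset"))
  psi_hat <- estimate_psi(pilot)
  delta_hat <- estimate_delta(pilot, "L")
  vr <- estimate_variance(pilot, "L", config)
  est <- list(psi_hat = psi_hat, delta_hat = delta_hat,
              sigma2_hat = vr$sigma2_hat, sigma2_upper = vr$sigma2_upper,
              pa_hat = estimate_foreground_prob(pilot, "A"),
              pb_hat = estimate_foreground_prob(pilot, "B"),
              pl_hat = estimate_foreground_prob(pilot, "L"),
              ph_hat = NA_real_, cov_hat = NA_real_,
              delta_mdd_hat = NA_real_,
              f_hat = NA_real_, omega_hat = NA_real_, rho_bar_hat = NA_real_,
              warnings = character())
  if (psi_hat > delta_hat^2) {
    est$f_hat <- estimate_design_factor(psi_hat, delta_hat, vr$sigma2_hat)
  } else {
    est$warnings <- c(est$warnings,
      "psi_hat <= delta_hat^2 (e.g. identical algorithms): no design factor")
  }
  if (!is.null(delta_mdd_H)) {
    if (is.null(pilot$h))
      stop("delta_mdd_H was given but the pilot has no high-quality ",
           "reference H; collect H segmentations to adjust the MDD")
    est$ph_hat <- estimate_foreground_prob(pilot, "H")
    est$cov_hat <- estimate_error_covariance(pilot)
    est$delta_mdd_hat <- adjust_mdd(reference_quality_params(
      delta_mdd_H, est$pa_hat, est$pb_hat, est$pl_hat, est$ph_hat,
      est$cov_hat))
  } else if (!is.null(pilot$h)) {
    est$ph_hat <- estimate_foreground_prob(pilot, "H")
    est$cov_hat <- estimate_error_covariance(pilot)
  }
  if (fit_precision && pilot$n_images >= 2L && psi_hat > delta_hat^2) {
    prec <- estimate_dirichlet_precision(pilot, "L", config, sigma_rho)
    est$omega_hat <- prec$omega_hat
    if (prec$capped)
      est$warnings <- c(est$warnings, "no detectable inter-image variability")
    est$rho_bar_hat <- estimate_rho_bar(vr$sigma2_hat, psi_hat, delta_hat,
                                        prec$omega_hat)
  }
  structure(est, class = "pilot_estimates")
}

#' @export
print.pilot_estimates <- function(x, ...) {
  cat("Pilot parameter estimates\n")
  cat(sprintf("  psi_hat = %.4g, delta_hat = %.4g\n", x$psi_hat, x$delta_hat))
  cat(sprintf("  sigma2_hat = %.4g (conservative upper bound %.4g)\n",
              x$sigma2_hat, x$sigma2_upper))
  if (is.finite(x$f_hat)) cat(sprintf("  design factor f_hat = %.4g\n", x$f_hat))
  if (is.finite(x$omega_hat))
    cat(sprintf("  omega_hat = %.4g, rho_bar_hat = %.4g\n",
                x$omega_hat, x$rho_bar_hat))
  cat(sprintf("  p_hat: a = %.4g, b = %.4g, l = %.4g, h = %s\n",
              x$pa_hat, x$pb_hat, x$pl_hat,
              if (is.finite(x$ph_hat)) sprintf("%.4g", x$ph_hat) else "-"))
  if (is.finite(x$cov_hat))
    cat(sprintf("  cov(A - B, L - H) = %.4g\n", x$cov_hat))
  if (is.finite(x$delta_mdd_hat))
    cat(sprintf("  adjusted delta_mdd = %.4g\n", x$delta_mdd_hat))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}
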