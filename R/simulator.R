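## Monte Carlo engine: spatially correlated per-voxel accuracy differences
## are generated by a Gaussian copula (NORTA) whose latent correlations are
## calibrated so that the Pearson correlations of the ordinal-coded
## (-1, 0, 1) differences match an exponential spatial kernel. Per-image
## marginal probabilities are drawn from a Dirichlet prior. The engine
## validates the sample size formulae and generates synthetic pilot data.

#' Spatial correlation model on a voxel lattice
#'
#' Builds the pairwise Euclidean distances between the voxels of a
#' `rows x cols` integer lattice and the target correlation matrix
#' `rho_ij = exp(-Dist_ij / sigma_rho^2)`. `sigma_rho = 0` yields the
#' identity (independent voxels). The average correlation `rho_bar` is the
#' grand mean over all ordered voxel pairs including the unit diagonal —
#' the convention under which independent voxels give `rho_bar = 1/v`.
#'
#' @param grid_shape Integer vector `c(rows, cols)`; a single integer `v` is
#'   accepted when `v` is a perfect square and means a `sqrt(v) x sqrt(v)`
#'   lattice.
#' @param sigma_rho Spatial correlation scale (>= 0).
#' @return An object of class `"spatial_model"`: list with `grid_shape`,
#'   `v`, `sigma_rho`, `dist`, `corr`, `rho_bar` plus internal fields used
#'   by the sampler.
#' @examples
#' sp <- build_spatial_model(c(6, 6), 0.7)
#' sp$rho_bar
#' @export
build_spatial_model <- function(grid_shape, sigma_rho) {
  if (length(grid_shape) == 1L) {
    s <- sqrt(grid_shape)
    if (s != floor(s))
      stop("a scalar grid_shape must be a perfect square; ",
           "use c(rows, cols) otherwise")
    grid_shape <- c(s, s)
  }
  grid_shape <- as.integer(grid_shape)
  if (any(grid_shape < 1L)) stop("grid dimensions must be positive")
  if (sigma_rho < 0) stop("sigma_rho must be non-negative")
  v <- prod(grid_shape)
  xy <- as.matrix(expand.grid(row = seq_len(grid_shape[1]),
                              col = seq_len(grid_shape[2])))
  D <- unname(as.matrix(dist(xy)))
  C <- if (sigma_rho == 0) diag(v) else exp(-D / sigma_rho^2)
  off <- sort(unique(C[upper.tri(C)]))
  structure(
    list(grid_shape = grid_shape, v = v, sigma_rho = sigma_rho,
         dist = D, corr = C, rho_bar = mean(C),
         identity = sigma_rho == 0,
         unique_targets = off,
         target_index = matrix(match(C, c(off, 1)), v, v)),
    class = "spatial_model")
}

#' @export
print.spatial_model <- function(x, ...) {
  cat(sprintf("Spatial model: %d x %d lattice (v = %d), sigma_rho = %g\n",
              x$grid_shape[1], x$grid_shape[2], x$v, x$sigma_rho))
  cat(sprintf("  average inter-voxel correlation rho_bar = %.5f\n", x$rho_bar))
  invisible(x)
}

#' Simulation configuration
#'
#' @param spatial A [build_spatial_model()] object (or a grid shape, which
#'   is passed through together with `sigma_rho`).
#' @param p_vec Population marginal probabilities `c(p1, p0, pm1)` of the
#'   per-voxel accuracy difference taking values 1, 0 and -1.
#' @param omega Dirichlet precision of the per-image prior (possibly `Inf`).
#' @param n_images Number of images per simulated study.
#' @param n_reps Number of simulated studies.
#' @param alpha Two-sided level of the per-study paired t-test.
#' @param seed Integer seed; the whole simulation is reproducible from it.
#' @param sigma_rho Used only when `spatial` is a grid shape.
#' @return An object of class `"simulation_config"`.
#' @export
simulation_config <- function(spatial, p_vec, omega, n_images,
                              n_reps = 2000L, alpha = 0.05, seed = NULL,
                              sigma_rho = 0) {
  if (!inherits(spatial, "spatial_model"))
    spatial <- build_spatial_model(spatial, sigma_rho)
  if (length(p_vec) != 3L || any(p_vec < 0) || abs(sum(p_vec) - 1) > 1e-12)
    stop("p_vec must be a probability 3-vector <p1, p0, pm1> summing to 1")
  if (!(omega > 0)) stop("omega must be positive")
  if (n_reps < 1L) stop("n_reps must be at least 1")
  if (n_images < 2L) stop("n_images must be at least 2 for the t-test")
  structure(list(spatial = spatial, p_vec = as.numeric(p_vec),
                 omega = omega, n_images = as.integer(n_images),
                 n_reps = as.integer(n_reps), alpha = alpha, seed = seed),
            class = "simulation_config")
}

#' Draw per-image marginal probability priors from the Dirichlet prior
#'
#' Samples `n` probability 3-vectors from `Dirichlet(omega, p_vec)`
#' (concentration `omega * p_vec`, so the mean is `p_vec` and the precision
#' `omega`). `omega = Inf` returns `p_vec` exactly for every draw. Zero
#' components of `p_vec` stay fixed at zero (degenerate categories).
#'
#' @param p_vec Probability 3-vector `c(p1, p0, pm1)`.
#' @param omega Dirichlet precision.
#' @param n Number of draws.
#' @return An `n x 3` matrix of simplex vectors.
#' @export
sample_image_prior <- function(p_vec, omega, n = 1L) {
  if (!(omega > 0)) stop("omega must be positive")
  if (is.infinite(omega))
    return(matrix(p_vec, n, 3, byrow = TRUE))
  out <- matrix(0, n, 3)
  pos <- p_vec > 0
  g <- matrix(rgamma(n * sum(pos), shape = rep(omega * p_vec[pos], each = n)),
              n, sum(pos))
  out[, pos] <- g / rowSums(g)
  out
}

## internal: ordinal Pearson correlation of two (-1, 0, 1) variables sharing
## marginals (pm1, p0, p1), as a function of the latent normal correlation.
## Vectorized over `latent`.
ordinal_corr_from_latent <- function(latent, pm1, p1) {
  d <- p1 - pm1
  v <- (p1 + pm1) - d^2
  if (v <= 0) return(rep(NA_real_, length(latent)))
  t1 <- qnorm(pm1)          # Z <= t1  ->  category -1
  t2 <- qnorm(1 - p1)       # Z >  t2  ->  category  1
  P11 <- 1 - 2 * pnorm(t2) + pbinorm(t2, t2, latent)
  Pmm <- pbinorm(t1, t1, latent)
  P1m <- pnorm(t1) - pbinorm(t2, t1, latent)
  exy <- P11 + Pmm - 2 * P1m
  (exy - d^2) / v
}

## internal: latent correlations reproducing the target ordinal Pearson
## correlations for common marginals o = c(p1, p0, pm1). Solves the
## monotone calibration equation on a fixed grid and inverts it by a
## monotone (Hyman-filtered) spline. Targets outside the attainable range
## fall back to latent = target with a warning.
.latent_grid <- c(0, 0.05, 0.1, 0.175, 0.25, 0.35, 0.45, 0.55, 0.65, 0.75,
                  0.825, 0.875, 0.925, 0.96, 0.985, 0.9965, 0.9995)
calibrate_latent_corr <- function(targets, o) {
  oc <- ordinal_corr_from_latent(.latent_grid, pm1 = o[3], p1 = o[1])
  if (any(!is.finite(oc)) || any(diff(oc) <= 0)) {
    warning("copula calibration failed for these marginals; ",
            "using latent = target")
    return(targets)
  }
  out <- numeric(length(targets))
  inside <- targets >= oc[1] & targets <= oc[length(oc)]
  if (any(!inside)) {
    warning("correlation targets outside the attainable range; ",
            "using latent = target for those pairs")
    out[!inside] <- targets[!inside]
  }
  if (any(inside))
    out[inside] <- splinefun(oc, .latent_grid, method = "hyman")(targets[inside])
  pmin(pmax(out, 0), 0.9995)
}

## internal: nearest positive semidefinite repair by eigenvalue clipping,
## rescaled back to unit diagonal
psd_repair <- function(M, eps = 1e-8) {
  e <- eigen(M, symmetric = TRUE)
  if (min(e$values) >= eps) return(M)
  M2 <- e$vectors %*% (pmax(e$values, eps) * t(e$vectors))
  s <- 1 / sqrt(diag(M2))
  M2 * outer(s, s)
}

#' Sample one image of spatially correlated per-voxel accuracy differences
#'
#' Given an image's marginal probabilities `o_k` and a spatial model, draws
#' `v` ordinal values in \{-1, 0, 1\} whose marginals are `o_k` and whose
#' pairwise Pearson correlations (of the ordinal codes) approximate the
#' spatial target matrix: a latent multivariate normal vector with a
#' calibrated correlation matrix is thresholded at the marginal quantiles
#' (NORTA). The calibrated matrix is repaired to the nearest positive
#' semidefinite correlation matrix (eigenvalue clipping) when needed.
#'
#' @param o_k Probability 3-vector `c(p1, p0, pm1)` for this image.
#' @param spatial A [build_spatial_model()] object.
#' @return Integer vector of length `spatial$v` with values in \{-1, 0, 1\}.
#' @export
sample_voxel_differences <- function(o_k, spatial) {
  stopifnot(inherits(spatial, "spatial_model"))
  v <- spatial$v
  p1 <- o_k[1]; pm1 <- o_k[3]
  if (spatial$identity) {
    return(sample(c(1L, 0L, -1L), v, replace = TRUE, prob = o_k))
  }
  ## degenerate marginals: at most one category has mass
  if (p1 + pm1 <= 0) return(rep(0L, v))
  if (p1 >= 1) return(rep(1L, v))
  if (pm1 >= 1) return(rep(-1L, v))
  lat <- calibrate_latent_corr(spatial$unique_targets, o_k)
  L <- matrix(c(lat, 1)[spatial$target_index], v, v)
  ch <- tryCatch(chol(L), error = function(e) NULL)
  if (is.null(ch)) ch <- chol(psd_repair(L))
  z <- drop(rnorm(v) %*% ch)
  t1 <- qnorm(pm1)
  t2 <- qnorm(1 - p1)
  out <- integer(v)
  out[z <= t1] <- -1L
  out[z > t2] <- 1L
  out
}

#' Simulate one segmentation evaluation study
#'
#' Draws `n_images` images (for each: a Dirichlet prior draw, then a
#' correlated voxel draw, then the per-image mean difference) and applies
#' the two-sided paired t-test at level `alpha`.
#'
#' @param config A [simulation_config()]. Its `seed`, if set, is applied
#'   first.
#' @return List with `d_bar` (per-image accuracy differences) and `test`
#'   (the [paired_t_test()] result).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  o <- sample_image_prior(config$p_vec, config$omega, config$n_images)
  d_bar <- vapply(seq_len(config$n_images), function(k)
    mean(sample_voxel_differences(o[k, ], config$spatial)), numeric(1))
  list(d_bar = d_bar, test = paired_t_test(d_bar, config$alpha))
}

#' Empirical power over repeated simulated studies
#'
#' Repeats [simulate_study()] `n_reps` times and aggregates: the proportion
#' of significant tests (with a 95% binomial confidence interval), the
#' pooled variance of the per-image accuracy differences, and the realized
#' marginal `psi` and `delta` across all simulated voxels.
#'
#' @param config A [simulation_config()]; set `config$seed` for
#'   reproducibility (identical seed and configuration give identical
#'   results).
#' @param keep_d_bar Keep the full matrix of per-image differences.
#' @return An object of class `"simulation_result"`: list with `positives`,
#'   `empirical_power`, `power_ci`, `empirical_variance`, `empirical_psi`,
#'   `empirical_delta`, `n_reps`, `n_images`, and optionally `d_bar_samples`.
#' @export
estimate_empirical_power <- function(config, keep_d_bar = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_images
  pos <- 0L
  sum_d <- 0; sum_absd <- 0; n_vox <- 0
  all_dbar <- if (keep_d_bar)
    matrix(NA_real_, config$n_reps, n) else NULL
  ss <- 0; s <- 0; n_db <- 0          # pooled variance accumulators
  for (r in seq_len(config$n_reps)) {
    o <- sample_image_prior(config$p_vec, config$omega, n)
    d_bar <- numeric(n)
    for (k in seq_len(n)) {
      d <- sample_voxel_differences(o[k, ], config$spatial)
      d_bar[k] <- mean(d)
      sum_d <- sum_d + sum(d); sum_absd <- sum_absd + sum(abs(d))
      n_vox <- n_vox + length(d)
    }
    if (keep_d_bar) all_dbar[r, ] <- d_bar
    s <- s + sum(d_bar); ss <- ss + sum(d_bar^2); n_db <- n_db + n
    if (paired_t_test(d_bar, config$alpha)$significant) pos <- pos + 1L
  }
  phat <- pos / config$n_reps
  se <- sqrt(phat * (1 - phat) / config$n_reps)
  structure(
    list(positives = pos, n_reps = config$n_reps, n_images = n,
         empirical_power = phat,
         power_ci = c(max(0, phat - 1.96 * se), min(1, phat + 1.96 * se)),
         empirical_variance = (ss - s^2 / n_db) / (n_db - 1),
         empirical_psi = sum_absd / n_vox,
         empirical_delta = sum_d / n_vox,
         d_bar_samples = all_dbar),
    class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    "Simulation: %d studies of %d images\n", x$n_reps, x$n_images))
  cat(sprintf("  empirical power %.4f (95%% CI %.4f-%.4f)\n",
              x$empirical_power, x$power_ci[1], x$power_ci[2]))
  cat(sprintf("  pooled d_bar variance %.6g; realized psi %.4f, delta %.4f\n",
              x$empirical_variance, x$empirical_psi, x$empirical_delta))
  invisible(x)
}

#' Model-based synthetic pilot dataset
#'
#' Samples per-voxel accuracy differences from the full model (Dirichlet
#' prior plus spatial copula) and encodes them losslessly as binary label
#' masks: with the reference standard all-background (`l = 0`), setting
#' `a = (d == -1)` and `b = (d == 1)` reproduces exactly the drawn
#' difference field (`|b - l| - |a - l| = d`). The resulting pilot has the
#' population `psi`, `delta`, design factor and Dirichlet precision of the
#' generating configuration, which makes it the natural fixture for
#' parameter-recovery checks. The masks are synthetic encodings — their
#' foreground probabilities are not meaningful segmentation statistics.
#'
#' @param config A [simulation_config()]; `n_images` images are drawn.
#' @return A [pilot_dataset()] with `grid_shape` set from the spatial model.
#' @export
simulate_pilot <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  o <- sample_image_prior(config$p_vec, config$omega, config$n_images)
  d <- lapply(seq_len(config$n_images), function(k)
    sample_voxel_differences(o[k, ], config$spatial))
  pilot_dataset(
    a = lapply(d, function(x) as.integer(x == -1L)),
    b = lapply(d, function(x) as.integer(x == 1L)),
    l = lapply(d, function(x) integer(length(x))),
    grid_shape = config$spatial$grid_shape)
}

## internal: expectation of the product of two thresholded-normal binaries
## with latent correlation r: E[XY] = P(Z1 > qnorm(1-px), Z2 > qnorm(1-py))
latent_cross_moment <- function(px, py, r) {
  a <- qnorm(1 - px); b <- qnorm(1 - py)
  1 - pnorm(a) - pnorm(b) + pbinorm(a, b, r)
}

#' Synthetic mask quadruples with controlled reference error statistics
#'
#' Generates a pilot dataset of binary masks for A, B, L and H whose pooled
#' statistics match the requested foreground probabilities and error
#' covariance `cov(A - B, L - H)` within sampling error. Each voxel's four
#' labels are thresholded from a four-dimensional Gaussian latent vector
#' (voxels independent): the latent correlations between the algorithms and
#' the references are fixed at `r_ab` and `r_ref`, the L-H correlation at
#' `r_lh`, and the A-L correlation is calibrated by root finding so the
#' implied covariance matches `cov_ab_lh`. A `cov_ab_lh` not attainable
#' with a positive semidefinite latent correlation raises an error. With
#' `perfect_reference = TRUE`, L is copied from H exactly (zero reference
#' error model; requires `pl = ph` and `cov_ab_lh = 0`).
#'
#' @param n_images,v Number of images and voxels per image.
#' @param pa,pb,pl,ph Target foreground probabilities.
#' @param cov_ab_lh Target covariance between `A - B` and `L - H`.
#' @param r_ab Latent correlation between A and B (algorithm agreement).
#' @param r_ref Baseline latent correlation between each algorithm and each
#'   reference standard.
#' @param r_lh Latent correlation between the two reference standards.
#' @param perfect_reference If `TRUE`, L is identical to H.
#' @param seed Optional seed.
#' @return A [pilot_dataset()].
#' @export
generate_synthetic_pilot <- function(n_images, v, pa, pb, pl, ph,
                                     cov_ab_lh = 0, r_ab = 0.9,
                                     r_ref = 0.75, r_lh = 0.9,
                                     perfect_reference = FALSE,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  probs <- c(A = pa, B = pb, L = pl, H = ph)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (perfect_reference) {
    if (pl != ph || cov_ab_lh != 0)
      stop("perfect_reference requires pl == ph and cov_ab_lh == 0")
  }
  ## cov(A-B, L-H) as a function of the A-L latent correlation, all other
  ## latent correlations held fixed (B-L, B-H, A-H at r_ref)
  cov_fun <- function(r_al) {
    eal <- latent_cross_moment(pa, pl, r_al)
    eah <- latent_cross_moment(pa, ph, r_ref)
    ebl <- latent_cross_moment(pb, pl, r_ref)
    ebh <- latent_cross_moment(pb, ph, r_ref)
    (eal - pa * pl) - (eah - pa * ph) - (ebl - pb * pl) + (ebh - pb * ph)
  }
  build_sigma <- function(r_al) {
    S <- diag(4)
    S[1, 2] <- S[2, 1] <- r_ab
    S[1, 3] <- S[3, 1] <- r_al
    S[1, 4] <- S[4, 1] <- r_ref
    S[2, 3] <- S[3, 2] <- r_ref
    S[2, 4] <- S[4, 2] <- r_ref
    S[3, 4] <- S[4, 3] <- if (perfect_reference) 0.9995 else r_lh
    S
  }
  if (perfect_reference) {
    r_al <- r_ref
  } else {
    lo <- cov_fun(-0.99); hi <- cov_fun(0.9995)
    if (cov_ab_lh < min(lo, hi) || cov_ab_lh > max(lo, hi))
      stop("requested cov(A - B, L - H) = ", cov_ab_lh,
           " is not attainable (range ", format(min(lo, hi), digits = 4),
           " to ", format(max(lo, hi), digits = 4), ")")
    r_al <- uniroot(function(r) cov_fun(r) - cov_ab_lh,
                    c(-0.99, 0.9995), tol = 1e-10)$root
  }
  S <- build_sigma(r_al)
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) < -1e-8)
    stop("the implied latent correlation matrix is not positive ",
         "semidefinite; relax r_ab/r_ref/r_lh or the requested covariance")
  R <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  thr <- qnorm(1 - probs)
  one_image <- function() {
    Z <- matrix(rnorm(4L * v), v, 4L) %*% R
    lab <- sweep(Z, 2, thr, ">")
    if (perfect_reference) lab[, 3] <- lab[, 4]
    lab
  }
  imgs <- lapply(seq_len(n_images), function(k) one_image())
  pilot_dataset(
    a = lapply(imgs, function(m) as.integer(m[, 1])),
    b = lapply(imgs, function(m) as.integer(m[, 2])),
    l = lapply(imgs, function(m) as.integer(m[, 3])),
    h = lapply(imgs, function(m) as.integer(m[, 4])))
}
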