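## Core domain types and metrics: population model, study design, pilot
## data containers, per-voxel accuracy differences and the paired t-test.

#' Population model of voxel-wise accuracy differences
#'
#' Describes the population distribution of the per-voxel accuracy difference
#' `D in {-1, 0, 1}` between two segmentation algorithms measured against a
#' common reference standard. The marginal probabilities `p1 = P(D = 1)`,
#' `p0 = P(D = 0)` and `pm1 = P(D = -1)` determine the population accuracy
#' difference `delta = p1 - pm1` and the disagreement probability
#' `psi = p1 + pm1`. Inter-image variability is described by the Dirichlet
#' precision `omega` (large `omega` means homogeneous images) and intra-image
#' inter-voxel correlation by its average `rho_bar`; together they give the
#' design factor `f = (1 + omega * rho_bar) / (omega + 1)`.
#'
#' @param p1,p0,pm1 Marginal probabilities of `D = 1`, `D = 0` and `D = -1`.
#'   Must be non-negative and sum to 1.
#' @param omega Dirichlet precision of the per-image prior; positive,
#'   possibly `Inf` (no inter-image variability).
#' @param rho_bar Average intra-image inter-voxel correlation, in `[0, 1]`,
#'   averaged over all ordered voxel pairs including each voxel with itself.
#' @param sigma2_null,sigma2_alt Optional variances of `O1 - O(-1)` under the
#'   per-image prior at `delta = 0` and at `delta = delta_mdd`; only needed
#'   for the moment-based path when not using the Dirichlet prior.
#'
#' @return An object of class `"population_model"`: a list with the supplied
#'   fields plus derived `delta`, `psi` and `f`.
#' @examples
#' m <- population_model(p1 = 0.09, p0 = 0.85, pm1 = 0.06,
#'                       omega = 128, rho_bar = 0.05)
#' m$delta  # 0.03
#' m$psi    # 0.15
#' @export
population_model <- function(p1, p0, pm1, omega = Inf, rho_bar = 0,
                             sigma2_null = NULL, sigma2_alt = NULL) {
  p <- c(p1, p0, pm1)
  if (any(!is.finite(p)) || any(p < 0))
    stop("p1, p0 and pm1 must be finite and non-negative")
  if (abs(sum(p) - 1) > 1e-12)
    stop("p1 + p0 + pm1 must equal 1 (got ", format(sum(p), digits = 15), ")")
  if (!(is.numeric(omega) && length(omega) == 1L && omega > 0))
    stop("omega must be a positive scalar (possibly Inf)")
  if (!(is.numeric(rho_bar) && length(rho_bar) == 1L &&
        rho_bar >= 0 && rho_bar <= 1))
    stop("rho_bar must lie in [0, 1]")
  for (s2 in list(sigma2_null, sigma2_alt))
    if (!is.null(s2) && (!is.numeric(s2) || s2 < 0))
      stop("sigma2_null/sigma2_alt must be non-negative")
  delta <- p1 - pm1
  psi <- p1 + pm1
  f <- design_factor(omega, rho_bar)
  structure(
    list(p1 = p1, p0 = p0, pm1 = pm1, delta = delta, psi = psi,
         omega = omega, rho_bar = rho_bar, f = f,
         sigma2_null = sigma2_null, sigma2_alt = sigma2_alt),
    class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  cat("Population model of voxel-wise accuracy differences\n")
  cat(sprintf("  p = <%g, %g, %g>  (delta = %g, psi = %g)\n",
              x$p1, x$p0, x$pm1, x$delta, x$psi))
  cat(sprintf("  omega = %g, rho_bar = %g  =>  design factor f = %g\n",
              x$omega, x$rho_bar, x$f))
  invisible(x)
}

#' Study design parameters
#'
#' Bundles the acceptable error rates and the minimum detectable difference
#' (MDD) together with the settings of the fixed-point sample size solver.
#'
#' @param alpha Two-sided type-I error rate, in (0, 1).
#' @param beta Type-II error rate, in (0, 1); the target power is `1 - beta`.
#' @param delta_mdd Minimum detectable accuracy difference (signed, as a
#'   fraction of voxels). The formulas use `delta_mdd^2`, so only the
#'   magnitude matters for the sample size.
#' @param tol Convergence tolerance on the continuous sample size during the
#'   fixed-point iteration.
#' @param max_iter Maximum number of fixed-point iterations.
#' @param use_normal If `TRUE`, use standard normal quantiles instead of
#'   t quantiles (the large-sample closed form; also the McNemar limit).
#'
#' @return An object of class `"study_design"`.
#' @export
study_design <- function(alpha = 0.05, beta = 0.20, delta_mdd,
                         tol = 1e-6, max_iter = 200L, use_normal = FALSE) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  if (!(beta > 0 && beta < 1)) stop("beta must lie in (0, 1)")
  if (missing(delta_mdd) || !is.numeric(delta_mdd) || length(delta_mdd) != 1L)
    stop("delta_mdd must be a numeric scalar")
  structure(
    list(alpha = alpha, beta = beta, delta_mdd = delta_mdd,
         tol = tol, max_iter = as.integer(max_iter),
         use_normal = isTRUE(use_normal)),
    class = "study_design")
}

#' Variance specification for the generic sample size formula
#'
#' The per-image accuracy difference variances under the null hypothesis
#' (`delta = 0`) and under the alternative (`delta = delta_mdd`).
#'
#' @param sigma2_null,sigma2_alt Variances in `[0, 2]`.
#' @return An object of class `"variance_spec"`.
#' @export
variance_spec <- function(sigma2_null, sigma2_alt = sigma2_null) {
  for (s2 in c(sigma2_null, sigma2_alt))
    if (!is.numeric(s2) || s2 < 0 || s2 > 2)
      stop("variances must lie in [0, 2]")
  structure(list(sigma2_null = sigma2_null, sigma2_alt = sigma2_alt),
            class = "variance_spec")
}

#' Pilot dataset of co-registered binary segmentations
#'
#' Holds per-image binary label vectors for algorithms A and B, the study
#' reference standard L and optionally a high-quality reference standard H.
#' Labels must be strictly 0/1 (see [read_mask_set()] for binarization of
#' raw mask volumes at ingestion). Images may have unequal numbers of voxels;
#' per-image quantities are then computed from each image's own voxel count.
#'
#' @param a,b,l,h Per-image labels: either matrices with one row per image,
#'   or lists of integer vectors (one per image). `h` may be `NULL`.
#' @param grid_shape Optional integer vector giving the voxel grid dimensions
#'   shared by all images (e.g. `c(rows, cols)`); required only by the
#'   spatially sparse Dirichlet precision estimator.
#'
#' @return An object of class `"pilot_dataset"`: a list with elements
#'   `a`, `b`, `l`, `h` (lists of integer vectors), `n_images`, `v`
#'   (per-image voxel counts) and `grid_shape`.
#' @export
pilot_dataset <- function(a, b, l, h = NULL, grid_shape = NULL) {
  as_label_list <- function(x, name) {
    if (is.null(x)) return(NULL)
    if (is.matrix(x)) x <- lapply(seq_len(nrow(x)), function(i) x[i, ])
    if (is.numeric(x)) x <- list(x)
    if (!is.list(x)) stop(name, " must be a matrix, vector or list of vectors")
    lapply(x, function(v) {
      if (any(is.na(v)) || !all(v %in% c(0, 1)))
        stop("labels in ", name, " must all be 0 or 1")
      as.integer(v)
    })
  }
  a <- as_label_list(a, "a"); b <- as_label_list(b, "b")
  l <- as_label_list(l, "l"); h <- as_label_list(h, "h")
  n <- length(a)
  if (length(b) != n || length(l) != n || (!is.null(h) && length(h) != n))
    stop("a, b, l (and h) must contain the same number of images")
  if (n == 0L) stop("pilot dataset must contain at least one image")
  v <- vapply(a, length, integer(1))
  for (src in list(b, l, h)) {
    if (is.null(src)) next
    if (!all(vapply(src, length, integer(1)) == v))
      stop("all sources must have the same voxel count within each image")
  }
  if (!is.null(grid_shape)) {
    grid_shape <- as.integer(grid_shape)
    if (any(grid_shape < 1L)) stop("grid_shape entries must be positive")
    if (!all(v == prod(grid_shape)))
      stop("grid_shape is inconsistent with the per-image voxel counts")
  }
  structure(list(a = a, b = b, l = l, h = h,
                 n_images = n, v = v, grid_shape = grid_shape),
            class = "pilot_dataset")
}

#' @export
print.pilot_dataset <- function(x, ...) {
  cat(sprintf("Pilot dataset: %d image(s), %s voxels/image, H %s\n",
              x$n_images,
              if (length(unique(x$v)) == 1L) x$v[1] else
                paste0(min(x$v), "-", max(x$v)),
              if (is.null(x$h)) "absent" else "present"))
  invisible(x)
}

## internal: pick the reference labels, erroring when H is requested but absent
reference_labels <- function(pilot, reference = c("L", "H")) {
  reference <- match.arg(reference)
  if (reference == "H") {
    if (is.null(pilot$h))
      stop("high-quality reference standard H is not present in this pilot dataset")
    pilot$h
  } else pilot$l
}

#' Per-voxel and per-image accuracy differences
#'
#' Computes the per-voxel accuracy difference
#' `D = |B - ref| - |A - ref|` for each voxel of each pilot image, and the
#' per-image means `d_bar`. `D` is 1 where A agrees with the reference and B
#' does not, -1 where B agrees and A does not, and 0 where A and B agree.
#'
#' @param pilot A [pilot_dataset()].
#' @param reference `"L"` (default) or `"H"`: which reference standard to
#'   measure accuracy against.
#' @return An object of class `"difference_field"`: a list with `d` (list of
#'   integer vectors per image) and `d_bar` (numeric vector of per-image
#'   means).
#' @examples
#' p <- pilot_dataset(a = c(1, 1, 0), b = c(0, 1, 0), l = c(1, 1, 1))
#' voxel_differences(p)$d_bar  # 1/3
#' @export
voxel_differences <- function(pilot, reference = c("L", "H")) {
  if (!inherits(pilot, "pilot_dataset")) stop("pilot must be a pilot_dataset")
  ref <- reference_labels(pilot, reference)
  d <- mapply(function(a, b, r) abs(b - r) - abs(a - r),
              pilot$a, pilot$b, ref, SIMPLIFY = FALSE)
  structure(list(d = d, d_bar = vapply(d, mean, numeric(1))),
            class = "difference_field")
}

#' Paired t-test on per-image accuracy differences
#'
#' One-sample two-sided t-test of the per-image accuracy differences against
#' zero, the analysis assumed by all sample size formulas in this package.
#' Degenerate inputs follow a documented convention: if all values are
#' exactly zero the statistic is 0 and the test is not significant; if the
#' values are constant and nonzero the difference is unambiguous at any
#' level, so the statistic is `+/-Inf` with p-value 0.
#'
#' @param d_bar Numeric vector of per-image accuracy differences (length >= 2).
#' @param alpha Two-sided significance level.
#' @return A list with `statistic`, `df`, `p_value` and `significant`.
#' @export
paired_t_test <- function(d_bar, alpha = 0.05) {
  n <- length(d_bar)
  if (n < 2L) stop("paired t-test needs at least 2 images")
  m <- mean(d_bar)
  s <- sd(d_bar)
  df <- n - 1
  if (s == 0) {
    if (m == 0) {
      statistic <- 0; p <- 1
    } else {
      statistic <- sign(m) * Inf; p <- 0
    }
  } else {
    statistic <- m / (s / sqrt(n))
    p <- 2 * pt(-abs(statistic), df)
  }
  list(statistic = statistic, df = df, p_value = p,
       significant = p < alpha)
}
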