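## Correction of the minimum detectable difference when a lower-quality
## reference standard L is used in place of a high-quality standard H.

#' Reference standard quality parameters
#'
#' Inputs to the MDD correction: the minimum detectable difference specified
#' against the high-quality reference standard, the foreground probabilities
#' of the four segmentation sources, and the covariance between algorithm
#' differences and reference standard errors. These may be supplied directly
#' or estimated from pilot data with [estimate_foreground_prob()] and
#' [estimate_error_covariance()]; this module performs no estimation itself.
#'
#' @param delta_mdd_H Minimum detectable difference with respect to H.
#' @param pa,pb,pl,ph Foreground probabilities `P(X = 1)` for a randomly
#'   selected voxel, for sources A, B, L and H.
#' @param cov_ab_lh Covariance `cov(A - B, L - H)` between errors in L
#'   (relative to H) and differences between the algorithms.
#' @return An object of class `"reference_quality_params"`.
#' @export
reference_quality_params <- function(delta_mdd_H, pa, pb, pl, ph,
                                     cov_ab_lh = 0) {
  probs <- c(pa = pa, pb = pb, pl = pl, ph = ph)
  if (any(probs < 0 | probs > 1))
    stop("foreground probabilities must lie in [0, 1]")
  if (abs(cov_ab_lh) > 1)
    stop("|cov(A - B, L - H)| cannot exceed 1")
  structure(list(delta_mdd_H = delta_mdd_H, pa = pa, pb = pb, pl = pl,
                 ph = ph, cov_ab_lh = cov_ab_lh),
            class = "reference_quality_params")
}

#' Decompose the reference-quality correction into its two terms
#'
#' The correction to the minimum detectable difference consists of a
#' contouring-bias term `2 * (p(a) - p(b)) * (p(l) - p(h))` — error induced
#' by systematic over- or under-contouring by L relative to H, which only
#' matters when one algorithm contours more foreground than the other — and
#' a covariance term `2 * cov(A - B, L - H)` reflecting errors in L that are
#' biased in favour of one algorithm.
#'
#' @param params A [reference_quality_params()].
#' @return Named numeric vector with elements `contouring` and `covariance`.
#' @export
bias_decomposition <- function(params) {
  stopifnot(inherits(params, "reference_quality_params"))
  c(contouring = 2 * (params$pa - params$pb) * (params$pl - params$ph),
    covariance = 2 * params$cov_ab_lh)
}

#' Adjust the minimum detectable difference for reference standard quality
#'
#' Translates a minimum detectable difference specified with respect to a
#' high-quality reference standard H into the detectable difference for a
#' study that will use the lower-quality standard L:
#' `delta_mdd = delta_mdd_H + 2 * (p(a) - p(b)) * (p(l) - p(h)) +
#' 2 * cov(A - B, L - H)`.
#'
#' The adjusted value is not clamped; if the correction flips the sign of
#' the detectable difference a warning is raised, since the low-quality
#' reference then reverses the apparent direction of the algorithm
#' difference.
#'
#' @param params A [reference_quality_params()].
#' @return The adjusted `delta_mdd` for use with reference standard L.
#' @examples
#' p <- reference_quality_params(0.05, pa = 0.246, pb = 0.195,
#'                               pl = 0.210, ph = 0.214, cov_ab_lh = -0.0029)
#' adjust_mdd(p)  # 0.043792
#' @export
adjust_mdd <- function(params) {
  stopifnot(inherits(params, "reference_quality_params"))
  out <- params$delta_mdd_H + sum(bias_decomposition(params))
  if (sign(out) != sign(params$delta_mdd_H) && params$delta_mdd_H != 0)
    warning("the adjusted delta_mdd changed sign: the low-quality reference ",
            "standard reverses the apparent direction of the difference")
  out
}
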