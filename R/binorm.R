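## Bivariate standard normal rectangle probabilities, vectorized over the
## correlation. Used by the Gaussian-copula calibration, where the same
## thresholds are evaluated at many latent correlations at once.

## Gauss-Legendre nodes/weights on [0, 1] via the Golub-Welsch eigenvalue
## method (symmetric tridiagonal Jacobi matrix).
gauss_legendre_01 <- function(n) {
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(x = (e$values[ord] + 1) / 2, w = e$vectors[1, ord]^2)
}

.binorm_gl <- gauss_legendre_01(48)

#' Bivariate standard normal CDF, vectorized over the correlation
#'
#' `P(Z1 <= a, Z2 <= b)` for standard normal margins with correlation `rho`,
#' computed by Gauss-Legendre quadrature of the single-integral identity
#' `Phi2(a, b; rho) = Phi(a) Phi(b) + (1 / 2 pi) *
#' int_0^rho exp(-(a^2 - 2 t a b + b^2) / (2 (1 - t^2))) / sqrt(1 - t^2) dt`.
#' `a` and `b` are scalars (possibly infinite); `rho` may be a vector with
#' `|rho| <= 0.9999`.
#'
#' @param a,b Scalar upper limits.
#' @param rho Numeric vector of correlations.
#' @return Vector of probabilities, one per element of `rho`.
#' @keywords internal
pbinorm <- function(a, b, rho) {
  if (any(abs(rho) > 0.9999))
    stop("pbinorm supports |rho| <= 0.9999")
  if (is.infinite(a) || is.infinite(b)) {
    if (a == -Inf || b == -Inf) return(rep(0, length(rho)))
    if (a == Inf) return(rep(pnorm(b), length(rho)))
    return(rep(pnorm(a), length(rho)))
  }
  t <- outer(rho, .binorm_gl$x)    # nodes on [0, rho] (sign carried by rho)
  f <- exp(-(a^2 - 2 * t * a * b + b^2) / (2 * (1 - t^2))) / sqrt(1 - t^2)
  pmin(pmax(pnorm(a) * pnorm(b) + rho * drop(f %*% .binorm_gl$w) / (2 * pi),
            0), 1)
}
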