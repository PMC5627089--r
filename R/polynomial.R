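# Polynomial utilities on plain coefficient vectors.
# Convention throughout the package: a polynomial p(x) = a0 + a1 x + ... + ad x^d
# is stored as the numeric vector c(a0, a1, ..., ad) (increasing powers).

#' Evaluate a polynomial by Horner's rule
#'
#' @param coef numeric coefficient vector, increasing powers.
#' @param x numeric or complex vector of evaluation points.
#' @return values of the polynomial at \code{x} (complex if \code{x} is).
#' @export
poly_eval <- function(coef, x) {
  acc <- rep(if (is.complex(x)) 0+0i else 0, length(x))
  for (a in rev(coef)) acc <- acc * x + a
  acc
}

#' Derivative of a polynomial
#' @param coef coefficient vector, increasing powers.
#' @return coefficient vector of the derivative.
#' @export
poly_deriv <- function(coef) {
  d <- length(coef) - 1L
  if (d < 1L) return(0)
  coef[-1L] * seq_len(d)
}

poly_trim <- function(coef, tol = 0) {
  keep <- which(abs(coef) > tol)
  if (length(keep) == 0L) return(0)
  coef[seq_len(max(keep))]
}

poly_add <- function(a, b) {
  n <- max(length(a), length(b))
  c(a, rep(0, n - length(a))) + c(b, rep(0, n - length(b)))
}

poly_mul <- function(a, b) {
  if (length(a) == 1L) return(a * b)
  if (length(b) == 1L) return(a * b)
  out <- rep(0, length(a) + length(b) - 1L)
  for (i in seq_along(a)) out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  out
}

#' Wronskian of two polynomials
#'
#' Computes the wedge \eqn{p \wedge q = p q' - p' q} as a coefficient vector.
#' The wedge is bilinear and antisymmetric; it vanishes identically when the
#' arguments are proportional.
#'
#' @param p,q coefficient vectors, increasing powers.
#' @return coefficient vector of \eqn{p q' - p' q}.
#' @export
poly_wronskian <- function(p, q) {
  poly_trim(poly_add(poly_mul(p, poly_deriv(q)), -poly_mul(poly_deriv(p), q)))
}

#' Triple Wronskian of three polynomials
#'
#' Determinant of the 3 x 3 matrix whose rows are \eqn{(p, q, r)} and their
#' first and second derivatives; alternating in its arguments.
#'
#' @param p,q,r coefficient vectors, increasing powers.
#' @return coefficient vector of the 3 x 3 Wronskian determinant.
#' @export
poly_wronskian3 <- function(p, q, r) {
  p1 <- poly_deriv(p); q1 <- poly_deriv(q); r1 <- poly_deriv(r)
  p2 <- poly_deriv(p1); q2 <- poly_deriv(q1); r2 <- poly_deriv(r1)
  det3 <- poly_add(
    poly_mul(p, poly_add(poly_mul(q1, r2), -poly_mul(q2, r1))),
    poly_add(
      -poly_mul(q, poly_add(poly_mul(p1, r2), -poly_mul(p2, r1))),
      poly_mul(r, poly_add(poly_mul(p1, q2), -poly_mul(p2, q1)))))
  poly_trim(det3)
}

#' Real roots of a polynomial
#'
#' Thin wrapper over \code{\link[base]{polyroot}} that trims negligible
#' leading coefficients and keeps roots whose imaginary part is small relative
#' to the root magnitude.
#'
#' @param coef coefficient vector, increasing powers.
#' @param imag_tol relative threshold on the imaginary part.
#' @return sorted numeric vector of real roots (possibly empty).
#' @export
poly_real_roots <- function(coef, imag_tol = 1e-7) {
  scale <- max(abs(coef))
  if (scale == 0) return(numeric(0))
  coef <- poly_trim(coef, tol = 1e-13 * scale)
  if (length(coef) < 2L) return(numeric(0))
  r <- polyroot(coef)
  re <- Re(r)[abs(Im(r)) <= imag_tol * (1 + abs(r))]
  sort(re)
}

# TRUE when the coefficient vector is numerically the zero polynomial,
# relative to a reference scale.
poly_is_zero <- function(coef, ref_scale = 1, tol = 1e-10) {
  all(abs(coef) <= tol * ref_scale)
}
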