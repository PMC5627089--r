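#' Build the characteristic function of a low-rank perturbation
#'
#' For \eqn{\tilde M(\rho_1,\rho_2) = M + \rho_1 f_1 g_1^T + \rho_2 f_2 g_2^T}
#' the characteristic polynomial is bilinear in the perturbation strengths:
#' \deqn{\det(\tilde M - \lambda I) = D(\lambda) + \rho_1 P_1(\lambda) +
#'   \rho_2 P_2(\lambda) + \rho_1\rho_2 Q(\lambda),}
#' where \eqn{D} is the characteristic polynomial of the base matrix
#' (degree N, leading coefficient \eqn{(-1)^N}), \eqn{P_1, P_2} have degree
#' at most N-1 and \eqn{Q} degree at most N-2.  No powers of \eqn{\rho_i}
#' above the first can occur, and \eqn{Q \equiv 0} whenever the two g-vectors
#' (or the two f-vectors) are linearly dependent.
#'
#' Three construction methods are available:
#' \describe{
#'   \item{interpolation}{(default) evaluates \eqn{\det(\tilde M-\lambda I)}
#'     at the four strength combinations (0,0), (1,0), (0,1), (1,1) on N+1
#'     Chebyshev-spaced \eqn{\lambda} nodes scaled to the spectral radius and
#'     solves for the four coefficient vectors.  Needs only a determinant
#'     routine and is robust for general (possibly defective) base matrices.}
#'   \item{cofactor}{uses \eqn{P_i(\lambda) = \langle g_i,
#'     \mathrm{cof}^t(M-\lambda I) f_i\rangle} and the 2x2 cofactor
#'     determinant identity for \eqn{Q}, sampling the transpose cofactor
#'     matrix \eqn{\det(A) A^{-1}} at the same nodes.}
#'   \item{spectral}{expands in the orthonormal eigenbasis of a symmetric
#'     base matrix; only available when \code{base_matrix} is symmetric,
#'     since the expansion requires an orthonormal eigenbasis.}
#' }
#'
#' Coefficients are stored in the monomial basis of the scaled variable
#' \eqn{t = \lambda / s}, where the recorded scale \eqn{s} is of the order of
#' the spectral radius; evaluation uses Horner's rule on \eqn{t} so that the
#' conditioning of high-degree terms stays under control.
#'
#' @param system a \code{\link{lowrank_system}} with N at most 64.
#' @param method one of \code{"interpolation"}, \code{"cofactor"},
#'   \code{"spectral"}.
#' @param tol positive evaluation tolerance recorded with the object.
#' @return An object of class \code{"char_function"} with coefficient vectors
#'   \code{D}, \code{P1}, \code{P2}, \code{Q} (increasing powers of the scaled
#'   variable), the scale \code{lambda_scale}, the matrix dimension \code{n},
#'   \code{build_method}, \code{tol}, and the originating \code{system}.
#' @export
char_function <- function(system,
                          method = c("interpolation", "cofactor", "spectral"),
                          tol = 1e-9) {
  stopifnot(inherits(system, "lowrank_system"))
  method <- match.arg(method)
  n <- system$n
  if (n > 64L) stop("matrix dimension capped at 64 for dense polynomial work")
  if (!is.numeric(tol) || tol <= 0) stop("tol must be positive")

  s <- max(1, max(abs(eigen(system$base_matrix, only.values = TRUE)$values)))
  rank1 <- length(system$pairs) == 1L

  polys <- switch(method,
    interpolation = charfun_by_interpolation(system, s),
    cofactor      = charfun_by_cofactor(system, s),
    spectral      = charfun_by_spectral(system, s))

  structure(c(polys,
              list(lambda_scale = s, n = n, build_method = method, tol = tol,
                   rank_one = rank1, system = system)),
            class = "char_function")
}

# Chebyshev nodes in the scaled variable, slightly inflated so the
# interpolation interval covers the spectrum.
charfun_nodes <- function(n) {
  k <- seq_len(n + 1L)
  1.15 * cos((2 * k - 1) / (2 * (n + 1L)) * pi)
}

# Least-squares monomial fit of degree <= deg through (t, y); exact for
# polynomial data.
fit_poly <- function(t, y, deg) {
  v <- outer(t, 0:deg, `^`)
  coef <- qr.solve(v, y)
  poly_trim(coef, tol = 1e-12 * max(1, max(abs(y))))
}

charfun_by_interpolation <- function(system, s) {
  n <- system$n
  tt <- charfun_nodes(n)
  lam <- s * tt
  detfun <- function(r1, r2)
    vapply(lam, function(l) det(assemble_matrix(system, r1, r2) - l * diag(n)), 0)
  d00 <- detfun(0, 0); d10 <- detfun(1, 0)
  if (length(system$pairs) == 2L) {
    d01 <- detfun(0, 1); d11 <- detfun(1, 1)
  } else {
    d01 <- d00; d11 <- d10
  }
  list(D  = fit_poly(tt, d00, n),
       P1 = fit_poly(tt, d10 - d00, max(0L, n - 1L)),
       P2 = fit_poly(tt, d01 - d00, max(0L, n - 1L)),
       Q  = fit_poly(tt, d11 - d10 - d01 + d00, max(0L, n - 2L)))
}

charfun_by_cofactor <- function(system, s) {
  n <- system$n
  tt <- charfun_nodes(n)
  f1 <- system$pairs[[1L]]$f; g1 <- system$pairs[[1L]]$g
  two <- length(system$pairs) == 2L
  if (two) { f2 <- system$pairs[[2L]]$f; g2 <- system$pairs[[2L]]$g }
  vals <- vapply(tt, function(t0) {
    a <- system$base_matrix - (s * t0) * diag(n)
    dv <- det(a)
    if (abs(dv) < 1e-12 * max(1, norm(a, "F"))^n) {
      # node accidentally at an eigenvalue of M; nudge it
      t0 <- t0 + 1e-6
      a <- system$base_matrix - (s * t0) * diag(n)
      dv <- det(a)
    }
    adj <- dv * solve(a)                      # transpose cofactor matrix
    p1 <- drop(crossprod(g1, adj %*% f1))
    if (!two) return(c(dv, p1, 0, 0, t0))
    p2  <- drop(crossprod(g2, adj %*% f2))
    q12 <- drop(crossprod(g1, adj %*% f2))
    q21 <- drop(crossprod(g2, adj %*% f1))
    c(dv, p1, p2, (p1 * p2 - q12 * q21) / dv, t0)
  }, numeric(5))
  tt <- vals[5L, ]
  list(D  = fit_poly(tt, vals[1L, ], n),
       P1 = fit_poly(tt, vals[2L, ], max(0L, n - 1L)),
       P2 = fit_poly(tt, vals[3L, ], max(0L, n - 1L)),
       Q  = fit_poly(tt, vals[4L, ], max(0L, n - 2L)))
}

charfun_by_spectral <- function(system, s) {
  m <- system$base_matrix
  if (max(abs(m - t(m))) > 1e-10 * max(1, max(abs(m))))
    stop("spectral method requires a symmetric base matrix (orthonormal eigenbasis)")
  n <- system$n
  es <- eigen(m, symmetric = TRUE)
  lam_t <- es$values / s                      # eigenvalues in scaled variable
  phi <- es$vectors
  f1 <- drop(crossprod(phi, system$pairs[[1L]]$f))
  g1 <- drop(crossprod(phi, system$pairs[[1L]]$g))
  two <- length(system$pairs) == 2L
  if (two) {
    f2 <- drop(crossprod(phi, system$pairs[[2L]]$f))
    g2 <- drop(crossprod(phi, system$pairs[[2L]]$g))
  }
  # Coefficient vector (in the scaled variable t) of
  # prod_{j not in excl} (lambda_j - lambda); each scaled factor
  # (lam_t[j] - t) equals (lambda_j - lambda)/s, hence the s^m correction.
  prod_excl <- function(excl) {
    p <- 1
    for (j in seq_len(n)) if (!(j %in% excl)) p <- poly_mul(p, c(lam_t[j], -1))
    p * s^(n - length(excl))
  }
  D <- prod_excl(integer(0))
  P1 <- 0; P2 <- 0; Q <- 0
  for (i in seq_len(n)) {
    pi_ <- prod_excl(i)
    P1 <- poly_add(P1, f1[i] * g1[i] * pi_)
    if (two) P2 <- poly_add(P2, f2[i] * g2[i] * pi_)
  }
  if (two) {
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      w <- f1[i] * g1[i] * f2[j] * g2[j] - f1[i] * g2[i] * f2[j] * g1[j]
      if (w != 0) Q <- poly_add(Q, w * prod_excl(c(i, j)))
    }
  }
  dscale <- max(abs(D))
  list(D = poly_trim(D, 1e-14 * dscale), P1 = poly_trim(P1, 1e-14 * dscale),
       P2 = poly_trim(P2, 1e-14 * dscale), Q = poly_trim(Q, 1e-14 * dscale))
}

#' Evaluate the characteristic function
#'
#' Returns \eqn{D(\lambda) + \rho_1 P_1(\lambda) + \rho_2 P_2(\lambda) +
#' \rho_1\rho_2 Q(\lambda)} via Horner evaluation on the scaled variable.
#' Equals \eqn{\det(\tilde M(\rho_1,\rho_2) - \lambda I)}.  Values overflow
#' for astronomically large \eqn{|\lambda|} like any monomial-basis
#' evaluation; within a few spectral radii they are accurate.
#'
#' @param cf a \code{\link{char_function}}.
#' @param lambda numeric or complex vector of spectral points.
#' @param rho1,rho2 perturbation strengths.
#' @return numeric or complex vector of characteristic-function values.
#' @export
eval_char <- function(cf, lambda, rho1 = 0, rho2 = 0) {
  t <- lambda / cf$lambda_scale
  poly_eval(cf$D, t) + rho1 * poly_eval(cf$P1, t) + rho2 * poly_eval(cf$P2, t) +
    rho1 * rho2 * poly_eval(cf$Q, t)
}

#' Characteristic-function coefficients in the unscaled variable
#'
#' Converts the internally stored scaled-variable coefficients back to
#' coefficients in \eqn{\lambda}.  Mostly useful for inspecting small systems;
#' for evaluation prefer \code{\link{eval_char}}.
#'
#' @param cf a \code{\link{char_function}}.
#' @return list with numeric coefficient vectors \code{D}, \code{P1},
#'   \code{P2}, \code{Q} in increasing powers of \eqn{\lambda}.
#' @export
char_poly_coefs <- function(cf) {
  s <- cf$lambda_scale
  unscale <- function(coef) coef / s^(seq_along(coef) - 1L)
  list(D = unscale(cf$D), P1 = unscale(cf$P1), P2 = unscale(cf$P2),
       Q = unscale(cf$Q))
}

#' @export
print.char_function <- function(x, ...) {
  cat(sprintf("char_function (N = %d, method = %s, lambda scale = %.4g)\n",
              x$n, x$build_method, x$lambda_scale))
  cat(sprintf("  degrees: D %d, P1 %d, P2 %d, Q %d\n",
              length(x$D) - 1L, length(x$P1) - 1L, length(x$P2) - 1L,
              length(x$Q) - 1L))
  invisible(x)
}

#' Resolvent inner-product matrix
#'
#' Computes the 2 x 2 (or 1 x 1 for rank-one systems) matrix
#' \eqn{R_{ij} = \langle g_i, (M - \lambda I)^{-1} f_j \rangle}.  The
#' characteristic function divided by \eqn{D(\lambda)} equals
#' \eqn{1 + \rho_1 R_{11} + \rho_2 R_{22} +
#' \rho_1\rho_2 (R_{11}R_{22} - R_{12}R_{21})}, the Aronszajn-Krein form of
#' the eigenvalue condition.
#'
#' @param system a \code{\link{lowrank_system}}.
#' @param lambda a single numeric or complex spectral point, not an
#'   eigenvalue of the base matrix.
#' @param cond_tol relative threshold on the smallest singular value of
#'   \eqn{M - \lambda I} below which the resolvent is declared singular.
#' @return complex matrix of resolvent inner products.
#' @export
resolvent_matrix <- function(system, lambda, cond_tol = 1e-10) {
  stopifnot(inherits(system, "lowrank_system"), length(lambda) == 1L)
  a <- system$base_matrix - lambda * diag(system$n)
  mnorm <- max(1, norm(system$base_matrix, "2"))
  if (min(svd(a, nu = 0, nv = 0)$d) < cond_tol * mnorm)
    stop("lambda is numerically an eigenvalue of the base matrix; resolvent is singular")
  fs <- vapply(system$pairs, function(p) p$f, numeric(system$n))
  x <- solve(a, fs + 0i)
  gs <- vapply(system$pairs, function(p) p$g, numeric(system$n))
  r <- crossprod(gs, x)
  dimnames(r) <- NULL
  r
}
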