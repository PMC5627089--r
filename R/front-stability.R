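# Stability of front solutions of the nonlocal Allen-Cahn model:
# exact elliptic spectrum of the cubic case, the Herglotz/Aronszajn-Krein
# moving-eigenvalue condition, the index theorem for the rank-one
# perturbed operator, and the quadrature family characterization.

# ---------------------------------------------------------------------------
# Elliptic front data

#' Elliptic front data for the cubic nonlinearity
#'
#' For the cubic bistable nonlinearity the (rescaled) stationary front is
#' \code{sn(x, k)} on \code{[-K(k), K(k)]}.  This constructor collects the
#' elliptic modulus \code{k}, the complete elliptic integrals \code{K},
#' \code{E}, the spectral constant \code{a = sqrt(1 - k^2 + k^4)} and the
#' original (pre-rescaling) half-width \code{L_original =
#' sqrt(1 + k^2) * K(k)}.
#'
#' @param k elliptic modulus in (0, 1).
#' @return object of class \code{"elliptic_front"}.
#' @export
elliptic_front <- function(k) {
  stopifnot(is.numeric(k), length(k) == 1L)
  if (!(k > 0 && k < 1)) stop("elliptic modulus k must lie in (0, 1)")
  ke <- pracma::ellipke(k^2)
  out <- list(k = k, K = ke$k, E = ke$e, a = sqrt(1 - k^2 + k^4),
              L_original = sqrt(1 + k^2) * ke$k)
  stopifnot(out$K > pi / 2, out$L_original > pi / 2,
            out$a > sqrt(3) / 2 - 1e-12, out$a <= 1 + 1e-12)
  class(out) <- "elliptic_front"
  out
}

#' @export
print.elliptic_front <- function(x, ...) {
  cat(sprintf("elliptic_front: k = %g, K = %.10g, E = %.10g, a = %.10g, L_original = %.10g\n",
              x$k, x$K, x$E, x$a, x$L_original))
  invisible(x)
}

#' Elliptic modulus for a given original half-width
#'
#' Inverts \code{sqrt(1 + k^2) * K(k) = L} for \code{k}; this is the map
#' between the physical half-width and the modulus of the rescaled front.
#'
#' @param L half-width, must exceed \code{pi/2}.
#' @return modulus \code{k} in (0, 1).
#' @export
modulus_for_halfwidth <- function(L) {
  stopifnot(is.numeric(L), length(L) == 1L)
  if (L <= pi / 2) stop("no front solution: require L > pi/2")
  fn <- function(k) sqrt(1 + k^2) * pracma::ellipke(k^2)$k - L
  stats::uniroot(fn, c(1e-12, 1 - 1e-12), tol = 1e-14)$root
}

# ---------------------------------------------------------------------------
# Symbolic elliptic monomials: sums of c * sn^a cn^b dn^c, closed under
# differentiation (sn' = cn dn, cn' = -sn dn, dn' = -k^2 sn cn).  Used to
# evaluate the exact eigenfunctions and their derivatives to machine
# precision for residual checks.

ep_terms <- function(coef, a, b, cc) {
  data.frame(coef = coef, a = a, b = b, cc = cc)
}

ep_deriv <- function(tm, k) {
  out <- list()
  add <- function(coef, a, b, cc) {
    keep <- abs(coef) > 0
    if (any(keep))
      out[[length(out) + 1L]] <<- data.frame(coef = coef[keep], a = a[keep],
                                             b = b[keep], cc = cc[keep])
  }
  add(tm$coef * tm$a, tm$a - 1L, tm$b + 1L, tm$cc + 1L)
  add(-tm$coef * tm$b, tm$a + 1L, tm$b - 1L, tm$cc + 1L)
  add(-tm$coef * tm$cc * k^2, tm$a + 1L, tm$b + 1L, tm$cc - 1L)
  if (length(out) == 0L) return(ep_terms(numeric(0), integer(0), integer(0), integer(0)))
  do.call(rbind, out)
}

ep_eval <- function(tm, k, x) {
  sj <- pracma::ellipj(x, k^2)
  val <- numeric(length(x))
  for (i in seq_len(nrow(tm)))
    val <- val + tm$coef[i] * sj$sn^tm$a[i] * sj$cn^tm$b[i] * sj$dn^tm$cc[i]
  val
}

# ---------------------------------------------------------------------------
# Exact Lame spectrum

#' Exact top of the spectrum of the cubic-front Lame operator
#'
#' The linearization about the cubic front is \eqn{H = \partial_{xx} +
#' (1 + k^2) - 6 k^2 sn^2(x, k)}, a two-gap Lame operator.  Its five
#' largest eigenvalues under periodic boundary conditions on
#' \code{[-2K, 2K]} are simple and known in closed form; each eigenfunction
#' satisfies either a Neumann (\code{"N"}) or Dirichlet (\code{"D"})
#' condition at \code{x = +-K}.  Only the first, \eqn{-(1 + k^2 - 2a)},
#' is positive.
#'
#' @param k elliptic modulus in (0, 1).
#' @return object of class \code{"lame_spectrum"}: the
#'   \code{\link{elliptic_front}} and a list of five eigenpairs (fields
#'   \code{name}, \code{bc}, \code{lambda}, \code{terms}, \code{phi}),
#'   ordered by decreasing eigenvalue.
#' @export
lame_spectrum <- function(k) {
  fr <- elliptic_front(k)
  a <- fr$a
  pairs <- list(
    list(name = "phi0N", bc = "N", lambda = -(1 + k^2 - 2 * a),
         terms = ep_terms(c(k^2, -(1 + k^2 + a) / 3), c(2L, 0L), c(0L, 0L), c(0L, 0L))),
    list(name = "phi1D", bc = "D", lambda = 0,
         terms = ep_terms(1, 0L, 1L, 1L)),
    list(name = "phi1N", bc = "N", lambda = -3 * k^2,
         terms = ep_terms(1, 1L, 0L, 1L)),
    list(name = "phi2D", bc = "D", lambda = -3,
         terms = ep_terms(1, 1L, 1L, 0L)),
    list(name = "phi2N", bc = "N", lambda = -(1 + k^2 + 2 * a),
         terms = ep_terms(c(k^2, -(1 + k^2 - a) / 3), c(2L, 0L), c(0L, 0L), c(0L, 0L))))
  for (i in seq_along(pairs)) {
    tm <- pairs[[i]]$terms
    pairs[[i]]$phi <- local({
      tm_loc <- tm
      function(x) ep_eval(tm_loc, k, x)
    })
  }
  lam <- vapply(pairs, function(p) p$lambda, 0)
  # non-strict up to roundoff: as k -> 0 the gaps -3*k^2 and
  # (1+k^2+2a) - 3 collapse to zero at machine precision
  stopifnot(all(diff(lam) < 1e-12))
  structure(list(front = fr, eigenpairs = pairs), class = "lame_spectrum")
}

#' @export
print.lame_spectrum <- function(x, ...) {
  cat(sprintf("lame_spectrum at k = %g:\n", x$front$k))
  for (p in x$eigenpairs)
    cat(sprintf("  %s (%s): lambda = %.12g\n", p$name, p$bc, p$lambda))
  invisible(x)
}

#' Maximum eigen-equation residual of the exact Lame eigenpairs
#'
#' Evaluates \eqn{\|H\phi - \lambda\phi\|_\infty} on a grid over
#' \code{[-2K, 2K]} for each of the five eigenpairs, differentiating the
#' eigenfunctions exactly through the elliptic-monomial closure.
#'
#' @param spectrum a \code{\link{lame_spectrum}}.
#' @param n_grid number of grid points.
#' @return named numeric vector of sup-norm residuals.
#' @export
lame_residual <- function(spectrum, n_grid = 1000L) {
  k <- spectrum$front$k
  x <- seq(-2 * spectrum$front$K, 2 * spectrum$front$K, length.out = n_grid)
  sj <- pracma::ellipj(x, k^2)
  pot <- (1 + k^2) - 6 * k^2 * sj$sn^2
  res <- vapply(spectrum$eigenpairs, function(p) {
    d2 <- ep_deriv(ep_deriv(p$terms, k), k)
    phi <- ep_eval(p$terms, k, x)
    max(abs(ep_eval(d2, k, x) + pot * phi - p$lambda * phi))
  }, 0)
  names(res) <- vapply(spectrum$eigenpairs, function(p) p$name, "")
  res
}

# ---------------------------------------------------------------------------
# Restricted two-by-two block and its nonzero eigenvalue

#' Restriction of the perturbed operator to span{1, sn^2}
#'
#' The rank-one perturbation acts only on the span of the even
#' eigenfunctions \code{phi0N}, \code{phi2N}, which equals
#' span\{1, sn^2\}.  In that (non-orthogonal) basis the restricted
#' operator is the 2 x 2 matrix returned here, assembled from complete
#' elliptic integrals.  Its determinant is exactly zero (the forced
#' mass-conservation kernel) and its trace equals \code{\link{lambda1}}.
#'
#' @param k elliptic modulus in (0, 1).
#' @return 2 x 2 numeric matrix.
#' @export
restricted_matrix <- function(k) {
  fr <- elliptic_front(k)
  K <- fr$K; E <- fr$E
  matrix(c(6 * (K - E) / K,           3 * (1 + k^2) * (K - E) / (k^2 * K),
           -6 * k^2,                  -3 * (1 + k^2)),
         nrow = 2, byrow = TRUE)
}

#' Nonzero eigenvalue of the restricted operator
#'
#' Closed form \eqn{\lambda_1 = ((3 - 3k^2) K(k) - 6 E(k)) / K(k)},
#' strictly negative on \code{[0, 1)}: together with the zero eigenvalue it
#' gives the spectrum of \code{\link{restricted_matrix}}, and with the
#' coercivity of the complementary block it proves stability of the cubic
#' front.
#'
#' @param k elliptic modulus in [0, 1).
#' @return numeric value.
#' @export
lambda1 <- function(k) {
  stopifnot(is.numeric(k))
  if (any(k < 0 | k >= 1)) stop("lambda1 requires k in [0, 1)")
  ke <- pracma::ellipke(k^2)
  ((3 - 3 * k^2) * ke$k - 6 * ke$e) / ke$k
}

# ---------------------------------------------------------------------------
# Finite-difference discretization of  d^2/dx^2 + potential(x)

#' Discretize a Schrodinger-type operator
#'
#' Second-order finite-difference matrix for \eqn{\partial_{xx} + V(x)}
#' on an interval, with Dirichlet, Neumann or periodic boundary
#' conditions.  Dirichlet uses the interior grid; Neumann uses the
#' cell-centred grid with ghost-point reflection (second order); periodic
#' wraps the uniform grid.  All three variants are symmetric and their
#' eigenvalues converge at \eqn{O(h^2)}.
#'
#' The result carries the grid, the potential samples and uniform
#' quadrature weights \code{w} (each equal to the grid spacing) so that
#' discrete inner products \code{sum(w * f * g)} approximate the continuum
#' integrals.
#'
#' @param potential function of x, vectorized.
#' @param domain numeric length-2 vector \code{c(a, b)}.
#' @param bc one of \code{"dirichlet"}, \code{"neumann"}, \code{"periodic"}.
#' @param n_grid number of grid points (at least 100).
#' @return object of class \code{"discretized_operator"} with fields
#'   \code{d} (diagonal), \code{e} (off-diagonal), \code{corner} (periodic
#'   wrap entry, 0 otherwise), \code{x}, \code{V}, \code{w}, \code{h},
#'   \code{bc}, \code{n}.
#' @export
discretize_operator <- function(potential, domain, bc = c("dirichlet", "neumann", "periodic"),
                                n_grid = 1000L) {
  bc <- match.arg(bc)
  stopifnot(is.function(potential), length(domain) == 2L, domain[2] > domain[1],
            n_grid >= 100L)
  n <- as.integer(n_grid)
  a <- domain[1]; b <- domain[2]
  if (bc == "dirichlet") {
    h <- (b - a) / (n + 1)
    x <- a + h * seq_len(n)
    V <- potential(x)
    d <- -2 / h^2 + V
    corner <- 0
  } else if (bc == "neumann") {
    h <- (b - a) / n
    x <- a + h * (seq_len(n) - 0.5)
    V <- potential(x)
    d <- -2 / h^2 + V
    d[c(1L, n)] <- -1 / h^2 + V[c(1L, n)]
    corner <- 0
  } else {
    h <- (b - a) / n
    x <- a + h * (seq_len(n) - 1L)
    V <- potential(x)
    d <- -2 / h^2 + V
    corner <- 1 / h^2
  }
  structure(list(d = d, e = rep(1 / h^2, n - 1L), corner = corner,
                 x = x, V = V, w = rep(h, n), h = h, bc = bc,
                 domain = domain, n = n),
            class = "discretized_operator")
}

#' @export
print.discretized_operator <- function(x, ...) {
  cat(sprintf("discretized_operator: %s on [%g, %g], n = %d, h = %g\n",
              x$bc, x$domain[1], x$domain[2], x$n, x$h))
  invisible(x)
}

#' @export
as.matrix.discretized_operator <- function(x, ...) {
  n <- x$n
  mt <- diag(x$d, n, n)
  idx <- seq_len(n - 1L)
  mt[cbind(idx, idx + 1L)] <- x$e
  mt[cbind(idx + 1L, idx)] <- x$e
  if (x$corner != 0) { mt[1L, n] <- mt[1L, n] + x$corner; mt[n, 1L] <- mt[n, 1L] + x$corner }
  mt
}

# Number of eigenvalues of the symmetric tridiagonal (d, e) strictly below
# sigma, by the Sturm/LDL^T negative-pivot count.
sturm_count <- function(d, e, sigma) {
  n <- length(d)
  cnt <- 0L
  q <- d[1] - sigma
  if (q < 0) cnt <- 1L
  for (i in seq_len(n - 1L)) {
    if (abs(q) < 1e-300) q <- -1e-300
    q <- d[i + 1L] - sigma - e[i]^2 / q
    if (q < 0) cnt <- cnt + 1L
  }
  cnt
}

# idx-th smallest eigenvalue of the symmetric tridiagonal (d, e), by
# Sturm-count bisection within the Gershgorin interval.
tridiag_eigenvalue <- function(d, e, idx) {
  r <- c(0, abs(e), 0)
  lo <- min(d - r[-length(r)] - r[-1L]); hi <- max(d + r[-length(r)] + r[-1L])
  for (it in seq_len(200L)) {
    mid <- (lo + hi) / 2
    if (sturm_count(d, e, mid) >= idx) hi <- mid else lo <- mid
    if (hi - lo <= 1e-13 * (1 + abs(lo) + abs(hi))) break
  }
  (lo + hi) / 2
}

#' Largest eigenvalues of a discretized operator
#'
#' For Dirichlet and Neumann discretizations (symmetric tridiagonal) the
#' eigenvalues are located by Sturm-sequence bisection, which is fast even
#' for very fine grids; the periodic variant falls back to a dense solve.
#'
#' @param op a \code{\link{discretize_operator}} result.
#' @param n_top how many of the largest eigenvalues to return.
#' @return numeric vector, decreasing.
#' @export
operator_eigenvalues <- function(op, n_top = 6L) {
  stopifnot(inherits(op, "discretized_operator"), n_top >= 1L, n_top <= op$n)
  if (op$corner != 0) {
    ev <- eigen(as.matrix(op), symmetric = TRUE, only.values = TRUE)$values
    return(ev[seq_len(n_top)])
  }
  vapply(seq_len(n_top),
         function(j) tridiag_eigenvalue(op$d, op$e, op$n - j + 1L), 0)
}

# Solve the symmetric tridiagonal system (d, e) y = b (Thomas algorithm).
solve_tridiag <- function(d, e, b) {
  n <- length(d)
  cp <- numeric(n - 1L); dp <- numeric(n)
  denom <- d[1]
  if (abs(denom) < 1e-300) stop("tridiagonal solve: zero pivot")
  if (n > 1L) cp[1] <- e[1] / denom
  dp[1] <- b[1] / denom
  for (i in seq_len(n - 1L)) {
    denom <- d[i + 1L] - e[i] * cp[i]
    if (abs(denom) < 1e-300) stop("tridiagonal solve: zero pivot")
    if (i < n - 1L) cp[i + 1L] <- e[i + 1L] / denom
    dp[i + 1L] <- (b[i + 1L] - e[i] * dp[i]) / denom
  }
  y <- numeric(n)
  y[n] <- dp[n]
  for (i in rev(seq_len(n - 1L))) y[i] <- dp[i] - cp[i] * y[i + 1L]
  y
}

# ---------------------------------------------------------------------------
# Herglotz / Aronszajn-Krein moving-eigenvalue condition

#' Scan the moving-eigenvalue condition on a real grid
#'
#' Eigenvalues of the perturbed operator whose eigenfunctions are not
#' orthogonal to \eqn{f'(u)} satisfy \eqn{1 = (\rho / 2L) \langle f'(u),
#' (H - \lambda)^{-1} 1\rangle}.  Using \eqn{H 1 = f'(u)} this is
#' equivalent to the vanishing of the Herglotz function
#' \deqn{h(\lambda) = (1/2L) \sum_i \langle 1, v_i\rangle^2 /
#'   (\lambda_i - \lambda) - (1 - \rho) / (\rho \lambda),}
#' whose zeros and poles are real for \eqn{\rho \in [0, 1]}.  The scan
#' evaluates \eqn{h} on the grid (masking points too close to the poles
#' \eqn{\lambda_i}), isolates real roots by sign change plus bisection,
#' and cross-checks reality by assembling the perturbed matrix and
#' reporting any eigenvalue with a nonreal part above tolerance as a
#' violation.
#'
#' @param op a \code{\link{discretize_operator}} result for the
#'   unperturbed operator \eqn{H = \partial_{xx} + f'(u)}.
#' @param L half-width of the domain (the nonlocal coupling is
#'   \eqn{-\rho/(2L) \langle f'(u), \cdot\rangle \mathbf{1}}).
#' @param rho coupling strength in [0, 1].
#' @param lambda_grid real grid to scan.
#' @param tol reality tolerance for the assembled-matrix cross-check.
#' @return list with \code{lambda_grid}, \code{h_values} (NA at masked
#'   points), \code{roots}, \code{poles} (eigenvalues of H with nonzero
#'   mean coupling), \code{nonreal_violations} (count), and
#'   \code{max_imag} of the assembled spectrum.
#' @export
herglotz_scan <- function(op, L, rho, lambda_grid, tol = 1e-8) {
  stopifnot(inherits(op, "discretized_operator"), rho > 0, rho <= 1, L > 0)
  es <- eigen(as.matrix(op), symmetric = TRUE)
  lam <- es$values
  cmean <- as.numeric(crossprod(rep(1, op$n), es$vectors)) * sqrt(op$h)
  c2 <- cmean^2
  hfun <- function(z) {
    base <- vapply(z, function(zz) sum(c2 / (lam - zz)), 0 + 0i) / (2 * L)
    if (rho < 1) base <- base - (1 - rho) / (rho * z) else base
  }
  hfun_real <- function(x) Re(hfun(as.complex(x)))
  # the moving-eigenvalue condition itself: 1 - (rho/2L)<f'(u),(H-lam)^-1 1>,
  # identically equal to -rho * lambda * h(lambda); regular at lambda = 0,
  # where it vanishes exactly when rho = 1
  gfun <- function(x) vapply(x, function(xx)
    (1 - rho) - (xx * rho / (2 * L)) * sum(c2 / (lam - xx)), 0)
  scale_lam <- max(abs(lam))
  pole_mask <- vapply(lambda_grid, function(x)
    min(abs(x - lam)) < 1e-6 * scale_lam, TRUE)
  hv <- rep(NA_real_, length(lambda_grid))
  nz <- !pole_mask & abs(lambda_grid) > 1e-6 * scale_lam
  hv[nz] <- hfun_real(lambda_grid[nz])
  # roots of the condition by sign change on unmasked consecutive pairs
  # with no pole between
  gv <- rep(NA_real_, length(lambda_grid))
  gv[!pole_mask] <- gfun(lambda_grid[!pole_mask])
  roots <- numeric(0)
  idx <- which(!pole_mask)
  for (j in seq_len(length(idx) - 1L)) {
    i1 <- idx[j]; i2 <- idx[j + 1L]
    if (i2 != i1 + 1L) next
    x1 <- lambda_grid[i1]; x2 <- lambda_grid[i2]
    if (any(lam > x1 & lam < x2)) next
    if (is.finite(gv[i1]) && is.finite(gv[i2]) && gv[i1] * gv[i2] <= 0 &&
        !(gv[i1] == 0 && gv[i2] == 0))
      roots <- c(roots, stats::uniroot(gfun, c(x1, x2), tol = 1e-12)$root)
  }
  if (length(roots) > 1L) {
    roots <- sort(roots)
    roots <- roots[c(TRUE, diff(roots) > 1e-6 * scale_lam)]
  }
  # reality cross-check on the assembled perturbed matrix
  ht <- as.matrix(op) - (rho / (2 * L)) * outer(rep(1, op$n), op$w * op$V)
  evp <- eigen(ht, only.values = TRUE)$values
  max_imag <- max(abs(Im(evp)))
  list(lambda_grid = lambda_grid, h_values = hv, condition_values = gv,
       roots = roots,
       poles = lam[abs(cmean) > 1e-8], rho = rho,
       nonreal_violations = sum(abs(Im(evp)) > tol * max(1, max(Mod(evp)))),
       max_imag = max_imag, herglotz = hfun)
}

# ---------------------------------------------------------------------------
# Index theorem for the perturbed operator

#' Positive-eigenvalue index of the perturbed operator
#'
#' For nonsingular \eqn{H} the perturbed operator \eqn{\tilde H = H -
#' (1/2L)\,\mathbf 1\langle f'(u), \cdot\rangle} has a simple kernel and
#' \eqn{n_+(\tilde H) = n_+(H)} when \eqn{\langle 1, H^{-1} 1\rangle < 0},
#' \eqn{n_+(H) - 1} when \eqn{\langle 1, H^{-1} 1\rangle > 0}.  The count
#' and the inner product are computed from the symmetric discretization
#' (Sturm bisection and a tridiagonal solve with quadrature weights); when
#' \code{direct} is enabled the dichotomy is cross-checked by a dense
#' eigendecomposition of the assembled perturbed matrix, and any
#' disagreement is a hard failure.
#'
#' @param op a \code{\link{discretize_operator}} result for \eqn{H}.
#' @param L half-width of the domain.
#' @param f_prime_u samples of \eqn{f'(u)} on the grid; defaults to the
#'   potential stored in \code{op} (for \eqn{H = \partial_{xx} + f'(u)}).
#' @param direct run the dense cross-check (default: when \code{n <= 1500}).
#' @param kernel_factor kernel-detection threshold is
#'   \code{kernel_factor * h^2 * scale}; near-zero eigenvalues below it are
#'   attributed to the forced kernel.
#' @return object of class \code{"index_result"}: fields
#'   \code{n_plus_unperturbed}, \code{inner}, \code{n_plus_perturbed},
#'   \code{kernel_dim}, \code{method}, and when the cross-check ran,
#'   \code{n_plus_direct}.
#' @export
stability_index <- function(op, L, f_prime_u = NULL, direct = NULL,
                            kernel_factor = 10) {
  stopifnot(inherits(op, "discretized_operator"), L > 0)
  if (op$corner != 0) stop("periodic discretizations are not supported here")
  if (is.null(f_prime_u)) f_prime_u <- op$V
  stopifnot(length(f_prime_u) == op$n)
  if (is.null(direct)) direct <- op$n <= 1500L
  scale <- max(abs(op$d)) + max(abs(op$e))
  kernel_thr <- kernel_factor * op$h^2 * max(abs(op$V), 1)
  # nonsingularity: the eigenvalues bracketing zero must clear the threshold
  m <- sturm_count(op$d, op$e, 0)
  near <- c(if (m >= 1L) tridiag_eigenvalue(op$d, op$e, m),
            if (m < op$n) tridiag_eigenvalue(op$d, op$e, m + 1L))
  if (min(abs(near)) < kernel_thr)
    stop(structure(class = c("remark_5_2_case", "error", "condition"),
                   list(message = paste0(
                     "unperturbed operator is singular to tolerance (|lambda| = ",
                     format(min(abs(near))), "): Remark 5.2 case, out of scope"),
                     call = sys.call(-1))))
  n_plus <- op$n - sturm_count(op$d, op$e, 0)
  y <- solve_tridiag(op$d, op$e, rep(1, op$n))
  inner <- sum(op$w * y)
  n_plus_pert <- if (inner > 0) n_plus - 1L else n_plus
  out <- list(n_plus_unperturbed = n_plus, inner = inner,
              n_plus_perturbed = n_plus_pert, kernel_dim = 1L,
              method = "theorem")
  if (direct) {
    ht <- as.matrix(op) - (1 / (2 * L)) * outer(rep(1, op$n), op$w * f_prime_u)
    evp <- eigen(ht, only.values = TRUE)$values
    kerdim <- sum(Mod(evp) < kernel_thr)
    ndir <- sum(Re(evp) > kernel_thr & Mod(evp) >= kernel_thr)
    if (kerdim != 1L || ndir != n_plus_pert)
      stop(sprintf(paste0("index cross-check failed: theorem gives n+ = %d ",
                          "(kernel 1), direct count gives n+ = %d (kernel %d)"),
                   n_plus_pert, ndir, kerdim))
    out$n_plus_direct <- ndir
    out$kernel_dim <- kerdim
    out$method <- "theorem+direct"
  }
  class(out) <- "index_result"
  out
}

#' @export
print.index_result <- function(x, ...) {
  cat(sprintf("index_result: n+(H) = %d, <1, H^-1 1> = %.6g, n+(perturbed) = %d, kernel dim %d [%s]\n",
              x$n_plus_unperturbed, x$inner, x$n_plus_perturbed,
              x$kernel_dim, x$method))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Quadrature family (period-type integrals along the P = 2L level set)

gl_cache <- new.env(parent = emptyenv())
gl_nodes <- function(n = 200L) {
  key <- as.character(n)
  if (is.null(gl_cache[[key]]))
    gl_cache[[key]] <- pracma::gaussLegendre(n, 0, pi / 2)
  gl_cache[[key]]
}

# Turning points of g(u) = 2E + 2 kappa u - 2F(u): the simple roots
# bracketing a positivity interval near the seed bracket.
qf_turning_points <- function(g, bracket) {
  u_grid <- seq(bracket[1], bracket[2], length.out = 2001L)
  gv <- g(u_grid)
  n <- length(gv)
  # candidate wells: interior local maxima of g (the bracket edges are
  # excluded so an unbounded positive tail is never mistaken for a well)
  locmax <- which(c(FALSE, gv[-1L] >= gv[-n]) & c(gv[-n] >= gv[-1L], FALSE) &
                    gv > 0)
  if (length(locmax) == 0L) stop("no positivity interval for the seed (E, kappa)")
  ipos <- locmax[which.max(gv[locmax])]
  ilo <- ipos
  while (ilo > 1L && gv[ilo - 1L] > 0) ilo <- ilo - 1L
  ihi <- ipos
  while (ihi < length(gv) && gv[ihi + 1L] > 0) ihi <- ihi + 1L
  if (ilo == 1L || ihi == length(gv))
    stop("positivity interval not bracketed: enlarge the search bracket")
  mu_minus <- stats::uniroot(g, c(u_grid[ilo - 1L], u_grid[ilo]), tol = 1e-14)$root
  mu_plus <- stats::uniroot(g, c(u_grid[ihi], u_grid[ihi + 1L]), tol = 1e-14)$root
  c(mu_minus, mu_plus)
}

# P, M, R at one (E, kappa) by the substitution u = mu- + (mu+ - mu-) sin^2(theta),
# which removes both inverse-square-root endpoint singularities exactly for
# simple turning points:  integral du / sqrt(g) = 2 d(theta) / sqrt(q) with
# q(u) = g(u) / ((u - mu-)(mu+ - u)) smooth and positive.
qf_integrals <- function(f, Fanti, E, kappa, bracket, n_gl = 200L) {
  g <- function(u) 2 * E + 2 * kappa * u - 2 * Fanti(u)
  mu <- qf_turning_points(g, bracket)
  delta <- mu[2] - mu[1]
  dg <- function(u) 2 * kappa - 2 * f(u)
  slopes <- dg(mu)
  if (min(abs(slopes)) * delta < 1e-8 * max(abs(g(mean(mu))), 1))
    stop("degenerate turning point: the energy level is not regular")
  gl <- gl_nodes(n_gl)
  th <- gl$x; wt <- gl$w
  s2 <- sin(th)^2
  u <- mu[1] + delta * s2
  q <- g(u) / pmax((u - mu[1]) * (mu[2] - u), 1e-300)
  # endpoint limits q(mu-) = g'(mu-)/delta, q(mu+) = -g'(mu+)/delta
  edge <- (u - mu[1]) < 1e-10 * delta | (mu[2] - u) < 1e-10 * delta
  if (any(edge))
    q[edge] <- ifelse(s2[edge] < 0.5, slopes[1] / delta, -slopes[2] / delta)
  invsq <- 2 / sqrt(q)
  list(P = sum(wt * invsq), M = sum(wt * u * invsq),
       R = sum(wt * f(u) * invsq), mu_minus = mu[1], mu_plus = mu[2])
}

# Finite-difference partials of (P, M, R) in (E, kappa).
qf_partials <- function(f, Fanti, E, kappa, bracket, n_gl = 200L, rel_h = 1e-6) {
  hE <- rel_h * (1 + abs(E)); hk <- rel_h * (1 + abs(kappa))
  pe <- qf_integrals(f, Fanti, E + hE, kappa, bracket, n_gl)
  me <- qf_integrals(f, Fanti, E - hE, kappa, bracket, n_gl)
  pk <- qf_integrals(f, Fanti, E, kappa + hk, bracket, n_gl)
  mk <- qf_integrals(f, Fanti, E, kappa - hk, bracket, n_gl)
  list(P_E = (pe$P - me$P) / (2 * hE), M_E = (pe$M - me$M) / (2 * hE),
       R_E = (pe$R - me$R) / (2 * hE), P_k = (pk$P - mk$P) / (2 * hk),
       M_k = (pk$M - mk$M) / (2 * hk), R_k = (pk$R - mk$R) / (2 * hk))
}

#' Continue the family of stationary fronts by quadrature
#'
#' Stationary solutions satisfy \eqn{u_x^2 / 2 + F(u) - \kappa u = E} and
#' are characterized by the period-type integrals \eqn{P}, \eqn{M} (mass)
#' and \eqn{R} (total reaction rate) over the oscillation interval
#' \eqn{(\mu_-, \mu_+)}.  Fixing the half-width pins the level set
#' \eqn{P(E, \kappa) = 2L}, along which this routine continues by the unit
#' arclength field \eqn{(dE, d\kappa)/ds \propto (-P_\kappa, P_E)},
#' re-projecting onto the level set after every step.  At each sample it
#' records \eqn{\mu_\pm}, \eqn{P}, \eqn{M}, \eqn{R}, the derivatives
#' \eqn{dM/ds}, \eqn{dR/ds} and the index ratio
#' \eqn{\tau = (M_E P_\kappa - M_\kappa P_E) / (R_E P_\kappa - R_\kappa
#' P_E)}, for which \eqn{\langle 1, H^{-1} 1\rangle = 2 L \tau}.
#'
#' @param f nonlinearity, a vectorized function of u.
#' @param L half-width defining the level set \eqn{P = 2L}.
#' @param seed_E,seed_kappa starting point; it need not lie exactly on the
#'   level set (it is projected in \code{E} first).
#' @param Fanti antiderivative of \code{f}; when \code{NULL} it is built by
#'   numeric quadrature from 0.
#' @param n_steps continuation steps (half in each direction from the seed).
#' @param ds arclength step.
#' @param bracket search bracket for the turning points.
#' @param n_gl Gauss-Legendre points per integral.
#' @return object of class \code{"quadrature_family"}: \code{samples}
#'   (data.frame with s, E, kappa, mu_minus, mu_plus, P, M, R, dM_ds,
#'   dR_ds, tau), plus \code{f}, \code{Fanti}, \code{L}.
#' @export
quadrature_family <- function(f, L, seed_E, seed_kappa = 0, Fanti = NULL,
                              n_steps = 20L, ds = 0.01, bracket = c(-5, 5),
                              n_gl = 200L) {
  stopifnot(is.function(f), L > 0)
  if (is.null(Fanti))
    Fanti <- function(u) vapply(u, function(uu)
      stats::integrate(f, 0, uu, rel.tol = 1e-12)$value, 0)
  project_E <- function(E, kappa) {
    # Newton in E to restore P(E, kappa) = 2L
    for (it in seq_len(30L)) {
      qi <- qf_integrals(f, Fanti, E, kappa, bracket, n_gl)
      err <- qi$P - 2 * L
      if (abs(err) < 1e-11 * (1 + 2 * L)) return(E)
      hE <- 1e-6 * (1 + abs(E))
      dP <- (qf_integrals(f, Fanti, E + hE, kappa, bracket, n_gl)$P -
             qf_integrals(f, Fanti, E - hE, kappa, bracket, n_gl)$P) / (2 * hE)
      if (abs(dP) < 1e-300) stop("level-set projection stalled: dP/dE = 0")
      E <- E - err / dP
    }
    stop("level-set projection did not converge")
  }
  sample_at <- function(s, E, kappa) {
    qi <- qf_integrals(f, Fanti, E, kappa, bracket, n_gl)
    pa <- qf_partials(f, Fanti, E, kappa, bracket, n_gl)
    nrm <- sqrt(pa$P_E^2 + pa$P_k^2)
    dE <- -pa$P_k / nrm; dk <- pa$P_E / nrm
    den <- pa$R_E * pa$P_k - pa$R_k * pa$P_E
    tau <- if (abs(den) < 1e-300) NA_real_
    else (pa$M_E * pa$P_k - pa$M_k * pa$P_E) / den
    list(row = data.frame(s = s, E = E, kappa = kappa,
                          mu_minus = qi$mu_minus, mu_plus = qi$mu_plus,
                          P = qi$P, M = qi$M, R = qi$R,
                          dM_ds = pa$M_E * dE + pa$M_k * dk,
                          dR_ds = pa$R_E * dE + pa$R_k * dk, tau = tau),
         dE = dE, dk = dk)
  }
  walk <- function(E, kappa, sgn, nst) {
    rows <- list(); s <- 0
    for (i in seq_len(nst)) {
      sm <- tryCatch(sample_at(s, E, kappa), error = function(e) e)
      if (inherits(sm, "error")) {
        attr(rows, "diagnostic") <- conditionMessage(sm)
        break
      }
      if (i > 1L) rows[[length(rows) + 1L]] <- sm$row
      E2 <- E + sgn * ds * sm$dE
      k2 <- kappa + sgn * ds * sm$dk
      E2 <- tryCatch(project_E(E2, k2), error = function(e) e)
      if (inherits(E2, "error")) {
        attr(rows, "diagnostic") <- conditionMessage(E2)
        break
      }
      E <- E2; kappa <- k2; s <- s + sgn * ds
    }
    rows
  }
  E0 <- project_E(seed_E, seed_kappa)
  center <- sample_at(0, E0, seed_kappa)
  half <- max(n_steps %/% 2L, 1L)
  fwd <- walk(E0, seed_kappa, +1, half + 1L)
  bwd <- walk(E0, seed_kappa, -1, half + 1L)
  samples <- rbind(do.call(rbind, c(rev(bwd), list(NULL))), center$row,
                   do.call(rbind, c(fwd, list(NULL))))
  samples <- samples[order(samples$s), , drop = FALSE]
  rownames(samples) <- NULL
  diag_msg <- c(attr(bwd, "diagnostic"), attr(fwd, "diagnostic"))
  structure(list(samples = samples, f = f, Fanti = Fanti, L = L,
                 diagnostic = if (length(diag_msg)) diag_msg else NULL),
            class = "quadrature_family")
}

#' @export
print.quadrature_family <- function(x, ...) {
  cat(sprintf("quadrature_family: %d samples on P = 2L (L = %g), kappa in [%g, %g]\n",
              nrow(x$samples), x$L, min(x$samples$kappa), max(x$samples$kappa)))
  if (!is.null(x$diagnostic))
    cat("  continuation stopped:", x$diagnostic[1], "\n")
  invisible(x)
}

#' Reconstruct a stationary front profile from the quadrature
#'
#' Inverts \eqn{x(u) = \int_{\mu_-}^{u} dv / \sqrt{2E + 2\kappa v - 2F(v)}}
#' through the singularity-free angular substitution, yielding the profile
#' \eqn{u(x)} on \code{[-L, L]} with \eqn{L = P/2}; used to discretize the
#' unperturbed operator \eqn{\partial_{xx} + f'(u)} for a general
#' nonlinearity.
#'
#' @param f nonlinearity.
#' @param E,kappa quadrature constants.
#' @param Fanti antiderivative of \code{f} (numeric quadrature when NULL).
#' @param n_theta resolution of the angular grid.
#' @param bracket turning-point search bracket.
#' @return list with \code{x}, \code{u} (profile samples), \code{L},
#'   \code{u_of_x} (spline interpolant), \code{mu_minus}, \code{mu_plus}.
#' @export
front_profile <- function(f, E, kappa = 0, Fanti = NULL, n_theta = 4001L,
                          bracket = c(-5, 5)) {
  if (is.null(Fanti))
    Fanti <- function(u) vapply(u, function(uu)
      stats::integrate(f, 0, uu, rel.tol = 1e-12)$value, 0)
  g <- function(u) 2 * E + 2 * kappa * u - 2 * Fanti(u)
  mu <- qf_turning_points(g, bracket)
  delta <- mu[2] - mu[1]
  dg <- function(u) 2 * kappa - 2 * f(u)
  th <- seq(0, pi / 2, length.out = n_theta)
  u <- mu[1] + delta * sin(th)^2
  q <- g(u) / pmax((u - mu[1]) * (mu[2] - u), 1e-300)
  q[1] <- dg(mu[1]) / delta
  q[n_theta] <- -dg(mu[2]) / delta
  integrand <- 2 / sqrt(q)
  dth <- th[2] - th[1]
  x <- c(0, cumsum((integrand[-1] + integrand[-n_theta]) / 2 * dth))
  L <- x[n_theta] / 2
  x <- x - L
  list(x = x, u = u, L = L, u_of_x = stats::splinefun(x, u, method = "hyman"),
       mu_minus = mu[1], mu_plus = mu[2])
}
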