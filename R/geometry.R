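# Curves in the (rho1, rho2) plane derived from the characteristic function:
# constant-eigenvalue curves, the envelope of that family (the locus of real
# double eigenvalues), singular bifurcation pieces, Hopf curves and
# triple-eigenvalue points.
#
# All polynomial work happens in the scaled spectral variable t = lambda/s
# stored inside the char_function.  Every formula used here is a ratio in
# which each Wronskian carries exactly one derivative (or each triple
# Wronskian three), so the powers of s cancel and the (rho1, rho2)
# coordinates are identical in the scaled and unscaled variables.

# wedge polynomials of the four characteristic-function components (t-space)
cf_wedges <- function(cf) {
  list(DP1 = poly_wronskian(cf$D, cf$P1),
       DP2 = poly_wronskian(cf$D, cf$P2),
       DQ  = poly_wronskian(cf$D, cf$Q),
       P12 = poly_wronskian(cf$P1, cf$P2),
       P1Q = poly_wronskian(cf$P1, cf$Q),
       P2Q = poly_wronskian(cf$P2, cf$Q))
}

cf_coef_scale <- function(cf) max(abs(c(cf$D, cf$P1, cf$P2, cf$Q)))

cf_q_is_zero <- function(cf) poly_is_zero(cf$Q, ref_scale = cf_coef_scale(cf))

# residual of (F, dF/dt) at sampled points, relative to term magnitudes
envelope_residual <- function(cf, t, rho1, rho2) {
  d0 <- poly_eval(cf$D, t);  p1 <- poly_eval(cf$P1, t)
  p2 <- poly_eval(cf$P2, t); q0 <- poly_eval(cf$Q, t)
  d1 <- poly_eval(poly_deriv(cf$D), t);  p11 <- poly_eval(poly_deriv(cf$P1), t)
  p21 <- poly_eval(poly_deriv(cf$P2), t); q1 <- poly_eval(poly_deriv(cf$Q), t)
  f  <- d0 + rho1 * p1 + rho2 * p2 + rho1 * rho2 * q0
  ft <- d1 + rho1 * p11 + rho2 * p21 + rho1 * rho2 * q1
  den  <- 1 + abs(d0) + abs(rho1 * p1) + abs(rho2 * p2) + abs(rho1 * rho2 * q0)
  dent <- 1 + abs(d1) + abs(rho1 * p11) + abs(rho2 * p21) + abs(rho1 * rho2 * q1)
  pmax(abs(f) / den, abs(ft) / dent)
}

#' Curve along which a fixed eigenvalue persists
#'
#' For a fixed real eigenvalue \eqn{\lambda_*}, the set of
#' \eqn{(\rho_1,\rho_2)} for which \eqn{\lambda_*} is in the spectrum is the
#' rational curve \eqn{\rho_1 = -(D + \rho_2 P_2)/(P_1 + \rho_2 Q)} (all
#' evaluated at \eqn{\lambda_*}); a line when \eqn{Q \equiv 0}.
#'
#' @param cf a \code{\link{char_function}}.
#' @param lambda_star the eigenvalue to hold fixed.
#' @param rho2_grid numeric grid of \eqn{\rho_2} values.
#' @param tol residual tolerance for the validity mask.
#' @return a \code{\link{parametric_curve}} of kind
#'   \code{"constant_eigenvalue"}, parametrised by \eqn{\rho_2}; points at
#'   poles of the rational expression are masked invalid.
#' @export
constant_eigenvalue_curve <- function(cf, lambda_star, rho2_grid, tol = 1e-8) {
  t0 <- lambda_star / cf$lambda_scale
  d0 <- poly_eval(cf$D, t0);  p1 <- poly_eval(cf$P1, t0)
  p2 <- poly_eval(cf$P2, t0); q0 <- poly_eval(cf$Q, t0)
  sc <- cf_coef_scale(cf)
  if (max(abs(c(d0, p1, p2, q0))) < 1e-12 * sc)
    stop("degenerate constant-eigenvalue curve: D, P1, P2, Q all vanish at lambda_star")
  den <- p1 + rho2_grid * q0
  pole <- abs(den) < 1e-10 * (abs(p1) + abs(rho2_grid * q0) + 1e-300)
  rho1 <- ifelse(pole, NA_real_, -(d0 + rho2_grid * p2) / den)
  f <- d0 + rho1 * p1 + rho2_grid * p2 + rho1 * rho2_grid * q0
  res <- abs(f) / (1 + abs(d0) + abs(rho1 * p1) + abs(rho2_grid * p2) +
                     abs(rho1 * rho2_grid * q0))
  valid <- !pole & is.finite(rho1) & res <= tol
  n <- length(rho2_grid)
  brk <- if (n > 1L) sign(den[-n]) * sign(den[-1L]) < 0 else logical(0)
  parametric_curve("constant_eigenvalue", "rho2", rho2_grid, rho1, rho2_grid,
                   branch = "linear", valid = valid, residual = res,
                   eigenvalue_tag = lambda_star, tol = tol, breaks = brk)
}

# Solve the pair of bilinear equations
#   r[1] + r[2] x + r[3] y + r[4] xy = 0      (one row per equation)
# for real (x, y).  Returns a data.frame with columns rho1, rho2, branch and
# attribute "diagnostic" describing degeneracies.
solve_bilinear_pair <- function(r1, r2, tol = 1e-11) {
  sc <- max(abs(c(r1, r2)), 1e-300)
  empty <- function(diag) {
    out <- data.frame(rho1 = numeric(0), rho2 = numeric(0),
                      branch = character(0))
    attr(out, "diagnostic") <- diag
    out
  }
  quad_roots <- function(a, b, c) {
    # stable quadratic solve; returns c(root_plus, root_minus) or NULL
    if (abs(a) < tol * max(abs(b), abs(c), 1)) {
      if (abs(b) < tol * max(abs(c), 1)) return(NULL)
      return(c(-c / b, NA_real_))
    }
    disc <- b^2 - 4 * a * c
    if (disc < 0) return(NULL)
    s <- sqrt(disc)
    c((-b + s) / (2 * a), (-b - s) / (2 * a))
  }
  if (max(abs(c(r1[4], r2[4]))) < tol * sc) {
    # both equations linear: single solution
    m <- rbind(r1[2:3], r2[2:3])
    if (abs(det(m)) < tol * sc^2) return(empty("degenerate linear system"))
    xy <- solve(m, -c(r1[1], r2[1]))
    out <- data.frame(rho1 = xy[1], rho2 = xy[2], branch = "linear")
    attr(out, "diagnostic") <- "ok"
    return(out)
  }
  cc <- r1 * r2[4] - r2 * r1[4]       # cc[4] == 0: the xy-free line
  c0 <- cc[1]; c1 <- cc[2]; c2 <- cc[3]
  if (max(abs(c(c1, c2))) < tol * sc^2)
    return(empty("elimination degenerate (rank condition fails)"))
  use <- if (abs(r1[4]) >= abs(r2[4])) r1 else r2
  if (abs(c2) >= abs(c1)) {
    # y = -(c0 + c1 x)/c2, substitute
    rt <- quad_roots(-use[4] * c1, use[2] * c2 - use[3] * c1 - use[4] * c0,
                     use[1] * c2 - use[3] * c0)
    if (is.null(rt)) return(empty("no real solutions"))
    x <- rt
    y <- -(c0 + c1 * x) / c2
  } else {
    rt <- quad_roots(-use[4] * c2, use[3] * c1 - use[2] * c2 - use[4] * c0,
                     use[1] * c1 - use[2] * c0)
    if (is.null(rt)) return(empty("no real solutions"))
    y <- rt
    x <- -(c0 + c2 * y) / c1
  }
  keep <- is.finite(x) & is.finite(y)
  out <- data.frame(rho1 = x[keep], rho2 = y[keep],
                    branch = c("plus", "minus")[which(keep)])
  attr(out, "diagnostic") <- "ok"
  out
}

# internal: envelope branch values on a t-grid (Q not identically zero)
envelope_values_general <- function(cf, tt, w) {
  A  <- poly_eval(w$P12, tt); B <- poly_eval(w$DQ, tt)
  Cq <- poly_eval(w$P1Q, tt); Dq <- poly_eval(w$P2Q, tt)
  DP1 <- poly_eval(w$DP1, tt)
  disc <- (A - B)^2 - 4 * DP1 * Dq
  ok <- disc >= 0 & abs(Cq) > 0 & abs(Dq) > 0
  s <- sqrt(pmax(disc, 0))
  list(plus  = list(rho1 = ifelse(ok, (-(A + B) + s) / (2 * Cq), NA_real_),
                    rho2 = ifelse(ok, ((A - B) - s) / (2 * Dq), NA_real_)),
       minus = list(rho1 = ifelse(ok, (-(A + B) - s) / (2 * Cq), NA_real_),
                    rho2 = ifelse(ok, ((A - B) + s) / (2 * Dq), NA_real_)),
       ok = ok)
}

#' Envelope (double-eigenvalue) curve of the constant-eigenvalue family
#'
#' Solves the envelope conditions \eqn{F = 0} and \eqn{\partial_\lambda F = 0}
#' for the characteristic function
#' \eqn{F = D + \rho_1 P_1 + \rho_2 P_2 + \rho_1\rho_2 Q}.  Along this curve
#' the matrix has a real eigenvalue of multiplicity at least two; crossing it
#' generically changes the number of real eigenvalues by two.
#'
#' For \eqn{Q \not\equiv 0} the curve has two square-root branches with
#' structurally paired signs (the plus sign in \eqn{\rho_1} pairs with the
#' minus sign in \eqn{\rho_2}); parameter values where the radicand is
#' negative are masked invalid.  For \eqn{Q \equiv 0} there is a single
#' rational branch
#' \eqn{\rho_1 = -(D\wedge P_2)/(P_1\wedge P_2)},
#' \eqn{\rho_2 = (D\wedge P_1)/(P_1\wedge P_2)}
#' (wedge convention \eqn{p\wedge q = pq' - p'q} throughout).
#'
#' @param cf a \code{\link{char_function}} of a rank-two system.
#' @param lambda_grid numeric grid of eigenvalue parameter values.
#' @param tol residual tolerance for the validity mask.
#' @param refine_passes number of adaptive refinement passes inserting
#'   grid points near validity transitions and tangent-norm minima (cusps).
#' @return list of two \code{\link{parametric_curve}} objects (branches
#'   \code{plus} and \code{minus}); for \eqn{Q\equiv 0} both entries share
#'   the single \code{linear} branch.
#' @export
envelope_curve <- function(cf, lambda_grid, tol = 1e-8, refine_passes = 1L) {
  w <- cf_wedges(cf)
  sc <- cf_coef_scale(cf)
  qzero <- cf_q_is_zero(cf)
  if (qzero && poly_is_zero(w$P12, sc))
    stop("all defining Wronskians vanish identically; see singular_pieces()")
  tt <- sort(unique(lambda_grid)) / cf$lambda_scale

  build <- function(tt) {
    if (!qzero) {
      ev <- envelope_values_general(cf, tt, w)
    } else {
      den <- poly_eval(w$P12, tt)
      ok <- abs(den) > 1e-12 * sc^2
      r1 <- ifelse(ok, -poly_eval(w$DP2, tt) / den, NA_real_)
      r2 <- ifelse(ok,  poly_eval(w$DP1, tt) / den, NA_real_)
      ev <- list(plus = list(rho1 = r1, rho2 = r2),
                 minus = list(rho1 = r1, rho2 = r2), ok = ok)
    }
    ev
  }
  for (pass in seq_len(refine_passes + 1L)) {
    ev <- build(tt)
    if (pass > refine_passes) break
    # refine near validity transitions and near tangent-norm minima
    flip <- which(ev$ok[-length(ev$ok)] != ev$ok[-1L])
    dr <- sqrt(diff(ev$plus$rho1)^2 + diff(ev$plus$rho2)^2)
    small <- which(is.finite(dr) & dr < stats::quantile(dr[is.finite(dr)], 0.05,
                                                       na.rm = TRUE))
    idx <- unique(c(flip, small))
    if (length(idx) == 0L) break
    newt <- as.vector(outer(seq(0.1, 0.9, by = 0.2), diff(tt)[idx])) +
      rep(tt[idx], each = 5L)
    tt <- sort(unique(c(tt, newt)))
  }
  # break the polyline where a branch denominator changes sign (pole jump)
  den <- if (!qzero) poly_eval(w$P1Q, tt) * poly_eval(w$P2Q, tt)
  else poly_eval(w$P12, tt)
  nt <- length(tt)
  brk <- if (nt > 1L) sign(den[-nt]) * sign(den[-1L]) < 0 else logical(0)
  mk <- function(br, name) {
    res <- envelope_residual(cf, tt, br$rho1, br$rho2)
    valid <- ev$ok & is.finite(br$rho1) & is.finite(br$rho2) & res <= tol
    parametric_curve("envelope", "lambda", tt * cf$lambda_scale,
                     br$rho1, br$rho2, branch = name, valid = valid,
                     residual = res, tol = tol, breaks = brk)
  }
  if (qzero) {
    one <- mk(ev$plus, "linear")
    list(plus = one, minus = one)
  } else {
    list(plus = mk(ev$plus, "plus"), minus = mk(ev$minus, "minus"))
  }
}

#' Envelope points at a single eigenvalue
#'
#' Solves the envelope conditions exactly at one eigenvalue
#' \eqn{\lambda_*}: a linear plus a quadratic equation in
#' \eqn{(\rho_1, \rho_2)} whose real solutions (0, 1 or 2 of them) are the
#' points where \eqn{\lambda_*} is a double eigenvalue.
#'
#' @param cf a \code{\link{char_function}}.
#' @param lambda_star the eigenvalue.
#' @param tol relative degeneracy threshold.
#' @return data.frame with columns \code{rho1}, \code{rho2}, \code{branch}
#'   (zero rows when the eigenvalue admits no real double point).  If the
#'   linear system for the envelope is inconsistent the eigenvalue cannot be
#'   reached at multiplicity two and an error of class
#'   \code{"eigenvalue_unreachable"} is signalled.
#' @export
envelope_point <- function(cf, lambda_star, tol = 1e-11) {
  t0 <- lambda_star / cf$lambda_scale
  r1 <- c(poly_eval(cf$D, t0), poly_eval(cf$P1, t0), poly_eval(cf$P2, t0),
          poly_eval(cf$Q, t0))
  r2 <- c(poly_eval(poly_deriv(cf$D), t0), poly_eval(poly_deriv(cf$P1), t0),
          poly_eval(poly_deriv(cf$P2), t0), poly_eval(poly_deriv(cf$Q), t0))
  sol <- solve_bilinear_pair(r1, r2, tol = tol)
  if (nrow(sol) == 0L &&
      attr(sol, "diagnostic") %in% c("elimination degenerate (rank condition fails)",
                                     "degenerate linear system")) {
    # distinguish inconsistent (unreachable) from underdetermined (singular)
    m <- rbind(r1[2:4], r2[2:4])
    aug <- cbind(m, -c(r1[1], r2[1]))
    if (qr(m / max(abs(m), 1e-300))$rank < qr(aug / max(abs(aug), 1e-300))$rank)
      stop(structure(class = c("eigenvalue_unreachable", "error", "condition"),
                     list(message = sprintf(
                       "eigenvalue %g cannot be reached at multiplicity two", lambda_star),
                       call = sys.call())))
  }
  if (nrow(sol)) {
    res <- envelope_residual(cf, rep(t0, nrow(sol)), sol$rho1, sol$rho2)
    sol <- sol[res <= 1e-7, , drop = FALSE]
  }
  sol
}

#' Singular pieces of the bifurcation curve
#'
#' At special eigenvalues the linear system defining the envelope is
#' consistent but rank deficient, and a whole curve in the
#' \eqn{(\rho_1,\rho_2)} plane carries that eigenvalue with multiplicity two
#' or more.  Candidate eigenvalues are located as common real roots of the
#' pairwise Wronskians (screened with polynomial resultants and confirmed
#' pointwise), then classified: full rank collapse (all six Wronskians
#' vanish) or the two one-sided rank conditions.
#'
#' @param cf a \code{\link{char_function}}.
#' @param rho_grid grid used to sample the emitted curves.
#' @param tol relative zero threshold on scaled Wronskian values.
#' @return list of \code{\link{parametric_curve}} objects of kind
#'   \code{"singular"} (empty for a generic system), each tagged with its
#'   eigenvalue.
#' @export
singular_pieces <- function(cf, rho_grid = seq(-10, 10, length.out = 401),
                            tol = 1e-9) {
  w <- cf_wedges(cf)
  sc <- cf_coef_scale(cf)
  wsc <- sc^2
  nonzero <- Filter(function(p) !poly_is_zero(p, wsc), w)
  if (length(nonzero) == 0L) return(list())
  cand <- sort(unique(unlist(lapply(nonzero, poly_real_roots))))
  if (length(cand) == 0L) return(list())
  # cluster nearby candidates
  cand <- cand[c(TRUE, diff(cand) > 1e-7 * (1 + abs(cand[-1])))]
  out <- list()
  for (t0 in cand) {
    if (!is_rank_deficient_at(cf, t0, tol)) next
    lam <- t0 * cf$lambda_scale
    d0 <- poly_eval(cf$D, t0);  p1 <- poly_eval(cf$P1, t0)
    p2 <- poly_eval(cf$P2, t0); q0 <- poly_eval(cf$Q, t0)
    # curve rho1(rho2) from F = 0, filtered on the derivative condition
    den <- p1 + rho_grid * q0
    pole <- abs(den) < 1e-10 * (abs(p1) + abs(rho_grid * q0) + 1e-300)
    r1v <- ifelse(pole, NA_real_, -(d0 + rho_grid * p2) / den)
    res <- envelope_residual(cf, rep(t0, length(rho_grid)), r1v, rho_grid)
    valid <- !pole & is.finite(r1v) & res <= 1e-7
    ng <- length(rho_grid)
    brk <- if (ng > 1L) sign(den[-ng]) * sign(den[-1L]) < 0 else logical(0)
    if (any(valid))
      out[[length(out) + 1L]] <- parametric_curve(
        "singular", "rho2", rho_grid, r1v, rho_grid, branch = "linear",
        valid = valid, residual = res, eigenvalue_tag = lam, breaks = brk)
    # vertical line rho2 = -P1/Q when it lies entirely on the curve
    if (abs(q0) > 1e-12 * sc) {
      y0 <- -p1 / q0
      if (abs(d0 + p2 * y0) < 1e-9 * (abs(d0) + abs(p2 * y0) + 1)) {
        r2v <- rep(y0, length(rho_grid))
        res2 <- envelope_residual(cf, rep(t0, length(rho_grid)), rho_grid, r2v)
        valid2 <- res2 <= 1e-7
        if (any(valid2))
          out[[length(out) + 1L]] <- parametric_curve(
            "singular", "rho1", rho_grid, rho_grid, r2v, branch = "linear",
            valid = valid2, residual = res2, eigenvalue_tag = lam)
      }
    }
  }
  out
}

# rank of the 2 x 4 matrix [D P1 P2 Q; D' P1' P2' Q'] at t0 is below 2,
# or one of the one-sided consistent-underdetermined conditions holds
is_rank_deficient_at <- function(cf, t0, tol = 1e-9) {
  w <- cf_wedges(cf)
  sc <- cf_coef_scale(cf)
  wv <- vapply(w, function(p) poly_eval(p, t0), 0)
  wref <- tol * sc^2 * (1 + abs(t0))^(cf$n)    # coefficient-scaled threshold
  allzero <- all(abs(wv) <= wref)
  if (allzero) {
    # confirm with the svd of the scaled 2 x 4 matrix
    m <- rbind(c(poly_eval(cf$D, t0), poly_eval(cf$P1, t0),
                 poly_eval(cf$P2, t0), poly_eval(cf$Q, t0)),
               c(poly_eval(poly_deriv(cf$D), t0), poly_eval(poly_deriv(cf$P1), t0),
                 poly_eval(poly_deriv(cf$P2), t0), poly_eval(poly_deriv(cf$Q), t0)))
    sv <- svd(m)$d
    return(sv[2] <= 1e-8 * max(sv[1], 1e-300))
  }
  # one-sided conditions: P1^Q != 0, P2^Q = 0, D^P1 = 0, P1^P2 = D^Q
  c2 <- abs(wv["P1Q"]) > wref && abs(wv["P2Q"]) <= wref &&
    abs(wv["DP1"]) <= wref && abs(wv["P12"] - wv["DQ"]) <= wref
  c3 <- abs(wv["P2Q"]) > wref && abs(wv["P1Q"]) <= wref &&
    abs(wv["DP2"]) <= wref && abs(wv["P12"] + wv["DQ"]) <= wref
  c2 || c3
}

#' Resultant of two polynomials
#'
#' Determinant of the Sylvester matrix; zero iff the polynomials share a
#' root.  Used to screen candidate eigenvalues for singular bifurcation
#' pieces without factoring.
#'
#' @param p,q coefficient vectors, increasing powers.
#' @return the resultant (a number).
#' @export
poly_resultant <- function(p, q) {
  p <- poly_trim(p); q <- poly_trim(q)
  m <- length(p) - 1L; n <- length(q) - 1L
  if (m < 1L || n < 1L) return(if (m < 1L) p[1]^n else q[1]^m)
  syl <- matrix(0, m + n, m + n)
  for (i in seq_len(n)) syl[i, i:(i + m)] <- rev(p)
  for (i in seq_len(m)) syl[n + i, i:(i + n)] <- rev(q)
  det(syl)
}

#' Hopf curve: loci of purely imaginary eigenvalue pairs
#'
#' For each frequency \eqn{\omega > 0} solves the real and imaginary parts
#' of \eqn{F(i\omega; \rho_1, \rho_2) = 0} — two bilinear equations in
#' \eqn{(\rho_1, \rho_2)} — by elimination to a quadratic with structurally
#' paired sign branches.  At valid points the assembled matrix has the
#' eigenvalue pair \eqn{\pm i\omega}.  \eqn{\omega = 0} is excluded: there
#' the imaginary part vanishes identically and the locus degenerates to the
#' zero-eigenvalue member of the constant-eigenvalue family
#' (\code{\link{constant_eigenvalue_curve}} with \code{lambda_star = 0}).
#'
#' @param cf a \code{\link{char_function}}.
#' @param omega_grid strictly positive frequencies.
#' @param tol residual tolerance for the validity mask.
#' @return list of two \code{\link{parametric_curve}} objects (branches
#'   \code{plus} and \code{minus}) parametrised by \eqn{\omega}.
#' @export
hopf_curve <- function(cf, omega_grid, tol = 1e-8) {
  if (any(omega_grid <= 0))
    stop("omega must be positive; use constant_eigenvalue_curve(cf, 0, ...) for omega = 0")
  n <- length(omega_grid)
  r1p <- r2p <- r1m <- r2m <- rep(NA_real_, n)
  resp <- resm <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    t0 <- 1i * omega_grid[i] / cf$lambda_scale
    vals <- c(poly_eval(cf$D, t0), poly_eval(cf$P1, t0), poly_eval(cf$P2, t0),
              poly_eval(cf$Q, t0))
    sol <- solve_bilinear_pair(Re(vals), Im(vals))
    for (k in seq_len(nrow(sol))) {
      v <- abs(vals[1] + sol$rho1[k] * vals[2] + sol$rho2[k] * vals[3] +
                 sol$rho1[k] * sol$rho2[k] * vals[4]) /
        (1 + sum(abs(vals * c(1, sol$rho1[k], sol$rho2[k],
                              sol$rho1[k] * sol$rho2[k]))))
      if (sol$branch[k] %in% c("plus", "linear")) {
        r1p[i] <- sol$rho1[k]; r2p[i] <- sol$rho2[k]; resp[i] <- v
      } else {
        r1m[i] <- sol$rho1[k]; r2m[i] <- sol$rho2[k]; resm[i] <- v
      }
    }
  }
  mk <- function(r1, r2, res, name) {
    valid <- is.finite(r1) & is.finite(r2) & !is.na(res) & res <= tol
    parametric_curve("hopf", "omega", omega_grid, r1, r2, branch = name,
                     valid = valid, residual = res, tol = tol)
  }
  list(plus = mk(r1p, r2p, resp, "plus"), minus = mk(r1m, r2m, resm, "minus"))
}

# Newton polish of a triple-point candidate: solve F = F' = F'' = 0 in the
# unknowns (t, rho1, rho2); returns c(t, rho1, rho2).
polish_triple <- function(cf, t0, x, y, iters = 8L) {
  polys <- list(cf$D, cf$P1, cf$P2, cf$Q)
  dk <- lapply(0:3, function(k) {
    ps <- polys
    for (j in seq_len(k)) ps <- lapply(ps, poly_deriv)
    ps
  })
  ev <- function(k, t) vapply(dk[[k + 1L]], function(q) poly_eval(q, t), 0)
  z <- c(t0, x, y)
  for (it in seq_len(iters)) {
    v0 <- ev(0, z[1]); v1 <- ev(1, z[1]); v2 <- ev(2, z[1]); v3 <- ev(3, z[1])
    w <- c(1, z[2], z[3], z[2] * z[3])
    Fv <- c(sum(v0 * w), sum(v1 * w), sum(v2 * w))
    J <- rbind(c(sum(v1 * w), v0[2] + z[3] * v0[4], v0[3] + z[2] * v0[4]),
               c(sum(v2 * w), v1[2] + z[3] * v1[4], v1[3] + z[2] * v1[4]),
               c(sum(v3 * w), v2[2] + z[3] * v2[4], v2[3] + z[2] * v2[4]))
    if (rcond(J) < 1e-14) break
    step <- solve(J, Fv)
    znew <- z - step
    if (!all(is.finite(znew)) || max(abs(step)) > 0.5 * (1 + max(abs(z)))) break
    z <- znew
    if (max(abs(step)) < 1e-14 * (1 + max(abs(z)))) break
  }
  z
}

#' Triple-eigenvalue (cusp) points
#'
#' Locates isolated points of the \eqn{(\rho_1,\rho_2)} plane where the
#' matrix has a real eigenvalue of multiplicity at least three — equivalently
#' cusps of the envelope curve, where its tangent vector vanishes.  In the
#' generic case candidates are real roots of
#' \eqn{(P_1\wedge P_2\wedge Q)(P_1\wedge P_2\wedge D) -
#'      (D\wedge P_2\wedge Q)(P_1\wedge D\wedge Q)}
#' with \eqn{P_1\wedge P_2\wedge Q \neq 0}; when the triple Wronskians
#' degenerate identically (forced, for example, by a model symmetry such as
#' \eqn{P_1 = P_2}) candidates come from the remaining nonzero triple
#' Wronskians and the points are recovered on the singular pieces.  Every
#' returned point is verified to carry at least three numerically coincident
#' eigenvalues of the assembled matrix.
#'
#' @param cf a \code{\link{char_function}} (carries its system for
#'   verification).
#' @param lambda_range length-2 numeric interval searched for candidate
#'   eigenvalues.
#' @param tol residual tolerance.
#' @return data.frame with columns \code{lambda}, \code{rho1}, \code{rho2}
#'   and the three defining-equation residuals \code{res_f}, \code{res_f1},
#'   \code{res_f2} (zero rows when no triple point exists).
#' @export
triple_points <- function(cf, lambda_range, tol = 1e-9) {
  s <- cf$lambda_scale
  trange <- sort(lambda_range / s)
  w3 <- list(PPQ = poly_wronskian3(cf$P1, cf$P2, cf$Q),
             PPD = poly_wronskian3(cf$P1, cf$P2, cf$D),
             DPQ = poly_wronskian3(cf$D, cf$P2, cf$Q),
             PDQ = poly_wronskian3(cf$P1, cf$D, cf$Q))
  sc3 <- max(abs(unlist(w3)), 1e-300)
  degen <- poly_is_zero(w3$PPQ, sc3, tol = 1e-10)
  if (!degen) {
    g <- poly_add(poly_mul(w3$PPQ, w3$PPD), -poly_mul(w3$DPQ, w3$PDQ))
    cand <- poly_real_roots(g)
    cand <- cand[abs(poly_eval(w3$PPQ, cand)) > 1e-9 * sc3 * (1 + abs(cand))^(2 * cf$n)]
  } else {
    cand <- sort(unique(unlist(lapply(
      Filter(function(p) !poly_is_zero(p, sc3, tol = 1e-10), w3),
      poly_real_roots))))
  }
  cand <- cand[cand >= trange[1] & cand <= trange[2]]
  pts <- list()
  for (t0 in cand) {
    vals0 <- c(poly_eval(cf$D, t0), poly_eval(cf$P1, t0), poly_eval(cf$P2, t0),
               poly_eval(cf$Q, t0))
    vals1 <- c(poly_eval(poly_deriv(cf$D), t0), poly_eval(poly_deriv(cf$P1), t0),
               poly_eval(poly_deriv(cf$P2), t0), poly_eval(poly_deriv(cf$Q), t0))
    vals2 <- c(poly_eval(poly_deriv(poly_deriv(cf$D)), t0),
               poly_eval(poly_deriv(poly_deriv(cf$P1)), t0),
               poly_eval(poly_deriv(poly_deriv(cf$P2)), t0),
               poly_eval(poly_deriv(poly_deriv(cf$Q)), t0))
    m3 <- rbind(vals0[2:4], vals1[2:4], vals2[2:4])
    rhs <- -c(vals0[1], vals1[1], vals2[1])
    cands_xy <- NULL
    if (rcond(m3) > 1e-10) {
      xyz <- solve(m3, rhs)
      if (abs(xyz[3] - xyz[1] * xyz[2]) <= 1e-6 * (1 + abs(xyz[1] * xyz[2])))
        cands_xy <- rbind(cands_xy, xyz[1:2])
    } else {
      # degenerate: closed-form candidates on the singular lines first (they
      # are exact and win the dedupe), then envelope points
      if (is_rank_deficient_at(cf, t0)) {
        # second-derivative condition along the two singular lines
        q0 <- vals0[4]
        if (abs(q0) > 1e-12 * cf_coef_scale(cf)) {
          x0 <- -vals0[3] / q0    # rho1 on the horizontal singular line
          den <- vals2[3] + vals2[4] * x0
          if (abs(den) > 1e-12 * max(abs(vals2), 1))
            cands_xy <- rbind(cands_xy, c(x0, -(vals2[1] + vals2[2] * x0) / den))
          y0 <- -vals0[2] / q0    # rho2 on the vertical singular line
          den <- vals2[2] + vals2[4] * y0
          if (abs(den) > 1e-12 * max(abs(vals2), 1))
            cands_xy <- rbind(cands_xy, c(-(vals2[1] + vals2[3] * y0) / den, y0))
        }
      }
      ep <- tryCatch(envelope_point(cf, t0 * s), error = function(e) NULL)
      if (!is.null(ep) && nrow(ep))
        cands_xy <- rbind(cands_xy, as.matrix(ep[, c("rho1", "rho2")]))
    }
    if (is.null(cands_xy)) next
    for (k in seq_len(nrow(cands_xy))) {
      p <- polish_triple(cf, t0, cands_xy[k, 1], cands_xy[k, 2])
      t0k <- p[1]; x <- p[2]; y <- p[3]
      vals0 <- vapply(list(cf$D, cf$P1, cf$P2, cf$Q),
                      function(q) poly_eval(q, t0k), 0)
      vals1 <- vapply(list(cf$D, cf$P1, cf$P2, cf$Q),
                      function(q) poly_eval(poly_deriv(q), t0k), 0)
      vals2 <- vapply(list(cf$D, cf$P1, cf$P2, cf$Q),
                      function(q) poly_eval(poly_deriv(poly_deriv(q)), t0k), 0)
      rr <- x * y
      den0 <- 1 + sum(abs(vals0 * c(1, x, y, rr)))
      den1 <- 1 + sum(abs(vals1 * c(1, x, y, rr)))
      den2 <- 1 + sum(abs(vals2 * c(1, x, y, rr)))
      rf  <- abs(sum(vals0 * c(1, x, y, rr))) / den0
      rf1 <- abs(sum(vals1 * c(1, x, y, rr))) / den1
      rf2 <- abs(sum(vals2 * c(1, x, y, rr))) / den2
      if (max(rf, rf1, rf2) > 1e-6) next
      # require >= 3 numerically coincident eigenvalues of the assembled matrix
      lam <- t0k * s
      ev <- eigen(assemble_matrix(cf$system, x, y), only.values = TRUE)$values
      d <- sort(abs(ev - lam))
      if (length(d) < 3L || d[3] > tol^(1/3) * (1 + abs(lam))) next
      pts[[length(pts) + 1L]] <- data.frame(lambda = lam, rho1 = x, rho2 = y,
                                            res_f = rf, res_f1 = rf1, res_f2 = rf2)
    }
  }
  if (length(pts) == 0L)
    return(data.frame(lambda = numeric(0), rho1 = numeric(0), rho2 = numeric(0),
                      res_f = numeric(0), res_f1 = numeric(0), res_f2 = numeric(0)))
  out <- do.call(rbind, pts)
  # dedupe coincident points by tolerance clustering
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))[-1L]) {
    prev <- which(keep[seq_len(i - 1L)])
    same <- abs(out$lambda[prev] - out$lambda[i]) < 1e-5 * (1 + abs(out$lambda[i])) &
      abs(out$rho1[prev] - out$rho1[i]) < 1e-5 * (1 + abs(out$rho1[i])) &
      abs(out$rho2[prev] - out$rho2[i]) < 1e-5 * (1 + abs(out$rho2[i]))
    if (any(same)) keep[i] <- FALSE
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
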