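# Oculomotor-integrator models: the discrete N+2 network (vestibular chain
# plus two Purkinje cells) and its continuum limit (vestibular line with
# two discrete Purkinje cells).

#' Chain coupling strength for a prescribed subnetwork time constant
#'
#' The vestibular chain matrix T (tridiagonal, diagonal \eqn{-1+\beta},
#' off-diagonal \eqn{\beta}) has largest eigenvalue
#' \eqn{-1+\beta(1+2\cos(\pi/(N+1)))}.  This solves for the \eqn{\beta}
#' making \eqn{\alpha\,\lambda_{max}(T)} equal the requested decay rate.
#'
#' @param N number of vestibular cells.
#' @param alpha membrane rate constant in s^-1.
#' @param subnet_rate dominant decay rate of the unperturbed subnetwork in
#'   s^-1 (negative; default -5, a 0.2 s time constant).
#' @return \eqn{\beta} in (0, 1).
#' @export
beta_for_time_constant <- function(N, alpha = 200, subnet_rate = -5) {
  if (abs(subnet_rate / alpha) >= 1)
    stop("|subnet_rate/alpha| must be below 1")
  beta <- (subnet_rate / alpha + 1) / (1 + 2 * cos(pi / (N + 1)))
  if (beta <= 0 || beta >= 1)
    stop(sprintf("resulting beta = %g is outside (0, 1)", beta))
  beta
}

# the two wiring patterns of the N = 6 example
integrator_wirings <- function(wiring) {
  switch(wiring,
         normal = list(w1 = c(-1, 1, -1, 0, -1, 0),
                       w2 = c(1, -1, 1, 1, 0, 0)),
         nystagmus = list(w1 = c(-1, 1, 0, 0, -1, 0),
                          w2 = c(1, -1, 0, 0, 1, 0)),
         stop("wiring must be 'normal' or 'nystagmus'"))
}

#' Build the discrete oculomotor integrator
#'
#' Assembles the (N+2)-dimensional low-rank system: base matrix
#' \eqn{\alpha\,[[T, 0, 0], [w_1^T, -1, 0], [w_2^T, 0, -1]]} with the
#' sparse Purkinje-to-vestibular feedback as the two rank-one
#' perturbations, \eqn{f_i = -\alpha\, e_{k_i}} (the minus sign of the
#' inhibitory connection folded into f) and \eqn{g_i = e_{N+i}}.  At
#' \eqn{\rho_1=\rho_2=0} the spectrum is \eqn{\alpha\cdot spec(T)} together
#' with \eqn{\{-\alpha, -\alpha\}}.
#'
#' @param N vestibular cells (the shipped wirings require N = 6).
#' @param alpha rate constant in s^-1.
#' @param subnet_rate unperturbed dominant rate in s^-1.
#' @param wiring \code{"normal"} or \code{"nystagmus"} (two preset
#'   vestibular-to-Purkinje patterns differing only in w1, w2), ignored
#'   when both \code{w1} and \code{w2} are supplied.
#' @param w1,w2 optional explicit vestibular-to-Purkinje weight vectors of
#'   length N.
#' @param k1,k2 indices of the vestibular cells receiving Purkinje
#'   feedback.
#' @return a \code{\link{lowrank_system}} carrying the alpha factor in the
#'   matrix and vectors (all rates in s^-1).
#' @export
build_discrete_integrator <- function(N = 6, alpha = 200, subnet_rate = -5,
                                      wiring = "normal", w1 = NULL, w2 = NULL,
                                      k1 = 1L, k2 = 3L) {
  if (is.null(w1) || is.null(w2)) {
    if (N != 6L)
      stop("preset wirings are defined for N = 6; supply w1 and w2 explicitly")
    w <- integrator_wirings(wiring)
    w1 <- w$w1; w2 <- w$w2
  }
  if (length(w1) != N || length(w2) != N) stop("w1, w2 must have length N")
  if (k1 < 1 || k1 > N || k2 < 1 || k2 > N || k1 == k2)
    stop("k1, k2 must be distinct indices in 1..N")
  beta <- beta_for_time_constant(N, alpha, subnet_rate)
  tmat <- diag(rep(-1 + beta, N))
  for (i in seq_len(N - 1L)) tmat[i, i + 1L] <- tmat[i + 1L, i] <- beta
  base <- matrix(0, N + 2L, N + 2L)
  base[1:N, 1:N] <- tmat
  base[N + 1L, 1:N] <- w1
  base[N + 2L, 1:N] <- w2
  base[N + 1L, N + 1L] <- -1
  base[N + 2L, N + 2L] <- -1
  base <- alpha * base
  unit <- function(i) { v <- numeric(N + 2L); v[i] <- 1; v }
  lowrank_system(base,
                 list(list(f = -alpha * unit(k1), g = unit(N + 1L)),
                      list(f = -alpha * unit(k2), g = unit(N + 2L))),
                 scale = alpha,
                 label = sprintf("discrete integrator (%s)",
                                 if (is.null(wiring)) "custom" else wiring))
}

#' rho1 holding a fixed eigenvalue, as a function of rho2
#'
#' Pointwise form of \code{\link{constant_eigenvalue_curve}}:
#' \eqn{\rho_1 = -(D + \rho_2 P_2)/(P_1 + \rho_2 Q)} at
#' \eqn{\lambda_*}.  Vectorized over \code{rho2}.
#'
#' @param cf a \code{\link{char_function}}.
#' @param lambda_star the eigenvalue to hold.
#' @param rho2 numeric vector.
#' @return numeric vector of \eqn{\rho_1} values (NaN at poles).
#' @export
constant_eigenvalue_rho1 <- function(cf, lambda_star, rho2) {
  t0 <- lambda_star / cf$lambda_scale
  d0 <- poly_eval(cf$D, t0);  p1 <- poly_eval(cf$P1, t0)
  p2 <- poly_eval(cf$P2, t0); q0 <- poly_eval(cf$Q, t0)
  -(d0 + rho2 * p2) / (p1 + rho2 * q0)
}

#' Gain of the dominant mode
#'
#' Computes \eqn{\gamma = \langle b,e_1\rangle\langle f_1,b\rangle /
#' (\langle f_1,e_1\rangle\,\|b\|^2)} where \eqn{e_1, f_1} are the unit
#' right and left eigenvectors of the eigenvalue with largest real part.
#' Large \eqn{|\gamma|} signals near-orthogonal left/right eigenvectors,
#' i.e. proximity to a degenerate double eigenvalue; for a normal matrix
#' \eqn{|\gamma| \le 1}.
#'
#' @param system a \code{\link{lowrank_system}}.
#' @param rho1,rho2 perturbation strengths.
#' @param b input/readout pattern.
#' @param overlap_threshold below this \eqn{|\langle f_1,e_1\rangle|} the
#'   dominant eigenvalue is flagged near-degenerate (gain still reported,
#'   with a warning).
#' @return list with \code{gamma}, \code{lambda_dominant}, \code{overlap}
#'   (\eqn{\langle f_1,e_1\rangle}), \code{separation}
#'   (\eqn{Re\lambda_2/Re\lambda_1}), \code{near_degenerate}.
#' @export
dominant_gain <- function(system, rho1, rho2, b,
                          overlap_threshold = 1e-8) {
  mt <- assemble_matrix(system, rho1, rho2)
  if (length(b) != nrow(mt)) stop("b has the wrong length")
  er <- eigen(mt)
  idx <- which.max(Re(er$values))
  lam <- er$values[idx]
  e1 <- er$vectors[, idx]
  el <- eigen(t(mt))
  jdx <- which.min(abs(el$values - lam))
  f1 <- el$vectors[, jdx]
  e1 <- e1 / sqrt(sum(Mod(e1)^2))
  f1 <- f1 / sqrt(sum(Mod(f1)^2))
  drop_im <- function(z) if (max(abs(Im(z))) < 1e-9 * max(abs(Re(z)), 1))
    Re(z) else z
  overlap <- drop_im(sum(Conj(f1) * e1))
  gamma <- drop_im(sum(Conj(b) * e1) * sum(Conj(f1) * b) /
                     (sum(Conj(f1) * e1) * sum(abs(b)^2)))
  near_deg <- Mod(overlap) < overlap_threshold
  if (near_deg)
    warning("dominant eigenvalue is near-degenerate; gain is ill-conditioned")
  re_sorted <- sort(Re(er$values), decreasing = TRUE)
  lam2 <- re_sorted[match(FALSE, abs(re_sorted - Re(lam)) < 1e-12 * (1 + abs(lam)))]
  if (is.na(lam2)) lam2 <- re_sorted[2]
  list(gamma = gamma, lambda_dominant = drop_im(lam), overlap = overlap,
       separation = lam2 / Re(lam), near_degenerate = near_deg)
}

#' Impulse response of the network
#'
#' Solves \eqn{dv/dt = \tilde M v}, \eqn{v(0) = b} (the impulse-forced
#' problem in free-decay form) by eigen-decomposition propagation, which is
#' exact up to the eigensolve, and reports the readout
#' \eqn{\langle b, v(t)\rangle} with the measured gain
#' \eqn{\max_t \langle b,v(t)\rangle / \|b\|^2}.  The maximum is located on
#' the supplied grid and polished by golden-section search.
#'
#' @param system a \code{\link{lowrank_system}}.
#' @param rho1,rho2 perturbation strengths.
#' @param b initial condition / readout vector.
#' @param t_max end of the time window; defaults to five dominant time
#'   constants.
#' @param n_t number of grid points.
#' @return list with \code{t}, \code{readout}, \code{measured_gain},
#'   \code{t_peak}, \code{diverged} (TRUE when the system is unstable).
#' @export
impulse_response <- function(system, rho1, rho2, b, t_max = NULL, n_t = 600L) {
  mt <- assemble_matrix(system, rho1, rho2)
  if (length(b) != nrow(mt)) stop("b has the wrong length")
  er <- eigen(mt)
  coef <- solve(er$vectors, as.complex(b))
  lam <- er$values
  max_re <- max(Re(lam))
  diverged <- max_re > 1e-12 * norm(mt, "2")
  if (is.null(t_max)) {
    rate <- abs(max_re)
    t_max <- if (rate > 0) 5 / rate else 5 / max(abs(Re(lam[Re(lam) < 0])), 1)
  }
  readout_at <- function(t)
    vapply(t, function(ti)
      Re(sum(Conj(as.complex(b)) * (er$vectors %*% (coef * exp(lam * ti))))), 0)
  tg <- seq(0, t_max, length.out = n_t)
  rd <- readout_at(tg)
  i0 <- which.max(rd)
  lo <- tg[max(i0 - 1L, 1L)]; hi <- tg[min(i0 + 1L, n_t)]
  opt <- stats::optimize(function(t) -readout_at(t), c(lo, hi))
  peak <- max(rd[i0], -opt$objective)
  t_peak <- if (-opt$objective >= rd[i0]) opt$minimum else tg[i0]
  list(t = tg, readout = rd, measured_gain = peak / sum(b^2),
       t_peak = t_peak, diverged = diverged)
}

#' rho2 where the subdominant complex pair meets the real axis
#'
#' Sweeps \code{rho2} along the constant-eigenvalue curve of
#' \code{lambda_star} (with \code{rho1} set by
#' \code{\link{constant_eigenvalue_rho1}}), tracks the imaginary part of
#' the subdominant eigenvalue pair (ranks 2-3 by real part), and locates
#' its vanishing by bisection.
#'
#' @param system a \code{\link{lowrank_system}}.
#' @param cf its \code{\link{char_function}}.
#' @param lambda_star the held eigenvalue.
#' @param interval search interval for \code{rho2}.
#' @param tol bisection tolerance on \code{rho2}.
#' @return the collision value of \code{rho2} (error if the imaginary part
#'   does not change sign over the interval).
#' @export
subdominant_collision <- function(system, cf, lambda_star,
                                  interval = c(0.9, 1.1), tol = 1e-8) {
  imag_sub <- function(rho2) {
    r1 <- constant_eigenvalue_rho1(cf, lambda_star, rho2)
    ev <- system_spectrum(system, r1, rho2)
    max(abs(Im(ev[2:3])))
  }
  eps <- 1e-9
  f <- function(rho2) imag_sub(rho2) - eps
  lo <- interval[1]; hi <- interval[2]
  if (f(lo) * f(hi) > 0)
    stop("subdominant pair does not collide within the interval")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# ---------------------------------------------------------------------------
# continuum model

#' Parameters of the continuum integrator
#'
#' The vestibular chain becomes a line \eqn{\psi(x)} on [0, L] with
#' Dirichlet ends; the two Purkinje cells couple through
#' \eqn{\delta(x - x_i)} (feedback, strength \eqn{\rho_i}; see
#' \code{\link{continuum_resolvent_entries}} for the sign convention) and
#' density \eqn{\phi_i} (projection).  Eigenvalues are
#' parametrized by \eqn{\omega}: exponential branch
#' \eqn{\lambda = -1+3\beta+\beta\Delta x^2\omega^2}, trigonometric branch
#' \eqn{\lambda = -1+3\beta-\beta\Delta x^2\omega^2} (dimensionless block;
#' multiply by alpha for s^-1).
#'
#' @param N sets \eqn{\Delta x = L/N} and the default \eqn{\beta}.
#' @param L domain length.
#' @param x1,x2 Purkinje innervation points, \eqn{0 < x_1 < x_2 < L}.
#' @param beta chain coupling; default from
#'   \code{\link{beta_for_time_constant}} with \code{alpha},
#'   \code{subnet_rate}.
#' @param alpha,subnet_rate passed to the \eqn{\beta} default.
#' @param branch \code{"exp"} or \code{"trig"}.
#' @return list of class \code{"continuum_params"}.
#' @export
continuum_params <- function(N = 12, L = 1, x1 = 1/3, x2 = 1/2, beta = NULL,
                             alpha = 200, subnet_rate = -5, branch = "exp") {
  if (!(0 < x1 && x1 < x2 && x2 < L)) stop("need 0 < x1 < x2 < L")
  if (is.null(beta)) beta <- beta_for_time_constant(N, alpha, subnet_rate)
  branch <- match.arg(branch, c("exp", "trig"))
  structure(list(N = N, L = L, x1 = x1, x2 = x2, beta = beta,
                 dx = L / N, branch = branch), class = "continuum_params")
}

#' Eigenvalue on the chosen continuum branch
#'
#' Returns the (dimensionless block-unit) eigenvalue associated with the
#' spatial frequency \code{omega} on the branch selected in \code{params}.
#'
#' @param params a \code{continuum_params} object.
#' @param omega spatial frequency (vectorised).
#' @return numeric vector of eigenvalues.
#' @export
continuum_lambda <- function(params, omega) {
  s <- if (params$branch == "exp") 1 else -1
  -1 + 3 * params$beta + s * params$beta * params$dx^2 * omega^2
}

#' Characteristic-function entries of the continuum model
#'
#' For unit projection densities \eqn{\phi_1=\phi_2=1} the resolvent
#' entries are \eqn{P_i(\omega) = \langle\phi_i, G(\cdot, x_i;\omega)
#' \rangle / (\Delta x(\lambda+1))} with G the Dirichlet Green's function
#' of \eqn{\beta\Delta x^2\partial_{xx} + 3\beta - (1+\lambda)}, which on
#' the exponential branch evaluates to
#' \deqn{P_i(\omega) = -\frac{1 - (\sinh\omega x_i + \sinh\omega(L-x_i))/
#'   \sinh\omega L}{\beta^2\Delta x^3\,\omega^2\,(3+\Delta x^2\omega^2)}
#'   \;(< 0)}
#' and the trigonometric analogue with \eqn{\sin}, \eqn{3-\Delta
#' x^2\omega^2} and opposite overall sign.  D = 1 and Q = 0 (the two
#' projections are identical, hence linearly dependent).  In this
#' convention \eqn{\rho_i > 0} corresponds to the coupling sign the paper
#' plots (its figures follow the characteristic function
#' \eqn{1+\rho_1P_1+\rho_2P_2} with these P's); the physically signed
#' feedback of the integro-differential model carries the opposite
#' \eqn{\rho} sign, and \code{\link{continuum_fd_matrix}} is assembled so
#' that it accepts \eqn{\rho}'s in this same convention.  Accepts complex
#' \eqn{\omega} (used for complex-step derivatives).
#'
#' @param params a \code{\link{continuum_params}} (unit densities).
#' @param omega frequency (vector, real or complex, nonzero).
#' @return list with \code{P1}, \code{P2}, \code{lambda}, \code{D = 1},
#'   \code{Q = 0}.
#' @export
continuum_resolvent_entries <- function(params, omega) {
  b <- params$beta; dx <- params$dx; L <- params$L
  pfun <- function(x) {
    if (params$branch == "exp")
      -(1 - (sinh(omega * x) + sinh(omega * (L - x))) / sinh(omega * L)) /
        (b^2 * dx^3 * omega^2 * (3 + dx^2 * omega^2))
    else
      (1 - (sin(omega * x) + sin(omega * (L - x))) / sin(omega * L)) /
        (b^2 * dx^3 * omega^2 * (3 - dx^2 * omega^2))
  }
  list(P1 = pfun(params$x1), P2 = pfun(params$x2),
       lambda = continuum_lambda(params, omega), D = 1, Q = 0)
}

# complex-step derivative d/domega of the P entries (machine precision)
continuum_P_deriv <- function(params, omega, h = 1e-100) {
  ent <- continuum_resolvent_entries(params, omega + h * 1i)
  list(dP1 = Im(ent$P1) / h, dP2 = Im(ent$P2) / h)
}

#' Unperturbed continuum modes
#'
#' At \eqn{\rho_1=\rho_2=0} the vestibular line decouples:
#' \eqn{\psi_n = \sin(n\pi x/L)},
#' \eqn{\lambda_n = -1+3\beta-\beta(n\pi/N)^2}, plus \eqn{\lambda=-1} with
#' multiplicity two (the Purkinje cells).  The Purkinje responses follow
#' from the P-equation: \eqn{P_n = N(1-\cos n\pi)/(n\pi\,\beta(3-(n\pi/N)^2))}
#' for unit densities — zero for every even mode, which therefore never
#' feels the perturbation.
#'
#' @param params a \code{\link{continuum_params}}.
#' @param n_modes number of sine modes.
#' @return list with data.frame \code{modes} (n, lambda, P) and
#'   \code{purkinje_lambda = -1} (multiplicity 2).
#' @export
continuum_modes <- function(params, n_modes = 10L) {
  n <- seq_len(n_modes)
  b <- params$beta
  lam <- -1 + 3 * b - b * (n * pi / params$N)^2
  pn <- params$N * (1 - cos(n * pi)) / (n * pi * b * (3 - (n * pi / params$N)^2))
  list(modes = data.frame(n = n, lambda = lam, P = pn),
       purkinje_lambda = -1, purkinje_multiplicity = 2L)
}

#' Bifurcation (envelope) curve of the continuum model
#'
#' With D = 1 and Q = 0 the envelope conditions \eqn{1+\rho_1P_1+\rho_2P_2
#' = 0}, \eqn{\rho_1P_1'+\rho_2P_2' = 0} solve to
#' \eqn{\rho_1 = -P_2'/(P_1\wedge P_2)},
#' \eqn{\rho_2 = P_1'/(P_1\wedge P_2)} with all derivatives in
#' \eqn{\omega} (the branch map makes \eqn{\lambda}- and
#' \eqn{\omega}-parametrizations identical, wedge ratios being
#' scale-invariant).  Derivatives are complex-step, i.e. exact to machine
#' precision.
#'
#' @param params a \code{\link{continuum_params}}.
#' @param omega_grid positive frequencies (trig branch: away from Green's
#'   poles, which are masked).
#' @param tol wedge-degeneracy mask tolerance.
#' @return a \code{\link{parametric_curve}} of kind \code{"envelope"},
#'   branch \code{"linear"}, parametrized by \eqn{\omega}.
#' @export
continuum_bifurcation_curve <- function(params, omega_grid, tol = 1e-10) {
  if (any(omega_grid <= 0)) stop("omega must be positive")
  ent <- continuum_resolvent_entries(params, omega_grid)
  der <- continuum_P_deriv(params, omega_grid)
  wedge <- ent$P1 * der$dP2 - der$dP1 * ent$P2
  scale <- abs(ent$P1 * der$dP2) + abs(der$dP1 * ent$P2) + 1e-300
  ok <- is.finite(wedge) & abs(wedge) > tol * scale
  rho1 <- ifelse(ok, -der$dP2 / wedge, NA_real_)
  rho2 <- ifelse(ok,  der$dP1 / wedge, NA_real_)
  res <- abs(1 + rho1 * ent$P1 + rho2 * ent$P2) /
    (1 + abs(rho1 * ent$P1) + abs(rho2 * ent$P2))
  parametric_curve("envelope", "omega", omega_grid, rho1, rho2,
                   branch = "linear", valid = ok & res <= 1e-8,
                   residual = res, tol = tol)
}

#' Small-omega endpoint of the exponential-branch curve
#'
#' Extrapolates \eqn{(\rho_1(\omega), \rho_2(\omega))} to
#' \eqn{\omega \to 0^+} by Richardson extrapolation in \eqn{\omega^2}.
#'
#' @param params a \code{\link{continuum_params}} (exponential branch).
#' @return named vector \code{c(rho1, rho2)}.
#' @export
continuum_curve_endpoint <- function(params) {
  om <- c(0.04, 0.02, 0.01)
  cv <- continuum_bifurcation_curve(params, om)
  extrap <- function(v) {
    # two Richardson steps for an expansion in omega^2 (ratio 2 grid)
    v1 <- (4 * v[-1] - v[-length(v)]) / 3
    (16 * v1[-1] - v1[-length(v1)]) / 15
  }
  c(rho1 = extrap(cv$rho1), rho2 = extrap(cv$rho2))
}

#' Lemma 4.1 profile: the omega-derivative of the resolvent entry
#'
#' \eqn{F_\omega(x) = \partial f/\partial\omega} for the exponential-branch
#' entry profile \eqn{f(\omega, x)}, where \eqn{P_1 = f(\omega, x_1)} and
#' \eqn{P_2 = f(\omega, x_2)} in the convention of
#' \code{\link{continuum_resolvent_entries}}.  Computed two
#' independent ways — analytic differentiation of the closed form and a
#' complex-step numerical derivative — plus the second x-derivative by
#' central differences.  The lemma's structure: \eqn{F_\omega(0) =
#' F_\omega(1) = 0}, \eqn{F_\omega > 0} and \eqn{\partial_x^2 F_\omega < 0}
#' on the interior, which forces \eqn{\rho_1\rho_2 < 0} along the curve.
#'
#' @param params a \code{\link{continuum_params}} with L = 1, exponential
#'   branch.
#' @param omega positive frequency (scalar).
#' @param x_grid points in [0, 1].
#' @return data.frame with \code{x}, \code{F} (analytic), \code{F_numeric}
#'   (complex-step), \code{d2F_dx2}.
#' @export
lemma41_profile <- function(params, omega, x_grid) {
  if (params$branch != "exp" || params$L != 1)
    stop("lemma41_profile requires the exponential branch with L = 1")
  b <- params$beta; dx <- params$dx
  f_of <- function(om, x) {
    # paper orientation f = -P
    -(1 - (sinh(om * x) + sinh(om * (1 - x))) / sinh(om)) /
      (b^2 * dx^3 * om^2 * (3 + dx^2 * om^2))
  }
  # analytic d/domega of f = -Nfun/(b^2 dx^3 g), g = om^2 (3 + dx^2 om^2)
  F_analytic <- function(om, x) {
    sh <- sinh(om)
    nfun <- 1 - (sinh(om * x) + sinh(om * (1 - x))) / sh
    nprime <- -(x * cosh(om * x) + (1 - x) * cosh(om * (1 - x))) / sh +
      (sinh(om * x) + sinh(om * (1 - x))) * cosh(om) / sh^2
    g <- om^2 * (3 + dx^2 * om^2)
    gprime <- 2 * om * (3 + 2 * dx^2 * om^2)
    -(nprime * g - nfun * gprime) / (b^2 * dx^3 * g^2)
  }
  Fa <- F_analytic(omega, x_grid)
  h <- 1e-100
  Fn <- Im(f_of(omega + h * 1i, x_grid)) / h
  hx <- 1e-4
  d2 <- (F_analytic(omega, pmin(x_grid + hx, 1)) -
           2 * Fa + F_analytic(omega, pmax(x_grid - hx, 0)))
  # one-sided stencils collapse at the boundary; mark them NA
  interior <- x_grid - hx >= 0 & x_grid + hx <= 1
  d2 <- ifelse(interior, d2 / hx^2, NA_real_)
  data.frame(x = x_grid, F = Fa, F_numeric = Fn, d2F_dx2 = d2)
}

#' Finite-difference discretization of the continuum eigenproblem
#'
#' Direct second-order discretization of the coupled system (line plus two
#' Purkinje responses) used as an independent oracle for continuum
#' eigenvalue claims: an (n-1+2) x (n-1+2) matrix whose spectrum
#' approaches the continuum spectrum at O(h^2).
#'
#' @param params a \code{\link{continuum_params}} (unit densities).
#' @param rho1,rho2 perturbation strengths.
#' @param n_grid number of subintervals.
#' @return the dense matrix (dimensionless block units).
#' @export
continuum_fd_matrix <- function(params, rho1 = 0, rho2 = 0, n_grid = 2000L) {
  b <- params$beta; dx <- params$dx; L <- params$L
  h <- L / n_grid
  xs <- seq(h, L - h, length.out = n_grid - 1L)
  m <- n_grid - 1L
  lap <- diag(-2, m)
  for (i in seq_len(m - 1L)) lap[i, i + 1L] <- lap[i + 1L, i] <- 1
  a11 <- b * dx^2 * lap / h^2 + diag(-1 + 3 * b, m)
  # delta(x - xi) sampled on the grid: weight 1/h at the nearest node
  di <- function(x0) { v <- numeric(m); i <- which.min(abs(xs - x0)); v[i] <- 1 / h; v }
  # psi equation coupling +rho_i P_i delta(x - x_i): the rho's are taken in
  # the convention of continuum_resolvent_entries (the integro-differential
  # model's physically signed feedback is the negative of these rho's)
  mt <- matrix(0, m + 2L, m + 2L)
  mt[1:m, 1:m] <- a11
  mt[1:m, m + 1L] <- rho1 * di(params$x1)
  mt[1:m, m + 2L] <- rho2 * di(params$x2)
  mt[m + 1L, 1:m] <- h / dx
  mt[m + 2L, 1:m] <- h / dx
  mt[m + 1L, m + 1L] <- -1
  mt[m + 2L, m + 2L] <- -1
  mt
}
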