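# Front stability: elliptic spectrum, restricted block, Herglotz scan,
# index theorem, quadrature family.

lame_pot <- function(k) function(x) (1 + k^2) - 6 * k^2 * pracma::ellipj(x, k^2)$sn^2

test_that("exact Lame eigenpairs have tiny residuals and pinned values", {
  for (k in c(0.3, 0.5, 0.9)) {
    sp <- lame_spectrum(k)
    expect_identical(sp$eigenpairs[[2]]$lambda, 0)
    expect_identical(sp$eigenpairs[[4]]$lambda, -3)
    expect_equal(sp$eigenpairs[[3]]$lambda, -3 * k^2)
    expect_lt(max(lame_residual(sp)), 1e-8)
  }
  # k -> 0 limit: Neumann ground state of d^2/dx^2 + 1
  spk <- lame_spectrum(1e-6)
  expect_equal(spk$eigenpairs[[1]]$lambda, 1, tolerance = 1e-9)
  phi <- spk$eigenpairs[[1]]$phi(seq(-1, 1, length.out = 11))
  expect_lt(diff(range(phi)) / max(abs(phi)), 1e-9)
})

test_that("restricted 2x2 block: det 0, trace lambda1, Galerkin agreement", {
  for (k in c(0.25, 0.6, 0.85)) {
    A <- restricted_matrix(k)
    expect_lt(abs(det(A)) / max(abs(A))^2, 1e-12)
    expect_equal(sum(diag(A)), lambda1(k), tolerance = 1e-12)
    expect_equal(sort(eigen(A, only.values = TRUE)$values),
                 sort(c(0, lambda1(k))), tolerance = 1e-10)
  }
  # Galerkin projection oracle at k = 0.6: apply the operator to the basis
  # exactly and fit the coefficients in {1, sn^2}
  k <- 0.6
  fr <- elliptic_front(k)
  x <- seq(-fr$K, fr$K, length.out = 8001)
  sj <- pracma::ellipj(x, k^2)
  sn2 <- sj$sn^2
  pot <- (1 + k^2) - 6 * k^2 * sn2
  h <- x[2] - x[1]
  trap <- function(v) (sum(v) - (v[1] + v[length(v)]) / 2) * h
  d2sn2 <- perturbspec:::ep_eval(
    perturbspec:::ep_deriv(perturbspec:::ep_deriv(
      perturbspec:::ep_terms(1, 2L, 0L, 0L), k), k), k, x)
  Hb1 <- pot - trap(pot) / (2 * fr$K)
  Hb2 <- d2sn2 + pot * sn2 - trap(pot * sn2) / (2 * fr$K)
  fit <- function(v) qr.solve(cbind(1, sn2), v)
  expect_lt(max(abs(cbind(fit(Hb1), fit(Hb2)) - restricted_matrix(k))), 1e-8)
})

test_that("lambda1 is negative on a k-grid and -3 at k = 0", {
  expect_equal(lambda1(0), -3)
  kg <- seq(0.01, 0.99, length.out = 99)
  expect_true(all(lambda1(kg) < 0))
  expect_error(lambda1(1))
})

test_that("discretization recovers known spectra at O(h^2)", {
  op <- discretize_operator(function(x) 0 * x, c(0, pi), "dirichlet", 600)
  expect_equal(operator_eigenvalues(op, 2), c(-1, -4), tolerance = 1e-4)
  k <- 0.6
  fr <- elliptic_front(k)
  opd <- discretize_operator(lame_pot(k), c(-fr$K, fr$K), "dirichlet", 4000)
  evd <- operator_eigenvalues(opd, 2)
  expect_equal(evd[1], 0, tolerance = 1e-3)
  expect_equal(evd[2], -3, tolerance = 1e-3)
  opd2 <- discretize_operator(lame_pot(k), c(-fr$K, fr$K), "dirichlet", 8000)
  err1 <- abs(operator_eigenvalues(opd2, 2)[2] + 3)
  expect_gt(abs(evd[2] + 3) / err1, 3)  # O(h^2) Richardson factor ~ 4
  # k-independence of the -3 Dirichlet eigenvalue
  fr3 <- elliptic_front(0.3)
  opd3 <- discretize_operator(lame_pot(0.3), c(-fr3$K, fr3$K), "dirichlet", 4000)
  expect_equal(operator_eigenvalues(opd3, 2)[2], -3, tolerance = 1e-3)
})

test_that("eigenvalues stay real for rho in [0, 1] and vanish only at rho = 1", {
  k <- 0.7
  fr <- elliptic_front(k)
  op <- discretize_operator(lame_pot(k), c(-fr$K, fr$K), "neumann", 700)
  grid <- seq(-5, 2, length.out = 401)
  for (rho in c(0.25, 0.5, 0.75, 1)) {
    hs <- herglotz_scan(op, fr$K, rho, grid)
    expect_identical(hs$nonreal_violations, 0L)
    has_zero_root <- length(hs$roots) > 0 && min(abs(hs$roots)) < 1e-4
    if (rho == 1) expect_true(has_zero_root) else expect_false(has_zero_root)
  }
  # Herglotz property in the upper half-plane
  hs <- herglotz_scan(op, fr$K, 0.5, grid)
  set.seed(3)
  z <- complex(real = stats::runif(20, -5, 2),
               imaginary = stats::runif(20, 0.1, 2))
  expect_true(all(Im(hs$herglotz(z)) > 0))
})

test_that("stability index: theorem equals direct count; cubic front stable", {
  k <- 0.8
  fr <- elliptic_front(k)
  op <- discretize_operator(lame_pot(k), c(-fr$K, fr$K), "neumann", 900)
  si <- stability_index(op, fr$K)
  expect_identical(si$n_plus_unperturbed, 1L)
  expect_gt(si$inner, 0)
  expect_identical(si$n_plus_perturbed, 0L)
  expect_identical(si$n_plus_direct, 0L)
  expect_identical(si$kernel_dim, 1L)
  # negative-definite toy: inner < 0 automatically, n+ stays 0
  opt <- discretize_operator(function(x) -1 + 0 * x, c(0, pi), "neumann", 500)
  sit <- stability_index(opt, pi / 2)
  expect_lt(sit$inner, 0)
  expect_identical(sit$n_plus_perturbed, 0L)
  # singular H routes to the Remark 5.2 error path: shift the toy potential
  # so an eigenvalue sits at zero (Neumann ground state of d^2/dx^2 is 0)
  op0 <- discretize_operator(function(x) 0 * x, c(0, pi), "neumann", 500)
  expect_error(stability_index(op0, pi / 2), class = "remark_5_2_case")
})

test_that("complementary block obeys the coercivity estimate", {
  k <- 0.6
  fr <- elliptic_front(k)
  sp <- lame_spectrum(k)
  op <- discretize_operator(lame_pot(k), c(-fr$K, fr$K), "neumann", 600)
  ht <- as.matrix(op) - (1 / (2 * fr$K)) * outer(rep(1, op$n), op$w * op$V)
  phi0 <- sp$eigenpairs[[1]]$phi(op$x); phi0 <- phi0 / sqrt(sum(phi0^2))
  phi2 <- sp$eigenpairs[[5]]$phi(op$x)
  phi2 <- phi2 - sum(phi2 * phi0) * phi0; phi2 <- phi2 / sqrt(sum(phi2^2))
  pj <- diag(op$n) - outer(phi0, phi0) - outer(phi2, phi2)
  evc <- sort(Re(eigen(pj %*% ht %*% pj, only.values = TRUE)$values),
              decreasing = TRUE)
  expect_lt(evc[3], -3 * k^2 + 1e-3)   # first two are the projected-out zeros
})

test_that("lambda1 equals the matching eigenvalue of the discretized operator", {
  for (k in c(0.4, 0.7)) {
    fr <- elliptic_front(k)
    op <- discretize_operator(lame_pot(k), c(-fr$K, fr$K), "neumann", 1500)
    ht <- as.matrix(op) - (1 / (2 * fr$K)) * outer(rep(1, op$n), op$w * op$V)
    ev <- Re(eigen(ht, only.values = TRUE)$values)
    expect_equal(min(abs(ev - lambda1(k))), 0, tolerance = 5e-3)
  }
})

test_that("quadrature family: level set, kappa P = R, Eq 5.20 within 1%", {
  k <- 0.6
  fr <- elliptic_front(k)
  fc <- function(u) (1 + k^2) * u - 2 * k^2 * u^3
  Fc <- function(u) (1 + k^2) * u^2 / 2 - k^2 * u^4 / 2
  qf <- quadrature_family(fc, fr$K, 0.5, 0, Fanti = Fc, n_steps = 12,
                          ds = 0.02, bracket = c(-3, 3))
  s <- qf$samples
  expect_lt(max(abs(s$P - 2 * fr$K)), 1e-8)
  expect_lt(max(abs(s$kappa * s$P - s$R)), 1e-8)
  i0 <- which.min(abs(s$s))
  expect_lt(abs(s$M[i0]), 1e-8)   # symmetric front: M = 0 by oddness
  inner_qf <- 2 * fr$K * s$dM_ds[i0] / s$dR_ds[i0]
  op <- discretize_operator(lame_pot(k), c(-fr$K, fr$K), "neumann", 2000)
  si <- stability_index(op, fr$K, direct = FALSE)
  expect_lt(abs(inner_qf - si$inner) / abs(si$inner), 0.01)
  expect_identical(sign(s$tau[i0]), sign(si$inner))
  expect_identical(sign(s$tau[i0]), sign(s$dR_ds[i0] / s$dM_ds[i0]))
})

test_that("non-odd nonlinearity: profile, index agreement, Eq 5.20", {
  fno <- function(u) u - u^3 + 0.1 * u^2
  fpno <- function(u) 1 - 3 * u^2 + 0.2 * u
  Fno <- function(u) u^2 / 2 - u^4 / 4 + 0.1 * u^3 / 3
  fp <- front_profile(fno, 0.2, 0.02, Fanti = Fno, bracket = c(-3, 3))
  op <- discretize_operator(function(x) fpno(fp$u_of_x(x)),
                            c(-fp$L, fp$L), "neumann", 800)
  si <- stability_index(op, fp$L)
  expect_identical(si$n_plus_perturbed, si$n_plus_direct)
  qf <- quadrature_family(fno, fp$L, 0.2, 0.02, Fanti = Fno, n_steps = 6,
                          ds = 0.01, bracket = c(-3, 3))
  s <- qf$samples
  expect_lt(max(abs(s$kappa * s$P - s$R)), 1e-8)
  i0 <- which.min(abs(s$s))
  inn <- 2 * fp$L * s$dM_ds[i0] / s$dR_ds[i0]
  expect_lt(abs(inn - si$inner) / abs(si$inner), 0.01)
})

test_that("front_profile reproduces the elliptic front", {
  k <- 0.6
  fr <- elliptic_front(k)
  fc <- function(u) (1 + k^2) * u - 2 * k^2 * u^3
  Fc <- function(u) (1 + k^2) * u^2 / 2 - k^2 * u^4 / 2
  fp <- front_profile(fc, 0.5, 0, Fanti = Fc, bracket = c(-3, 3))
  expect_equal(fp$L, fr$K, tolerance = 1e-7)
  xs <- seq(-0.99 * fr$K, 0.99 * fr$K, length.out = 30)
  expect_lt(max(abs(fp$u_of_x(xs) - pracma::ellipj(xs, k^2)$sn)), 1e-6)
})

test_that("half-width to modulus map inverts L = sqrt(1+k^2) K(k)", {
  k <- modulus_for_halfwidth(3)
  expect_equal(sqrt(1 + k^2) * pracma::ellipke(k^2)$k, 3, tolerance = 1e-10)
  expect_error(modulus_for_halfwidth(1))
})
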