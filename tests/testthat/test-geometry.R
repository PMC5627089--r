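# Curves in the (rho1, rho2) plane: constant-eigenvalue, envelope, Hopf,
# singular pieces, triple points.

e27 <- e27_system()
cf27 <- char_function(e27)

test_that("constant-eigenvalue curve members carry the pinned eigenvalue", {
  lam_star <- -2.6
  cv <- constant_eigenvalue_curve(cf27, lam_star, seq(-3, 1, length.out = 41))
  ok <- which(cv$valid)
  expect_gt(length(ok), 10)
  for (i in ok[seq(1, length(ok), by = 5)]) {
    ev <- system_spectrum(e27, cv$rho1[i], cv$rho2[i])
    expect_lt(min(Mod(ev - lam_star)), 1e-8)
  }
})

test_that("envelope samples carry a double eigenvalue (double-root residual)", {
  env <- envelope_curve(cf27, seq(-4.5, -0.5, length.out = 161))
  for (cv in env) {
    ok <- which(cv$valid)
    for (i in ok[seq(1, length(ok), by = 7)]) {
      ev <- system_spectrum(e27, cv$rho1[i], cv$rho2[i])
      d <- sort(Mod(ev - cv$parameter[i]))
      expect_lt(d[2], 1e-5)   # two eigenvalues coincide with the parameter
    }
  }
})

test_that("E27 envelope has the gap between -5/2 and -3/2", {
  lam <- seq(-2.45, -1.55, length.out = 31)
  env <- envelope_curve(cf27, lam)
  # the only admissible point inside the gap is the isolated degeneracy at
  # lambda = -2, where the unperturbed matrix already has a double
  # eigenvalue and the envelope collapses to the origin
  for (cv in env) {
    ok <- which(cv$valid)
    if (length(ok)) {
      expect_true(all(abs(cv$parameter[ok] + 2) < 1e-9))
      expect_true(all(abs(cv$rho1[ok]) < 1e-5 & abs(cv$rho2[ok]) < 1e-5))
    }
  }
  # just outside the gap both branches resume
  env2 <- envelope_curve(cf27, c(-2.7, -1.3))
  expect_true(any(env2$plus$valid) || any(env2$minus$valid))
})

test_that("envelope_point signals unreachable eigenvalues", {
  # diagonal base with off-diagonal rank-one pairs: P1, P2 and Q vanish
  # identically, so no non-spectral point can ever be a double eigenvalue
  sys <- lowrank_system(diag(c(-1, -2, -3)),
                        list(list(f = c(1, 0, 0), g = c(0, 1, 0)),
                             list(f = c(0, 1, 0), g = c(0, 0, 1))))
  cf <- char_function(sys)
  expect_error(envelope_point(cf, -0.5), class = "eigenvalue_unreachable")
  # Q == 0 wiring with independent P rows stays solvable: a unique
  # double-eigenvalue point on the degenerate (linear) envelope branch
  sysn <- build_discrete_integrator(wiring = "nystagmus")
  cfn <- char_function(sysn)
  ep <- envelope_point(cfn, -0.05)
  expect_identical(ep$branch, "linear")
  ev <- system_spectrum(sysn, ep$rho1, ep$rho2)
  expect_lt(sort(Mod(ev - (-0.05)))[2], 1e-3)
})

test_that("Hopf samples put an eigenvalue pair on the imaginary axis", {
  sys <- build_discrete_integrator(wiring = "nystagmus")
  cf <- char_function(sys)
  hc <- hopf_curve(cf, seq(0.5, 60, length.out = 120))
  found <- 0L
  for (cv in hc) {
    ok <- which(cv$valid)
    for (i in ok[seq_len(min(8, length(ok)))]) {
      ev <- system_spectrum(sys, cv$rho1[i], cv$rho2[i])
      expect_lt(min(Mod(ev - 1i * cv$parameter[i])), 1e-6 * (1 + cv$parameter[i]))
      found <- found + 1L
    }
  }
  expect_gt(found, 0L)
})

test_that("E27 singular lines sit at rho = -1/2 and carry double eigenvalues", {
  sp <- singular_pieces(cf27, rho_grid = seq(-4, 2, length.out = 121))
  expect_gte(length(sp), 2L)
  lam_tags <- vapply(sp, function(cv) cv$eigenvalue_tag, 0)
  expect_true(all(abs(lam_tags - (-2 + sqrt(2) / 2)) < 1e-8))
  # one horizontal line rho2 = -1/2 and one vertical line rho1 = -1/2
  const_r2 <- vapply(sp, function(cv)
    if (stats::sd(cv$rho2[cv$valid]) < 1e-10) cv$rho2[which(cv$valid)[1]] else NA_real_, 0)
  const_r1 <- vapply(sp, function(cv)
    if (stats::sd(cv$rho1[cv$valid]) < 1e-10) cv$rho1[which(cv$valid)[1]] else NA_real_, 0)
  expect_true(any(abs(const_r2 + 0.5) < 1e-8, na.rm = TRUE) ||
                any(abs(const_r1 + 0.5) < 1e-8, na.rm = TRUE))
  # arbitrary points on the pieces carry a double eigenvalue at the tag
  for (cv in sp) {
    i <- which(cv$valid)[5]
    ev <- system_spectrum(e27, cv$rho1[i], cv$rho2[i])
    expect_lt(sort(Mod(ev - cv$eigenvalue_tag))[2], 1e-6)
  }
})

test_that("E27 triple points are found and verified", {
  tp <- triple_points(cf27, lambda_range = c(-6, 1))
  expect_equal(nrow(tp), 2L)
  tp <- tp[order(tp$rho1), ]
  expect_equal(tp$rho1, c(-1.5, -0.5), tolerance = 1e-4)
  expect_equal(tp$rho2, c(-0.5, -1.5), tolerance = 1e-4)
  for (j in seq_len(nrow(tp))) {
    ev <- system_spectrum(e27, tp$rho1[j], tp$rho2[j])
    expect_lt(sort(Mod(ev - tp$lambda[j]))[3], 1e-3)
  }
})

test_that("triple-point cubic has its simple root near -2.35", {
  w3 <- poly_wronskian3(cf27$P1, cf27$D, cf27$Q)
  roots <- poly_real_roots(w3) * cf27$lambda_scale
  simple <- roots[vapply(roots, function(r) sum(abs(roots - r) < 1e-6) == 1L, TRUE)]
  expect_equal(simple, -2 - sqrt(2) / 4, tolerance = 1e-8)
})

test_that("rank-one system: envelope curve from D and P1 alone", {
  sys <- lowrank_system(diag(c(0, -1, -2)),
                        list(list(f = c(1, 1, 1) / sqrt(3), g = c(1, 1, 1) / sqrt(3))))
  cf <- char_function(sys)
  # rank-one: rho1(lambda) = -D/P1 pins lambda as an eigenvalue
  lam <- -0.5
  t0 <- lam / cf$lambda_scale
  r1 <- -poly_eval(cf$D, t0) / poly_eval(cf$P1, t0)
  ev <- system_spectrum(sys, r1, 0)
  expect_lt(min(Mod(ev - lam)), 1e-10)
})

test_that("Q == 0 envelope branch produces double eigenvalues", {
  v <- rep(1, 3) / sqrt(3)
  toy <- lowrank_system(diag(c(0, -1, -2)),
                        list(list(f = v, g = v), list(f = c(1, 0, 0), g = 2 * v)))
  cft <- char_function(toy)
  expect_true(perturbspec:::cf_q_is_zero(cft))
  env <- envelope_curve(cft, seq(-4, 2, length.out = 121))
  ok <- which(env$plus$valid)
  expect_gt(length(ok), 5)
  for (i in ok[seq(1, length(ok), by = 6)]) {
    ev <- system_spectrum(toy, env$plus$rho1[i], env$plus$rho2[i])
    expect_lt(sort(Mod(ev - env$plus$parameter[i]))[2], 1e-4)
  }
})
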