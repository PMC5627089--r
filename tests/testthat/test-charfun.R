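# Characteristic-function assembly D + rho1 P1 + rho2 P2 + rho1 rho2 Q

brute_det <- function(system, lambda, rho1, rho2) {
  vapply(lambda, function(l)
    det(assemble_matrix(system, rho1, rho2) - l * diag(system$n)), 0)
}

test_that("characteristic function matches brute-force determinants", {
  for (sys in list(e27_system(), fixture_generator(11, 5),
                   fixture_generator(12, 8))) {
    cf <- char_function(sys)
    lam <- seq(-4, 2, length.out = 13)
    for (rho in list(c(0, 0), c(0.7, -1.3), c(-2.1, 0.4))) {
      lhs <- eval_char(cf, lam, rho[1], rho[2])
      rhs <- brute_det(sys, lam, rho[1], rho[2])
      expect_lt(max(abs(lhs - rhs)) / max(abs(rhs), 1), 1e-9)
    }
  }
})

test_that("the three build methods agree", {
  sys <- fixture_generator(21, 6)
  cfs <- lapply(c("interpolation", "cofactor"), function(m)
    char_function(sys, method = m))
  sys_sa <- fixture_generator(22, 6, "selfadjoint_base")
  cfs_sa <- lapply(c("interpolation", "cofactor", "spectral"), function(m)
    char_function(sys_sa, method = m))
  lam <- seq(-5, 5, length.out = 21)
  ref <- eval_char(cfs[[1]], lam, 0.6, -0.8)
  expect_lt(max(abs(eval_char(cfs[[2]], lam, 0.6, -0.8) - ref)) /
              max(abs(ref)), 1e-8)
  ref_sa <- eval_char(cfs_sa[[1]], lam, 0.6, -0.8)
  for (cf in cfs_sa[-1])
    expect_lt(max(abs(eval_char(cf, lam, 0.6, -0.8) - ref_sa)) /
                max(abs(ref_sa)), 1e-7)
})

test_that("degrees follow the lemma: deg P_i <= n-1, deg Q <= n-2", {
  sys <- fixture_generator(31, 6)
  cf <- char_function(sys)
  expect_identical(length(cf$D), sys$n + 1L)
  expect_lte(length(cf$P1), sys$n)
  expect_lte(length(cf$P2), sys$n)
  expect_lte(length(cf$Q), sys$n - 1L)
})

test_that("dependent projection directions force Q to vanish", {
  cf <- char_function(fixture_generator(41, 6, "dependent_g"))
  expect_true(perturbspec:::cf_q_is_zero(cf))
  cf2 <- char_function(fixture_generator(42, 6, "generic"))
  expect_false(perturbspec:::cf_q_is_zero(cf2))
})

test_that("perturbed spectrum solves the assembled characteristic function", {
  sys <- fixture_generator(51, 7)
  cf <- char_function(sys)
  ev <- system_spectrum(sys, 0.9, -0.4)
  vals <- eval_char(cf, ev, 0.9, -0.4)
  expect_lt(max(Mod(vals)) / perturbspec:::cf_coef_scale(cf), 1e-7)
})
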