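# Region classification and the curve-crossing audit.

test_that("classify_point counts sum to N and detect the configurations", {
  sys <- e27_system()
  lab <- classify_point(sys, 0, 0)
  expect_identical(lab$n_real_lhp + lab$n_real_rhp +
                     lab$n_complex_lhp + lab$n_complex_rhp, 4L)
  expect_identical(lab$n_real_lhp, 4L)
  expect_identical(lab$dominant, "real_stable")
  # push the dominant eigenvalue across zero along the rank-one direction
  cf <- char_function(sys)
  t0 <- 0.5 / cf$lambda_scale
  r1 <- -poly_eval(cf$D, t0) / poly_eval(cf$P1, t0)
  lab2 <- classify_point(sys, r1, 0)
  expect_identical(lab2$n_real_rhp, 1L)
  expect_identical(lab2$dominant, "real_unstable")
})

test_that("complex pairs are counted in mirrored half-planes", {
  sys <- fixture_generator(61, 6)
  lab <- classify_point(sys, 2.5, -1.5)
  expect_identical(lab$n_complex_lhp %% 2L, 0L)
  expect_identical(lab$n_complex_rhp %% 2L, 0L)
})

test_that("phase diagram with crossing audit is clean on E27", {
  pd <- build_phase_diagram(e27_system(), c(-3, 1, -3, 1), nx = 25, ny = 25,
                            n_curve = 300)
  expect_gt(length(pd$curves), 2L)
  audit <- curve_crossing_audit(pd)
  expect_gt(audit$checked, 50L)
  expect_identical(nrow(audit$violations), 0L)
})

test_that("crossing audit is clean on a random fixture", {
  sys <- fixture_generator(71, 5)
  pd <- build_phase_diagram(sys, c(-2, 2, -2, 2), nx = 21, ny = 21,
                            n_curve = 250)
  audit <- curve_crossing_audit(pd)
  expect_identical(nrow(audit$violations), 0L)
})

test_that("real-eigenvalue count jumps by two across the envelope", {
  # Lemma 2.4 property: sample envelope points on E27 and compare counts on
  # the two sides along the normal direction
  sys <- e27_system()
  cf <- char_function(sys)
  env <- envelope_curve(cf, seq(-4.4, -2.6, length.out = 41))
  cv <- env$plus
  ok <- which(cv$valid)
  idx <- ok[ok > 1L & ok < length(cv$parameter)]
  idx <- idx[cv$valid[idx - 1L] & cv$valid[idx + 1L]][c(3, 10, 17)]
  idx <- idx[!is.na(idx)]
  expect_gt(length(idx), 0L)
  for (i in idx) {
    tang <- c(cv$rho1[i + 1L] - cv$rho1[i - 1L], cv$rho2[i + 1L] - cv$rho2[i - 1L])
    nrm <- c(-tang[2], tang[1]) / sqrt(sum(tang^2))
    h <- 1e-3
    n_real <- function(p) {
      lab <- classify_point(sys, p[1], p[2])
      lab$n_real_lhp + lab$n_real_rhp
    }
    a <- n_real(c(cv$rho1[i], cv$rho2[i]) + h * nrm)
    b <- n_real(c(cv$rho1[i], cv$rho2[i]) - h * nrm)
    expect_identical(abs(a - b), 2L)
  }
})
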