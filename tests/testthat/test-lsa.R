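test_that("characteristic-polynomial coefficients match known expansions", {
  cp <- char_poly_coeffs(diag(c(-1, -2, -3)), 0, 0)
  expect_equal(cp$coefficients, c(6, 11, 6))
  cp2 <- char_poly_coeffs(ai_jacobian(), c(1, 10), 1)
  expect_equal(cp2$coefficients, c(12, 3))
  expect_error(char_poly_coeffs(matrix(1, 2, 3)), "square")
})

test_that("coefficients agree with the polynomial-interpolation oracle", {
  set.seed(7)
  for (rep in 1:100) {
    n <- sample(2:5, 1)
    M <- random_jacobian(n)
    got <- char_poly_coeffs(M, 0, 0)$coefficients
    expect_equal(got, poly_coeffs_oracle(M), tolerance = 1e-8)
  }
})

test_that("Routh-Hurwitz matches direct eigenvalue stability", {
  expect_true(routh_hurwitz_stable(c(6, 11, 6)))
  expect_false(routh_hurwitz_stable(c(1, 1, 2)))
  # coefficients of a matrix whose eigenvalues all have negative real part
  gen <- rbind(c(-1, 0, 2), c(0, -1, 2), c(-1, -0.5, 0.25))
  expect_true(eigen_stable(gen))
  expect_true(routh_hurwitz_stable(char_poly_coeffs(gen, 0, 0)))
  expect_equal(char_poly_coeffs(gen, 0, 0)$coefficients,
               c(1.75, 3.5, 2.75), tolerance = 1e-12)
  expect_error(routh_hurwitz_stable(c(1, 2, 3, 4, 5, 6)), "unsupported")
  set.seed(13)
  for (n in 2:5) {
    for (rep in 1:200) {
      M <- random_jacobian(n)
      mre <- max(Re(eigen(M, only.values = TRUE)$values))
      if (abs(mre) < 1e-7) next # skip marginal cases
      expect_identical(routh_hurwitz_stable(char_poly_coeffs(M, 0, 0)),
                       mre < 0)
    }
  }
})

test_that("dispersion relation has the right structure and limits", {
  # pure decay: growth strictly decreasing in q^2, maximum at the origin
  d0 <- dispersion(diag(c(-1, -1)), c(1, 1))
  expect_true(all(diff(d0$max_re_lambda) < 0))
  expect_lt(d0$max_growth, 0)
  # the activator-inhibitor system crosses zero at a finite q^2
  d1 <- dispersion(ai_jacobian(), c(1, 10))
  expect_gt(d1$max_growth, 0)
  expect_true(is.finite(d1$q2_star))
  # at q^2 = 0 the dispersion equals the spectral abscissa of J
  set.seed(3)
  for (rep in 1:100) {
    M <- random_jacobian(3)
    d <- dispersion(M, c(1, 2, 0), q2_range = c(1e-9, 1e3))
    expect_equal(d$max_re_lambda[1],
                 max(Re(eigen(M, only.values = TRUE)$values)),
                 tolerance = 1e-5)
  }
  # q -> Inf limit is the spectral abscissa of the non-diffusible block
  gen <- rbind(c(-1, 0, 2), c(0, -1, 2), c(-1, -0.5, 0.25))
  d2 <- dispersion(gen, c(0.3, 0.7, 0))
  expect_equal(d2$limit_at_infinity, 0.25)
  expect_identical(d2$q_star, Inf)
  # all nodes diffusible: limit is -Inf
  expect_identical(dispersion(ai_jacobian(), c(1, 10))$limit_at_infinity,
                   -Inf)
})

test_that("dispersion scales linearly and shifts under equal diffusion", {
  set.seed(21)
  J <- random_jacobian(3)
  D <- c(0.5, 1.5, 0)
  s <- 3.7
  d1 <- dispersion(J, D)
  d2 <- dispersion(s * J, s * D)
  expect_equal(d2$max_re_lambda, s * d1$max_re_lambda, tolerance = 1e-8)
  # with D = d * identity, max Re lambda(q^2) = max Re eig(J) - d q^2
  dd <- 0.8
  d3 <- dispersion(J, rep(dd, 3))
  mre <- max(Re(eigen(J, only.values = TRUE)$values))
  expect_equal(d3$max_re_lambda, mre - dd * d3$q2_grid, tolerance = 1e-8)
})

test_that("diffusion-driven instability reproduces the 2-node threshold", {
  J <- ai_jacobian() # critical ratio 4 + 2 sqrt(3) ~ 7.464
  expect_true(is_turing_unstable(J, D = c(1, 10))$turing_unstable)
  expect_false(is_turing_unstable(J, D = c(1, 1))$turing_unstable)
  expect_false(is_turing_unstable(J, D = c(1, 7.2))$turing_unstable)
  expect_true(is_turing_unstable(J, D = c(1, 7.7))$turing_unstable)
  # diffusion-driven only: an unstable reaction part never counts
  expect_false(is_turing_unstable(rbind(c(1, 0), c(0, -1)),
                                  D = c(1, 10))$turing_unstable)
  expect_true(is_turing_unstable(rbind(c(1, 0), c(0, -1)),
                                 D = c(1, 10))$stable_at_q0 == FALSE)
})

test_that("the capacitor channel is captured by mode any and excluded by band", {
  gen <- rbind(c(-1, 0, 2), c(0, -1, 2), c(-1, -0.5, 0.25))
  rep_any <- is_turing_unstable(gen, D = c(0.3, 0.7, 0))
  expect_true(rep_any$turing_unstable)
  expect_identical(rep_any$q_star, Inf)
  rep_band <- is_turing_unstable(gen, D = c(0.3, 0.7, 0), mode = "band")
  expect_false(rep_band$turing_unstable)
  # the activator-inhibitor instability is a finite band: both modes agree
  expect_true(is_turing_unstable(ai_jacobian(), D = c(1, 10),
                                 mode = "band")$turing_unstable)
})

test_that("turing instability requires homogeneous stability", {
  set.seed(31)
  for (rep in 1:50) {
    J <- random_jacobian(3)
    rep_ <- is_turing_unstable(J, D = c(runif(1), runif(1), 0))
    if (rep_$turing_unstable) expect_true(rep_$stable_at_q0)
    if (!rep_$stable_at_q0) expect_false(rep_$turing_unstable)
  }
})
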