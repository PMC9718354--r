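test_that("Wald density matches closed-form special cases", {
  # at t = alpha/rho the exponent vanishes: f = 1/sqrt(2*pi)
  expect_equal(dwald(1, drift = 1, noise = 1, threshold = 1),
               1 / sqrt(2 * pi), tolerance = 1e-12)
  # zero before the non-decision shift
  expect_identical(dwald(0.1, drift = 2, shift = 0.2), 0)
  expect_identical(dwald(0.2, drift = 2, shift = 0.2), 0)
  # invalid specs rejected
  expect_error(dwald(1, drift = 1, noise = 0), "sigma")
  expect_error(pwald(1, drift = 1, threshold = -1), "alpha")
  expect_error(rwald(1, drift = 1, shift = -0.1), "t0")
})

test_that("Wald density is the time-derivative of the CDF", {
  h <- 1e-6
  specs <- list(c(0.5, 1, 1, 0.2), c(2, 0.7, 1.3, 0), c(-1, 1, 1, 0.1))
  for (s in specs) {
    t <- s[4] + 0.6
    num <- (pwald(t + h, s[1], s[2], s[3], s[4]) -
              pwald(t - h, s[1], s[2], s[3], s[4])) / (2 * h)
    expect_equal(dwald(t, s[1], s[2], s[3], s[4]), num,
                 tolerance = 1e-5)
  }
})

test_that("Wald CDF has the right limits and integrates the density", {
  expect_equal(pwald(1e6, drift = 1), 1, tolerance = 1e-9)
  expect_equal(pwald(1e6, drift = -1), exp(-2), tolerance = 1e-6)
  # no overflow for strong positive drift
  expect_true(is.finite(pwald(0.5, drift = 40, noise = 0.5)))
  # F(t) equals the integral of f over (t0, t]
  for (s in list(c(1, 1, 1, 0), c(-0.8, 1.2, 0.9, 0.3))) {
    t <- s[4] + 1.2
    q <- integrate(dwald, s[4], t, drift = s[1], noise = s[2],
                   threshold = s[3], shift = s[4],
                   rel.tol = 1e-10)$value
    expect_equal(pwald(t, s[1], s[2], s[3], s[4]), q, tolerance = 1e-6)
  }
})

test_that("Wald total mass is 1 for positive drift, exp(2*a*r/s^2) below", {
  for (s in list(c(1.5, 1, 1), c(0.5, 0.8, 1.4), c(-0.7, 1, 1),
                 c(-1.5, 1.3, 0.8))) {
    mass <- integrate(dwald, 0, Inf, drift = s[1], noise = s[2],
                      threshold = s[3], rel.tol = 1e-9)$value
    expected <- if (s[1] > 0) 1 else exp(2 * s[3] * s[1] / s[2]^2)
    expect_equal(mass, expected, tolerance = 1e-5)
  }
})

test_that("Wald CDF is non-decreasing for randomized specs", {
  set.seed(101)
  grid <- seq(1e-3, 8, length.out = 1000)
  for (i in 1:10) {
    drift <- runif(1, -2, 4)
    F <- pwald(grid, drift, noise = runif(1, 0.3, 2),
               threshold = runif(1, 0.5, 2), shift = runif(1, 0, 0.3))
    expect_true(all(diff(F) >= -1e-12))
    expect_true(all(F >= 0 & F <= 1))
  }
})

test_that("drift link reproduces hand-computed values and symmetries", {
  r <- drift_rates(0.99, 0.08, v0 = 1, vd = 2, vs = 0.5)
  expect_equal(r$rho_l, 3.355)
  expect_equal(r$rho_r, -0.285)
  # equal contrasts: both rates v0 + 2*vs*s
  r2 <- drift_rates(0.4, 0.4, v0 = 0.7, vd = 5, vs = 0.3)
  expect_equal(r2$rho_l, r2$rho_r)
  expect_equal(r2$rho_l, 0.7 + 2 * 0.3 * 0.4)
  # zero coefficients: baseline only
  r3 <- drift_rates(0.9, 0.1, v0 = 1.1, vd = 0, vs = 0)
  expect_equal(c(r3$rho_l, r3$rho_r), c(1.1, 1.1))
  # swapping stimuli swaps the rates
  set.seed(7)
  for (i in 1:20) {
    s <- runif(2); cf <- rnorm(3)
    a <- drift_rates(s[1], s[2], cf[1], cf[2], cf[3])
    b <- drift_rates(s[2], s[1], cf[1], cf[2], cf[3])
    expect_equal(a$rho_l, b$rho_r)
    expect_equal(a$rho_r, b$rho_l)
  }
  expect_error(drift_rates(1.2, 0.5, 1, 1, 1))
})

test_that("bias maps to complementary thresholds summing to 2", {
  expect_equal(biased_thresholds(0.5), list(alpha_l = 1, alpha_r = 1))
  expect_equal(biased_thresholds(0.75),
               list(alpha_l = 1.5, alpha_r = 0.5))
  set.seed(8)
  for (w in runif(20, 0.01, 0.99)) {
    th <- biased_thresholds(w)
    expect_equal(th$alpha_l + th$alpha_r, 2)
    expect_true(th$alpha_l > 0 && th$alpha_r > 0)
  }
  expect_error(biased_thresholds(0))
  expect_error(biased_thresholds(1))
})

test_that("rwald matches analytic moments and the path-simulation oracle", {
  set.seed(11)
  # inverse Gaussian mean alpha/rho
  x <- rwald(1e5, drift = 2, noise = 1, threshold = 1)
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - 0.5), 3 * se)
  # crossing probability under negative drift
  y <- rwald(1e5, drift = -1, noise = 1, threshold = 1)
  p_hat <- mean(is.finite(y))
  p <- exp(-2)
  expect_lt(abs(p_hat - p), 3 * sqrt(p * (1 - p) / 1e5))
  # conditional crossing times follow the reflected law: compare with
  # the Euler-Maruyama oracle by two-sample KS at the 1% level
  set.seed(12)
  n <- 4000
  em <- em_fpt(n, drift = 1.5, noise = 1, threshold = 1, dt = 1e-3)
  direct <- rwald(n, drift = 1.5, noise = 1, threshold = 1)
  ks <- suppressWarnings(stats::ks.test(em, direct))
  expect_gt(ks$p.value, 0.01)
  # negative drift, conditional on crossing (both samples truncated at
  # the oracle horizon so the comparison conditions on the same event)
  em2 <- em_fpt(1.5e4, drift = -0.5, noise = 1, threshold = 1,
                dt = 1e-3, t_max = 12)
  dir2 <- rwald(1.5e4, drift = -0.5, noise = 1, threshold = 1)
  ks2 <- suppressWarnings(
    stats::ks.test(em2[is.finite(em2)], dir2[dir2 < 12]))
  expect_gt(ks2$p.value, 0.01)
})

test_that("pwald agrees with the path-simulation oracle", {
  set.seed(13)
  em <- em_fpt(2e4, drift = 1, noise = 1, threshold = 1, dt = 1e-3)
  at <- c(0.3, 0.6, 1, 1.5, 2.5)
  emp <- vapply(at, function(t) mean(em <= t), numeric(1))
  th <- pwald(at, drift = 1)
  # Monte-Carlo error ~ 3*sqrt(p(1-p)/n) plus small discretisation bias
  expect_true(all(abs(emp - th) < 3 * sqrt(0.25 / 2e4) + 0.01))
})
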