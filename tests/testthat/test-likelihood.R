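test_that("timer-triggered choice probability behaves as specified", {
  # gamma = 0: coin flip regardless of evidence
  expect_equal(timer_choice_prob(5, -3, eta_c = 1, gamma = 0, t = 0.7),
               0.5)
  # equal drifts: 0.5 for any gamma
  expect_equal(timer_choice_prob(2, 2, eta_c = 0.8, gamma = 0.9, t = 1),
               0.5)
  # fully evidence-based, unit gap: standard normal CDF at -1/sqrt(2)
  expect_equal(timer_choice_prob(0, 1, eta_c = 1, gamma = 1, t = 1),
               pnorm(-1 / sqrt(2)), tolerance = 1e-12)
  expect_equal(timer_choice_prob(0, 1, eta_c = 1, gamma = 1, t = 1),
               0.23975, tolerance = 1e-4)
  # printed variance mode is time-invariant; diffusion mode is not
  expect_equal(timer_choice_prob(1, 0, 1, 0.5, t = 0.2),
               timer_choice_prob(1, 0, 1, 0.5, t = 5))
  expect_false(isTRUE(all.equal(
    timer_choice_prob(1, 0, 1, 0.5, t = 0.2, variance_mode = "diffusion"),
    timer_choice_prob(1, 0, 1, 0.5, t = 5, variance_mode = "diffusion"))))
  # bounded and complementary
  set.seed(21)
  for (i in 1:25) {
    rl <- rnorm(1, 0, 3); rr <- rnorm(1, 0, 3)
    g <- runif(1); t <- runif(1, 0.05, 3)
    p <- timer_choice_prob(rl, rr, 1, g, t)
    q <- timer_choice_prob(rr, rl, 1, g, t)
    expect_true(p >= 0 && p <= 1)
    expect_equal(p + q, 1)
  }
})

test_that("TRDM with a negligible timer nests the RDM", {
  trdm <- race_params("TRDM", omega = 0.45, t0 = 0.15, v0 = 1, vd = 2,
                      vs = 0.4, eta_c = 1, rho_t = 1e-6, eta_t = 1e-6,
                      gamma = 0.5)
  rdm <- race_params("RDM", omega = 0.45, t0 = 0.15, v0 = 1, vd = 2,
                     vs = 0.4, eta_c = 1)
  t <- seq(0.16, 3, length.out = 200)
  for (ch in c("left", "right")) {
    expect_equal(drace(t, ch, trdm, 0.8, 0.3),
                 drace(t, ch, rdm, 0.8, 0.3), tolerance = 1e-8)
  }
  # dataset-level nesting
  set.seed(22)
  tr <- simulate_race(rdm, stim = grid_stim(20))
  expect_equal(loglik_race(tr, trdm), loglik_race(tr, rdm),
               tolerance = 1e-6)
})

test_that("defective densities integrate to 1 over choices (positive drifts)", {
  sets <- list(
    ref_trdm_params(),
    race_params("TRDM", omega = 0.6, t0 = 0.2, v0 = 2, vd = 1, vs = 0.3,
                eta_c = 0.7, rho_t = 1.5, eta_t = 1.2, gamma = 0.7),
    race_params("RDM", omega = 0.5, t0 = 0.1, v0 = 1.5, vd = 1,
                vs = 0.5, eta_c = 1))
  for (p in sets) {
    total <- integrate(function(t) drace(t, "left", p, 0.8, 0.3),
                       p$t0, Inf, rel.tol = 1e-9)$value +
      integrate(function(t) drace(t, "right", p, 0.8, 0.3),
                p$t0, Inf, rel.tol = 1e-9)$value
    expect_equal(total, 1, tolerance = 1e-4)
  }
})

test_that("RDM density: a hopeless rival concedes the full mass", {
  # right drift so negative it never wins: left choice carries ~all mass
  p <- race_params("RDM", omega = 0.5, t0 = 0, v0 = 1, vd = 25,
                   vs = 0.5, eta_c = 1)
  # s_l=1, s_r=0 -> rho_l = 26.5, rho_r = -23.5
  mass_l <- integrate(function(t) drace(t, "left", p, 1, 0), 0, Inf,
                      rel.tol = 1e-9)$value
  expect_equal(mass_l, 1, tolerance = 1e-4)
  # symmetric stimulus: left and right densities identical pointwise
  t <- seq(0.01, 4, length.out = 300)
  expect_equal(drace(t, "left", p, 0.5, 0.5),
               drace(t, "right", p, 0.5, 0.5))
})

test_that("compiled log-likelihood equals the R reference density", {
  set.seed(23)
  for (p in list(ref_trdm_params(),
                 race_params("RDM", omega = 0.35, t0 = 0.12, v0 = 1.2,
                             vd = 1.5, vs = 0.2, eta_c = 0.9))) {
    tr <- simulate_race(p, stim = grid_stim(10))
    ref <- sum(log(pmax(drace(tr$rt, tr$choice, p, tr$s_l, tr$s_r),
                        1e-300)))
    expect_equal(loglik_race(tr, p), ref, tolerance = 1e-12)
  }
})

test_that("log-likelihood is additive, floored, and rejects bad input", {
  p <- ref_trdm_params()
  set.seed(24)
  tr <- simulate_race(p, stim = grid_stim(5))
  one <- tr[1, , drop = FALSE]
  expect_equal(loglik_race(one, p),
               log(drace(one$rt, one$choice, p, one$s_l, one$s_r)))
  a <- tr[1:80, ]; b <- tr[81:nrow(tr), ]
  expect_equal(loglik_race(tr, p),
               loglik_race(a, p) + loglik_race(b, p), tolerance = 1e-10)
  # an impossible trial (rt below t0) is floored, not -Inf
  bad <- tr
  bad$rt[1] <- 0.05
  expect_true(is.finite(loglik_race(bad, p)))
  expect_lt(loglik_race(bad, p), loglik_race(tr, p))
  expect_error(loglik_race(tr[0, ], p), "non-empty")
})

test_that("true parameters dominate perturbed ones in likelihood", {
  p <- ref_trdm_params()
  worse <- race_params("TRDM", omega = 0.5, t0 = 0.1, v0 = 1.5,
                       vd = 4.5, vs = 0.75, eta_c = 1.5, rho_t = 4.5,
                       eta_t = 0.75, gamma = 0.3)
  for (seed in 1:5) {
    set.seed(seed)
    g <- contrast_grid()
    tr <- simulate_race(p, stim = g[sample.int(36, 5000, TRUE), ])
    expect_gt(loglik_race(tr, p), loglik_race(tr, worse))
  }
})

test_that("simulated RTs follow the defective densities (KS check)", {
  set.seed(25)
  sets <- list(ref_trdm_params(),
               race_params("RDM", omega = 0.5, t0 = 0.1, v0 = 1.5,
                           vd = 2, vs = 0.5, eta_c = 1))
  for (p in sets) {
    sim <- simulate_race(p, n = 1e5, s_l = 0.626, s_r = 0.262)
    for (ch in c("left", "right")) {
      x <- sim$rt[sim$choice == ch]
      cdf <- race_cond_cdf(ch, p, 0.626, 0.262)
      # one-sample KS critical value at the 1% level
      expect_lt(ks_distance(x, cdf), 1.628 / sqrt(length(x)))
    }
    # choice proportions match the defective masses within 3 SE
    m_l <- integrate(function(t) drace(t, "left", p, 0.626, 0.262),
                     p$t0, Inf, rel.tol = 1e-9)$value
    se <- sqrt(m_l * (1 - m_l) / 1e5)
    expect_lt(abs(mean(sim$choice == "left") - m_l), 3 * se)
  }
})
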