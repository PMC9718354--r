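test_that("default priors cover exactly the free parameters", {
  pr_r <- default_priors("RDM")
  pr_t <- default_priors("TRDM")
  expect_equal(nrow(pr_r), 6)
  expect_equal(nrow(pr_t), 9)
  expect_setequal(pr_t$parameter,
                  c("omega", "t0", "v0", "vd", "vs", "eta_c", "rho_t",
                    "eta_t", "gamma"))
  # family medians: IL(0, .) -> 0.5; LN(1.56, .) -> exp(1.56);
  # gamma's IL(-1, .) -> plogis(-1) ~ 0.27
  expect_equal(plogis(pr_t["omega", "location"]), 0.5)
  expect_equal(exp(pr_t["v0", "location"]), 4.759, tolerance = 1e-3)
  expect_equal(plogis(pr_t["gamma", "location"]), 0.269, tolerance = 1e-3)
})

test_that("prior density matches a sampling oracle through the transforms", {
  set.seed(61)
  pr <- default_priors("TRDM")
  z <- matrix(rnorm(2e5 * 9, pr$location, pr$scale),
              ncol = 9, byrow = TRUE)
  # log-normal parameters: quantiles of exp(z) match qlnorm
  v0_draws <- exp(z[, which(pr$parameter == "v0")])
  qs <- quantile(v0_draws, c(0.1, 0.25, 0.5, 0.75, 0.9))
  expect_equal(unname(qs),
               qlnorm(c(0.1, 0.25, 0.5, 0.75, 0.9), 1.56, 1.5),
               tolerance = 0.03)
  # inverse-logit parameters: plogis(z) quantiles match analytic
  om_draws <- plogis(z[, which(pr$parameter == "omega")])
  expect_equal(unname(quantile(om_draws, c(0.25, 0.5, 0.75))),
               plogis(qnorm(c(0.25, 0.5, 0.75), 0, 1.4)),
               tolerance = 0.01)
  # density route agrees with R's dlnorm / transformed dnorm
  p <- ref_trdm_params()
  manual <- sum(dlnorm(c(1, 3, 0.5, 1, 3, 0.5), 1.56, 1.5, log = TRUE)) +
    dnorm(qlogis(0.5), 0, 1.4, log = TRUE) - log(0.5 * 0.5) +
    dnorm(qlogis(0.1), 0, 1.4, log = TRUE) - log(0.1 * 0.9) +
    dnorm(qlogis(0.2), -1, 1.0, log = TRUE) - log(0.2 * 0.8)
  expect_equal(prior_logpdf(p), manual, tolerance = 1e-10)
  # outside support
  expect_identical(prior_logpdf(c(omega = 1.2, t0 = 0.1, v0 = 1, vd = 1,
                                  vs = 1, eta_c = 1),
                                default_priors("RDM")), -Inf)
})

test_that("DE proposal collapses to jitter for a null difference", {
  set.seed(62)
  states <- matrix(rep(c(1, 2, 3), each = 3), nrow = 3)  # equal rows
  prop <- de_propose(states, 1)
  expect_true(all(abs(prop - states[1, ]) <= 1e-4))
  expect_error(de_propose(states[1:2, ], 1), "3 chains")
})

test_that("Metropolis rule accepts by the posterior ratio", {
  up <- mh_accept(c(0), c(1), -10, -5)
  expect_true(up$accepted)
  same <- mh_accept(c(0), c(0), -3, -3)
  expect_true(same$accepted)
  # empirical acceptance at a fixed ratio r = 0.3
  set.seed(63)
  r <- 0.3
  acc <- replicate(1e5, mh_accept(0, 1, 0, log(r))$accepted)
  expect_lt(abs(mean(acc) - r), 3 * sqrt(r * (1 - r) / 1e5))
})

test_that("DE-MCMC reproduces a conjugate normal posterior within 2%", {
  set.seed(64)
  y <- rnorm(50, 1.2, 1)
  # prior mu ~ N(0, 1), likelihood N(mu, 1): posterior closed form
  post_var <- 1 / (1 + length(y))
  post_mean <- post_var * sum(y)
  res <- demcmc_sample(
    log_lik = function(z) sum(dnorm(y, z[1], 1, log = TRUE)),
    log_prior = function(z) dnorm(z[1], 0, 1, log = TRUE),
    n_pars = 1, n_chains = 10, burn = 200, samples = 1000,
    init_fun = function(n) matrix(rnorm(n), ncol = 1))
  draws <- as.vector(res$draws)
  expect_equal(mean(draws), post_mean, tolerance = 0.02)
  expect_equal(sd(draws), sqrt(post_var), tolerance = 0.02)
  # decile check against the analytic posterior, in units of its SD
  qs <- quantile(draws, seq(0.1, 0.9, 0.1))
  qtrue <- qnorm(seq(0.1, 0.9, 0.1), post_mean, sqrt(post_var))
  expect_lt(max(abs(qs - qtrue)) / sqrt(post_var), 0.08)
})

test_that("pooled posteriors from different seeds are exchangeable", {
  set.seed(65)
  y <- rnorm(40, 0.5, 1)
  run <- function() demcmc_sample(
    log_lik = function(z) sum(dnorm(y, z[1], 1, log = TRUE)),
    log_prior = function(z) dnorm(z[1], 0, 1, log = TRUE),
    n_pars = 1, n_chains = 10, burn = 200, samples = 400,
    init_fun = function(n) matrix(rnorm(n), ncol = 1))
  a <- as.vector(run()$draws)
  b <- as.vector(run()$draws)
  # thin to weaken autocorrelation before the two-sample KS
  a <- a[seq(1, length(a), 40)]
  b <- b[seq(1, length(b), 40)]
  expect_gt(suppressWarnings(stats::ks.test(a, b))$p.value, 0.01)
})

test_that("race posterior samples respect parameter supports and seeds", {
  p <- ref_trdm_params()
  set.seed(66)
  tr <- simulate_race(p, stim = grid_stim(6))
  s1 <- run_demcmc(tr, "TRDM", burn = 5, samples = 10, seed = 99)
  s2 <- run_demcmc(tr, "TRDM", burn = 5, samples = 10, seed = 99)
  expect_identical(s1$draws, s2$draws)
  expect_equal(dim(s1$draws), c(90, 10, 9))
  d <- s1$draws
  expect_true(all(d[, , "omega"] > 0 & d[, , "omega"] < 1))
  expect_true(all(d[, , "gamma"] > 0 & d[, , "gamma"] < 1))
  expect_true(all(d[, , c("v0", "vd", "vs", "eta_c", "rho_t",
                          "eta_t")] > 0))
  # chain count rule: 10 per free parameter
  s3 <- run_demcmc(tr, "RDM", burn = 2, samples = 3, seed = 1)
  expect_equal(s3$n_chains, 60)
  expect_equal(s1$n_chains, 90)
})
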