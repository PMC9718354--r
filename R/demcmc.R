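#' Differential-evolution proposal
#'
#' Proposal for chain `i` in a DE-MCMC population: the chain's state
#' plus a scaled difference of two other randomly chosen chains plus a
#' small uniform jitter,
#' \deqn{\theta' = \theta_i + g(\theta_a - \theta_b) + \epsilon,}
#' with distinct \eqn{a, b \ne i}, the standard scale
#' \eqn{g = 2.38/\sqrt{2d}} for a `d`-dimensional target, and
#' \eqn{\epsilon \sim U(-10^{-4}, 10^{-4})} per coordinate.
#'
#' @param states numeric matrix of chain states (chains x parameters).
#' @param i index of the chain being updated.
#' @param gamma_de difference scaling; default `2.38/sqrt(2 * ncol)`.
#' @param jitter half-width of the uniform jitter.
#' @return proposal vector on the same (unconstrained) scale.
#' @export
de_propose <- function(states, i, gamma_de = NULL, jitter = 1e-4) {
  if (nrow(states) < 3)
    stop("DE proposals need at least 3 chains", call. = FALSE)
  d <- ncol(states)
  if (is.null(gamma_de)) gamma_de <- 2.38 / sqrt(2 * d)
  ab <- sample(seq_len(nrow(states))[-i], 2L)
  states[i, ] + gamma_de * (states[ab[1L], ] - states[ab[2L], ]) +
    runif(d, -jitter, jitter)
}

#' Metropolis-Hastings acceptance step
#'
#' Accepts the proposal with probability
#' `min(1, exp(logpost_prop - logpost_curr))` (the proposal is
#' symmetric, so the posterior ratio is the acceptance ratio).
#'
#' @param current,proposal state vectors.
#' @param logpost_current,logpost_proposal their log posterior values.
#' @return a list with the winning `state`, its `logpost` and a flag
#'   `accepted`.
#' @export
mh_accept <- function(current, proposal, logpost_current,
                      logpost_proposal) {
  accept <- is.finite(logpost_proposal) &&
    log(runif(1)) < (logpost_proposal - logpost_current)
  if (accept)
    list(state = proposal, logpost = logpost_proposal, accepted = TRUE)
  else
    list(state = current, logpost = logpost_current, accepted = FALSE)
}

#' Generic DE-MCMC sampler
#'
#' Population MCMC with differential-evolution proposals
#' ([de_propose()]) and Metropolis acceptance ([mh_accept()]) on an
#' unconstrained parameter space. `log_lik` and `log_prior` are kept
#' separate so that the per-sample likelihood (needed for BIC) is
#' tracked alongside the posterior.
#'
#' @param log_lik function of a parameter vector returning the log
#'   likelihood (set to `function(z) 0` to sample a bare target given
#'   by `log_prior`).
#' @param log_prior function returning the log prior.
#' @param n_pars dimension of the space.
#' @param n_chains number of parallel chains (at least 3).
#' @param burn,samples burn-in and retained iterations.
#' @param init matrix of initial states (chains x parameters); chains
#'   with non-finite posterior are re-drawn from `init_fun` up to 100
#'   times.
#' @param init_fun function(n) generating n initial state rows.
#' @param init_pool when `init` is not given, draw
#'   `init_pool * n_chains` candidate states from `init_fun` and start
#'   the population from the `n_chains` with the highest posterior.
#'   Diffuse priors otherwise leave most of the population so far from
#'   the data that a short burn-in cannot recover.
#' @param jitter DE jitter half-width.
#' @param p_jump probability of a mode-jumping iteration using a
#'   difference scale of 0.98 instead of `2.38/sqrt(2d)`; the proposal
#'   stays symmetric, so both phases remain valid Metropolis steps.
#' @param migrate_prob during burn-in only, probability per iteration
#'   of a migration step that resets the worst 5% of chains to
#'   jittered copies of randomly chosen top-quartile chains. This
#'   greedy contraction is discarded with the burn-in; without it a
#'   short burn-in can strand most of the population in a minor mode.
#' @param greedy_frac fraction of the burn-in run as a greedy
#'   differential-evolution search (proposals accepted only when they
#'   improve the posterior). The race posteriors are multimodal — a
#'   "dead evidence" mode in which the timer and the choice mixture
#'   explain everything competes with the data-generating mode — and
#'   plain Metropolis burn-in regularly fails to cross between them on
#'   a short schedule. The remaining burn-in re-diffuses the
#'   population under the exact Metropolis rule before any samples are
#'   kept.
#' @param refine when `TRUE`, polish the best `refine_starts` pool
#'   draws by Nelder-Mead on the log posterior and initialise the
#'   population over-dispersed around the best optimum
#'   (`refine_sd` jitter per coordinate) instead of at raw pool
#'   draws. Burn-in then only has to contract the population, which a
#'   short schedule can do; finding the dominant mode is delegated to
#'   the optimizer's multi-start.
#' @param refine_starts,refine_sd multi-start count and jitter SD of
#'   the refined initialisation.
#' @return a list with `draws` (array indexed
#'   `[chain, iteration, parameter]`, post-burn-in only), `loglik`
#'   (chains x all iterations), `best` (state with the highest
#'   likelihood seen at any point, burn-in included, and its value),
#'   and `accept_rate`.
#' @export
demcmc_sample <- function(log_lik, log_prior, n_pars,
                          n_chains = 10 * n_pars, burn = 200,
                          samples = 500, init = NULL, init_fun = NULL,
                          init_pool = 20, jitter = 1e-4, p_jump = 0.1,
                          migrate_prob = 0.1, greedy_frac = 0.3,
                          refine = FALSE, refine_starts = 5,
                          refine_sd = 0.15) {
  stopifnot(n_chains >= 3, burn >= 0, samples >= 1)
  if (is.null(init)) {
    if (is.null(init_fun))
      stop("provide `init` or `init_fun`", call. = FALSE)
    pool <- init_fun(max(1, init_pool) * n_chains)
    lp_pool <- apply(pool, 1L, function(z) {
      v <- log_lik(z) + log_prior(z)
      if (is.finite(v)) v else -Inf
    })
    ord_pool <- order(lp_pool, decreasing = TRUE)
    if (refine) {
      neg_post <- function(z) {
        v <- log_lik(z) + log_prior(z)
        if (is.finite(v)) -v else 1e12
      }
      best_val <- Inf
      best_z <- pool[ord_pool[1L], ]
      for (s in seq_len(min(refine_starts, nrow(pool)))) {
        opt <- optim(pool[ord_pool[s], ], neg_post,
                     method = "Nelder-Mead",
                     control = list(maxit = 2000))
        if (opt$value < best_val) {
          best_val <- opt$value
          best_z <- opt$par
        }
      }
      init <- matrix(rep(best_z, each = n_chains), nrow = n_chains) +
        matrix(rnorm(n_chains * n_pars, 0, refine_sd), nrow = n_chains)
    } else {
      init <- pool[ord_pool[seq_len(n_chains)], , drop = FALSE]
    }
  }
  stopifnot(nrow(init) == n_chains, ncol(init) == n_pars)
  gamma_de <- 2.38 / sqrt(2 * n_pars)

  ll <- apply(init, 1L, log_lik)
  lp <- apply(init, 1L, log_prior)
  for (attempt in seq_len(100L)) {
    bad <- !is.finite(ll + lp)
    if (!any(bad)) break
    if (is.null(init_fun) || attempt == 100L)
      stop("could not initialise all chains at finite posterior",
           call. = FALSE)
    redraw <- init_fun(sum(bad))
    init[bad, ] <- redraw
    ll[bad] <- apply(redraw, 1L, log_lik)
    lp[bad] <- apply(redraw, 1L, log_prior)
  }

  states <- init
  total <- burn + samples
  draws <- array(NA_real_, c(n_chains, samples, n_pars))
  ll_trace <- matrix(NA_real_, n_chains, total)
  best_ll <- max(ll)
  best_state <- states[which.max(ll), ]
  n_accept <- 0L

  n_greedy <- floor(greedy_frac * burn)
  for (iter in seq_len(total)) {
    greedy <- iter <= n_greedy
    g_iter <- if (runif(1) < p_jump) 0.98 else gamma_de
    if (iter <= burn && runif(1) < migrate_prob) {
      # burn-in migration: worst chains adopt jittered copies of good ones
      n_bad <- max(1L, floor(0.05 * n_chains))
      ord <- order(ll + lp)
      bad <- ord[seq_len(n_bad)]
      good <- sample(ord[seq(floor(0.75 * n_chains), n_chains)],
                     n_bad, replace = TRUE)
      for (m in seq_len(n_bad)) {
        cand <- states[good[m], ] + rnorm(n_pars, 0, 1e-3)
        ll_c <- log_lik(cand)
        lp_c <- log_prior(cand)
        if (is.finite(ll_c + lp_c)) {
          states[bad[m], ] <- cand
          ll[bad[m]] <- ll_c
          lp[bad[m]] <- lp_c
          if (ll_c > best_ll) {
            best_ll <- ll_c
            best_state <- cand
          }
        }
      }
    }
    for (i in seq_len(n_chains)) {
      prop <- de_propose(states, i, g_iter, jitter)
      ll_p <- log_lik(prop)
      lp_p <- log_prior(prop)
      res <- if (greedy) {
        if (is.finite(ll_p + lp_p) && ll_p + lp_p >= ll[i] + lp[i])
          list(accepted = TRUE) else list(accepted = FALSE)
      } else {
        mh_accept(states[i, ], prop, ll[i] + lp[i], ll_p + lp_p)
      }
      if (res$accepted) {
        states[i, ] <- prop
        ll[i] <- ll_p
        lp[i] <- lp_p
        n_accept <- n_accept + 1L
        if (ll_p > best_ll) {
          best_ll <- ll_p
          best_state <- prop
        }
      }
      ll_trace[i, iter] <- ll[i]
    }
    if (iter > burn)
      draws[, iter - burn, ] <- states
  }
  list(draws = draws, loglik = ll_trace,
       best = list(state = best_state, loglik = best_ll),
       accept_rate = n_accept / (total * n_chains))
}

#' Posterior sampling of a racing diffusion model by DE-MCMC
#'
#' Samples the posterior of the RDM or TRDM parameters given
#' trial-level data. Sampling happens on the unconstrained scale
#' (logit for the (0,1)-supported parameters, log for the positive
#' ones), where the priors of [default_priors()] are
#' independent normals; chains are initialised at prior draws. The
#' population size is 10 chains per free parameter (60 for the RDM, 90
#' for the TRDM), with 200 burn-in and 500 sampling iterations by
#' default.
#'
#' @param trials data frame of trials (see [loglik_race()]),
#'   preferably culled with [boxcox_cull()] first.
#' @param model `"RDM"` or `"TRDM"`.
#' @param priors a [default_priors()]-style data frame.
#' @param burn,samples DE-MCMC schedule.
#' @param chains_per_par chains per free parameter.
#' @param polish refine the maximum-likelihood surrogate by a
#'   Nelder-Mead climb of the likelihood from the best sampled state
#'   (default `TRUE`). The maximum over a finite sample
#'   underestimates the maximised likelihood by a few units with
#'   run-to-run noise of similar size, which BIC differences inherit;
#'   polishing removes most of that noise from model comparisons.
#' @param seed integer seed; fixed seed gives identical output.
#' @inheritParams drace
#' @return an object of class `race_samples`: a list with `draws`
#'   (array `[chain, iteration, parameter]`, natural scale,
#'   post-burn-in), `loglik` (chains x all iterations), `best`
#'   (natural-scale parameter vector with the highest likelihood seen
#'   anywhere, burn-in included, and that likelihood), `accept_rate`,
#'   `model`, `priors`, `n_trials` and the schedule metadata.
#' @export
run_demcmc <- function(trials, model = c("TRDM", "RDM"),
                       priors = NULL, burn = 200, samples = 500,
                       chains_per_par = 10, polish = TRUE, seed = NULL,
                       gamma_variance = c("printed", "diffusion"),
                       timer_t0 = c("shared", "zero")) {
  model <- match.arg(model)
  gamma_variance <- match.arg(gamma_variance)
  timer_t0 <- match.arg(timer_t0)
  check_trials(trials)
  if (is.null(priors)) priors <- default_priors(model)
  stopifnot(setequal(priors$parameter, param_names(model)))
  priors <- priors[match(param_names(model), priors$parameter), ]
  if (!is.null(seed)) set.seed(seed)

  d <- nrow(priors)
  n_chains <- chains_per_par * d
  is_trdm <- model == "TRDM"
  rt <- trials$rt; is_left <- trials$choice == "left"
  s_l <- trials$s_l; s_r <- trials$s_r
  printed <- gamma_variance == "printed"
  shared <- timer_t0 == "shared"
  il <- priors$family == "IL"

  log_lik <- function(z) {
    theta <- ifelse(il, plogis(z), exp(z))
    race_loglik_cpp(rt, is_left, s_l, s_r, theta, is_trdm, printed,
                    shared)
  }
  log_prior <- function(z) prior_logpdf_z(z, priors)

  res <- demcmc_sample(log_lik, log_prior, n_pars = d,
                       n_chains = n_chains, burn = burn,
                       samples = samples, refine = TRUE,
                       init_fun = function(n) rprior_z(n, priors))

  nat <- res$draws
  for (j in seq_len(d))
    nat[, , j] <- if (il[j]) plogis(nat[, , j]) else exp(nat[, , j])
  dimnames(nat) <- list(NULL, NULL, priors$parameter)
  best <- list(params = to_natural(res$best$state, priors),
               loglik = res$best$loglik)
  if (polish) {
    neg_ll <- function(z) {
      v <- log_lik(z)
      if (is.finite(v)) -v else 1e12
    }
    opt <- optim(res$best$state, neg_ll, method = "Nelder-Mead",
                 control = list(maxit = 2000))
    if (-opt$value > best$loglik)
      best <- list(params = to_natural(opt$par, priors),
                   loglik = -opt$value)
  }
  # the componentwise posterior median is a natural point estimate;
  # include it in the maximum-likelihood surrogate so the reported
  # maximum always dominates it
  med <- apply(nat, 3L, median)
  ll_med <- race_loglik_cpp(rt, is_left, s_l, s_r, med, is_trdm,
                            printed, shared)
  if (ll_med > best$loglik)
    best <- list(params = med, loglik = ll_med)
  structure(list(draws = nat, loglik = res$loglik, best = best,
                 accept_rate = res$accept_rate, model = model,
                 priors = priors, n_trials = nrow(trials),
                 burn = burn, samples = samples, n_chains = n_chains,
                 seed = seed, gamma_variance = gamma_variance,
                 timer_t0 = timer_t0),
            class = "race_samples")
}

#' @export
print.race_samples <- function(x, ...) {
  cat(sprintf(
    "DE-MCMC posterior samples: %s, %d chains x %d iterations (+%d burn-in)\n",
    x$model, x$n_chains, x$samples, x$burn))
  cat(sprintf("n = %d trials, acceptance rate %.2f, best log-lik %.2f\n",
              x$n_trials, x$accept_rate, x$best$loglik))
  cat("posterior medians:\n")
  print(round(apply(x$draws, 3L, median), 4))
  invisible(x)
}
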