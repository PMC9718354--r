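#' Fit a racing diffusion model to choice-RT data
#'
#' The main model-fitting entry point: Bayesian posterior sampling of
#' the RDM or TRDM parameters by DE-MCMC (see [run_demcmc()] for the
#' sampler and its schedule), returning a classed fit with the usual
#' accessor methods (`print`, `summary`, `coef`, `logLik`, `predict`,
#' `simulate`, `plot`).
#'
#' @inheritParams run_demcmc
#' @param cull apply [boxcox_cull()] to the RTs before fitting.
#' @param ... passed on to [run_demcmc()] (e.g. `chains_per_par`,
#'   `gamma_variance`).
#' @return an object of class `race_fit` wrapping the `race_samples`
#'   posterior, the (culled) data and fit metadata.
#' @examples
#' \donttest{
#' set.seed(42)
#' trials <- simulate_race(agent_fast_timer(),
#'                         stim = contrast_grid()[rep(1:36, 10), ])
#' fit <- fit_race(trials, "TRDM", burn = 20, samples = 30, seed = 1)
#' coef(fit)
#' }
#' @export
fit_race <- function(trials, model = c("TRDM", "RDM"), priors = NULL,
                     burn = 200, samples = 500, seed = NULL,
                     cull = FALSE, ...) {
  model <- match.arg(model)
  check_trials(trials)
  n_culled <- 0L
  if (cull) {
    keep <- boxcox_cull(trials$rt)
    n_culled <- sum(!keep)
    trials <- trials[keep, , drop = FALSE]
  }
  post <- run_demcmc(trials, model = model, priors = priors,
                     burn = burn, samples = samples, seed = seed, ...)
  structure(list(posterior = post, trials = trials, model = model,
                 n_culled = n_culled, call = match.call()),
            class = "race_fit")
}

#' @export
print.race_fit <- function(x, ...) {
  cat(sprintf("%s fit to %d trials%s\n", x$model, nrow(x$trials),
              if (x$n_culled > 0)
                sprintf(" (%d culled)", x$n_culled) else ""))
  cat(sprintf("DE-MCMC: %d chains, %d + %d iterations, accept %.2f\n",
              x$posterior$n_chains, x$posterior$burn,
              x$posterior$samples, x$posterior$accept_rate))
  cat("posterior medians:\n")
  print(round(coef(x), 4))
  invisible(x)
}

#' @export
coef.race_fit <- function(object, ...) {
  apply(object$posterior$draws, 3L, median)
}

#' @export
logLik.race_fit <- function(object, ...) {
  # maximum likelihood over all sampled parameter vectors (burn-in
  # included): the MCMC surrogate for the BIC's maximised likelihood
  val <- object$posterior$best$loglik
  attr(val, "df") <- length(param_names(object$model))
  attr(val, "nobs") <- nrow(object$trials)
  class(val) <- "logLik"
  val
}

#' @export
summary.race_fit <- function(object, probs = c(0.025, 0.5, 0.975), ...) {
  draws <- object$posterior$draws
  qs <- t(apply(draws, 3L, quantile, probs = probs))
  out <- data.frame(mean = apply(draws, 3L, mean), qs,
                    check.names = FALSE)
  structure(list(table = out, model = object$model,
                 n = nrow(object$trials),
                 best_loglik = object$posterior$best$loglik,
                 accept_rate = object$posterior$accept_rate),
            class = "summary.race_fit")
}

#' @export
print.summary.race_fit <- function(x, ...) {
  cat(sprintf("%s posterior summary (n = %d trials)\n", x$model, x$n))
  print(round(x$table, 4))
  cat(sprintf("best log-likelihood %.2f, acceptance rate %.2f\n",
              x$best_loglik, x$accept_rate))
  invisible(x)
}

#' Fitted parameters as a `race_params` object
#'
#' @param fit a `race_fit`.
#' @param type `"median"` (posterior medians) or `"best"` (highest
#'   sampled likelihood).
#' @return a [race_params()] object.
#' @export
fitted_params <- function(fit, type = c("median", "best")) {
  type <- match.arg(type)
  theta <- switch(type, median = coef(fit),
                  best = fit$posterior$best$params)
  vector_to_params(theta, fit$model)
}

#' @export
simulate.race_fit <- function(object, nsim = 1, seed = NULL, ...,
                              stim = NULL, type = "median") {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(stim))
    stim <- object$trials[sample.int(nrow(object$trials), nsim,
                                     replace = TRUE),
                          c("s_l", "s_r")]
  simulate_race(fitted_params(object, type), stim = stim)
}

#' @export
predict.race_fit <- function(object, newdata = NULL,
                             type = "median", ...) {
  if (is.null(newdata)) {
    stim <- unique(object$trials[c("s_l", "s_r")])
  } else {
    stim <- newdata[c("s_l", "s_r")]
  }
  p <- fitted_params(object, type)
  upper <- max(object$trials$rt) * 5 + p$t0
  out <- do.call(rbind, lapply(seq_len(nrow(stim)), function(i) {
    f_l <- function(t) drace(t, "left", p, stim$s_l[i], stim$s_r[i])
    f_r <- function(t) drace(t, "right", p, stim$s_l[i], stim$s_r[i])
    p_l <- integrate(f_l, p$t0, upper, stop.on.error = FALSE)$value
    p_r <- integrate(f_r, p$t0, upper, stop.on.error = FALSE)$value
    m <- integrate(function(t) t * (f_l(t) + f_r(t)), p$t0, upper,
                   stop.on.error = FALSE)$value / max(p_l + p_r, 1e-12)
    data.frame(s_l = stim$s_l[i], s_r = stim$s_r[i], p_left = p_l,
               p_right = p_r, mean_rt = m)
  }))
  rownames(out) <- NULL
  out
}

#' @export
residuals.race_fit <- function(object, ...) {
  # signed deviation of each observed choice from its model
  # probability, a rough trial-level diagnostic
  pred <- predict(object)
  key <- paste(object$trials$s_l, object$trials$s_r)
  pk <- paste(pred$s_l, pred$s_r)
  p_left <- pred$p_left[match(key, pk)] /
    pmax(pred$p_left + pred$p_right, 1e-12)[match(key, pk)]
  (object$trials$choice == "left") - p_left
}

#' @export
plot.race_fit <- function(x, breaks = 40, rt_max = NULL, ...) {
  rts <- x$trials$rt
  if (is.null(rt_max)) rt_max <- quantile(rts, 0.995)
  h <- hist(rts[rts <= rt_max], breaks = breaks, freq = FALSE,
            main = sprintf("%s fit", x$model), xlab = "response time (s)",
            col = "grey85", border = "white", ...)
  p <- fitted_params(x, "median")
  grid <- seq(p$t0 + 1e-4, rt_max, length.out = 300)
  stim <- unique(x$trials[c("s_l", "s_r")])
  w <- table(paste(x$trials$s_l, x$trials$s_r))
  w <- as.numeric(w[paste(stim$s_l, stim$s_r)]) / nrow(x$trials)
  dens <- rowSums(vapply(seq_len(nrow(stim)), function(i)
    w[i] * (drace(grid, "left", p, stim$s_l[i], stim$s_r[i]) +
              drace(grid, "right", p, stim$s_l[i], stim$s_r[i])),
    numeric(length(grid))))
  lines(grid, dens, lwd = 2, col = "firebrick")
  legend("topright", bty = "n", lwd = c(NA, 2),
         pch = c(22, NA), pt.bg = c("grey85", NA),
         col = c("grey60", "firebrick"),
         legend = c("observed", "model (posterior median)"))
  invisible(x)
}
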