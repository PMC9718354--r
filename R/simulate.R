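#' Simulate choice-RT trials from a racing diffusion model
#'
#' Runs the stochastic race trial by trial: first-passage times are
#' drawn for both evidence accumulators (thresholds set by the bias via
#' [biased_thresholds()]) and, for the TRDM, for the timer; the
#' earliest finite crossing wins. A timer win emits a choice by a
#' Bernoulli draw with probability [timer_choice_prob()] evaluated at
#' the timer's crossing time, and the trial is labelled
#' `source = "timer"`; evidence wins are labelled `"evidence"`. The
#' shared non-decision time `t0` is added once to the winning decision
#' time. RDM trials on which neither accumulator ever reaches threshold
#' (possible under negative drifts) are resampled, with a warning
#' giving the count.
#'
#' @param params a [race_params()] object.
#' @param stim a data frame with columns `s_l`, `s_r` (one row per
#'   trial), or a single pair via `s_l`/`s_r` scalars and `n`.
#' @param n number of trials when `stim` is omitted.
#' @param s_l,s_r scalar contrasts used with `n`.
#' @inheritParams drace
#' @return a data frame with columns `s_l`, `s_r`, `choice`, `rt`,
#'   `source`, `correct` (a choice of the higher-contrast side; on
#'   equal-contrast trials the correct side is drawn uniformly).
#' @examples
#' p <- race_params("TRDM", t0 = 0.1, v0 = 1, vd = 3, vs = 0.5,
#'                  eta_c = 1, rho_t = 3, eta_t = 0.5, gamma = 0.2)
#' sim <- simulate_race(p, n = 100, s_l = 0.99, s_r = 0.08)
#' table(sim$source)
#' @export
simulate_race <- function(params, stim = NULL, n = NULL,
                          s_l = NULL, s_r = NULL,
                          gamma_variance = c("printed", "diffusion"),
                          timer_t0 = c("shared", "zero")) {
  gamma_variance <- match.arg(gamma_variance)
  timer_t0 <- match.arg(timer_t0)
  validate_race_params(params)
  if (is.null(stim)) {
    stopifnot(!is.null(n), !is.null(s_l), !is.null(s_r))
    stim <- data.frame(s_l = rep_len(s_l, n), s_r = rep_len(s_r, n))
  }
  stopifnot(all(c("s_l", "s_r") %in% names(stim)))
  n <- nrow(stim)
  rho <- drift_rates(stim$s_l, stim$s_r, params$v0, params$vd, params$vs)
  thr <- biased_thresholds(params$omega)

  res <- race_core(n, rho$rho_l, rho$rho_r, params, thr,
                   gamma_variance, timer_t0)
  # resample never-terminating RDM trials (free-response task: only
  # completed trials are observed)
  n_resampled <- 0L
  while (any(bad <- !is.finite(res$dt))) {
    n_resampled <- n_resampled + sum(bad)
    if (n_resampled > 1e6)
      stop("race fails to terminate; drifts too negative", call. = FALSE)
    redo <- race_core(sum(bad), rho$rho_l[bad], rho$rho_r[bad], params,
                      thr, gamma_variance, timer_t0)
    res$dt[bad] <- redo$dt
    res$left[bad] <- redo$left
    res$timer[bad] <- redo$timer
  }
  if (n_resampled > 0L)
    warning(sprintf("resampled %d never-terminating trial(s)", n_resampled),
            call. = FALSE)
  choice <- ifelse(res$left, "left", "right")
  correct_side <- ifelse(stim$s_l > stim$s_r, "left",
                         ifelse(stim$s_r > stim$s_l, "right",
                                ifelse(runif(n) < 0.5, "left", "right")))
  data.frame(s_l = stim$s_l, s_r = stim$s_r, choice = choice,
             rt = res$dt + params$t0,
             source = ifelse(res$timer, "timer", "evidence"),
             correct = choice == correct_side,
             stringsAsFactors = FALSE)
}

# one pass of the race; returns decision times (no t0), winners, sources
race_core <- function(n, rho_l, rho_r, params, thr,
                      gamma_variance, timer_t0) {
  if (n == 0L)
    return(list(dt = numeric(0), left = logical(0), timer = logical(0)))
  t_l <- rwald_drifts(n, rho_l, params$eta_c, thr$alpha_l)
  t_r <- rwald_drifts(n, rho_r, params$eta_c, thr$alpha_r)
  if (params$model == "TRDM") {
    t_T <- rwald(n, params$rho_t, params$eta_t, 1)
    if (timer_t0 == "zero") t_T <- pmax(t_T - params$t0, 1e-12)
    timer <- t_T < pmin(t_l, t_r)
    left <- t_l <= t_r
    if (any(timer)) {
      p_left <- timer_choice_prob(rho_l[timer], rho_r[timer],
                                  params$eta_c, params$gamma, t_T[timer],
                                  variance_mode = gamma_variance)
      left[timer] <- runif(sum(timer)) < p_left
    }
    dt <- pmin(t_l, t_r, t_T)
  } else {
    timer <- rep(FALSE, n)
    left <- t_l <= t_r
    dt <- pmin(t_l, t_r)
  }
  list(dt = dt, left = left, timer = timer)
}

# rwald with a different drift per draw (shared noise and threshold)
rwald_drifts <- function(n, drift, noise, threshold) {
  drift <- rep_len(drift, n)
  out <- numeric(n)
  for (d in unique(drift)) {
    idx <- which(drift == d)
    out[idx] <- rwald(length(idx), d, noise, threshold)
  }
  out
}

#' Fraction of timer-induced choices
#'
#' Proportion of trials whose decision was triggered by the timer
#' accumulator rather than an evidence accumulator — the model's
#' account of fast guesses.
#'
#' @param trials a data frame with a `source` column
#'   (`"evidence"`/`"timer"`).
#' @return a proportion in \[0, 1\].
#' @export
timer_fraction <- function(trials) {
  if (!is.data.frame(trials) || nrow(trials) == 0L)
    stop("`trials` must be a non-empty data frame", call. = FALSE)
  if (is.null(trials$source))
    stop("`trials` lacks a `source` column", call. = FALSE)
  mean(trials$source == "timer")
}
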