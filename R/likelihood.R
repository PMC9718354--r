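#' Choice probability of a timer-triggered decision
#'
#' When the timer accumulator wins the race at time `t`, the emitted
#' choice follows the accumulated evidence with probability `gamma` and
#' is a fair coin flip otherwise:
#' \deqn{P_T(\mathrm{left}) = \gamma F_X(0) + \tfrac{1}{2}(1 - \gamma)}
#' where \eqn{X} is the difference of the two accumulated evidence
#' totals, normal with mean \eqn{(\rho_r - \rho_l) t}. The default
#' variance is \eqn{2(\eta_c t)^2} (`variance_mode = "printed"`), under
#' which the probability is independent of `t`; the alternative
#' `"diffusion"` mode uses the Brownian-difference variance
#' \eqn{2 \eta_c^2 t} instead (see the methods vignette for why both
#' are offered).
#'
#' @param rho_l,rho_r mean drift rates of the left and right evidence
#'   accumulators.
#' @param eta_c within-trial evidence noise (> 0).
#' @param gamma evidence-dependence weight in \[0, 1\].
#' @param t time of the timer's threshold crossing (s, > 0), measured
#'   on the decision clock.
#' @param variance_mode `"printed"` (default) or `"diffusion"`.
#' @return probability of a LEFT choice, in \[0, 1\]; the right-choice
#'   probability is its complement.
#' @examples
#' timer_choice_prob(1, 2, eta_c = 1, gamma = 1, t = 1)  # pnorm(-1/sqrt(2))
#' timer_choice_prob(5, -3, eta_c = 1, gamma = 0, t = 1) # 0.5, coin flip
#' @export
timer_choice_prob <- function(rho_l, rho_r, eta_c, gamma, t,
                              variance_mode = c("printed", "diffusion")) {
  variance_mode <- match.arg(variance_mode)
  stopifnot(eta_c > 0, gamma >= 0, gamma <= 1, all(t > 0))
  # F_X(0) with X ~ N((rho_r - rho_l) t, var); the printed variance
  # 2 (eta_c t)^2 cancels t, the diffusion variance 2 eta_c^2 t does not
  z <- if (variance_mode == "printed") {
    (rho_l - rho_r) / (sqrt(2) * eta_c)
  } else {
    (rho_l - rho_r) * sqrt(t) / (sqrt(2) * eta_c)
  }
  gamma * pnorm(z) + 0.5 * (1 - gamma)
}

#' Defective choice-RT density of the racing diffusion models
#'
#' Joint density of observing a given choice at response time `t` under
#' the racing diffusion model (RDM) or the timed racing diffusion model
#' (TRDM). For the TRDM, a left response at decision time \eqn{\tau}
#' arises either from the left evidence accumulator winning the
#' three-way race, or from the timer winning and the subsequent
#' evidence-weighted coin landing left:
#' \deqn{\mathrm{PDF}_{left}(t) = f_{E,l}(1 - F_{E,r})(1 - F_T)
#'   + P_T\, f_T (1 - F_{E,l})(1 - F_{E,r})}
#' with all accumulators evaluated at \eqn{\tau = t - t_0} (the shared
#' non-decision time) and \eqn{P_T} from [timer_choice_prob()]. The RDM
#' density is \eqn{f_{E,choice} (1 - F_{E,other})}. Densities are
#' *defective*: integrated over time they give the probability of that
#' choice, and under negative drifts the two choices may not exhaust
#' probability 1 (races that never terminate).
#'
#' @param t response times (s); 0 is returned for `t <= t0`.
#' @param choice `"left"` or `"right"` (scalar or vector).
#' @param params a [race_params()] object.
#' @param s_l,s_r stimulus contrasts (scalar or vectors matching `t`).
#' @param gamma_variance passed to [timer_choice_prob()] as
#'   `variance_mode`.
#' @param timer_t0 `"shared"` (default; the timer runs on the same
#'   shifted clock as the evidence accumulators) or `"zero"` (timer
#'   unshifted).
#' @return vector of non-negative densities (1/s).
#' @seealso [loglik_race()] for the dataset log-likelihood.
#' @export
drace <- function(t, choice, params, s_l, s_r,
                  gamma_variance = c("printed", "diffusion"),
                  timer_t0 = c("shared", "zero")) {
  gamma_variance <- match.arg(gamma_variance)
  timer_t0 <- match.arg(timer_t0)
  validate_race_params(params)
  n <- max(length(t), length(choice), length(s_l), length(s_r))
  t <- rep_len(t, n); choice <- rep_len(choice, n)
  s_l <- rep_len(s_l, n); s_r <- rep_len(s_r, n)
  stopifnot(all(choice %in% c("left", "right")))

  rho <- drift_rates(s_l, s_r, params$v0, params$vd, params$vs)
  al <- 2 * params$omega
  ar <- 2 * (1 - params$omega)
  tau <- t - params$t0
  out <- numeric(n)
  ok <- tau > 0
  if (!any(ok)) return(out)
  tau <- tau[ok]
  rl <- rep_len(rho$rho_l, n)[ok]
  rr <- rep_len(rho$rho_r, n)[ok]
  left <- choice[ok] == "left"

  f_win <- ifelse(left,
                  dwald_v(tau, rl, params$eta_c, al),
                  dwald_v(tau, rr, params$eta_c, ar))
  S_lose <- ifelse(left,
                   1 - pwald_v(tau, rr, params$eta_c, ar),
                   1 - pwald_v(tau, rl, params$eta_c, al))
  if (params$model == "RDM") {
    out[ok] <- f_win * S_lose
    return(out)
  }
  tau_T <- if (timer_t0 == "shared") tau else tau + params$t0
  F_T <- pwald_v(tau_T, params$rho_t, params$eta_t, 1)
  f_T <- dwald_v(tau_T, params$rho_t, params$eta_t, 1)
  p_left <- timer_choice_prob(rl, rr, params$eta_c, params$gamma, tau,
                              variance_mode = gamma_variance)
  P_T <- ifelse(left, p_left, 1 - p_left)
  S_l <- 1 - pwald_v(tau, rl, params$eta_c, al)
  S_r <- 1 - pwald_v(tau, rr, params$eta_c, ar)
  out[ok] <- f_win * S_lose * (1 - F_T) + P_T * f_T * S_l * S_r
  out
}

# internal vectorised-in-drift/threshold Wald density and CDF (tau > 0)
dwald_v <- function(tau, drift, noise, threshold) {
  exp(log(threshold) - 0.5 * log(2 * pi) - log(noise) - 1.5 * log(tau) -
        (threshold - drift * tau)^2 / (2 * noise^2 * tau))
}

pwald_v <- function(tau, drift, noise, threshold) {
  sq <- noise * sqrt(tau)
  pmin(pnorm((drift * tau - threshold) / sq) +
         exp(2 * threshold * drift / noise^2 +
               pnorm(-(drift * tau + threshold) / sq, log.p = TRUE)), 1)
}

#' Dataset log-likelihood of a racing diffusion model
#'
#' Sum over trials of the log defective choice-RT density ([drace()]).
#' Densities are floored at `1e-300` before taking the log, so a single
#' impossible trial yields a very negative but finite value rather than
#' `-Inf` (which would stall MCMC exploration at the support boundary).
#' Equal-contrast trials are scored like any others: the likelihood
#' conditions on the observed choice, never on a "correct" label.
#'
#' The computation runs in compiled code; `drace()` is the pure-R
#' reference implementation of the same density.
#'
#' @param trials a data frame with columns `rt` (s, > 0), `choice`
#'   (`"left"`/`"right"`), `s_l`, `s_r`.
#' @param params a [race_params()] object.
#' @inheritParams drace
#' @return the log-likelihood (scalar).
#' @export
loglik_race <- function(trials, params,
                        gamma_variance = c("printed", "diffusion"),
                        timer_t0 = c("shared", "zero")) {
  gamma_variance <- match.arg(gamma_variance)
  timer_t0 <- match.arg(timer_t0)
  validate_race_params(params)
  check_trials(trials)
  race_loglik_cpp(trials$rt, trials$choice == "left",
                  trials$s_l, trials$s_r,
                  params_to_vector(params),
                  params$model == "TRDM",
                  gamma_variance == "printed",
                  timer_t0 == "shared")
}

check_trials <- function(trials) {
  if (!is.data.frame(trials) || nrow(trials) == 0L)
    stop("`trials` must be a non-empty data frame", call. = FALSE)
  need <- c("rt", "choice", "s_l", "s_r")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    stop("`trials` lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(trials$rt <= 0) || any(!is.finite(trials$rt)))
    stop("all RTs must be positive and finite", call. = FALSE)
  if (!all(trials$choice %in% c("left", "right")))
    stop("`choice` must be 'left' or 'right'", call. = FALSE)
  invisible(trials)
}
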