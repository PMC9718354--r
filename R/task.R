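#' Configuration of the synthetic contrast-discrimination task
#'
#' Bundles the session structure of the 2AFC contrast-discrimination
#' task: six evenly spaced contrast levels on \[0.08, 0.99\] crossed
#' into all 36 ordered pairs, 550 trials per session (the task yields
#' 500-600 per day), a punishment scheme for incorrect responses
#' ([delay_scheme()]), truncated-normal intertrial intervals and reward
#' durations, a 150 ul/s reward flow rate, and a 10-trial window for
#' real-time side-bias correction.
#'
#' The reward-duration distribution is truncated normal with location
#' 0.1 s, SD 0.06 s and bounds \[0.2, 0.4\] s: the location lies below
#' the lower bound, which is unusual but well-defined, and its mean of
#' about 0.22 s gives the nominal 33 ul average reward. The ITI
#' distribution (location 0.6 s, SD 1 s, bounds \[0.5, 0.7\] s) is
#' nearly uniform on its bounds. Both are implemented exactly as
#' specified rather than "fixed".
#'
#' @param contrast_levels ascending contrast levels in \[0, 1\].
#' @param trials_per_session trials per simulated day.
#' @param sessions number of sessions in [generate_dataset()].
#' @param delay a [delay_scheme()].
#' @param iti location/SD/bounds (s) of the ITI distribution.
#' @param reward location/SD/bounds (s) of the reward-duration
#'   distribution.
#' @param flow_rate_ul_s reward flow rate (ul/s).
#' @param bias_window number of past choices used for bias correction.
#' @param bias_correction enable real-time side-bias correction.
#' @param lick_fun function drawing the number of blank-screen licks
#'   after an error (default: always 0; the task model has no
#'   lick-rate process).
#' @param seed integer seed recorded in dataset metadata.
#' @return an object of class `task_config` (a list).
#' @export
task_config <- function(contrast_levels = seq(0.08, 0.99, length.out = 6),
                        trials_per_session = 550L,
                        sessions = 1L,
                        delay = delay_scheme("fixed"),
                        iti = list(mean = 0.6, sd = 1, lower = 0.5,
                                   upper = 0.7),
                        reward = list(mean = 0.1, sd = 0.06, lower = 0.2,
                                      upper = 0.4),
                        flow_rate_ul_s = 150,
                        bias_window = 10L,
                        bias_correction = TRUE,
                        lick_fun = function() 0L,
                        seed = 1L) {
  stopifnot(is.numeric(contrast_levels), !is.unsorted(contrast_levels),
            all(contrast_levels >= 0 & contrast_levels <= 1),
            iti$lower < iti$upper, reward$lower < reward$upper,
            trials_per_session >= 1, sessions >= 1)
  structure(list(contrast_levels = contrast_levels,
                 trials_per_session = as.integer(trials_per_session),
                 sessions = as.integer(sessions), delay = delay,
                 iti = iti, reward = reward,
                 flow_rate_ul_s = flow_rate_ul_s,
                 bias_window = as.integer(bias_window),
                 bias_correction = isTRUE(bias_correction),
                 lick_fun = lick_fun, seed = as.integer(seed)),
            class = "task_config")
}

#' Punishment delay schemes
#'
#' Incorrect responses are punished with a between-trial delay. The
#' `"fixed"` scheme uses a 4 s base, 0.8 s per blank-screen lick, and
#' an 8 s cap. The `"exponential"` scheme derives the delay from the
#' trial's RT through a decaying exponential (see
#' [exponential_delay()]), so fast errors are punished most, with a
#' 1.5 s per-lick penalty and no cap.
#'
#' @param kind `"fixed"` or `"exponential"`.
#' @return a list of class `delay_scheme`.
#' @export
delay_scheme <- function(kind = c("fixed", "exponential")) {
  kind <- match.arg(kind)
  if (kind == "fixed")
    structure(list(kind = "fixed", base = 4, lick_penalty = 0.8, cap = 8),
              class = "delay_scheme")
  else
    structure(list(kind = "exponential", location = 0.1, scale = 1.7,
                   lick_penalty = 1.5), class = "delay_scheme")
}

#' All ordered stimulus pairs of the contrast grid
#'
#' Cartesian product of the configured contrast levels with themselves:
#' with the default six levels (0.08 to 0.99, spacing 0.182) there are
#' 36 ordered pairs, six of them equal-contrast.
#'
#' @param config a [task_config()].
#' @return data frame with columns `s_l`, `s_r`.
#' @export
contrast_grid <- function(config = task_config()) {
  g <- expand.grid(s_l = config$contrast_levels,
                   s_r = config$contrast_levels,
                   KEEP.OUT.ATTRS = FALSE)
  g[order(g$s_l, g$s_r), , drop = FALSE]
}

#' Punishment delay after an incorrect response, fixed scheme
#'
#' `min(4 + 0.8 * n_licks, 8)` seconds.
#'
#' @param n_licks number of blank-screen licks during the delay.
#' @return delay in seconds, capped at 8.
#' @export
fixed_delay <- function(n_licks = 0L) {
  if (any(n_licks < 0)) stop("`n_licks` must be non-negative", call. = FALSE)
  pmin(4 + 0.8 * n_licks, 8)
}

#' Punishment delay after an incorrect response, exponential scheme
#'
#' The base delay decays exponentially with the trial's response time,
#' \eqn{T = (1/s) \exp(-(RT - l)/s)} with location `l = 0.1` s and
#' scale `s = 1.7`, so fast errors cost most. Each blank-screen lick
#' adds 1.5 s, and the total delay is `max(T, t_passed + penalty)` with
#' no upper limit.
#'
#' @param rt response time of the incorrect trial (s, > 0).
#' @param n_licks number of blank-screen licks.
#' @param t_passed delay time already elapsed when the last lick
#'   occurred (s).
#' @param location,scale curve parameters `l` and `s`.
#' @param lick_penalty seconds added per lick.
#' @return delay in seconds.
#' @export
exponential_delay <- function(rt, n_licks = 0L, t_passed = 0,
                              location = 0.1, scale = 1.7,
                              lick_penalty = 1.5) {
  if (any(rt <= 0)) stop("`rt` must be positive", call. = FALSE)
  if (any(n_licks < 0)) stop("`n_licks` must be non-negative", call. = FALSE)
  T_base <- (1 / scale) * exp(-(rt - location) / scale)
  pmax(T_base, t_passed + lick_penalty * n_licks)
}

#' Real-time side-bias correction rule
#'
#' The probability that the next trial's correct side is rightward is
#' one minus the proportion of rightward choices in the last
#' `window` trials, so a streak of rightward licking steers upcoming
#' trials leftward (and vice versa). Shorter histories use what
#' exists.
#'
#' @param choices character vector of past choices
#'   (`"left"`/`"right"`), most recent last.
#' @param window number of trials considered.
#' @return probability of a rightward trial in \[0, 1\]; 0.5 for an
#'   empty history.
#' @export
next_side_prob <- function(choices, window = 10L) {
  if (length(choices) == 0L) return(0.5)
  recent <- utils::tail(choices, window)
  1 - mean(recent == "right")
}

# truncated normal draws by inverse-CDF
rtruncnorm <- function(n, mean, sd, lower, upper) {
  pl <- pnorm(lower, mean, sd)
  pu <- pnorm(upper, mean, sd)
  qnorm(pl + runif(n) * (pu - pl), mean, sd)
}

# analytic truncated normal mean
truncnorm_mean <- function(mean, sd, lower, upper) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  mean + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}

#' Draw an intertrial interval
#'
#' @param config a [task_config()].
#' @param n number of draws.
#' @return ITI(s) in seconds, within the configured bounds.
#' @export
draw_iti <- function(config = task_config(), n = 1L) {
  with(config$iti, rtruncnorm(n, mean, sd, lower, upper))
}

#' Draw a reward duration and volume
#'
#' Valve-opening durations are truncated-normal; the volume is duration
#' times the flow rate (150 ul/s by default).
#'
#' @param config a [task_config()].
#' @param n number of draws.
#' @return data frame with `duration_s` and `volume_ul`.
#' @export
draw_reward <- function(config = task_config(), n = 1L) {
  d <- with(config$reward, rtruncnorm(n, mean, sd, lower, upper))
  data.frame(duration_s = d, volume_ul = d * config$flow_rate_ul_s)
}

#' Expected reward volume per correct trial
#'
#' Analytic mean of the truncated-normal valve duration, rounded to the
#' valve-control resolution of 0.01 s, times the flow rate. With the
#' default configuration this is 33 ul (0.22 s).
#'
#' @param config a [task_config()].
#' @return volume in microlitres.
#' @export
expected_reward_volume <- function(config = task_config()) {
  m <- with(config$reward, truncnorm_mean(mean, sd, lower, upper))
  round(m, 2) * config$flow_rate_ul_s
}
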