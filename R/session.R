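#' Reference TRDM agents for the two delay schemes
#'
#' Two ready-made parameter sets emulating the behavioural phenotypes
#' observed under the two punishment schemes. Both share the same
#' evidence machinery (`v0 = 1.4`, `vd = 0.8`, `vs = 0.3`,
#' `eta_c = 0.45`, `t0 = 0.1`, unbiased); only the timer differs,
#' reflecting the finding that the between-trial delay scheme acts on
#' the time accumulator:
#'
#' * `agent_fast_timer()` ("fixed-delay animal"): a high-variability
#'   timer (`rho_t = 0.4`, `eta_t = 3`) whose noise drives frequent
#'   very early threshold crossings. Sessions show a bimodal RT
#'   distribution with an early fast-guess mode at near-chance accuracy
#'   and a later, accurate evidence mode, and a substantial fraction of
#'   timer-induced choices.
#' * `agent_slow_timer()` ("exponential-delay animal"): a slow, stable
#'   timer (`rho_t = 0.3`, `eta_t = 0.4`) that almost never wins the
#'   race. Sessions show a unimodal, log-normal-like RT distribution
#'   with above-chance accuracy throughout.
#'
#' @return a [race_params()] object of TRDM kind.
#' @export
agent_fast_timer <- function() {
  race_params("TRDM", omega = 0.5, t0 = 0.1, v0 = 1.4, vd = 0.8,
              vs = 0.3, eta_c = 0.45, rho_t = 0.4, eta_t = 3,
              gamma = 0.2)
}

#' @rdname agent_fast_timer
#' @export
agent_slow_timer <- function() {
  race_params("TRDM", omega = 0.5, t0 = 0.1, v0 = 1.4, vd = 0.8,
              vs = 0.3, eta_c = 0.45, rho_t = 0.3, eta_t = 0.4,
              gamma = 0.2)
}

#' Generate one synthetic behavioural session
#'
#' Runs a simulated agent through one session of the 2AFC
#' contrast-discrimination task: each trial draws a stimulus pair from
#' the contrast grid (steered by real-time side-bias correction when
#' enabled), simulates the agent's choice and RT, assigns correctness
#' (the correct side of an equal-contrast pair is drawn at random),
#' and books the consequence — a truncated-normal reward for correct
#' responses, a scheme-dependent punishment delay for errors — plus the
#' intertrial interval.
#'
#' Stimulus selection under bias correction: with probability
#' [next_side_prob()] the upcoming trial's correct side is rightward.
#' Equal-contrast pairs are drawn with their marginal grid probability
#' (6/36 under the default levels) so that, for an unbiased agent,
#' all 36 ordered conditions remain uniformly represented.
#'
#' @param agent a [race_params()] object, or a function
#'   `function(s_l, s_r)` returning a list with elements `choice`,
#'   `rt`, `source` (useful for deterministic stubs).
#' @param config a [task_config()].
#' @param session session number written into the records.
#' @param animal_id label written into the records.
#' @return a data frame of trial records with columns `animal_id`,
#'   `session`, `trial_index`, `s_l`, `s_r`, `correct_side`, `choice`,
#'   `rt`, `correct`, `iti`, `delay`, `reward_ul`, `source`.
#' @seealso [generate_dataset()] for multi-session runs with seed
#'   metadata.
#' @export
generate_session <- function(agent, config = task_config(),
                             session = 1L, animal_id = "synthetic") {
  n <- config$trials_per_session
  levels <- config$contrast_levels
  k <- length(levels)
  # unequal ordered pairs by correct side
  grid <- contrast_grid(config)
  right_pairs <- grid[grid$s_r > grid$s_l, , drop = FALSE]
  left_pairs <- grid[grid$s_l > grid$s_r, , drop = FALSE]
  p_equal <- k / k^2

  rec <- vector("list", n)
  choices <- character(0)
  for (i in seq_len(n)) {
    p_right <- if (config$bias_correction)
      next_side_prob(choices, config$bias_window) else 0.5
    if (runif(1) < p_equal) {
      lev <- levels[sample.int(k, 1L)]
      s_l <- s_r <- lev
      correct_side <- if (runif(1) < p_right) "right" else "left"
    } else if (runif(1) < p_right) {
      j <- sample.int(nrow(right_pairs), 1L)
      s_l <- right_pairs$s_l[j]; s_r <- right_pairs$s_r[j]
      correct_side <- "right"
    } else {
      j <- sample.int(nrow(left_pairs), 1L)
      s_l <- left_pairs$s_l[j]; s_r <- left_pairs$s_r[j]
      correct_side <- "left"
    }
    if (is.function(agent)) {
      resp <- agent(s_l, s_r)
    } else {
      sim <- simulate_race(agent, n = 1L, s_l = s_l, s_r = s_r)
      resp <- list(choice = sim$choice, rt = sim$rt, source = sim$source)
    }
    correct <- resp$choice == correct_side
    if (correct) {
      rew <- draw_reward(config, 1L)
      delay <- 0
      reward_ul <- rew$volume_ul
    } else {
      n_licks <- config$lick_fun()
      delay <- if (config$delay$kind == "fixed") {
        fixed_delay(n_licks)
      } else {
        exponential_delay(resp$rt, n_licks, t_passed = 0,
                          location = config$delay$location,
                          scale = config$delay$scale,
                          lick_penalty = config$delay$lick_penalty)
      }
      reward_ul <- 0
    }
    choices <- c(choices, resp$choice)
    rec[[i]] <- data.frame(
      animal_id = animal_id, session = as.integer(session),
      trial_index = i, s_l = s_l, s_r = s_r,
      correct_side = correct_side, choice = resp$choice, rt = resp$rt,
      correct = correct, iti = draw_iti(config, 1L), delay = delay,
      reward_ul = reward_ul, source = resp$source,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rec)
}

#' Generate a multi-session synthetic dataset
#'
#' Calls [generate_session()] for `config$sessions` sessions under the
#' configured seed and attaches reproducibility metadata (seed, agent
#' parameters, configuration summary) as the `"meta"` attribute.
#'
#' @inheritParams generate_session
#' @return a data frame of trial records across sessions.
#' @export
generate_dataset <- function(agent, config = task_config(),
                             animal_id = "synthetic") {
  set.seed(config$seed)
  out <- do.call(rbind, lapply(seq_len(config$sessions), function(s)
    generate_session(agent, config, session = s, animal_id = animal_id)))
  attr(out, "meta") <- list(
    seed = config$seed,
    sessions = config$sessions,
    trials_per_session = config$trials_per_session,
    delay_scheme = config$delay$kind,
    agent = if (is.function(agent)) "custom function"
            else unclass(agent)[!vapply(agent, is.null, TRUE)])
  out
}
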