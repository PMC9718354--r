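#' Box-Cox three-SD outlier culling of response times
#'
#' Estimates the Box-Cox power \eqn{\lambda} by profile maximum
#' likelihood on the RTs (via [MASS::boxcox()] on an intercept-only
#' model), transforms the RTs, and flags values farther than
#' `n_sd` standard deviations from the transformed mean. Applied
#' per animal-dataset, mirroring a per-animal preprocessing pipeline.
#'
#' @param rts vector of response times (s, > 0), length at least 20.
#' @param n_sd cut in SD units of the transformed distribution.
#' @return logical keep-mask of the same length (`TRUE` = keep). The
#'   estimated `lambda` is attached as an attribute. Degenerate input
#'   with zero variance keeps all trials with a warning.
#' @examples
#' rt <- exp(rnorm(500, -1, 0.3))
#' mean(boxcox_cull(rt))   # about 0.997
#' @export
boxcox_cull <- function(rts, n_sd = 3) {
  if (any(rts <= 0) || any(!is.finite(rts)))
    stop("RTs must be positive and finite", call. = FALSE)
  if (length(rts) < 20)
    stop("need at least 20 RTs to estimate the transform", call. = FALSE)
  if (sd(rts) == 0) {
    warning("zero-variance RTs; keeping all trials", call. = FALSE)
    mask <- rep(TRUE, length(rts))
    attr(mask, "lambda") <- NA_real_
    return(mask)
  }
  prof <- MASS::boxcox(rt ~ 1, data = data.frame(rt = rts),
                       lambda = seq(-3, 3, 0.01), plotit = FALSE)
  lambda <- prof$x[which.max(prof$y)]
  z <- if (abs(lambda) < 1e-8) log(rts) else (rts^lambda - 1) / lambda
  mask <- abs(z - mean(z)) <= n_sd * sd(z)
  attr(mask, "lambda") <- lambda
  mask
}

#' Psychometric function: choice proportion by signed contrast difference
#'
#' Proportion of rightward choices at each distinct signed contrast
#' difference `s_r - s_l`, with Wilson score confidence intervals.
#'
#' @param trials data frame with `s_l`, `s_r`, `choice`.
#' @param conf confidence level.
#' @return data frame with `diff`, `n`, `p_right`, `lower`, `upper`,
#'   ordered by `diff`.
#' @export
psychometric <- function(trials, conf = 0.95) {
  check_trials_basic(trials, c("s_l", "s_r", "choice"))
  d <- round(trials$s_r - trials$s_l, 6)
  x <- tapply(trials$choice == "right", d, sum)
  n <- tapply(d, d, length)
  ci <- wilson_ci(as.numeric(x), as.numeric(n), conf)
  out <- data.frame(diff = as.numeric(names(x)), n = as.numeric(n),
                    p_right = as.numeric(x) / as.numeric(n),
                    lower = ci$lower, upper = ci$upper)
  out[order(out$diff), , drop = FALSE]
}

wilson_ci <- function(x, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  list(lower = pmax(0, centre - half), upper = pmin(1, centre + half))
}

#' Chronometric summary: mean RT by task difficulty
#'
#' Mean response time per absolute contrast difference, with
#' normal-approximation confidence intervals; optionally split by
#' correctness.
#'
#' @param trials data frame with `s_l`, `s_r`, `rt` and (for the
#'   split) `correct`.
#' @param split_by_correctness separate correct and incorrect trials.
#' @param conf confidence level.
#' @return data frame with `abs_diff`, (`correct`,) `n`, `mean_rt`,
#'   `lower`, `upper`.
#' @export
rt_by_difficulty <- function(trials, split_by_correctness = FALSE,
                             conf = 0.95) {
  check_trials_basic(trials, c("s_l", "s_r", "rt"))
  z <- qnorm(1 - (1 - conf) / 2)
  trials$abs_diff <- round(abs(trials$s_r - trials$s_l), 6)
  grp <- if (split_by_correctness) {
    stopifnot(!is.null(trials$correct))
    list(abs_diff = trials$abs_diff, correct = trials$correct)
  } else {
    list(abs_diff = trials$abs_diff)
  }
  agg <- aggregate(trials$rt, grp,
                   function(v) c(n = length(v), m = mean(v),
                                 se = sd(v) / sqrt(length(v))))
  stats <- as.data.frame(agg$x)
  out <- cbind(agg[names(grp)], n = stats$n, mean_rt = stats$m,
               lower = stats$m - z * stats$se,
               upper = stats$m + z * stats$se)
  out[order(out$abs_diff), , drop = FALSE]
}

#' Descriptive RT-difficulty slope
#'
#' Ordinary least-squares slope of RT on absolute contrast difference,
#' a per-animal descriptive diagnostic of the chronometric effect (not
#' a substitute for inferential group-level modelling).
#'
#' @param trials data frame with `s_l`, `s_r`, `rt`.
#' @return the slope (s per unit contrast difference).
#' @export
rt_slope <- function(trials) {
  check_trials_basic(trials, c("s_l", "s_r", "rt"))
  unname(coef(lm(rt ~ abs_diff,
                 data = transform(trials,
                                  abs_diff = abs(s_r - s_l))))[2])
}

#' Accuracy as a function of response time
#'
#' Bins RTs (default 50 ms bins), computes per-bin accuracy, and fits
#' a logistic curve with the lower asymptote fixed at the 2AFC chance
#' level 0.5 and the upper asymptote bounded by 1:
#' \deqn{Acc(t) = 0.5 + (A - 0.5) \, \mathrm{logistic}((t - m)/s)}
#' by least squares weighted by bin counts.
#'
#' @param trials data frame with `rt` and `correct`.
#' @param bin_width RT bin width (s).
#' @return an object of class `acc_sigmoid`: a list with `coef`
#'   (`A`, `m`, `s`), `fun` (the fitted curve, clipped to \[0, 1\]),
#'   and the binned data.
#' @export
accuracy_vs_rt <- function(trials, bin_width = 0.05) {
  check_trials_basic(trials, c("rt", "correct"))
  bins <- floor(trials$rt / bin_width)
  acc <- tapply(trials$correct, bins, mean)
  n <- tapply(bins, bins, length)
  t_mid <- (as.numeric(names(acc)) + 0.5) * bin_width
  keep <- n >= 1
  binned <- data.frame(t = t_mid[keep], acc = as.numeric(acc)[keep],
                       n = as.numeric(n)[keep])
  if (nrow(binned) < 5)
    stop("need at least 5 non-empty RT bins", call. = FALSE)
  fit <- tryCatch(
    nls(acc ~ 0.5 + (A - 0.5) * plogis((t - m) / s), data = binned,
        weights = binned$n,
        start = list(A = min(max(binned$acc), 0.999),
                     m = stats::weighted.mean(binned$t, binned$n),
                     s = diff(range(binned$t)) / 4 + 1e-3),
        lower = c(A = 0.5, m = -Inf, s = 1e-6),
        upper = c(A = 1, m = Inf, s = Inf),
        algorithm = "port", control = list(warnOnly = TRUE)),
    error = function(e)
      stop("sigmoid fit failed: ", conditionMessage(e), call. = FALSE))
  cf <- coef(fit)
  fun <- function(t)
    pmin(pmax(0.5 + (cf[["A"]] - 0.5) * plogis((t - cf[["m"]]) / cf[["s"]]),
              0), 1)
  structure(list(coef = cf, fun = fun, binned = binned),
            class = "acc_sigmoid")
}

#' @export
print.acc_sigmoid <- function(x, ...) {
  cat("Accuracy-vs-RT sigmoid (lower asymptote 0.5):\n")
  print(round(x$coef, 4))
  invisible(x)
}

#' Theoretical reward rate for a response time
#'
#' Expected rewards per unit time for responding at time `t` with
#' accuracy `acc`, when errors incur an additional delay:
#' \deqn{RR(t) = \frac{Acc(t)}{Acc(t)\,t + (1 - Acc(t))(t + Delay(t))}}
#'
#' @param t response time(s) (s, > 0).
#' @param acc accuracy: a number, a vector matching `t`, a function of
#'   `t` (e.g. the `fun` of an [accuracy_vs_rt()] fit).
#' @param delay error delay (s): a number, vector, or function of `t`
#'   (4 under the fixed scheme; [exponential_delay()] under the
#'   exponential scheme).
#' @return reward rate(s), 1/s.
#' @examples
#' reward_rate(1, acc = 0.5, delay = 4)   # 1/6
#' reward_rate(2, acc = 1, delay = 4)     # 1/2: errors never happen
#' @export
reward_rate <- function(t, acc, delay) {
  stopifnot(all(t > 0))
  a <- if (is.function(acc)) acc(t) else acc
  d <- if (is.function(delay)) delay(t) else delay
  stopifnot(all(a >= 0 & a <= 1), all(d >= 0))
  a / (a * t + (1 - a) * (t + d))
}

check_trials_basic <- function(trials, cols) {
  if (!is.data.frame(trials) || nrow(trials) == 0L)
    stop("`trials` must be a non-empty data frame", call. = FALSE)
  miss <- setdiff(cols, names(trials))
  if (length(miss))
    stop("`trials` lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  invisible(trials)
}
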