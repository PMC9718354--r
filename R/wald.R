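#' Wald (inverse Gaussian) first-passage time distribution
#'
#' Density, distribution function and random generation for the
#' first-passage time of a single-boundary diffusion process with mean
#' drift rate `drift` (\eqn{\rho}), within-trial noise `noise`
#' (\eqn{\sigma}), absorbing threshold `threshold` (\eqn{\alpha}) and a
#' non-decision shift `shift` (\eqn{t_0}). For \eqn{\rho > 0} this is the
#' inverse Gaussian distribution with mean \eqn{\alpha/\rho} and shape
#' \eqn{(\alpha/\sigma)^2}, shifted by \eqn{t_0}. For \eqn{\rho \le 0}
#' the distribution is defective: the boundary is only reached with
#' probability \eqn{\exp(2\alpha\rho/\sigma^2) < 1}, and `rwald()`
#' returns `Inf` on the complementary event.
#'
#' The density for \eqn{t > t_0}, with \eqn{\tau = t - t_0}, is
#' \deqn{f(t) = \frac{\alpha}{\sigma\sqrt{2\pi\tau^3}}
#'   \exp\!\left(-\frac{(\alpha - \rho\tau)^2}{2\sigma^2\tau}\right)}
#' and the distribution function is
#' \deqn{F(t) = \Phi\!\left(\frac{\rho\tau - \alpha}{\sigma\sqrt{\tau}}\right)
#'   + e^{2\alpha\rho/\sigma^2}
#'     \Phi\!\left(-\frac{\rho\tau + \alpha}{\sigma\sqrt{\tau}}\right).}
#' The second term is evaluated in log space,
#' \eqn{\exp(2\alpha\rho/\sigma^2 + \log\Phi(\cdot))}, so that large
#' positive drifts do not overflow.
#'
#' @param t vector of times (s).
#' @param drift mean drift rate \eqn{\rho}; may be negative or zero.
#' @param noise within-trial drift variability \eqn{\sigma > 0}.
#' @param threshold threshold \eqn{\alpha > 0} (the models here fix it
#'   to 1.0 unless response bias splits it, see [biased_thresholds()]).
#' @param shift non-decision time \eqn{t_0 \ge 0} (s).
#' @param n number of draws for `rwald()`.
#' @return `dwald()` a density (1/s), 0 for `t <= shift`; `pwald()` a
#'   probability; `rwald()` draws in \eqn{(t_0, \infty)}, `Inf` marking
#'   paths that never reach the boundary.
#' @examples
#' dwald(1, drift = 1)          # 1/sqrt(2*pi)
#' pwald(1e6, drift = -1)       # defective mass exp(-2)
#' mean(rwald(1e4, drift = 2))  # about 1/2
#' @export
dwald <- function(t, drift, noise = 1, threshold = 1, shift = 0) {
  check_wald_spec(drift, noise, threshold, shift)
  tau <- t - shift
  out <- numeric(length(tau))
  ok <- is.finite(tau) & tau > 0
  tv <- tau[ok]
  out[ok] <- exp(log(threshold) - 0.5 * log(2 * pi) - log(noise) -
                   1.5 * log(tv) -
                   (threshold - drift * tv)^2 / (2 * noise^2 * tv))
  out
}

#' @rdname dwald
#' @export
pwald <- function(t, drift, noise = 1, threshold = 1, shift = 0) {
  check_wald_spec(drift, noise, threshold, shift)
  tau <- t - shift
  out <- numeric(length(tau))
  ok <- is.finite(tau) & tau > 0
  tv <- tau[ok]
  sq <- noise * sqrt(tv)
  term1 <- pnorm((drift * tv - threshold) / sq)
  term2 <- exp(2 * threshold * drift / noise^2 +
                 pnorm(-(drift * tv + threshold) / sq, log.p = TRUE))
  out[ok] <- pmin(term1 + term2, 1)
  out[is.finite(tau) & tau <= 0] <- 0
  # limit for t = Inf: total crossing probability
  inf <- is.infinite(tau) & tau > 0
  out[inf] <- if (drift >= 0) 1 else exp(2 * threshold * drift / noise^2)
  out
}

#' @rdname dwald
#' @export
rwald <- function(n, drift, noise = 1, threshold = 1, shift = 0) {
  check_wald_spec(drift, noise, threshold, shift)
  # |drift| floored so the zero-drift limit stays well-defined
  if (abs(drift) < 1e-10) drift <- sign(drift + .Machine$double.eps) * 1e-10
  if (drift > 0) {
    return(shift + rinvgauss(n, mean = threshold / drift,
                             shape = (threshold / noise)^2))
  }
  # negative drift: crossing happens w.p. exp(2*alpha*rho/sigma^2);
  # conditional on crossing, the first-passage time has the |drift| law
  # (reflection identity for the single-boundary Wald process)
  p_cross <- exp(2 * threshold * drift / noise^2)
  out <- rep(Inf, n)
  hit <- runif(n) < p_cross
  k <- sum(hit)
  if (k > 0)
    out[hit] <- shift + rinvgauss(k, mean = threshold / abs(drift),
                                  shape = (threshold / noise)^2)
  out
}

# Michael-Schucany-Haas inverse Gaussian sampler
rinvgauss <- function(n, mean, shape) {
  y <- rnorm(n)^2
  x <- mean + mean^2 * y / (2 * shape) -
    mean / (2 * shape) * sqrt(4 * mean * shape * y + mean^2 * y^2)
  swap <- runif(n) > mean / (mean + x)
  x[swap] <- mean^2 / x[swap]
  x
}

check_wald_spec <- function(drift, noise, threshold, shift) {
  stopifnot(is.numeric(drift), length(drift) == 1L, is.finite(drift))
  if (!is.numeric(noise) || noise <= 0)
    stop("`noise` (sigma) must be a positive number", call. = FALSE)
  if (!is.numeric(threshold) || threshold <= 0)
    stop("`threshold` (alpha) must be a positive number", call. = FALSE)
  if (!is.numeric(shift) || shift < 0)
    stop("`shift` (t0) must be non-negative", call. = FALSE)
  invisible(TRUE)
}

#' Stimulus-to-drift linking function
#'
#' Maps a pair of stimulus contrasts onto the mean drift rates of the
#' left and right evidence accumulators through a baseline, a contrast
#' difference term and a contrast summation term:
#' \deqn{\rho_l = v_0 + v_d (s_l - s_r) + v_s (s_l + s_r)}
#' \deqn{\rho_r = v_0 + v_d (s_r - s_l) + v_s (s_l + s_r)}
#'
#' @param s_l,s_r left and right stimulus contrasts in \[0, 1\]
#'   (vectorised).
#' @param v0 baseline drift rate.
#' @param vd coefficient of the contrast difference term.
#' @param vs coefficient of the contrast summation term.
#' @return a list with numeric components `rho_l` and `rho_r`.
#' @examples
#' drift_rates(0.99, 0.08, v0 = 1, vd = 2, vs = 0.5)
#' @export
drift_rates <- function(s_l, s_r, v0, vd, vs) {
  stopifnot(all(s_l >= 0 & s_l <= 1), all(s_r >= 0 & s_r <= 1))
  list(rho_l = v0 + vd * (s_l - s_r) + vs * (s_l + s_r),
       rho_r = v0 + vd * (s_r - s_l) + vs * (s_l + s_r))
}

#' Response bias as complementary thresholds
#'
#' The bias parameter \eqn{\omega \in (0, 1)} enters the race as a
#' complementary perturbation of the two choice thresholds,
#' \eqn{\alpha_l = 2\omega}, \eqn{\alpha_r = 2(1 - \omega)}, so the two
#' thresholds always sum to 2 and \eqn{\omega = 0.5} recovers the fixed
#' threshold of 1.0 for both accumulators. A lower left threshold
#' (`omega < 0.5`) makes leftward responses faster and more likely.
#' This linkage is a package convention: the
#' bias could equally enter as a start-point or drift offset, and the
#' chosen form is the simplest one that is monotone in choice
#' probability and preserves the unbiased threshold of 1.
#'
#' @param omega bias in (0, 1); 0.5 is unbiased.
#' @return list with positive `alpha_l` and `alpha_r`, summing to 2.
#' @examples
#' biased_thresholds(0.5)   # both 1.0
#' biased_thresholds(0.75)  # 1.5, 0.5
#' @export
biased_thresholds <- function(omega) {
  if (!is.numeric(omega) || any(omega <= 0) || any(omega >= 1))
    stop("`omega` must lie strictly between 0 and 1", call. = FALSE)
  list(alpha_l = 2 * omega, alpha_r = 2 * (1 - omega))
}
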