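#' Racing diffusion model parameters
#'
#' Bundles the free parameters of the racing diffusion model (`"RDM"`)
#' or the timed racing diffusion model (`"TRDM"`). Both models share a
#' response bias `omega` (which sets the two choice thresholds via
#' [biased_thresholds()]), a non-decision time `t0` shared by all
#' accumulators, the three drift-link coefficients `v0`, `vd`, `vs`
#' (see [drift_rates()]) and the within-trial evidence noise `eta_c`.
#' The TRDM adds a stimulus-independent timer accumulator with mean
#' drift `rho_t` and noise `eta_t` (threshold fixed at 1), and the
#' mixture weight `gamma` governing how strongly a timer-triggered
#' choice leans on the evidence accumulated so far (`gamma = 1` fully
#' evidence-based, `gamma = 0` a coin flip).
#'
#' @param model `"RDM"` or `"TRDM"`.
#' @param omega response bias in (0, 1); 0.5 is unbiased.
#' @param t0 non-decision time (s), non-negative.
#' @param v0,vd,vs drift-link coefficients (baseline, difference,
#'   summation).
#' @param eta_c within-trial noise of the evidence accumulators (> 0).
#' @param rho_t timer mean drift rate (> 0; TRDM only).
#' @param eta_t timer within-trial noise (> 0; TRDM only).
#' @param gamma evidence-dependence of timer-triggered choices, in
#'   (0, 1) (TRDM only).
#' @return an object of class `race_params` (a named list).
#' @examples
#' race_params("TRDM", t0 = 0.1, v0 = 1, vd = 3, vs = 0.5,
#'             eta_c = 1, rho_t = 3, eta_t = 0.5, gamma = 0.2)
#' @export
race_params <- function(model = c("TRDM", "RDM"), omega = 0.5, t0,
                        v0, vd, vs, eta_c,
                        rho_t = NULL, eta_t = NULL, gamma = NULL) {
  model <- match.arg(model)
  p <- list(model = model, omega = omega, t0 = t0, v0 = v0, vd = vd,
            vs = vs, eta_c = eta_c)
  if (model == "TRDM") {
    if (is.null(rho_t) || is.null(eta_t) || is.null(gamma))
      stop("TRDM requires `rho_t`, `eta_t` and `gamma`", call. = FALSE)
    p$rho_t <- rho_t
    p$eta_t <- eta_t
    p$gamma <- gamma
  } else if (!is.null(rho_t) || !is.null(eta_t) || !is.null(gamma)) {
    stop("RDM carries no timer parameters", call. = FALSE)
  }
  validate_race_params(p)
  structure(p, class = "race_params")
}

validate_race_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  with(p, {
    if (!num1(omega) || omega <= 0 || omega >= 1)
      stop("`omega` must be in (0, 1)", call. = FALSE)
    if (!num1(t0) || t0 < 0)
      stop("`t0` must be non-negative", call. = FALSE)
    if (!num1(v0) || !num1(vd) || !num1(vs))
      stop("drift coefficients must be finite numbers", call. = FALSE)
    if (!num1(eta_c) || eta_c <= 0)
      stop("`eta_c` must be positive", call. = FALSE)
  })
  if (p$model == "TRDM") {
    if (!is.numeric(p$rho_t) || p$rho_t <= 0)
      stop("`rho_t` must be positive", call. = FALSE)
    if (!is.numeric(p$eta_t) || p$eta_t <= 0)
      stop("`eta_t` must be positive", call. = FALSE)
    if (!is.numeric(p$gamma) || p$gamma <= 0 || p$gamma >= 1)
      stop("`gamma` must be in (0, 1)", call. = FALSE)
  }
  invisible(p)
}

# free-parameter names in canonical order
param_names <- function(model) {
  base <- c("omega", "t0", "v0", "vd", "vs", "eta_c")
  if (model == "TRDM") c(base, "rho_t", "eta_t", "gamma") else base
}

params_to_vector <- function(p) {
  unlist(p[param_names(p$model)])
}

vector_to_params <- function(theta, model) {
  p <- as.list(theta)
  names(p) <- param_names(model)
  p$model <- model
  structure(p, class = "race_params")
}

#' @export
print.race_params <- function(x, ...) {
  cat(sprintf("%s parameters (%d free):\n", x$model,
              length(param_names(x$model))))
  v <- params_to_vector(x)
  print(round(v, 4))
  invisible(x)
}
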