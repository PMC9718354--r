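#' Default priors for the racing diffusion models
#'
#' The priors of the free parameters, one row per parameter. Two
#' families are used, each parameterised by the location and scale of
#' an underlying normal:
#' * `IL(m, s)`: the parameter is `plogis(z)` with `z ~ Normal(m, s)`
#'   (inverse-logit family, support (0, 1));
#' * `LN(m, s)`: `log(parameter) ~ Normal(m, s)` (log-normal family,
#'   support (0, Inf)).
#'
#' Bias `omega` and non-decision time `t0` get `IL(0, 1.4)` (prior
#' median 0.5); the drift-rate coefficients `v0`, `vd`, `vs`, the timer
#' drift `rho_t` and both noise parameters `eta_c`, `eta_t` get
#' `LN(1.56, 1.5)` (prior median `exp(1.56)` of about 4.8, matching
#' sub-second decision times at threshold 1); the timer-choice mixture
#' `gamma` gets `IL(-1, 1.0)` (prior median about 0.27).
#'
#' @param model `"RDM"` (6 free parameters) or `"TRDM"` (9).
#' @return a data frame of class `race_priors` with columns
#'   `parameter`, `family`, `location`, `scale`.
#' @export
default_priors <- function(model = c("TRDM", "RDM")) {
  model <- match.arg(model)
  pr <- data.frame(
    parameter = c("omega", "t0", "v0", "vd", "vs", "eta_c",
                  "rho_t", "eta_t", "gamma"),
    family = c("IL", "IL", "LN", "LN", "LN", "LN", "LN", "LN", "IL"),
    location = c(0, 0, 1.56, 1.56, 1.56, 1.56, 1.56, 1.56, -1),
    scale = c(1.4, 1.4, 1.5, 1.5, 1.5, 1.5, 1.5, 1.5, 1.0),
    stringsAsFactors = FALSE)
  pr <- pr[pr$parameter %in% param_names(model), , drop = FALSE]
  rownames(pr) <- pr$parameter
  class(pr) <- c("race_priors", "data.frame")
  pr
}

#' Log prior density of a parameter set
#'
#' Sum over free parameters of the log prior density evaluated on the
#' natural scale (change-of-variables Jacobians included). Parameters
#' outside their support give `-Inf`.
#'
#' @param params a [race_params()] object, or a named numeric vector.
#' @param priors a [default_priors()]-style data frame.
#' @return scalar log density.
#' @export
prior_logpdf <- function(params, priors = NULL) {
  if (inherits(params, "race_params")) {
    if (is.null(priors)) priors <- default_priors(params$model)
    theta <- params_to_vector(params)
  } else {
    stopifnot(!is.null(priors), !is.null(names(params)))
    theta <- params
  }
  if (!setequal(names(theta), priors$parameter))
    stop("every free parameter needs exactly one prior", call. = FALSE)
  lp <- 0
  for (i in seq_len(nrow(priors))) {
    x <- theta[[priors$parameter[i]]]
    m <- priors$location[i]; s <- priors$scale[i]
    lp <- lp + switch(priors$family[i],
      IL = if (x <= 0 || x >= 1) -Inf
           else dnorm(qlogis(x), m, s, log = TRUE) - log(x * (1 - x)),
      LN = if (x <= 0) -Inf else dlnorm(x, m, s, log = TRUE),
      stop("unknown prior family: ", priors$family[i], call. = FALSE))
  }
  lp
}

# natural <-> unconstrained transforms implied by the prior families;
# on the unconstrained scale the prior of each coordinate is
# Normal(location, scale), which is what the DE-MCMC sampler uses
to_unconstrained <- function(theta, priors) {
  z <- numeric(nrow(priors))
  for (i in seq_len(nrow(priors))) {
    x <- theta[[priors$parameter[i]]]
    z[i] <- if (priors$family[i] == "IL") qlogis(x) else log(x)
  }
  names(z) <- priors$parameter
  z
}

to_natural <- function(z, priors) {
  x <- ifelse(priors$family == "IL", plogis(z), exp(z))
  names(x) <- priors$parameter
  x
}

# z-scale log prior (no Jacobian: the Normal is the prior of z itself)
prior_logpdf_z <- function(z, priors) {
  sum(dnorm(z, priors$location, priors$scale, log = TRUE))
}

# prior draws on the unconstrained scale
rprior_z <- function(n, priors) {
  matrix(rnorm(n * nrow(priors), priors$location, priors$scale),
         nrow = n, byrow = TRUE,
         dimnames = list(NULL, priors$parameter))
}
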