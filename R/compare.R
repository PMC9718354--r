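#' Bayesian information criterion
#'
#' `BIC = k * ln(n) - 2 * max_loglik`.
#'
#' @param max_loglik maximised log-likelihood.
#' @param k number of free parameters.
#' @param n number of data points (trials after culling).
#' @return the BIC value.
#' @export
bic <- function(max_loglik, k, n) {
  stopifnot(n >= 1, k >= 1)
  k * log(n) - 2 * max_loglik
}

#' Log Bayes factor approximated from BIC
#'
#' `ln BF_ij = -(BIC_i - BIC_j) / 2`; positive values favour model i.
#'
#' @param bic_i,bic_j BIC values of models i and j.
#' @return the log Bayes factor of model i over model j.
#' @export
ln_bayes_factor <- function(bic_i, bic_j) {
  -0.5 * (bic_i - bic_j)
}

#' Interpret a log Bayes factor
#'
#' Conventional evidence categories: `|ln BF|` above 1, 3 and 5 read
#' as positive, strong and very strong evidence (below 1:
#' inconclusive); the sign says which model is favoured.
#'
#' @param ln_bf log Bayes factor of model i over model j.
#' @param model_i,model_j display names.
#' @return a string such as `"very strong evidence for TRDM over RDM"`.
#' @export
interpret_lnbf <- function(ln_bf, model_i = "model i",
                           model_j = "model j") {
  mag <- abs(ln_bf)
  label <- if (mag > 5) "very strong" else if (mag > 3) "strong"
           else if (mag > 1) "positive" else "inconclusive"
  if (label == "inconclusive") return("inconclusive")
  winner <- if (ln_bf > 0) c(model_i, model_j) else c(model_j, model_i)
  sprintf("%s evidence for %s over %s", label, winner[1L], winner[2L])
}

#' Compare two fitted racing diffusion models
#'
#' BIC-based comparison of two [fit_race()] fits to the *same* trials:
#' each model's maximised log-likelihood is taken as the highest
#' likelihood over all its posterior samples (burn-in included), BIC
#' is computed with the trial count, and the BIC difference is turned
#' into an approximate log Bayes factor.
#'
#' @param fit_i,fit_j `race_fit` objects (conventionally the TRDM
#'   first, so positive `ln_bf` favours the timed model).
#' @return an object of class `race_comparison`: a list with a
#'   per-model table (`max_loglik`, `k`, `n`, `bic`), `ln_bf` of model
#'   i over model j, and the `verdict` string.
#' @export
compare_models <- function(fit_i, fit_j) {
  stopifnot(inherits(fit_i, "race_fit"), inherits(fit_j, "race_fit"))
  if (nrow(fit_i$trials) != nrow(fit_j$trials))
    warning("models were fitted to different numbers of trials",
            call. = FALSE)
  row <- function(f) {
    ll <- as.numeric(logLik(f))
    k <- length(param_names(f$model))
    n <- nrow(f$trials)
    data.frame(model = f$model, max_loglik = ll, k = k, n = n,
               bic = bic(ll, k, n))
  }
  tab <- rbind(row(fit_i), row(fit_j))
  lnbf <- ln_bayes_factor(tab$bic[1L], tab$bic[2L])
  structure(list(table = tab, ln_bf = lnbf,
                 verdict = interpret_lnbf(lnbf, tab$model[1L],
                                          tab$model[2L])),
            class = "race_comparison")
}

#' @export
print.race_comparison <- function(x, ...) {
  print(transform(x$table, max_loglik = round(max_loglik, 2),
                  bic = round(bic, 2)), row.names = FALSE)
  cat(sprintf("ln BF(%s over %s) = %.2f: %s\n", x$table$model[1L],
              x$table$model[2L], x$ln_bf, x$verdict))
  invisible(x)
}
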