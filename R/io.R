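#' Read and write trial tables
#'
#' Trial records travel as plain CSV (comma-separated, one header
#' line, UTF-8, `.` decimal separator, RTs in seconds with six
#' decimals) plus an optional JSON metadata sidecar
#' (`<file>.meta.json`) carrying the seed, configuration and agent
#' parameters attached by [generate_dataset()]. Written files
#' round-trip bit-stably through [read_trials()].
#'
#' @param trials a trial data frame.
#' @param file path of the CSV file.
#' @param meta list of metadata to write alongside; defaults to the
#'   table's `"meta"` attribute.
#' @return `read_trials()` the data frame (metadata, when present, in
#'   the `"meta"` attribute); `write_trials()` the file path,
#'   invisibly.
#' @export
write_trials <- function(trials, file, meta = attr(trials, "meta")) {
  out <- trials
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], function(x) sprintf("%.6f", x))
  if (!is.null(out$session)) out$session <- trials$session
  if (!is.null(out$trial_index)) out$trial_index <- trials$trial_index
  write.csv(out, file, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  if (!is.null(meta))
    jsonlite::write_json(meta, paste0(file, ".meta.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}

#' @rdname write_trials
#' @export
read_trials <- function(file) {
  x <- read.csv(file, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!is.null(x$correct)) x$correct <- as.logical(x$correct)
  side <- paste0(file, ".meta.json")
  if (file.exists(side))
    attr(x, "meta") <- jsonlite::read_json(side, simplifyVector = TRUE)
  x
}

#' Serialise posterior samples
#'
#' Writes a `race_samples` object (or the posterior of a `race_fit`)
#' as a long-format CSV — columns `chain`, `iteration`, `parameter`,
#' `value` — plus a JSON sidecar with the model kind, schedule, seed,
#' acceptance rate and best likelihood.
#'
#' @param samples a `race_samples` or `race_fit` object.
#' @param file path of the CSV file.
#' @return the file path, invisibly.
#' @export
write_posterior <- function(samples, file) {
  if (inherits(samples, "race_fit")) samples <- samples$posterior
  stopifnot(inherits(samples, "race_samples"))
  d <- dim(samples$draws)
  long <- data.frame(
    chain = rep(seq_len(d[1L]), times = d[2L] * d[3L]),
    iteration = rep(rep(seq_len(d[2L]), each = d[1L]), times = d[3L]),
    parameter = rep(dimnames(samples$draws)[[3L]], each = d[1L] * d[2L]),
    value = sprintf("%.8g", as.vector(samples$draws)))
  write.csv(long, file, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  meta <- samples[c("model", "n_trials", "burn", "samples", "n_chains",
                    "accept_rate", "seed", "gamma_variance", "timer_t0")]
  meta$best_loglik <- samples$best$loglik
  meta$best_params <- as.list(samples$best$params)
  jsonlite::write_json(meta, paste0(file, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}

#' @rdname write_posterior
#' @export
read_posterior <- function(file) {
  long <- read.csv(file, stringsAsFactors = FALSE)
  pars <- unique(long$parameter)
  nc <- max(long$chain)
  ni <- max(long$iteration)
  draws <- array(NA_real_, c(nc, ni, length(pars)),
                 dimnames = list(NULL, NULL, pars))
  for (p in pars) {
    sub <- long[long$parameter == p, ]
    draws[cbind(sub$chain, sub$iteration, match(p, pars))] <- sub$value
  }
  out <- list(draws = draws)
  side <- paste0(file, ".meta.json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    out <- c(out, meta[setdiff(names(meta), "best_params")])
    out$best <- list(params = unlist(meta$best_params),
                     loglik = meta$best_loglik)
  }
  class(out) <- "race_samples"
  out
}
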