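#' Persist posterior samples to delimited text
#'
#' Writes all retained draws (chains stacked, with a `chain` column) as CSV
#' preceded by a single JSON-style metadata header line (prefixed `#`)
#' recording the model label, covariate set, seed and chain protocol.
#'
#' @param fit a `fruit_fit`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_samples <- function(fit, path) {
  cfg <- fit$config
  meta <- sprintf(
    paste0('# {"label": "%s", "covariate_set": "%s", "seed": %d,',
           ' "n_chains": %d, "n_iter": %d, "n_burnin": %d, "thin": %d}'),
    fit$model$label, fit$model$design$covariate_set, cfg$seed, cfg$n_chains,
    cfg$n_iter, cfg$n_burnin, cfg$thin)
  draws <- data.frame(
    chain = rep(seq_along(fit$samples), vapply(fit$samples, nrow, 0L)),
    do.call(rbind, fit$samples), check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  write.csv(draws, con, row.names = FALSE)
  invisible(path)
}

#' Read samples written by [write_samples()]
#'
#' @param path file written by [write_samples()].
#' @return list with `meta` (the header line, sans prefix) and `draws`
#'   (data frame including the `chain` column).
#' @export
read_samples <- function(path) {
  meta <- sub("^# ", "", readLines(path, n = 1))
  draws <- read.csv(path, skip = 1, check.names = FALSE)
  list(meta = meta, draws = draws)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic PSRF from between- and within-chain variances:
#' `Rhat = sqrt(((n-1)/n * W + B/n) / W)`. Values near 1 indicate the
#' chains have mixed; 1.1 is the conventional convergence threshold used
#' throughout the package.
#'
#' @param x a `fruit_fit` or a list of draw matrices (one per chain, equal
#'   dimensions, named columns).
#' @return named numeric vector of Rhat per parameter (`NaN` for
#'   zero-variance parameters, which are reported as 1).
#' @export
gelman_rubin <- function(x) {
  chains <- if (inherits(x, "fruit_fit")) x$samples else x
  m <- length(chains)
  if (m < 2) stopf("need >= 2 chains for the Gelman-Rubin diagnostic; rerun with a multi-chain mcmc_config()")
  n <- nrow(chains[[1]])
  if (n < 10) stopf("need >= 10 retained draws per chain")
  means <- sapply(chains, colMeans)
  vars <- sapply(chains, function(ch) apply(ch, 2, var))
  if (is.null(dim(means))) { means <- rbind(means); vars <- rbind(vars) }
  W <- rowMeans(vars)
  B_over_n <- apply(means, 1, var)
  rhat <- sqrt(((n - 1) / n * W + B_over_n) / W)
  rhat[W == 0 & B_over_n == 0] <- 1
  # values below 1 are estimator noise; report the nominal floor
  setNames(pmax(rhat, 1), colnames(chains[[1]]))
}

# Effective sample size via the lag-autocorrelation spectral estimate
# (AR-model spectrum at frequency zero), summed over chains.
ess_one <- function(v) {
  n <- length(v)
  if (var(v) == 0) return(n)
  sp <- tryCatch(ar(v, aic = TRUE, order.max = min(30, n - 1)),
                 error = function(e) NULL)
  if (is.null(sp)) return(n)
  s0 <- sp$var.pred / (1 - sum(sp$ar))^2
  max(1, min(n, n * var(v) / s0))
}

#' Summarize the posterior distribution
#'
#' Per-parameter posterior mean, SD, two interval constructions at 95% and
#' 87% coverage (SD-based: mean +- 2 SD and +- 1.5 SD; and central
#' quantile intervals), the Gelman-Rubin Rhat, and an effective sample
#' size. Warns when any Rhat is at or above 1.1.
#'
#' @param fit a `fruit_fit` (or list of chain matrices).
#' @param params optional character vector restricting the parameters.
#' @return data frame of class `posterior_summary`, one row per parameter:
#'   `mean`, `sd`, `sd95_lo/hi`, `sd87_lo/hi`, `q2.5`, `q97.5`, `q6.5`,
#'   `q93.5`, `rhat`, `ess`.
#' @export
summarize_posterior <- function(fit, params = NULL) {
  chains <- if (inherits(fit, "fruit_fit")) fit$samples else fit
  if (!length(chains) || !nrow(chains[[1]])) stopf("empty samples")
  if (!is.null(params))
    chains <- lapply(chains, function(ch) ch[, params, drop = FALSE])
  all_draws <- do.call(rbind, chains)
  mn <- colMeans(all_draws)
  sdv <- apply(all_draws, 2, sd)
  qs <- t(apply(all_draws, 2, quantile, c(0.025, 0.975, 0.065, 0.935)))
  rhat <- if (length(chains) >= 2 && nrow(chains[[1]]) >= 10)
    gelman_rubin(chains) else rep(NA_real_, length(mn))
  ess <- apply(all_draws, 2, ess_one)
  out <- data.frame(parameter = names(mn), mean = mn, sd = sdv,
                    sd95_lo = mn - 2 * sdv, sd95_hi = mn + 2 * sdv,
                    sd87_lo = mn - 1.5 * sdv, sd87_hi = mn + 1.5 * sdv,
                    q2.5 = qs[, 1], q97.5 = qs[, 2],
                    q6.5 = qs[, 3], q93.5 = qs[, 4],
                    rhat = rhat, ess = ess,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (any(is.finite(out$rhat) & out$rhat >= 1.1))
    warnf("%d parameter(s) have Rhat >= 1.1; chains may not have converged",
          sum(is.finite(out$rhat) & out$rhat >= 1.1))
  class(out) <- c("posterior_summary", "data.frame")
  out
}
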