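# Internal numeric helpers shared across modules.

# log(plogis(x)) computed stably: log sigma(x) = -log1p(exp(-x)).
# NaN inputs (e.g. from overflowed proposals) propagate to NaN so the
# sampler can reject them.
log_sigmoid <- function(x) {
  out <- x
  pos <- which(x >= 0)
  neg <- which(x < 0)
  out[pos] <- -log1p(exp(-x[pos]))
  out[neg] <- x[neg] - log1p(exp(x[neg]))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x == floor(x) && x >= 0

# Deterministic derived seeds that stay inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483629) + 1L
}

#' Random-walk Metropolis sampler for a generic log-density
#'
#' A minimal adaptive random-walk Metropolis sampler over an unconstrained
#' real vector. This is the primitive the model samplers are built from; it
#' is exported so that its correctness can be checked directly against
#' closed-form posteriors (e.g. a conjugate normal-mean model).
#'
#' @param log_post function taking a numeric vector, returning a scalar
#'   log-density (unnormalized).
#' @param init numeric vector of starting values.
#' @param n_iter total iterations.
#' @param n_burnin iterations discarded; proposal scale adapts only here.
#' @param scale initial proposal standard deviation.
#' @param target target acceptance rate for adaptation.
#' @param seed integer seed.
#' @return matrix of retained draws (rows = iterations after burn-in).
#' @examples
#' draws <- rw_metropolis(function(x) -0.5 * x^2, 0, 4000, 1000, seed = 1)
#' mean(draws)
#' @export
rw_metropolis <- function(log_post, init, n_iter, n_burnin = floor(n_iter / 4),
                          scale = 1, target = 0.234, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- length(init)
  if (d == 1L) target <- max(target, 0.44)
  x <- as.numeric(init)
  lp <- log_post(x)
  if (!is.finite(lp)) stopf("log_post not finite at init")
  ls <- log(scale)
  keep <- matrix(NA_real_, n_iter - n_burnin, d)
  for (t in seq_len(n_iter)) {
    prop <- x + exp(ls) * rnorm(d)
    lp_prop <- log_post(prop)
    acc <- is.finite(lp_prop) && log(runif(1)) < lp_prop - lp
    if (acc) {
      x <- prop
      lp <- lp_prop
    }
    if (t <= n_burnin) ls <- ls + t^-0.6 * ((if (acc) 1 else 0) - target)
    if (t > n_burnin) keep[t - n_burnin, ] <- x
  }
  keep
}
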