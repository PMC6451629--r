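# Shared numerical helpers.

# 99% two-sided normal quantile used throughout (2.5758...)
z99 <- function() stats::qnorm(0.995)

#' Round half away from zero
#'
#' Reported percentages use commercial rounding (0.5 rounds away from zero),
#' not banker's rounding; full precision is retained internally.
#'
#' @param x numeric vector
#' @param digits integer number of decimal places
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Derive a reproducible substream seed (< 2^31) from a master seed and a
# stage label, so e.g. changing the number of bootstrap draws never perturbs
# the simulation stream.
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 7919 + h * 104729) %% .Machine$integer.max)
}

# Multivariate normal draws via eigen decomposition, with the PSD repair
# contract used for parameter-simulation intervals: small negative
# eigenvalues are floored at zero; a covariance that is badly indefinite
# (negative mass beyond numerical noise) is an error.
mvn_draws <- function(mean, sigma, n, seed = NULL) {
  stopifnot(is.matrix(sigma), nrow(sigma) == ncol(sigma),
            length(mean) == nrow(sigma), n >= 1)
  if (any(!is.finite(sigma))) stop("covariance contains non-finite values", call. = FALSE)
  sigma <- (sigma + t(sigma)) / 2
  e <- eigen(sigma, symmetric = TRUE)
  tol <- 1e-8 * max(abs(e$values), 1e-300)
  if (min(e$values) < -sqrt(tol) * max(abs(e$values), 1) - 1e-6) {
    stop("covariance is not positive semi-definite and could not be repaired",
         call. = FALSE)
  }
  vals <- pmax(e$values, 0)
  if (!is.null(seed)) set.seed(seed)
  z <- matrix(stats::rnorm(n * length(mean)), nrow = length(mean))
  drop_dims <- sqrt(vals) * z          # scale rows
  draws <- e$vectors %*% drop_dims + mean
  t(draws)                             # n x p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
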