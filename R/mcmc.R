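#' MCMC sampler settings
#'
#' Defaults follow the study convention: four chains of 2000 warm-up
#' (adaptation) iterations followed by 2000 sampling iterations, with 1000
#' posterior samples retained for reporting. Reduce for simulation studies.
#'
#' @param chains Number of chains.
#' @param warmup Warm-up iterations per chain (discarded; used to adapt
#'   random-walk scales).
#' @param draws Sampling iterations per chain.
#' @param report_draws Posterior samples subsampled for reporting.
#' @param seed Integer seed.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(chains = 4, warmup = 2000, draws = 2000,
                        report_draws = 1000, seed = 1) {
  stopifnot(chains >= 1, warmup >= 0, draws >= 1)
  structure(list(chains = chains, warmup = warmup, draws = draws,
                 report_draws = report_draws, seed = seed),
            class = "mcmc_config")
}

#' Highest posterior density interval
#'
#' The narrowest contiguous interval containing `ceiling(prob * n)` of the
#' sorted draws. Ties go to the first (lowest) such window.
#'
#' @param draws Numeric vector of posterior draws.
#' @param prob Probability mass, in (0, 1).
#' @return Numeric `c(low, high)`.
#' @export
hpdi <- function(draws, prob = 0.95) {
  if (prob <= 0 || prob >= 1) stop("prob must be in (0, 1)")
  draws <- sort(draws[is.finite(draws)])
  n <- length(draws)
  if (n < 1L) stop("no finite draws")
  w <- ceiling(prob * n)
  if (w >= n) return(c(draws[1L], draws[n]))
  widths <- draws[(w):n] - draws[1:(n - w + 1L)]
  i <- which.min(widths)
  c(draws[i], draws[i + w - 1L])
}

#' Split-chain R-hat
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half (so within-chain drift registers as between-chain variance).
#'
#' @param draws Matrix of draws, iterations x chains.
#' @return R-hat (>= 1; values below 1.01 indicate convergence).
#' @export
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  half <- floor(n / 2)
  sp <- cbind(draws[seq_len(half), , drop = FALSE],
              draws[(n - half + 1L):n, , drop = FALSE])
  m <- ncol(sp); nn <- nrow(sp)
  means <- colMeans(sp)
  vars <- apply(sp, 2L, stats::var)
  W <- mean(vars)
  B <- nn * stats::var(means)
  if (W == 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' Effective sample size
#'
#' Geyer initial-positive-sequence estimate computed per chain on pooled
#' autocorrelations, summed over chains.
#'
#' @inheritParams split_rhat
#' @return Estimated number of independent draws.
#' @export
ess_basic <- function(draws) {
  draws <- as.matrix(draws)
  per_chain <- apply(draws, 2L, function(x) {
    n <- length(x)
    if (stats::var(x) == 0) return(n)
    ac <- stats::acf(x, lag.max = min(n - 1L, 200L), plot = FALSE,
                     demean = TRUE)$acf[, 1L, 1L]
    s <- 0
    for (k in seq(2L, length(ac) - 1L, by = 2L)) {
      pair <- ac[k] + ac[k + 1L]
      if (!is.finite(pair) || pair < 0) break
      s <- s + pair
    }
    n / (1 + 2 * s)
  })
  sum(per_chain)
}

## adaptive random-walk scale update (Roberts-Rosenthal style) used by the
## Metropolis-within-Gibbs samplers during warm-up
adapt_scale <- function(scale, accepted, iter, target = 0.44) {
  scale * exp(min(0.1, 1 / sqrt(iter)) * (as.numeric(accepted) - target))
}

## log prior density of a half-Normal(0, sd) evaluated at s > 0
log_half_normal <- function(s, sd = 1) {
  if (s <= 0) return(-Inf)
  stats::dnorm(s, 0, sd, log = TRUE) + log(2)
}

## subsample rows for reporting (the study convention keeps 1000)
report_subsample <- function(x, n_keep, seed) {
  x <- as.matrix(x)
  if (nrow(x) <= n_keep) return(x)
  withr_seed(seed + 999L, ix <- sort(sample.int(nrow(x), n_keep)))
  x[ix, , drop = FALSE]
}
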