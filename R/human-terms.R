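#' Human-arrival suppression terms
#'
#' Deterministic suppression of log10 Ne following *H. sapiens* arrival at
#' `t_arr` years BP. Time runs on the BP axis, so `t < t_arr` is *after*
#' arrival. All terms are non-positive and monotone non-increasing in
#' time-since-arrival for non-negative parameters; the internal timescale of
#' 10,000 yr keeps rate parameters order-1.
#'
#' * `logistic`: `-delta / (1 + exp(-k (t_arr - t) / 1e4))` — a smooth
#'   S-shaped decline centred on the arrival time (value `-delta/2` at
#'   arrival, asymptote `-delta`).
#' * `exponential`: `-delta (1 - exp(-k (t_arr - t) / 1e4))` after arrival,
#'   0 before.
#' * `linear`: `-min(delta, b (t_arr - t) / 1e4)` after arrival, 0 before
#'   (a ramp saturating at `-delta`).
#'
#' @param t_yr Times in years BP.
#' @param trend One of `"logistic"`, `"exponential"`, `"linear"`.
#' @param t_arr Arrival time, years BP.
#' @param k Rate parameter (logistic/exponential), per 10 kyr.
#' @param delta Asymptotic drop in log10 Ne units (non-negative).
#' @param b Linear decline rate in log10 Ne per 10 kyr.
#' @return Numeric vector of log10 Ne offsets (all `<= 0`).
#' @export
human_trend_term <- function(t_yr, trend = c("logistic", "exponential", "linear"),
                             t_arr, k = 1, delta = 1, b = 1) {
  trend <- match.arg(trend)
  dt <- (t_arr - t_yr) / 1e4  # positive after arrival
  switch(trend,
    logistic = -delta / (1 + exp(-k * dt)),
    exponential = ifelse(dt > 0, -delta * (1 - exp(-k * dt)), 0),
    linear = ifelse(dt > 0, -pmin(delta, b * dt), 0)
  )
}

#' Probability-of-human-presence ramp
#'
#' A deterministic covariate rising linearly from 0 at the earliest plausible
#' arrival time to 1 at the latest: the simplest monotone stand-in for the
#' probability that humans are established by time `t`.
#'
#' @param t_yr Times in years BP.
#' @param earliest_yr,latest_yr Arrival-window bounds
#'   (`earliest_yr > latest_yr` on the BP axis).
#' @return Values in `[0, 1]`.
#' @export
human_presence_ramp <- function(t_yr, earliest_yr, latest_yr) {
  if (earliest_yr <= latest_yr)
    stop("arrival window must satisfy earliest_yr > latest_yr (BP axis)")
  p <- (earliest_yr - t_yr) / (earliest_yr - latest_yr)
  pmin(pmax(p, 0), 1)
}
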