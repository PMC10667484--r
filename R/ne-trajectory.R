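#' Effective population size trajectory
#'
#' A step function of effective population size (diploid individuals) over
#' years before present (BP). The trajectory has `m` intervals delimited by
#' `m + 1` ascending boundaries; `ne[k]` applies on the right-open interval
#' `[boundaries[k], boundaries[k + 1])`. Larger times are older.
#'
#' @param species_id Character scalar identifying the species
#'   (conventionally `Genus_species`).
#' @param boundaries Numeric vector of years BP, strictly increasing,
#'   non-negative, length `m + 1`.
#' @param ne Numeric vector of effective population sizes, positive,
#'   length `m` with `m >= 2`.
#' @return An object of class `ne_trajectory`.
#' @export
ne_trajectory <- function(species_id, boundaries, ne) {
  stopifnot(is.character(species_id), length(species_id) == 1L)
  boundaries <- as.numeric(boundaries)
  ne <- as.numeric(ne)
  if (length(boundaries) != length(ne) + 1L)
    stop("'boundaries' must have length(ne) + 1 entries")
  if (length(ne) < 2L)
    stop("a trajectory needs at least 2 intervals")
  if (any(!is.finite(boundaries)) || any(boundaries < 0))
    stop("boundaries must be finite and non-negative")
  if (any(diff(boundaries) <= 0))
    stop("boundaries must be strictly increasing")
  if (any(!is.finite(ne)) || any(ne <= 0))
    stop("ne values must be finite and positive")
  structure(list(species_id = species_id, boundaries = boundaries, ne = ne),
            class = "ne_trajectory")
}

#' @export
print.ne_trajectory <- function(x, ...) {
  cat(sprintf("<ne_trajectory> %s: %d intervals, %s-%s yr BP, Ne %s-%s\n",
              x$species_id, length(x$ne),
              format(min(x$boundaries), big.mark = ","),
              format(max(x$boundaries), big.mark = ","),
              format(signif(min(x$ne), 3), big.mark = ","),
              format(signif(max(x$ne), 3), big.mark = ",")))
  invisible(x)
}

#' Climate series on a time grid
#'
#' Step functions of mean annual temperature and precipitation over years BP,
#' with the same right-open interval semantics as [ne_trajectory()].
#'
#' @param boundaries Years BP, strictly increasing, length `m + 1`.
#' @param temp Mean annual temperature per interval (degrees C), length `m`.
#' @param precip Mean annual precipitation per interval (mm/yr), length `m`.
#' @return An object of class `climate_series`.
#' @export
climate_series <- function(boundaries, temp, precip) {
  boundaries <- as.numeric(boundaries)
  if (length(temp) != length(precip))
    stop("'temp' and 'precip' must have equal length")
  if (length(boundaries) != length(temp) + 1L)
    stop("'boundaries' must have length(temp) + 1 entries")
  if (any(diff(boundaries) <= 0))
    stop("boundaries must be strictly increasing")
  structure(list(boundaries = boundaries, temp = as.numeric(temp),
                 precip = as.numeric(precip)),
            class = "climate_series")
}

## time-weighted mean of a step function over [start, end)
step_window_mean <- function(boundaries, values, start_yr, end_yr) {
  if (!is.finite(start_yr) || !is.finite(end_yr) || start_yr >= end_yr)
    stop("window must satisfy start_yr < end_yr")
  if (start_yr < boundaries[1L] || end_yr > boundaries[length(boundaries)])
    stop(sprintf("window [%g, %g) outside series support [%g, %g)",
                 start_yr, end_yr, boundaries[1L], boundaries[length(boundaries)]))
  lo <- pmax(boundaries[-length(boundaries)], start_yr)
  hi <- pmin(boundaries[-1L], end_yr)
  w <- pmax(hi - lo, 0)
  sum(w * values) / sum(w)
}

#' Time-weighted mean of a trajectory or climate series over a window
#'
#' Integrates the step function over `[start_yr, end_yr)` and divides by the
#' window width. The window must lie inside the series support.
#'
#' @param x An [ne_trajectory()] or [climate_series()].
#' @param start_yr,end_yr Window bounds in years BP, `start_yr < end_yr`.
#' @param var For a climate series, which variable to average
#'   (`"temp"` or `"precip"`).
#' @return Numeric scalar.
#' @export
window_mean <- function(x, start_yr, end_yr, var = c("temp", "precip")) {
  UseMethod("window_mean")
}

#' @export
window_mean.ne_trajectory <- function(x, start_yr, end_yr, var = NULL) {
  step_window_mean(x$boundaries, x$ne, start_yr, end_yr)
}

#' @export
window_mean.climate_series <- function(x, start_yr, end_yr,
                                       var = c("temp", "precip")) {
  var <- match.arg(var)
  step_window_mean(x$boundaries, x[[var]], start_yr, end_yr)
}

#' Window midpoints and per-window values of a trajectory
#'
#' Convenience accessor used by the regression modules: one row per interval
#' with midpoint time and log10-transformed size.
#'
#' @param traj An [ne_trajectory()].
#' @return A data.frame with columns `species_id`, `start_yr`, `end_yr`,
#'   `mid_yr`, `ne`, `log10_ne`.
#' @export
trajectory_windows <- function(traj) {
  stopifnot(inherits(traj, "ne_trajectory"))
  m <- length(traj$ne)
  data.frame(
    species_id = traj$species_id,
    start_yr = traj$boundaries[seq_len(m)],
    end_yr = traj$boundaries[-1L],
    mid_yr = (traj$boundaries[seq_len(m)] + traj$boundaries[-1L]) / 2,
    ne = traj$ne,
    log10_ne = log10(traj$ne)
  )
}

#' Average population-size trend across trajectories
#'
#' Evaluates each species' log10 Ne on a common time grid and fits a locally
#' weighted (loess) regression of log10 Ne on log10 time pooled across
#' species, returning the fitted mean curve with a pointwise 95% band
#' (mean +/- 1.96 standard errors of the local fit).
#'
#' @param trajs List of [ne_trajectory()] objects (at least 2).
#' @param grid Numeric vector of years BP at which to evaluate; must lie
#'   inside the support of every trajectory.
#' @param span Loess span (fraction of points in each local fit).
#' @return A data.frame with columns `time_yr`, `mean_log10_ne`, `lower`,
#'   `upper`.
#' @export
average_trend <- function(trajs, grid, span = 0.3) {
  if (length(trajs) < 2L) stop("need at least 2 trajectories")
  grid <- sort(as.numeric(grid))
  if (length(grid) == 0L) stop("empty evaluation grid")
  pts <- do.call(rbind, lapply(trajs, function(tr) {
    vals <- vapply(grid, function(g) evaluate_trajectory(tr, g), numeric(1))
    data.frame(x = log10(grid), y = log10(vals))
  }))
  fit <- stats::loess(y ~ x, data = pts, span = span, degree = 1,
                      surface = "direct")
  pr <- stats::predict(fit, newdata = data.frame(x = log10(grid)), se = TRUE)
  se <- ifelse(is.finite(pr$se.fit), pr$se.fit, 0)
  data.frame(time_yr = grid, mean_log10_ne = as.numeric(pr$fit),
             lower = as.numeric(pr$fit) - 1.96 * se,
             upper = as.numeric(pr$fit) + 1.96 * se)
}

## step-function value at a single time (right-open intervals)
evaluate_trajectory <- function(traj, t_yr) {
  b <- traj$boundaries
  if (t_yr < b[1L] || t_yr >= b[length(b)]) {
    ## tolerate the upper end point (useful for grids touching the edge)
    if (isTRUE(all.equal(t_yr, b[length(b)]))) return(traj$ne[length(traj$ne)])
    stop(sprintf("time %g outside trajectory support [%g, %g)",
                 t_yr, b[1L], b[length(b)]))
  }
  traj$ne[findInterval(t_yr, b, rightmost.closed = FALSE)]
}
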