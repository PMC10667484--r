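#' A single PSMC run
#'
#' One run of the PSMC program (one `-p` setting), reduced to its final
#' iteration block: the scaled mutation and recombination parameters of the
#' last round and the per-interval (time, relative size) estimates. Times are
#' in units of 2 N0 generations; sizes are multipliers of N0.
#'
#' @param p_pattern Text label of the `-p` time-interval pattern.
#' @param theta0 Scaled mutation parameter of the final round (positive).
#' @param rho0 Scaled recombination parameter.
#' @param t Interval start times, strictly increasing with `t[1] == 0`.
#' @param lambda Relative population size multipliers, positive, same
#'   length as `t`.
#' @param n_recomb Per-interval counts of recombination events informing the
#'   estimates (same length as `t`).
#' @return An object of class `psmc_run`.
#' @export
psmc_run <- function(p_pattern, theta0, rho0, t, lambda, n_recomb) {
  t <- as.numeric(t); lambda <- as.numeric(lambda)
  n_recomb <- as.numeric(n_recomb)
  if (theta0 <= 0) stop("theta0 must be positive")
  if (length(t) != length(lambda) || length(t) != length(n_recomb))
    stop("'t', 'lambda' and 'n_recomb' must have equal length")
  if (t[1L] != 0) stop("first interval time must be 0")
  if (any(diff(t) <= 0)) stop("interval times must be strictly increasing")
  if (any(lambda <= 0)) stop("lambda values must be positive")
  structure(list(p_pattern = p_pattern, theta0 = theta0, rho0 = rho0,
                 t = t, lambda = lambda, n_recomb = n_recomb),
            class = "psmc_run")
}

#' @export
print.psmc_run <- function(x, ...) {
  cat(sprintf("<psmc_run> -p '%s': theta0 = %g, %d intervals\n",
              x$p_pattern, x$theta0, length(x$t)))
  invisible(x)
}

#' Parse PSMC program text output
#'
#' Reads PSMC-format text containing one or more runs. Each run consists of
#' iteration blocks (`RD`/`TR`/`RS`/`PA` lines, blocks terminated by `//`);
#' a new run is recognised when the `RD` round counter does not increase.
#' Only each run's final iteration block is kept, per PSMC convention.
#' `RS` lines are read as `RS k t_k lambda_k pi_k n_recomb_k`.
#'
#' @param x Path to a `.psmc` file, a single string containing the whole
#'   stream, or a character vector of lines.
#' @return A list of [psmc_run()] objects, one per run.
#' @export
parse_psmc_output <- function(x) {
  lines <- psmc_input_lines(x)
  if (length(lines) == 0L || all(!nzchar(trimws(lines))))
    stop("empty PSMC stream")
  tag <- substr(lines, 1L, 2L)
  rd_idx <- which(tag == "RD")
  if (length(rd_idx) == 0L)
    stop("no RD lines found: not PSMC output")
  block_end <- c(rd_idx[-1L] - 1L, length(lines))
  blocks <- lapply(seq_along(rd_idx), function(i) {
    parse_psmc_block(lines, rd_idx[i], block_end[i])
  })
  rd_vals <- vapply(blocks, `[[`, numeric(1), "rd")
  ## a non-increasing round counter marks the start of a new run
  run_id <- cumsum(c(TRUE, diff(rd_vals) <= 0))
  lapply(split(seq_along(blocks), run_id), function(ix) {
    b <- blocks[[ix[length(ix)]]]  # final iteration block of the run
    if (is.null(b$theta0))
      stop(sprintf("malformed PSMC block at line %d: missing TR line", b$line))
    if (length(b$t) == 0L)
      stop(sprintf("malformed PSMC block at line %d: missing RS lines", b$line))
    psmc_run(p_pattern = b$pattern %||% "", theta0 = b$theta0, rho0 = b$rho0,
             t = b$t, lambda = b$lambda, n_recomb = b$n_recomb)
  }) |> unname()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

psmc_input_lines <- function(x) {
  if (length(x) == 1L && !grepl("\n", x, fixed = TRUE) && file.exists(x))
    return(readLines(x))
  if (length(x) == 1L && grepl("\n", x, fixed = TRUE))
    return(strsplit(x, "\n", fixed = TRUE)[[1L]])
  as.character(x)
}

parse_psmc_block <- function(lines, from, to) {
  out <- list(rd = NA_real_, theta0 = NULL, rho0 = NA_real_,
              t = numeric(0), lambda = numeric(0), n_recomb = numeric(0),
              pattern = NULL, line = from)
  for (i in from:to) {
    ln <- lines[i]
    tag <- substr(ln, 1L, 2L)
    fields <- strsplit(trimws(ln), "[ \t]+")[[1L]]
    if (tag == "RD") {
      out$rd <- as.numeric(fields[2L])
    } else if (tag == "TR") {
      if (length(fields) < 3L || anyNA(suppressWarnings(as.numeric(fields[2:3]))))
        stop(sprintf("malformed TR line at line %d", i))
      out$theta0 <- as.numeric(fields[2L])
      out$rho0 <- as.numeric(fields[3L])
    } else if (tag == "RS") {
      v <- suppressWarnings(as.numeric(fields[-1L]))
      if (length(v) < 3L || anyNA(v[1:3]))
        stop(sprintf("malformed RS line at line %d", i))
      out$t <- c(out$t, v[2L])
      out$lambda <- c(out$lambda, v[3L])
      out$n_recomb <- c(out$n_recomb, if (length(v) >= 5L) v[5L] else NA_real_)
    } else if (tag == "PA") {
      out$pattern <- fields[2L]
    }
  }
  out
}

#' Write PSMC runs to a file in PSMC text format
#'
#' Emits one final-iteration block per run (`RD`, `TR`, `RS`, `PA`, `//`)
#' in the dialect read by [parse_psmc_output()]. Numeric fields carry 10
#' significant digits so that write-then-parse round-trips are exact to
#' floating-point noise.
#'
#' @param runs A [psmc_run()] or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_psmc <- function(runs, path) {
  if (inherits(runs, "psmc_run")) runs <- list(runs)
  con <- file(path, "w")
  on.exit(close(con))
  for (run in runs) {
    writeLines("RD\t20", con)
    writeLines(sprintf("TR\t%.10g\t%.10g", run$theta0, run$rho0), con)
    for (k in seq_along(run$t)) {
      writeLines(sprintf("RS\t%d\t%.10g\t%.10g\t%.10g\t%.10g",
                         k - 1L, run$t[k], run$lambda[k], 0,
                         run$n_recomb[k]), con)
    }
    writeLines(sprintf("PA\t%s", run$p_pattern), con)
    writeLines("//", con)
  }
  invisible(path)
}

#' Run-selection criterion value
#'
#' The number of recombination events supporting a run, summarised either as
#' the minimum per-interval count (default: a run is only as good as its
#' worst-supported interval) or the total across intervals.
#'
#' @param run A [psmc_run()].
#' @param criterion `"min_interval"` or `"total"`.
#' @return Numeric scalar.
#' @export
recomb_events <- function(run, criterion = c("min_interval", "total")) {
  criterion <- match.arg(criterion)
  v <- run$n_recomb
  if (all(is.na(v))) return(NA_real_)
  switch(criterion, min_interval = min(v, na.rm = TRUE),
         total = sum(v, na.rm = TRUE))
}

#' Select the best-supported PSMC run
#'
#' Picks, from several runs of the same species (different `-p` settings),
#' the run maximising the recombination-event criterion. Ties are broken by
#' first occurrence.
#'
#' @param runs Non-empty list of [psmc_run()] objects.
#' @inheritParams recomb_events
#' @return The selected [psmc_run()].
#' @export
select_run <- function(runs, criterion = c("min_interval", "total")) {
  if (inherits(runs, "psmc_run")) runs <- list(runs)
  if (length(runs) == 0L) stop("no runs to select from")
  criterion <- match.arg(criterion)
  vals <- vapply(runs, recomb_events, numeric(1), criterion = criterion)
  runs[[which.max(vals)]]
}

#' Convert a PSMC run to an effective-size trajectory in calendar years
#'
#' Applies the standard PSMC rescaling: `N0 = theta0 / (4 mu bin_size)`,
#' `Ne_k = N0 lambda_k`, and interval boundaries
#' `2 N0 t_k gen_time_yr` years BP. The final interval's upper boundary is
#' closed off by one geometric step (`t_m^2 / t_{m-1}`), since PSMC itself
#' leaves it unbounded.
#'
#' @param run A [psmc_run()].
#' @param mu Mutation rate per site per generation.
#' @param gen_time_yr Generation time in years.
#' @param bin_size Sites per PSMC input bin (PSMC default 100).
#' @param species_id Identifier attached to the trajectory.
#' @return An [ne_trajectory()].
#' @export
scale_to_real_units <- function(run, mu, gen_time_yr, bin_size = 100,
                                species_id = "species") {
  if (mu <= 0 || gen_time_yr <= 0 || bin_size <= 0)
    stop("mu, gen_time_yr and bin_size must be positive")
  n0 <- run$theta0 / (4 * mu * bin_size)
  m <- length(run$t)
  if (m < 2L) stop("run must have at least 2 intervals")
  upper_t <- if (run$t[m - 1L] > 0) run$t[m]^2 / run$t[m - 1L] else 2 * run$t[m]
  boundaries <- 2 * n0 * gen_time_yr * c(run$t, upper_t)
  ne_trajectory(species_id, boundaries, n0 * run$lambda)
}

#' Encode a trajectory as a PSMC run (inverse rescaling)
#'
#' Used by the synthetic-data generator to emit PSMC-format fixtures whose
#' parse-and-rescale round-trip reproduces the trajectory. `N0` is taken as
#' the first interval's Ne so `lambda[1] == 1`.
#'
#' @inheritParams scale_to_real_units
#' @param traj An [ne_trajectory()] whose first boundary is 0.
#' @param p_pattern Label recorded on the run's `PA` line.
#' @param n_recomb Per-interval recombination-event counts (recycled).
#' @return A [psmc_run()].
#' @export
trajectory_to_psmc <- function(traj, mu, gen_time_yr, bin_size = 100,
                               p_pattern = "4+25*2+4+6", n_recomb = 1000) {
  stopifnot(inherits(traj, "ne_trajectory"))
  if (traj$boundaries[1L] != 0)
    stop("PSMC encoding requires the first boundary to be 0 yr")
  n0 <- traj$ne[1L]
  m <- length(traj$ne)
  t <- traj$boundaries[seq_len(m)] / (2 * n0 * gen_time_yr)
  psmc_run(p_pattern = p_pattern, theta0 = 4 * n0 * mu * bin_size,
           rho0 = n0 * mu * bin_size,  # filler: rho0 unused downstream
           t = t, lambda = traj$ne / n0,
           n_recomb = rep_len(n_recomb, m))
}
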