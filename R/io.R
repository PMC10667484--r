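#' Read and write the pipeline's tabular inputs and outputs
#'
#' Species metadata is a TSV with header columns `species_id`, `mass_kg`,
#' `gen_time_yr`, `mu`, `realm`, `biome`, `iucn_census`, `met_rate_kj_day`,
#' `status`; climate is a CSV with `start_yr`, `end_yr`, `temp`, `precip`;
#' arrival windows a TSV with `realm`, `earliest_yr`, `latest_yr`;
#' trajectories a tidy CSV with `species_id`, `start_yr`, `end_yr`, `ne`.
#'
#' @param path File path.
#' @return A data.frame (or, for [read_climate()], a [climate_series()];
#'   for [read_trajectories_csv()], a named list of [ne_trajectory()]).
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
read_traits <- function(path) {
  tr <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("species_id", "mass_kg", "gen_time_yr", "mu", "realm")
  missing <- setdiff(needed, names(tr))
  if (length(missing))
    stop("traits table lacks columns: ", paste(missing, collapse = ", "))
  tr
}

#' @rdname pipeline_io
#' @param traits Species metadata data.frame.
#' @export
write_traits <- function(traits, path) {
  utils::write.table(traits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_climate <- function(path) {
  cl <- utils::read.csv(path, stringsAsFactors = FALSE)
  climate_series(c(cl$start_yr, cl$end_yr[nrow(cl)]), cl$temp, cl$precip)
}

#' @rdname pipeline_io
#' @param climate A [climate_series()].
#' @export
write_climate <- function(climate, path) {
  m <- length(climate$temp)
  utils::write.csv(
    data.frame(start_yr = climate$boundaries[seq_len(m)],
               end_yr = climate$boundaries[-1L],
               temp = climate$temp, precip = climate$precip),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_arrivals <- function(path) {
  ar <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("realm", "earliest_yr", "latest_yr") %in% names(ar)))
  if (any(ar$earliest_yr <= ar$latest_yr))
    stop("arrival windows must satisfy earliest_yr > latest_yr (BP axis)")
  ar
}

#' @rdname pipeline_io
#' @param arrivals Arrival-window data.frame.
#' @export
write_arrivals <- function(arrivals, path) {
  utils::write.table(arrivals, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @param trajs Named list of [ne_trajectory()] objects.
#' @export
write_trajectories_csv <- function(trajs, path) {
  if (inherits(trajs, "ne_trajectory")) trajs <- list(trajs)
  tab <- do.call(rbind, lapply(trajs, function(tr) {
    w <- trajectory_windows(tr)
    w[, c("species_id", "start_yr", "end_yr", "ne")]
  }))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_trajectories_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("species_id", "start_yr", "end_yr", "ne") %in% names(tab)))
  out <- lapply(split(tab, tab$species_id), function(d) {
    d <- d[order(d$start_yr), ]
    ne_trajectory(d$species_id[1L], c(d$start_yr, d$end_yr[nrow(d)]), d$ne)
  })
  out[unique(tab$species_id)]
}

#' Predict a mutation rate from generation time
#'
#' Mammalian per-generation mutation rates scale allometrically with
#' generation time; species lacking a direct estimate get one from an
#' ordinary least-squares fit of log10(mu) on log10(generation time) over a
#' calibration table of species with known rates, back-transformed at the
#' query generation time.
#'
#' @param calibration Data.frame with positive columns `gen_time_yr` and `mu`
#'   (at least 3 rows).
#' @param query_gen_time Generation time(s), years, positive.
#' @return Predicted mutation rate(s) per site per generation.
#' @export
predict_mutation_rate <- function(calibration, query_gen_time) {
  if (nrow(calibration) < 3L)
    stop("need at least 3 calibration species")
  if (any(calibration$gen_time_yr <= 0) || any(calibration$mu <= 0))
    stop("calibration values must be positive")
  if (any(query_gen_time <= 0)) stop("query generation time must be positive")
  fit <- stats::lm(log10(mu) ~ log10(gen_time_yr), data = calibration)
  10^as.numeric(stats::predict(fit,
      newdata = data.frame(gen_time_yr = query_gen_time)))
}
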