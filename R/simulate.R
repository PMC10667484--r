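#' PSMC-like time grid
#'
#' Default evaluation grid for synthetic trajectories: a first interval
#' starting at the present plus log-spaced boundaries approximating PSMC's
#' atomic-interval spacing.
#'
#' @param n Total number of boundaries (intervals = `n - 1`).
#' @param min_yr First positive boundary (years BP).
#' @param max_yr Oldest boundary (years BP).
#' @return Numeric vector `c(0, log-spaced min_yr..max_yr)` of length `n`.
#' @export
psmc_grid <- function(n = 64, min_yr = 1e3, max_yr = 3e6) {
  c(0, 10^seq(log10(min_yr), log10(max_yr), length.out = n - 1L))
}

#' Default *H. sapiens* arrival windows per biogeographic realm
#'
#' Synthetic stand-ins for realm-level arrival (Afrotropic: establishment)
#' ranges, in years BP, of the order reported in the archaeological
#' literature: early establishment in Africa, Late Pleistocene arrival in
#' Australasia and Eurasia, terminal-Pleistocene arrival in the Americas.
#'
#' @return Data.frame with columns `realm`, `earliest_yr`, `latest_yr`.
#' @export
default_arrival_windows <- function() {
  data.frame(
    realm = c("Afrotropic", "Palearctic", "Nearctic", "Neotropic",
              "Australasia"),
    earliest_yr = c(200000, 60000, 23000, 16000, 65000),
    latest_yr = c(100000, 45000, 14000, 11000, 50000)
  )
}

#' Scenario parameters for synthetic trajectories
#'
#' Bundles the generating parameters of one demographic scenario. Defaults
#' reproduce the headline study conditions: a mild long-term decline
#' breaking to a severe decline at 50 kyr BP (slopes in d log10 Ne per
#' decade of log10 time toward the present).
#'
#' @param scenario One of `"stable"`, `"piecewise_decline"`,
#'   `"climate_forced"`, `"human_logistic"`, `"human_exponential"`,
#'   `"human_linear"`, or `"climate_human"` (climate forcing plus a
#'   logistic post-arrival suppression).
#' @param base_log10_ne Log10 Ne at the oldest end of the trajectory.
#' @param pre_slope,post_slope Slopes before/after `breakpoint_yr`
#'   (negative = decline toward the present).
#' @param breakpoint_yr Breakpoint, years BP.
#' @param temp_coef,precip_coef Effects of standardised window temperature
#'   and precipitation on log10 Ne (climate scenario).
#' @param temp_lag_coef,precip_lag_coef Effects of the preceding (older)
#'   window's standardised climate.
#' @param human_k Human-trend rate per 10 kyr; `human_delta` the asymptotic
#'   log10 drop; `human_b` the linear rate (per 10 kyr).
#' @param noise_sd Gaussian observation noise on log10 Ne.
#' @return A list of class `scenario_params`.
#' @export
scenario_params <- function(scenario = "piecewise_decline",
                            base_log10_ne = 4.3,
                            pre_slope = -0.01, post_slope = -0.55,
                            breakpoint_yr = 5e4,
                            temp_coef = 0.15, precip_coef = 0.08,
                            temp_lag_coef = 0, precip_lag_coef = 0,
                            human_k = 1.5, human_delta = 1, human_b = 0.5,
                            noise_sd = 0.1) {
  scenario <- match.arg(scenario,
    c("stable", "piecewise_decline", "climate_forced", "human_logistic",
      "human_exponential", "human_linear", "climate_human"))
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (human_delta < 0) stop("human_delta must be non-negative")
  structure(list(scenario = scenario, base_log10_ne = base_log10_ne,
                 pre_slope = pre_slope, post_slope = post_slope,
                 breakpoint_yr = breakpoint_yr, temp_coef = temp_coef,
                 precip_coef = precip_coef, temp_lag_coef = temp_lag_coef,
                 precip_lag_coef = precip_lag_coef, human_k = human_k,
                 human_delta = human_delta, human_b = human_b,
                 noise_sd = noise_sd),
            class = "scenario_params")
}

#' Simulate a glacial-cycle-like climate series
#'
#' Global mean annual temperature and precipitation on fixed-width windows:
#' an asymmetric sawtooth (slow cooling, rapid deglacial warming) plus a
#' faster sinusoidal component and AR(1) noise, emulating the shape of
#' late-Quaternary glacial cycles.
#'
#' @param duration_yr Total span, years BP (must be at least 2 periods).
#' @param window_yr Window width (must divide `duration_yr`); the 1,000-yr
#'   default matches common paleoclimate compilations.
#' @param period_yr Dominant cycle period.
#' @param temp_amp,precip_amp Half-amplitudes (deg C, mm/yr), non-negative.
#' @param temp_mean,precip_mean Long-term means.
#' @param seed Integer seed; same seed gives an identical series.
#' @return A [climate_series()].
#' @export
simulate_climate <- function(duration_yr = 8e5, window_yr = 1e3,
                             period_yr = 1e5, temp_amp = 4, precip_amp = 150,
                             temp_mean = 10, precip_mean = 900, seed = 1) {
  if (temp_amp < 0 || precip_amp < 0) stop("amplitudes must be non-negative")
  if (duration_yr < 2 * period_yr) stop("duration must cover >= 2 periods")
  if (duration_yr %% window_yr != 0) stop("window_yr must divide duration_yr")
  m <- duration_yr / window_yr
  boundaries <- seq(0, duration_yr, by = window_yr)
  mid <- (boundaries[-1L] + boundaries[-(m + 1L)]) / 2
  phase <- (mid %% period_yr) / period_yr
  ## sawtooth rises slowly with age and drops fast: seen forward in time this
  ## is slow cooling into glacials and rapid deglacial warming
  saw <- ifelse(phase < 0.85, phase / 0.85, (1 - phase) / 0.15)
  cyc <- 2 * saw - 1 + 0.3 * sin(2 * pi * mid / (period_yr / 2.3))
  withr_seed(seed, {
    ar <- as.numeric(stats::filter(stats::rnorm(m, 0, 0.15), 0.8,
                                   method = "recursive"))
    temp <- temp_mean + temp_amp * (cyc + ar)
    ar2 <- as.numeric(stats::filter(stats::rnorm(m, 0, 0.15), 0.8,
                                    method = "recursive"))
    precip <- precip_mean + precip_amp * (0.8 * cyc + ar2)
  })
  climate_series(boundaries, temp, precip)
}

## evaluate a function under a seed without disturbing the caller's RNG
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Simulate species traits
#'
#' Draws a megafauna-like species pool: log-normal adult masses with a 22-kg
#' floor (the smallest species admitted to the study system), allometric
#' generation times, mutation rates increasing with generation time, field
#' metabolic rates scaling as mass^0.73, census sizes declining with mass,
#' and realms assigned round-robin. Each species carries its true
#' post-breakpoint slope `base_post_slope + mass_slope_effect * z(log10
#' mass)` plus scatter, so mass-effect recovery can be checked against
#' ground truth.
#'
#' @param n Number of species (>= 1).
#' @param mass_log_mean,mass_log_sd Mean and SD of log10 mass (kg); the
#'   defaults centre the pool near the study's 120-kg median.
#' @param mass_slope_effect True effect of standardised log10 mass on the
#'   post-breakpoint slope.
#' @param base_post_slope Mean post-breakpoint slope.
#' @param slope_sd Species-level scatter of the true slope.
#' @param mass_floor_kg Minimum admitted adult mass.
#' @param seed Integer seed.
#' @return Data.frame of traits (see [read_traits()]) plus columns
#'   `true_post_slope` and `genus`.
#' @export
simulate_species <- function(n, mass_log_mean = log10(120),
                             mass_log_sd = 0.6, mass_slope_effect = -0.1,
                             base_post_slope = -0.55, slope_sd = 0.05,
                             mass_floor_kg = 22, seed = 1) {
  if (n < 1) stop("need at least 1 species")
  realms <- default_arrival_windows()$realm
  biomes <- c("grassland", "forest", "savanna", "tundra")
  withr_seed(seed, {
    mass <- numeric(n)
    for (i in seq_len(n)) {
      repeat {
        m <- 10^stats::rnorm(1, mass_log_mean, mass_log_sd)
        if (m >= mass_floor_kg) break  # resample below the floor
      }
      mass[i] <- m
    }
    gen_time <- pmax(1.5, 3.2 * (mass / 100)^0.25 *
                       exp(stats::rnorm(n, 0, 0.1)))
    mu <- 10^(-8.6 + 0.35 * log10(gen_time) + stats::rnorm(n, 0, 0.08))
    met_rate <- 500 * mass^0.73 * exp(stats::rnorm(n, 0, 0.1))
    census <- 10^(6.2 - 0.5 * log10(mass) + stats::rnorm(n, 0, 0.4))
    zmass <- as.numeric(scale(log10(mass)))
    if (any(!is.finite(zmass))) zmass <- rep(0, n)  # n == 1 edge
    slope <- base_post_slope + mass_slope_effect * zmass +
      stats::rnorm(n, 0, slope_sd)
  })
  n_genera <- max(1L, ceiling(n * 0.7))
  genus <- sprintf("Genus%03d", ((seq_len(n) - 1L) %% n_genera) + 1L)
  data.frame(
    species_id = sprintf("%s_sp%03d", genus, seq_len(n)),
    mass_kg = mass, gen_time_yr = gen_time, mu = mu,
    realm = rep_len(realms, n), biome = rep_len(biomes, n),
    iucn_census = census, met_rate_kj_day = met_rate,
    status = "extant_included", true_post_slope = slope, genus = genus
  )
}

## window-mean climate for trajectory windows, clamping to the climate
## support (windows older than the record take its oldest window's value)
climate_at_windows <- function(climate, start_yr, end_yr) {
  sup <- range(climate$boundaries)
  get1 <- function(s, e, var) {
    s2 <- max(s, sup[1L]); e2 <- min(e, sup[2L])
    if (s2 >= e2) {  # entirely outside: clamp to the nearer edge window
      if (s >= sup[2L]) {
        m <- length(climate$temp)
        return(climate[[var]][m])
      }
      return(climate[[var]][1L])
    }
    step_window_mean(climate$boundaries, climate[[var]], s2, e2)
  }
  list(temp = mapply(get1, start_yr, end_yr, MoreArgs = list(var = "temp")),
       precip = mapply(get1, start_yr, end_yr,
                       MoreArgs = list(var = "precip")))
}

## deterministic (noise-free) log10 Ne signal of a scenario at window mids
scenario_signal <- function(params, mid_yr, start_yr, end_yr,
                            climate = NULL, t_arr = NULL) {
  base <- params$base_log10_ne
  lg <- log10(pmax(mid_yr, 1))  # first window midpoint may sit below 1 kyr
  oldest <- max(lg)
  y <- rep(base, length(mid_yr))
  if (params$scenario %in% c("piecewise_decline", "human_logistic",
                             "human_exponential", "human_linear")) {
    bp <- log10(params$breakpoint_yr)
    ## slopes act per decade of log10 time toward the present
    pre <- params$pre_slope * (oldest - pmax(lg, bp))
    post <- params$post_slope * (bp - pmin(lg, bp))
    y <- base + pre + if (params$scenario == "piecewise_decline") post else 0
  }
  if (params$scenario %in% c("climate_forced", "climate_human")) {
    if (is.null(climate)) stop("climate-forced scenarios need a climate series")
    cw <- climate_at_windows(climate, start_yr, end_yr)
    lag <- climate_at_windows(climate, end_yr,
                              end_yr + (end_yr - start_yr))
    z <- function(v) if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else v * 0
    y <- base + params$temp_coef * z(cw$temp) + params$precip_coef * z(cw$precip) +
      params$temp_lag_coef * z(lag$temp) + params$precip_lag_coef * z(lag$precip)
  }
  if (grepl("^human_", params$scenario) || params$scenario == "climate_human") {
    if (is.null(t_arr))
      stop("human scenario needs an arrival time (realm arrival window)")
    trend <- if (params$scenario == "climate_human") "logistic" else
      sub("human_", "", params$scenario)
    y <- y + human_trend_term(mid_yr, trend, t_arr = t_arr, k = params$human_k,
                              delta = params$human_delta, b = params$human_b)
  }
  y
}

#' Simulate one effective-size trajectory under a known scenario
#'
#' Builds log10 Ne from the scenario's deterministic signal evaluated at
#' window midpoints, adds Gaussian observation noise, and exponentiates.
#' Human scenarios draw the latent arrival time uniformly from the realm's
#' arrival window (mirroring the fitting-side prior).
#'
#' @param traits One-row traits data.frame (needs `species_id`, `realm`).
#' @param params A [scenario_params()].
#' @param grid Trajectory boundaries, years BP (default [psmc_grid()]).
#' @param climate A [climate_series()] (required for `climate_forced`).
#' @param arrivals Arrival-window table (required for human scenarios).
#' @param seed Integer seed.
#' @return An [ne_trajectory()] with attributes `signal` (noise-free log10
#'   Ne) and `t_arr` (the generating arrival time, or `NA`).
#' @export
simulate_trajectory <- function(traits, params, grid = psmc_grid(),
                                climate = NULL, arrivals = NULL, seed = 1) {
  stopifnot(inherits(params, "scenario_params"))
  m <- length(grid) - 1L
  start_yr <- grid[seq_len(m)]; end_yr <- grid[-1L]
  mid <- (start_yr + end_yr) / 2
  t_arr <- NA_real_
  withr_seed(seed, {
    if (grepl("^human_", params$scenario) ||
        params$scenario == "climate_human") {
      if (is.null(arrivals))
        stop("human scenario needs an arrival-window table")
      w <- arrivals[arrivals$realm == traits$realm, ]
      if (nrow(w) != 1L)
        stop("no arrival window for realm ", traits$realm)
      t_arr <- stats::runif(1, w$latest_yr, w$earliest_yr)
    }
    signal <- scenario_signal(params, mid, start_yr, end_yr,
                              climate = climate, t_arr = t_arr)
    if (params$breakpoint_yr <= grid[1L] || params$breakpoint_yr >= grid[m + 1L])
      stop("breakpoint must lie inside the trajectory support")
    y <- signal + stats::rnorm(m, 0, params$noise_sd)
  })
  out <- ne_trajectory(traits$species_id, grid, 10^y)
  attr(out, "signal") <- signal
  attr(out, "t_arr") <- t_arr
  out
}

#' Simulate a complete study dataset on disk
#'
#' Generates species traits, a climate series, arrival windows and one
#' trajectory per species under the requested scenario(s); writes the traits
#' TSV, climate CSV, arrivals TSV, tidy trajectory CSV, one PSMC-format
#' `.psmc` fixture per species (via inverse rescaling, so parsing and
#' rescaling them reproduces the trajectories exactly), and a
#' `ground_truth.json` of all generating parameters.
#'
#' @param dir Output directory (created if needed).
#' @param n_species Number of species (> 0).
#' @param scenario Scenario name, or vector recycled across species.
#' @param noise_sd Observation noise on log10 Ne.
#' @param mass_slope_effect True mass effect on the post-breakpoint slope.
#' @param grid Trajectory boundaries.
#' @param seed Integer seed governing every draw.
#' @param ... Further arguments to [scenario_params()].
#' @return Invisibly, a list with the traits, climate, arrivals,
#'   trajectories and the ground-truth list.
#' @export
simulate_dataset <- function(dir, n_species = 24,
                             scenario = "piecewise_decline", noise_sd = 0.1,
                             mass_slope_effect = -0.1, grid = psmc_grid(),
                             seed = 1, ...) {
  if (n_species <= 0) stop("n_species must be positive")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  traits <- simulate_species(n_species, mass_slope_effect = mass_slope_effect,
                             seed = seed)
  climate <- simulate_climate(seed = seed + 1L)
  arrivals <- default_arrival_windows()
  scen <- rep_len(scenario, n_species)
  trajs <- vector("list", n_species)
  truth <- vector("list", n_species)
  for (i in seq_len(n_species)) {
    params <- scenario_params(scenario = scen[i], noise_sd = noise_sd,
                              post_slope = traits$true_post_slope[i], ...)
    tr <- simulate_trajectory(traits[i, ], params, grid = grid,
                              climate = climate, arrivals = arrivals,
                              seed = seed + 100L + i)
    trajs[[i]] <- tr
    truth[[i]] <- list(species_id = traits$species_id[i], scenario = scen[i],
                       post_slope = traits$true_post_slope[i],
                       t_arr = attr(tr, "t_arr"),
                       signal_log10_ne = attr(tr, "signal"))
  }
  names(trajs) <- traits$species_id
  write_traits(traits, file.path(dir, "species.tsv"))
  write_climate(climate, file.path(dir, "climate.csv"))
  write_arrivals(arrivals, file.path(dir, "arrivals.tsv"))
  write_trajectories_csv(trajs, file.path(dir, "trajectories.csv"))
  psmc_dir <- file.path(dir, "psmc")
  dir.create(psmc_dir, showWarnings = FALSE)
  for (i in seq_len(n_species)) {
    run <- trajectory_to_psmc(trajs[[i]], mu = traits$mu[i],
                              gen_time_yr = traits$gen_time_yr[i])
    write_psmc(run, file.path(psmc_dir, paste0(traits$species_id[i], ".psmc")))
  }
  gt <- list(seed = seed, n_species = n_species, noise_sd = noise_sd,
             mass_slope_effect = mass_slope_effect, species = truth)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(traits = traits, climate = climate, arrivals = arrivals,
                 trajectories = trajs, ground_truth = gt))
}

#' Simulate a cohort with a known total-census decline
#'
#' Builds piecewise-decline trajectories whose post-breakpoint slopes are
#' calibrated (per species, by root finding on the noise-free signal) so
#' that the Holocene-mean census is exactly `1 - total_decline` times the
#' baseline-mean census; IUCN census sizes are then set consistently with a
#' per-species Ne/Nc ratio, so the generating total decline is known.
#'
#' @param n_species Cohort size.
#' @param total_decline Target fractional decline of total census from the
#'   baseline (100-742 kya) mean to the Holocene mean.
#' @param baseline Baseline window, years BP.
#' @param holocene Holocene window, years BP.
#' @param noise_sd Observation noise on log10 Ne.
#' @param ne_nc_ratio Generating Ne/Nc ratio (recycled across species).
#' @param seed Integer seed.
#' @return List with `traits`, `trajectories`, and `true_decline` (the
#'   realised noise-free total-census decline, equal to `total_decline` up
#'   to root-finding tolerance).
#' @export
simulate_decline_cohort <- function(n_species = 12, total_decline = 0.93,
                                    baseline = c(1e5, 742000),
                                    holocene = c(0, 11700), noise_sd = 0.05,
                                    ne_nc_ratio = 0.5, seed = 1) {
  traits <- simulate_species(n_species, seed = seed)
  grid <- psmc_grid()
  target_ratio <- 1 - total_decline
  ## per-species base levels decline with mass (larger species are rarer);
  ## each species' Holocene/baseline ratio is calibrated to the target, so
  ## the total-census decline equals the target whatever the levels are
  zmass <- as.numeric(scale(log10(traits$mass_kg)))
  if (any(!is.finite(zmass))) zmass <- rep(0, n_species)
  withr_seed(seed + 31L, {
    base_levels <- 4.3 - 0.4 * zmass + stats::rnorm(n_species, 0, 0.25)
    ratio <- ne_nc_ratio * exp(stats::rnorm(n_species, 0, 0.4))
  })
  trajs <- vector("list", n_species)
  for (i in seq_len(n_species)) {
    ratio_at <- function(ps) {
      p <- scenario_params(scenario = "piecewise_decline", noise_sd = 0,
                           post_slope = ps, base_log10_ne = base_levels[i])
      tr <- simulate_trajectory(traits[i, ], p, grid = grid, seed = 1)
      window_mean(tr, holocene[1L], holocene[2L]) /
        window_mean(tr, baseline[1L], baseline[2L])
    }
    ps <- stats::uniroot(function(s) log10(ratio_at(s)) - log10(target_ratio),
                         c(-3, 0), tol = 1e-10)$root
    params <- scenario_params(scenario = "piecewise_decline",
                              noise_sd = noise_sd, post_slope = ps,
                              base_log10_ne = base_levels[i])
    trajs[[i]] <- simulate_trajectory(traits[i, ], params, grid = grid,
                                      seed = seed + 200L + i)
  }
  names(trajs) <- traits$species_id
  ## census consistent with the noise-free Holocene mean and a known ratio
  hol_ne <- vapply(seq_len(n_species), function(i) {
    sig <- attr(trajs[[i]], "signal")
    tr0 <- ne_trajectory(traits$species_id[i], grid, 10^sig)
    window_mean(tr0, holocene[1L], holocene[2L])
  }, numeric(1))
  traits$iucn_census <- hol_ne / ratio
  list(traits = traits, trajectories = trajs, true_decline = total_decline)
}

#' Simulate a cohort for slope-model recovery studies
#'
#' Log-linear trajectories (one slope over the whole time range) whose
#' species slopes follow the hierarchical slope model's own generative
#' process: `s_i = base_slope + beta_mass * z(log10 mass) + N(0, slope_sd)`,
#' with Gaussian observation noise on log10 Ne. Because generator and
#' estimator share this structure, posterior coverage of `beta_mass` can be
#' checked directly.
#'
#' @param n Number of species.
#' @param beta_mass True mass effect on the slope.
#' @param base_slope Mean slope (d log10 Ne per decade toward the present).
#' @param slope_sd Species-level slope scatter.
#' @param noise_sd Observation noise on log10 Ne.
#' @param grid Trajectory boundaries.
#' @param seed Integer seed.
#' @return List with `traits`, `trajectories`, `true_beta`, `true_slopes`.
#' @export
simulate_slope_cohort <- function(n = 60, beta_mass = -0.1,
                                  base_slope = -0.25, slope_sd = 0.05,
                                  noise_sd = 0.1, grid = psmc_grid(),
                                  seed = 1) {
  traits <- simulate_species(n, seed = seed)
  z <- as.numeric(scale(log10(traits$mass_kg)))
  withr_seed(seed + 17L, {
    slopes <- base_slope + beta_mass * z + stats::rnorm(n, 0, slope_sd)
  })
  trajs <- lapply(seq_len(n), function(i) {
    params <- scenario_params(scenario = "piecewise_decline",
                              pre_slope = slopes[i], post_slope = slopes[i],
                              noise_sd = noise_sd)
    simulate_trajectory(traits[i, ], params, grid = grid,
                        seed = seed + 300L + i)
  })
  names(trajs) <- traits$species_id
  list(traits = traits, trajectories = trajs, true_beta = beta_mass,
       true_slopes = slopes)
}
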