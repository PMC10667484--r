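#' Standard reporting windows for the last 100 kyr
#'
#' Four 25-kyr windows plus the `"current"` pseudo-window (which takes
#' census sizes directly from IUCN estimates rather than from trajectories).
#'
#' @return Data.frame with `label`, `start_yr`, `end_yr` (`NA` for
#'   `"current"`).
#' @export
default_windows <- function() {
  data.frame(label = c("75-100", "50-75", "25-50", "0-25", "current"),
             start_yr = c(75000, 50000, 25000, 0, NA),
             end_yr = c(100000, 75000, 50000, 25000, NA))
}

#' Effective-to-census size ratio for one species
#'
#' The Holocene mean Ne proxies the species' current effective size; its
#' ratio to the current IUCN census estimate converts effective sizes to
#' census sizes throughout the trajectory. The baseline ratio (baseline
#' mean Ne over current census) indexes extinction risk: values above 1
#' mean the species' census has fallen below its long-term effective size.
#'
#' @param traj An [ne_trajectory()] covering the Holocene and at least part
#'   of the baseline period.
#' @param traits One-row traits data.frame (`iucn_census` may be `NA`:
#'   ratios are then undefined, not zero).
#' @param holocene Holocene window, years BP.
#' @param baseline Baseline window, years BP.
#' @return One-row data.frame: `species_id`, `holocene_ne`, `baseline_ne`,
#'   `iucn_nc`, `ne_to_nc`, `baseline_ratio`.
#' @export
ne_to_nc <- function(traj, traits, holocene = c(0, 11700),
                     baseline = c(1e5, 742000)) {
  hol <- window_mean(traj, holocene[1L], holocene[2L])
  sup <- range(traj$boundaries)
  base <- step_window_mean(traj$boundaries, traj$ne,
                           max(baseline[1L], sup[1L]),
                           min(baseline[2L], sup[2L]))
  nc <- traits$iucn_census
  defined <- length(nc) == 1L && is.finite(nc) && nc > 0
  data.frame(species_id = traj$species_id, holocene_ne = hol,
             baseline_ne = base, iucn_nc = if (defined) nc else NA_real_,
             ne_to_nc = if (defined) hol / nc else NA_real_,
             baseline_ratio = if (defined) base / nc else NA_real_)
}

#' Census size through time for one species
#'
#' Past census sizes are window-mean Ne divided by the species' Ne/Nc
#' ratio; the `"current"` window uses the IUCN census directly.
#'
#' @param traj An [ne_trajectory()].
#' @param ratio The species' [ne_to_nc()] row (must be defined).
#' @param windows Window table as from [default_windows()].
#' @return Data.frame with `species_id`, `label`, `census`.
#' @export
census_through_time <- function(traj, ratio, windows = default_windows()) {
  if (!is.finite(ratio$ne_to_nc))
    stop("undefined Ne/Nc ratio for ", traj$species_id)
  census <- vapply(seq_len(nrow(windows)), function(i) {
    if (windows$label[i] == "current") return(ratio$iucn_nc)
    window_mean(traj, windows$start_yr[i], windows$end_yr[i]) / ratio$ne_to_nc
  }, numeric(1))
  data.frame(species_id = traj$species_id, label = windows$label,
             census = census)
}

#' Ecosystem totals for one window
#'
#' Sums census, biomass and energy turnover across species. Biomass assumes
#' adult mass is 15% carbon (`Gt C = sum(census * mass_kg) * 0.15 / 1e12`);
#' energy converts per-individual daily metabolic rates from kJ/day to
#' pJ/day (`/ 1e12`). Species lacking a metabolic rate are excluded from
#' the energy total only.
#'
#' @param census_df Data.frame with `species_id` and `census` for one
#'   window.
#' @param traits Traits table (`mass_kg`, `met_rate_kj_day`).
#' @param label Window label attached to the output.
#' @return One-row data.frame: `label`, `total_census`, `total_biomass_gtc`,
#'   `total_energy_pj_day`, `n_species`.
#' @export
totals <- function(census_df, traits, label = "window") {
  ix <- match(census_df$species_id, traits$species_id)
  if (anyNA(ix)) stop("species missing from traits table")
  mass <- traits$mass_kg[ix]
  met <- traits$met_rate_kj_day[ix]
  c_tot <- sum(census_df$census)
  b_tot <- sum(census_df$census * mass) * 0.15 / 1e12
  has_met <- is.finite(met)
  if (any(!has_met))
    message(sum(!has_met), " species lack metabolic rates; ",
            "excluded from the energy total")
  e_tot <- sum(census_df$census[has_met] * met[has_met]) / 1e12
  data.frame(label = label, total_census = c_tot,
             total_biomass_gtc = b_tot, total_energy_pj_day = e_tot,
             n_species = nrow(census_df))
}

#' Percent change of ecosystem totals against the baseline
#'
#' @param totals_df Data.frame of [totals()] rows for the target windows.
#' @param baseline_row A [totals()] row for the baseline period.
#' @return Data.frame: per window, percent change
#'   (`100 (value - baseline) / baseline`) of census, biomass and energy.
#' @export
baseline_contrast <- function(totals_df, baseline_row) {
  vars <- c("total_census", "total_biomass_gtc", "total_energy_pj_day")
  if (any(unlist(baseline_row[vars]) == 0))
    stop("baseline totals contain zeros; contrasts undefined")
  out <- data.frame(label = totals_df$label)
  for (v in vars) {
    out[[paste0("pct_", sub("total_", "", v))]] <-
      100 * (totals_df[[v]] - baseline_row[[v]]) / baseline_row[[v]]
  }
  out
}

#' Census-size vs mass regression with smearing retransformation
#'
#' OLS of log10 census on log10 mass across species; predictions are
#' back-transformed with Duan's smearing factor (the mean of
#' back-transformed residuals), correcting the log-normal retransformation
#' bias. Used to impute census sizes of extinct species and extant species
#' missing from the dataset.
#'
#' @param dataset Data.frame with positive `mass_kg` and `census` (>= 10
#'   rows).
#' @return List of class `census_mass_fit`: `intercept`, `slope`, `smear`,
#'   and `predict(mass_kg)`.
#' @export
census_mass_regression <- function(dataset) {
  if (nrow(dataset) < 10L) stop("need at least 10 species")
  if (any(dataset$mass_kg <= 0) || any(dataset$census <= 0))
    stop("mass and census must be positive")
  fit <- stats::lm(log10(census) ~ log10(mass_kg), data = dataset)
  smear <- mean(10^stats::residuals(fit))
  cf <- stats::coef(fit)
  pred <- function(mass_kg) {
    if (any(mass_kg <= 0)) stop("mass must be positive")
    smear * 10^(cf[[1L]] + cf[[2L]] * log10(mass_kg))
  }
  structure(list(intercept = cf[[1L]], slope = cf[[2L]], smear = smear,
                 predict = pred),
            class = "census_mass_fit")
}

#' Historical-census calibration factor for the Ne/Nc ratio
#'
#' Pre-industrial census estimates of reference species (e.g. 19th-century
#' bison and elephant counts) can re-anchor the reconstruction: the factor
#' is the geometric mean, over references, of historical over model-implied
#' census, and multiplies all reconstructed census sizes.
#'
#' @param reference Data.frame with `species_id` and `historical_census`.
#' @param implied Data.frame with `species_id` and `implied_census` (the
#'   model-implied pre-industrial census of the same species).
#' @return Scalar multiplicative calibration factor.
#' @export
calibrate_ratio <- function(reference, implied) {
  if (nrow(reference) == 0L) stop("empty reference set")
  ix <- match(reference$species_id, implied$species_id)
  if (anyNA(ix)) stop("reference species missing from implied-census table")
  r <- reference$historical_census / implied$implied_census[ix]
  exp(mean(log(r)))
}

#' Extinction-risk summary from Ne/Nc ratios
#'
#' @param ratios Data.frame of [ne_to_nc()] rows.
#' @param traits Traits table (`mass_kg`).
#' @return List: `median_baseline_ratio`, `share_above_1` (strict),
#'   `spearman_rho` and `spearman_p` of the Ne/Nc ratio against log10
#'   mass, `n`.
#' @export
risk_summary <- function(ratios, traits) {
  ok <- is.finite(ratios$baseline_ratio)
  if (sum(ok) < 3L) stop("need at least 3 species with defined ratios")
  r <- ratios[ok, ]
  mass <- traits$mass_kg[match(r$species_id, traits$species_id)]
  ct <- suppressWarnings(
    stats::cor.test(r$ne_to_nc, log10(mass), method = "spearman",
                    exact = FALSE))
  list(median_baseline_ratio = stats::median(r$baseline_ratio),
       share_above_1 = mean(r$baseline_ratio > 1),
       spearman_rho = unname(ct$estimate), spearman_p = ct$p.value,
       n = nrow(r))
}

#' Full ecosystem-history reconstruction for a cohort
#'
#' Computes each species' Ne/Nc ratio, census through the reporting windows
#' and the baseline period, window totals, and percent contrasts against
#' the baseline. Species with undefined ratios are excluded from totals
#' (their count is reported).
#'
#' @param trajs Named list of trajectories.
#' @param traits Traits table.
#' @param windows Reporting windows (see [default_windows()]).
#' @param holocene,baseline Periods in years BP.
#' @return List: `ratios`, `totals` (one row per window plus `"baseline"`),
#'   `contrasts`, `n_excluded`.
#' @export
ecosystem_history <- function(trajs, traits, windows = default_windows(),
                              holocene = c(0, 11700),
                              baseline = c(1e5, 742000)) {
  ratios <- do.call(rbind, lapply(trajs, function(tr) {
    ne_to_nc(tr, traits[traits$species_id == tr$species_id, , drop = FALSE],
             holocene = holocene, baseline = baseline)
  }))
  defined <- is.finite(ratios$ne_to_nc)
  n_excluded <- sum(!defined)
  if (n_excluded)
    message(n_excluded, " species with undefined Ne/Nc excluded from totals")
  keep <- ratios$species_id[defined]
  wins <- rbind(windows,
                data.frame(label = "baseline", start_yr = baseline[1L],
                           end_yr = baseline[2L]))
  census <- do.call(rbind, lapply(keep, function(sp) {
    census_through_time(trajs[[sp]], ratios[ratios$species_id == sp, ],
                        windows = wins)
  }))
  tot <- do.call(rbind, lapply(split(census, census$label), function(d)
    totals(d, traits, label = d$label[1L])))
  tot <- tot[match(wins$label, tot$label), ]
  rownames(tot) <- NULL
  base_row <- tot[tot$label == "baseline", ]
  contrasts <- baseline_contrast(tot[tot$label != "baseline", ], base_row)
  list(ratios = ratios, totals = tot, contrasts = contrasts,
       n_excluded = n_excluded)
}
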