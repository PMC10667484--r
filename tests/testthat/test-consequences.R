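test_that("Ne/Nc ratios follow their defining arithmetic", {
  b <- c(0, 10^seq(3, 6, length.out = 39))
  const <- ne_trajectory("Equus_ferus", b, rep(1e4, 39))
  tra <- data.frame(species_id = "Equus_ferus", iucn_census = 1e4)
  r <- ne_to_nc(const, tra)
  expect_equal(r$ne_to_nc, 1); expect_equal(r$baseline_ratio, 1)
  tra2 <- data.frame(species_id = "Equus_ferus", iucn_census = 1e5)
  expect_equal(ne_to_nc(const, tra2)$ne_to_nc, 0.1)
  ## missing census: undefined, not zero
  tra3 <- data.frame(species_id = "Equus_ferus", iucn_census = NA)
  expect_true(is.na(ne_to_nc(const, tra3)$ne_to_nc))
  ## window means agree with 1-yr Riemann sums
  set.seed(6)
  ne <- 10^runif(39, 3, 5)
  tr <- ne_trajectory("Equus_ferus", b, ne)
  r2 <- ne_to_nc(tr, tra, holocene = c(0, 11700), baseline = c(1e5, 742000))
  expect_equal(r2$holocene_ne, riemann_mean(b, ne, 0, 11700),
               tolerance = 1e-4)
  expect_equal(r2$baseline_ne, riemann_mean(b, ne, 1e5, 742000),
               tolerance = 1e-4)
})

test_that("census reconstruction scales inversely with the ratio", {
  b <- c(0, 10^seq(3, 6, length.out = 29))
  set.seed(9)
  tr <- ne_trajectory("Bison_bison", b, 10^runif(29, 3, 5))
  traits <- data.frame(species_id = "Bison_bison", iucn_census = 5e4)
  r <- ne_to_nc(tr, traits)
  ct <- census_through_time(tr, r)
  w <- default_windows()
  for (i in 1:4)
    expect_equal(ct$census[i],
                 window_mean(tr, w$start_yr[i], w$end_yr[i]) / r$ne_to_nc)
  expect_equal(ct$census[ct$label == "current"], 5e4)
  r_half <- r; r_half$ne_to_nc <- r$ne_to_nc / 2
  ct2 <- census_through_time(tr, r_half)
  expect_equal(ct2$census[1:4], 2 * ct$census[1:4])
  r_na <- r; r_na$ne_to_nc <- NA_real_
  expect_error(census_through_time(tr, r_na), "undefined")
})

test_that("ecosystem totals perform the audited unit conversions", {
  traits <- data.frame(species_id = c("A_a", "B_b"),
                       mass_kg = c(100, 100),
                       met_rate_kj_day = c(1e4, NA))
  cen <- data.frame(species_id = c("A_a", "B_b"), census = c(1e6, 1e6))
  expect_message(tot <- totals(cen, traits, "w"), "lack metabolic")
  expect_equal(tot$total_census, 2e6)
  ## 2 x 1e6 individuals x 100 kg x 15% C / 1e12 kg/Gt
  expect_equal(tot$total_biomass_gtc, 3e-5)
  ## 1e6 x 1e4 kJ/day = 1e10 kJ/day = 0.01 pJ/day (B_b excluded)
  expect_equal(tot$total_energy_pj_day, 0.01)
  ## additivity over disjoint species sets
  t1 <- totals(cen[1, ], traits[1, ], "w")
  t2 <- totals(cen[2, ], traits[2, ], "w")
  expect_equal(t1$total_census + t2$total_census, tot$total_census)
  expect_equal(t1$total_biomass_gtc + t2$total_biomass_gtc,
               tot$total_biomass_gtc)
})

test_that("baseline contrasts recompute exactly from the totals", {
  base <- data.frame(label = "baseline", total_census = 1e6,
                     total_biomass_gtc = 0.02, total_energy_pj_day = 5)
  tgt <- data.frame(label = c("same", "crash"),
                    total_census = c(1e6, 4e4),
                    total_biomass_gtc = c(0.02, 8e-4),
                    total_energy_pj_day = c(5, 0.2))
  con <- baseline_contrast(tgt, base)
  expect_equal(con$pct_census, c(0, -96))
  expect_equal(con$pct_biomass_gtc, c(0, -96))
  expect_equal(con$pct_energy_pj_day, c(0, -96))
  zero <- base; zero$total_census <- 0
  expect_error(baseline_contrast(tgt, zero), "zero")
})

test_that("census-mass regression matches the normal equations with smearing", {
  mass <- 10^seq(1.5, 4, length.out = 12)
  exact <- data.frame(mass_kg = mass, census = 10^(8 - log10(mass)))
  fit <- census_mass_regression(exact)
  expect_equal(fit$smear, 1, tolerance = 1e-12)
  expect_equal(fit$predict(1e4), 1e4, tolerance = 1e-9)
  set.seed(2)
  noisy <- exact; noisy$census <- noisy$census * 10^rnorm(12, 0, 0.3)
  fit2 <- census_mass_regression(noisy)
  X <- cbind(1, log10(noisy$mass_kg))
  beta <- solve(crossprod(X), crossprod(X, log10(noisy$census)))
  expect_equal(c(fit2$intercept, fit2$slope), as.numeric(beta),
               tolerance = 1e-10)
  resid <- log10(noisy$census) - X %*% beta
  expect_equal(fit2$smear, mean(10^resid), tolerance = 1e-12)
  expect_error(census_mass_regression(exact[1:5, ]), "at least 10")
  bad <- exact; bad$census[1] <- -1
  expect_error(census_mass_regression(bad), "positive")
})

test_that("historical calibration is a geometric mean of census ratios", {
  implied <- data.frame(species_id = c("Bison_bison", "Loxodonta_africana"),
                        implied_census = c(3e6, 3e6))
  ref1 <- data.frame(species_id = "Bison_bison", historical_census = 3e6)
  expect_equal(calibrate_ratio(ref1, implied), 1)
  ref10 <- data.frame(species_id = "Bison_bison", historical_census = 3e7)
  expect_equal(calibrate_ratio(ref10, implied), 10)
  ref2 <- data.frame(species_id = c("Bison_bison", "Loxodonta_africana"),
                     historical_census = c(4 * 3e6, 9 * 3e6))
  expect_equal(calibrate_ratio(ref2, implied), 6)
  expect_error(calibrate_ratio(ref2[0, ], implied), "empty")
})

test_that("risk summary recomputes from the raw ratio table", {
  ratios <- data.frame(species_id = paste0("Sp_", letters[1:6]),
                       ne_to_nc = c(0.2, 0.5, 1.1, 2.0, 0.8, 1.5),
                       baseline_ratio = c(1, 1, 1, 1, 1, 1))
  traits <- data.frame(species_id = paste0("Sp_", letters[1:6]),
                       mass_kg = c(30, 80, 200, 900, 120, 400))
  rs <- risk_summary(ratios, traits)
  expect_equal(rs$median_baseline_ratio, 1)
  expect_equal(rs$share_above_1, 0)  # strictly greater than 1
  ## ratios monotone in mass: perfect rank correlation
  ratios2 <- ratios; ratios2$ne_to_nc <- rank(traits$mass_kg) / 6
  expect_equal(risk_summary(ratios2, traits)$spearman_rho, 1)
  ## independent recomputation of every summary
  set.seed(5)
  ratios3 <- data.frame(species_id = traits$species_id,
                        ne_to_nc = runif(6, 0.1, 2),
                        baseline_ratio = runif(6, 0.2, 3))
  rs3 <- risk_summary(ratios3, traits)
  expect_equal(rs3$median_baseline_ratio, median(ratios3$baseline_ratio))
  expect_equal(rs3$share_above_1, mean(ratios3$baseline_ratio > 1))
  expect_equal(rs3$spearman_rho,
               cor(ratios3$ne_to_nc, log10(traits$mass_kg),
                   method = "spearman"))
  expect_error(risk_summary(ratios3[1:2, ], traits), "at least 3")
})

test_that("the full ecosystem-history pipeline excludes undefined species and balances", {
  dir <- withr::local_tempdir()
  res <- simulate_dataset(dir, n_species = 6, noise_sd = 0.05, seed = 71)
  traits <- res$traits
  traits$iucn_census[3] <- NA
  expect_message(eh <- ecosystem_history(res$trajectories, traits),
                 "excluded")
  expect_equal(eh$n_excluded, 1L)
  expect_equal(nrow(eh$totals), 6L)  # 5 reporting windows + baseline
  expect_equal(eh$totals$n_species, rep(5L, 6))
  ## contrasts recompute from totals
  base <- eh$totals[eh$totals$label == "baseline", ]
  expect_equal(eh$contrasts$pct_census,
               100 * (eh$totals$total_census[1:5] - base$total_census) /
                 base$total_census)
})
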