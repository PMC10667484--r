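test_that("decline severity matches brute force and is scale-invariant", {
  const <- ne_trajectory("c", c(0, 10, 20, 30), c(500, 500, 500))
  expect_equal(decline_severity(const)$severity, 0)
  two <- ne_trajectory("d", c(0, 10, 20), c(100, 1000))
  expect_equal(decline_severity(two)$severity, 0.9)
  set.seed(12)
  for (i in 1:10) {
    ne <- 10^runif(12, 2, 5)
    tr <- ne_trajectory("r", c(0, sort(runif(11, 1, 1e6)), 2e6), ne)
    rec <- decline_severity(tr)
    expect_equal(rec$ne_min, min(ne))
    expect_equal(rec$ne_max, max(ne))
    expect_equal(rec$severity, 1 - min(ne) / max(ne))
    scaled <- ne_trajectory("r", tr$boundaries, ne * 3.7)
    expect_equal(decline_severity(scaled)$severity, rec$severity)
  }
  ## ties break toward the most recent occurrence
  tie <- ne_trajectory("t", c(0, 10, 20, 30, 40), c(100, 900, 100, 900))
  rec <- decline_severity(tie)
  expect_equal(rec$t_min_yr, 5)
  expect_equal(rec$t_max_yr, 15)
})

test_that("hpdi equals the exhaustive narrowest-window scan", {
  expect_equal(hpdi(1:100, 0.95), c(1, 95))
  expect_equal(diff(hpdi(1:100, 0.95)), 94)
  expect_equal(hpdi(rep(3.3, 50)), c(3.3, 3.3))
  expect_error(hpdi(1:100, 1.2), "prob")
  set.seed(8)
  for (i in 1:20) {
    draws <- switch(1 + i %% 3, rnorm(500), rexp(300), c(rnorm(200), rnorm(100, 5)))
    for (p in c(0.5, 0.9, 0.95))
      expect_equal(hpdi(draws, p), hpdi_scan(draws, p))
  }
  ## symmetric unimodal draws: interval roughly symmetric about the mode
  set.seed(9); d <- rnorm(20000)
  h <- hpdi(d, 0.9)
  expect_lt(abs(h[1] + h[2]), 0.1)
})

test_that("pooled Spearman correlation reflects monotone structure", {
  up <- ne_trajectory("u", c(0, 10, 20, 30, 40), c(10, 20, 30, 40))
  expect_equal(spearman_ne_time(list(up))$rho, 1)
  down <- ne_trajectory("d", c(0, 10, 20, 30, 40), c(40, 30, 20, 10))
  expect_equal(spearman_ne_time(list(down))$rho, -1)
  set.seed(4)
  rand <- lapply(1:6, function(i)
    ne_trajectory(paste0("r", i), c(0, sort(runif(20, 1, 1e6)), 2e6),
                  10^runif(21, 3, 5)))
  out <- spearman_ne_time(rand)
  expect_lt(abs(out$rho), 0.25)
  expect_gt(out$p, 0.001)
  tiny <- ne_trajectory("x", c(0, 1, 2), c(5, 6))
  expect_error(spearman_ne_time(list(tiny)), "at least 3")
})

test_that("genus subsetting keeps one representative per genus, deterministically", {
  traits <- data.frame(
    species_id = c("Loxodonta_africana", "Loxodonta_cyclotis",
                   "Bison_bison", "Cervus_elaphus"),
    mass_kg = c(4000, 2500, 600, 200))
  sub <- genus_subset(traits)
  expect_equal(nrow(sub), 3L)
  expect_true("Loxodonta_africana" %in% sub$species_id)  # alphabetical tie
  ## distinct genera: identity
  expect_identical(genus_subset(traits[3:4, ]), traits[3:4, ])
  ## idempotent
  expect_identical(genus_subset(sub), sub)
  ## window-count criterion beats alphabetical order
  trajs <- list(Loxodonta_africana = toy_trajectory(),
                Loxodonta_cyclotis = ne_trajectory("Loxodonta_cyclotis",
                  c(0, 10^seq(3, 6, length.out = 10)), rep(1000, 10)))
  sub2 <- genus_subset(traits, trajs)
  expect_true("Loxodonta_cyclotis" %in% sub2$species_id)
  expect_error(genus_subset(data.frame(species_id = "nounderscore")),
               "row 1")
  ## randomized: subset size equals the number of unique genera
  set.seed(2)
  g <- sample(sprintf("Genus%02d", 1:12), 40, replace = TRUE)
  tr2 <- data.frame(species_id = paste0(g, "_sp", 1:40))
  expect_equal(nrow(genus_subset(tr2)), length(unique(g)))
})

test_that("the hierarchical slope model recovers a known mass effect", {
  co <- simulate_slope_cohort(n = 40, beta_mass = -0.12, noise_sd = 0.1,
                              seed = 19)
  fit <- fit_slope_model(co$trajectories, co$traits,
                         mcmc_config(chains = 2, warmup = 400, draws = 500,
                                     seed = 5))
  h <- hpdi(fit$beta)
  expect_true(h[1] <= -0.12 && -0.12 <= h[2])
  expect_true(all(fit$rhat < 1.05))
  expect_gte(nrow(fit$slopes), 1000)
  ## per-species slope posteriors track the generating slopes
  expect_gt(cor(colMeans(fit$slopes), co$true_slopes), 0.95)
  expect_error(fit_slope_model(co$trajectories,
                               transform(co$traits, mass_kg = 100)),
               "unidentifiable")
})

test_that("slope-model posterior means agree with an independent REML fit", {
  co <- simulate_slope_cohort(n = 30, beta_mass = -0.1, noise_sd = 0.08,
                              seed = 23)
  fit <- fit_slope_model(co$trajectories, co$traits,
                         mcmc_config(chains = 2, warmup = 400, draws = 400,
                                     seed = 2))
  ## frame the same model as a linear mixed model: fixed slope and
  ## slope-by-mass interaction, random intercepts and slopes by species
  pts <- do.call(rbind, lapply(co$trajectories, function(tr) {
    w <- trajectory_windows(tr)
    x <- -log10(pmax(w$mid_yr, 1))
    data.frame(sp = w$species_id, x = x - mean(x), y = w$log10_ne)
  }))
  z <- as.numeric(scale(log10(co$traits$mass_kg)))
  pts$z <- z[match(pts$sp, co$traits$species_id)]
  lf <- lme4::lmer(y ~ x + x:z + (1 + x || sp), data = pts, REML = TRUE)
  fe <- lme4::fixef(lf)
  expect_equal(mean(fit$alpha), unname(fe["x"]), tolerance = 0.02)
  expect_equal(mean(fit$beta), unname(fe["x:z"]), tolerance = 0.02)
})

test_that("severity regression ranks the generating predictor first", {
  set.seed(3)
  n <- 60
  traits <- simulate_species(n, seed = 3)
  t_min <- runif(n, 1e3, 4e4); t_max <- runif(n, 1e5, 1e6)
  eta <- 1.2 - 1.5 * as.numeric(scale(t_min))  # t_min drives severity
  sev <- data.frame(species_id = traits$species_id,
                    severity = plogis(eta + rnorm(n, 0, 0.1)),
                    t_min_yr = t_min, t_max_yr = t_max)
  fit <- fit_severity_model(sev, traits,
                            mcmc_config(chains = 2, warmup = 300,
                                        draws = 300, seed = 4))
  expect_identical(fit$ranking[1], "z_t_min")
  expect_gt(fit$r2, 0.9)
  ## noiseless single-predictor signal: near-perfect fit
  sev0 <- sev; sev0$severity <- plogis(eta)
  fit0 <- fit_severity_model(sev0, traits,
                             mcmc_config(chains = 2, warmup = 300,
                                         draws = 300, seed = 4))
  expect_gt(fit0$r2, 0.999)
  ## boundary severities are winsorised, not fatal
  sevb <- sev; sevb$severity[1] <- 1
  expect_message(fit_severity_model(sevb, traits,
                                    mcmc_config(chains = 1, warmup = 100,
                                                draws = 100, seed = 1)),
                 "winsorised")
})

test_that("phylogenetic regression reduces to the independent model on a star tree", {
  co <- simulate_slope_cohort(n = 16, beta_mass = -0.1, noise_sd = 0.08,
                              seed = 29)
  star <- ape::stree(16, type = "star")
  star$tip.label <- co$traits$species_id
  star$edge.length <- rep(1, nrow(star$edge))
  mc <- mcmc_config(chains = 2, warmup = 400, draws = 400, seed = 6)
  f_ind <- fit_slope_model(co$trajectories, co$traits, mc)
  f_star <- fit_phylo_slope_model(co$trajectories, co$traits, star, mc)
  expect_equal(mean(f_star$beta), mean(f_ind$beta), tolerance = 0.02)
  ## lambda fixed at 0 is the independent-residual model
  set.seed(1)
  coal <- ape::rcoal(16, tip.label = co$traits$species_id)
  f_l0 <- fit_phylo_slope_model(co$trajectories, co$traits, coal,
                                mc, lambda_fixed = 0)
  expect_equal(mean(f_l0$beta), mean(f_ind$beta), tolerance = 0.02)
  ## species missing from the tree are excluded with a warning
  set.seed(2)
  small <- ape::rcoal(14, tip.label = co$traits$species_id[1:14])
  w <- testthat::capture_warnings(
    fit_phylo_slope_model(co$trajectories, co$traits, small,
                          mcmc_config(chains = 1, warmup = 100,
                                      draws = 100, seed = 1)))
  expect_true(any(grepl("excluded", w)))
  notree <- ape::stree(16, type = "star")
  notree$tip.label <- co$traits$species_id
  expect_error(fit_phylo_slope_model(co$trajectories, co$traits, notree),
               "branch lengths")
})

test_that("strong phylogenetic residual signal pushes lambda away from zero", {
  set.seed(44)
  n <- 24
  tree <- ape::rcoal(n)
  traits <- simulate_species(n, seed = 44)
  tree$tip.label <- traits$species_id
  C <- ape::vcv(tree, corr = TRUE)
  z <- as.numeric(scale(log10(traits$mass_kg)))
  ## slopes with residuals drawn from the Brownian correlation
  slopes <- -0.25 - 0.1 * z +
    as.numeric(t(chol(C)) %*% rnorm(n)) * 0.12
  grid <- psmc_grid()
  trajs <- lapply(seq_len(n), function(i) {
    par <- scenario_params("piecewise_decline", pre_slope = slopes[i],
                           post_slope = slopes[i], noise_sd = 0.05)
    simulate_trajectory(traits[i, ], par, grid = grid, seed = 600 + i)
  })
  names(trajs) <- traits$species_id
  fit <- fit_phylo_slope_model(trajs, traits, tree,
                               mcmc_config(chains = 2, warmup = 800,
                                           draws = 600, seed = 7))
  expect_gt(stats::median(fit$lambda), 0.3)
})
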