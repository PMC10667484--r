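test_that("the model family enumerates exactly 12 + 4 + 16 unique specs", {
  specs <- enumerate_models()
  fam <- vapply(specs, `[[`, character(1), "family")
  expect_length(specs, 32L)
  expect_equal(unname(table(fam)[c("climate", "human", "combined")]),
               c(12L, 4L, 16L), ignore_attr = TRUE)
  labels <- vapply(specs, `[[`, character(1), "label")
  expect_false(anyDuplicated(labels) > 0)
  ## combined specs reference only the configured best climate specs
  comb <- specs[fam == "combined"]
  comb_climate <- vapply(comb, function(s)
    megadecline:::model_spec("climate", s$temp_effect, s$precip_effect,
                             s$lag)$label, character(1))
  expect_setequal(unique(comb_climate),
                  c("linT_linP", "quadT_linP", "linT_quadP", "linT_linP_L"))
  expect_error(model_spec("climate", human_trend = "logistic"), "cannot")
  expect_error(model_spec("human", temp_effect = "linear"), "cannot")
  expect_error(enumerate_models(best_climate = c("a", "b", "c", "nope")),
               "unknown|exactly")
})

test_that("design construction follows the model-spec covariate rules", {
  dir <- withr::local_tempdir()
  res <- simulate_dataset(dir, n_species = 1, seed = 55)
  tr <- res$trajectories[[1]]
  specs <- enumerate_models()
  d_lin <- build_design(tr, specs[["linT"]], climate = res$climate)
  expect_identical(colnames(d_lin$X), c("intercept", "T"))
  expect_equal(mean(d_lin$X[, "T"]), 0, tolerance = 1e-9)
  expect_equal(sd(d_lin$X[, "T"]), 1, tolerance = 1e-9)
  ## constant climate: standardised columns are zero (intercept-only model)
  flat <- climate_series(res$climate$boundaries,
                         rep(9, length(res$climate$temp)),
                         rep(800, length(res$climate$precip)))
  d_flat <- build_design(tr, specs[["linT_linP"]], climate = flat)
  expect_true(all(abs(d_flat$X[, c("T", "P")]) < 1e-12))
  ## pH ramp endpoints
  d_ph <- build_design(tr, specs[["pH"]], arrival = c(60000, 45000))
  expect_true(all(d_ph$X[d_ph$mid_yr > 60000, "pH"] == 0))
  expect_true(all(d_ph$X[d_ph$mid_yr < 45000, "pH"] == 1))
  ## lag columns shift toward the older neighbour; oldest lags itself
  d_lag <- build_design(tr, specs[["linT_L"]], climate = res$climate)
  m <- nrow(d_lag$X)
  raw_T <- megadecline:::climate_at_windows(res$climate, d_lag$start_yr,
                                            d_lag$end_yr)$temp
  sc <- d_lag$scaler$lagT
  expect_equal(d_lag$X[1:(m - 1), "lagT"],
               (raw_T[2:m] - sc["mean"]) / sc["sd"], ignore_attr = TRUE)
  expect_equal(d_lag$X[m, "lagT"], (raw_T[m] - sc["mean"]) / sc["sd"],
               ignore_attr = TRUE)
  expect_error(build_design(tr, specs[["logH"]], climate = res$climate),
               "arrival")
})

test_that("null data leave human-trend and slope coefficients centred on zero", {
  sp <- simulate_species(1, seed = 61)
  par <- scenario_params("stable", noise_sd = 0.05, base_log10_ne = 4)
  tr <- simulate_trajectory(sp, par, seed = 8)
  mc <- mcmc_config(chains = 2, warmup = 400, draws = 400, seed = 11)
  d <- build_design(tr, enumerate_models()[["logH"]],
                    arrival = c(60000, 45000))
  f <- fit_model(d, mc)
  hp <- hpdi(-f$draws$theta[, "delta"])
  expect_gte(hp[2], -0.15)  # no support for a real drop
  cl <- simulate_climate(seed = 61)
  d2 <- build_design(tr, enumerate_models()[["linT_linP"]], climate = cl)
  f2 <- fit_model(d2, mc)
  for (cc in c("T", "P")) {
    h <- hpdi(f2$draws$beta[, which(colnames(d2$X) == cc)])
    expect_true(h[1] < 0 && h[2] > 0)
  }
})

test_that("logistic human-trend parameters are recovered from generated data", {
  arr <- default_arrival_windows()
  mc <- mcmc_config(chains = 2, warmup = 500, draws = 500, seed = 13)
  hits <- 0L
  for (r in 1:5) {
    sp <- simulate_species(1, seed = 70 + r)
    sp$realm <- "Palearctic"
    par <- scenario_params("human_logistic", noise_sd = 0.05, pre_slope = 0,
                           human_k = 1.5, human_delta = 1)
    tr <- simulate_trajectory(sp, par, arrivals = arr, seed = 80 + r)
    d <- build_design(tr, enumerate_models()[["logH"]],
                      arrival = c(60000, 45000))
    f <- fit_model(d, mc)
    hd <- hpdi(f$draws$theta[, "delta"])
    ha <- hpdi(f$draws$theta[, "t_arr"])
    t_true <- attr(tr, "t_arr")
    if (hd[1] <= 1 && 1 <= hd[2] && ha[1] <= t_true && t_true <= ha[2])
      hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("PSIS-LOO behaves additively and reproducibly", {
  sp <- simulate_species(1, seed = 91)
  cl <- simulate_climate(seed = 91)
  par <- scenario_params("climate_forced", noise_sd = 0.1)
  tr <- simulate_trajectory(sp, par, climate = cl, seed = 5)
  mc <- mcmc_config(chains = 2, warmup = 400, draws = 400, seed = 3)
  d <- build_design(tr, enumerate_models()[["linT_linP"]], climate = cl)
  f <- fit_model(d, mc)
  l1 <- loo_score(f)
  l2 <- loo_score(fit_model(d, mc))
  expect_identical(l1$elpd, l2$elpd)
  ## duplicated dataset: elpd approximately doubles
  dd <- d; dd$y <- c(d$y, d$y); dd$X <- rbind(d$X, d$X)
  dd$mid_yr <- c(d$mid_yr, d$mid_yr); dd$n <- 2L * d$n
  fd <- fit_model(dd, mc)
  ld <- loo_score(fd)
  expect_equal(ld$elpd, 2 * l1$elpd, tolerance = 0.12)
})

test_that("PSIS-LOO matches exact leave-one-out refits on a small problem", {
  set.seed(17)
  n <- 20
  X <- cbind(1, scale(rnorm(n)))
  colnames(X) <- c("intercept", "T")
  y <- 4 + 0.3 * X[, 2] + rnorm(n, 0, 0.15)
  S <- 4000
  withr::with_seed(21, full <- megadecline:::nig_draws(X, y, S))
  ll <- megadecline:::pointwise_loglik(y, X %*% t(full$beta), full$sigma)
  psis <- psis_loo(ll)
  exact <- vapply(seq_len(n), function(i) {
    withr::with_seed(100 + i,
      dr <- megadecline:::nig_draws(X[-i, , drop = FALSE], y[-i], S))
    mu_i <- as.numeric(X[i, , drop = FALSE] %*% t(dr$beta))
    megadecline:::logsumexp(stats::dnorm(y[i], mu_i, dr$sigma, log = TRUE)) -
      log(S)
  }, numeric(1))
  expect_lt(abs(psis$elpd - sum(exact)), 2 * psis$se)
  expect_true(psis$reliable)
})

test_that("model ranking handles duplicates and reports gaps", {
  dir <- withr::local_tempdir()
  res <- simulate_dataset(dir, n_species = 2, scenario = "human_logistic",
                          noise_sd = 0.05, seed = 101)
  mc <- mcmc_config(chains = 1, warmup = 200, draws = 300, seed = 2)
  specs <- enumerate_models()[c("logH", "pH")]
  out <- fit_all_models(res$trajectories, res$traits, res$climate,
                        res$arrivals, specs = specs, mcmc = mc)
  ## inject a duplicate spec under a new name: tied totals
  fits <- out$fits
  for (sp in names(fits)) fits[[sp]][["pH_copy"]] <- fits[[sp]][["pH"]]
  rk <- rank_models(fits)
  tab <- rk$table
  expect_equal(tab$elpd[tab$label == "pH"], tab$elpd[tab$label == "pH_copy"])
  fits[[2]][["pH_copy"]] <- NULL
  expect_error(rank_models(fits), "missing")
})

test_that("hold-out prediction is self-consistent and asymmetric under human impact", {
  cl <- simulate_climate(seed = 7)
  sp <- simulate_species(1, seed = 7)
  specs <- enumerate_models()
  ## noiseless data from the fitted model class: near-zero MSE everywhere
  par0 <- scenario_params("climate_forced", noise_sd = 0, temp_coef = 0.2,
                          precip_coef = 0.1)
  tr0 <- simulate_trajectory(sp, par0, climate = cl, seed = 3)
  mc <- mcmc_config(chains = 2, warmup = 300, draws = 300, seed = 9)
  h0 <- fit_predict_holdout(tr0, specs[["linT_linP"]], climate = cl,
                            mcmc = mc)
  expect_lt(max(h0$interval_mse), 0.01)
  expect_error(fit_predict_holdout(tr0, specs[["linT_linP"]], climate = cl,
                                   split_yr = 10), "held-out")
})

test_that("window contrasts match the paired t-test and detect shifts", {
  set.seed(23)
  n <- 30
  obs <- rnorm(n, 4, 0.3)
  op_id <- data.frame(species_id = paste0("s", 1:n), interval = "0-25",
                      observed = obs, predicted = obs)
  ident <- compare_windows(op_id)
  expect_equal(ident$t, 0); expect_equal(ident$cohens_d, 0)
  ## constant offset with tiny spread: huge effect, CI excludes 0
  op_sh <- op_id; op_sh$predicted <- obs + 0.5 + rnorm(n, 0, 0.01)
  sh <- compare_windows(op_sh)
  expect_lt(sh$ci_hi, 0)
  expect_lt(sh$cohens_d, -10)
  ## known paired normals: agree with t.test under the n-1 convention
  op <- data.frame(species_id = paste0("s", 1:n), interval = "25-50",
                   observed = rnorm(n, 4.2, 0.4),
                   predicted = rnorm(n, 4.0, 0.4))
  ours <- compare_windows(op, df_convention = "n-1")
  tt <- t.test(op$observed, op$predicted, paired = TRUE)
  expect_equal(ours$t, unname(tt$statistic))
  expect_equal(ours$p, tt$p.value)
  expect_equal(ours$df, unname(tt$parameter))
  expect_equal(c(ours$ci_lo, ours$ci_hi), as.numeric(tt$conf.int))
  dd <- op$observed - op$predicted
  expect_equal(ours$cohens_d, mean(dd) / sd(dd))
  ## the reporting convention df = n
  expect_equal(compare_windows(op, df_convention = "n")$df, n)
  expect_error(compare_windows(op_id[1:2, ]), "at least 3")
})

test_that("human-megafauna correlations recover exact relationships", {
  b <- c(0, 10^seq(3, 6.4, length.out = 40))
  mid <- (b[-1] + b[-41]) / 2
  mega <- lapply(1:3, function(i)
    ne_trajectory(paste0("m", i), b, 10^(3 + 0.4 * log10(mid))))
  trend <- average_trend(mega, mid[5:35])
  human_anti <- ne_trajectory("Homo_sapiens", b, 10^(8 - 0.4 * log10(mid)))
  cc <- human_megafauna_correlation(human_anti, trend,
                                    range = c(2e6, 2e4))
  ## step-function evaluation vs smoothed trend: near-exact
  expect_equal(cc$pearson, -1, tolerance = 0.01)
  expect_lt(cc$spearman, -0.99)
  human_same <- ne_trajectory("Homo_sapiens", b, 10^(3 + 0.4 * log10(mid)))
  cc2 <- human_megafauna_correlation(human_same, trend, range = c(2e6, 2e4))
  expect_equal(cc2$pearson, 1, tolerance = 0.01)
  expect_error(human_megafauna_correlation(human_same, trend,
                                           range = c(1e7, 9e6)),
               "overlap")
})

test_that("with no real drop the logistic human model nests down to the intercept model", {
  sp <- simulate_species(1, seed = 131)
  par <- scenario_params("stable", noise_sd = 0.08, base_log10_ne = 4)
  tr <- simulate_trajectory(sp, par, seed = 14)
  mc <- mcmc_config(chains = 2, warmup = 400, draws = 400, seed = 21)
  d_log <- build_design(tr, enumerate_models()[["logH"]],
                        arrival = c(60000, 45000))
  f_log <- fit_model(d_log, mc)
  l_log <- loo_score(f_log)
  ## intercept-only reference: a linear spec whose climate column is zero
  flat <- climate_series(c(0, 4e5, 8e5), c(9, 9), c(800, 800))
  d_int <- build_design(tr, enumerate_models()[["linT"]], climate = flat)
  f_int <- fit_model(d_int, mc)
  l_int <- loo_score(f_int)
  expect_lt(abs(l_log$elpd - l_int$elpd),
            2 * sqrt(l_log$se^2 + l_int$se^2))
})
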