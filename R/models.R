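#' Trajectory model specification
#'
#' One member of the climate / human-arrival / combined model family for a
#' species' log10 Ne trajectory over the last 742 kyr. Labels follow the
#' field's shorthand: `linT`/`quadT` linear/quadratic temperature effect,
#' `linP`/`quadP` precipitation, `L` the preceding-window climatic lag,
#' `logH`/`expH`/`linH` a logistic/exponential/linear post-arrival trend,
#' `pH` the probability-of-human-presence ramp covariate.
#'
#' @param family `"climate"`, `"human"` or `"combined"`.
#' @param temp_effect `"none"`, `"linear"` or `"quadratic"`.
#' @param precip_effect `"none"`, `"linear"` or `"quadratic"`.
#' @param lag Logical: include previous-window temperature and
#'   precipitation.
#' @param human_trend `"none"`, `"logistic"`, `"exponential"`, `"linear"`
#'   or `"presence"`.
#' @return A list of class `model_spec` with a deterministic `label`.
#' @export
model_spec <- function(family, temp_effect = "none", precip_effect = "none",
                       lag = FALSE, human_trend = "none") {
  family <- match.arg(family, c("climate", "human", "combined"))
  temp_effect <- match.arg(temp_effect, c("none", "linear", "quadratic"))
  precip_effect <- match.arg(precip_effect, c("none", "linear", "quadratic"))
  human_trend <- match.arg(human_trend,
    c("none", "logistic", "exponential", "linear", "presence"))
  has_climate <- temp_effect != "none" || precip_effect != "none" || lag
  if (family == "climate" && human_trend != "none")
    stop("climate-family specs cannot carry a human trend")
  if (family == "human" && has_climate)
    stop("human-family specs cannot carry climate terms")
  if (family == "combined" && (human_trend == "none" || !has_climate))
    stop("combined specs need both climate terms and a human trend")
  hl <- c(none = "", logistic = "logH", exponential = "expH",
          linear = "linH", presence = "pH")[human_trend]
  tl <- c(none = "", linear = "linT", quadratic = "quadT")[temp_effect]
  pl <- c(none = "", linear = "linP", quadratic = "quadP")[precip_effect]
  label <- paste(c(hl, tl, pl, if (lag) "L"), collapse = "_")
  label <- gsub("_+", "_", label); label <- gsub("^_|_$", "", label)
  structure(list(family = family, temp_effect = temp_effect,
                 precip_effect = precip_effect, lag = lag,
                 human_trend = human_trend, label = label),
            class = "model_spec")
}

climate_spec_from_label <- function(label) {
  parts <- strsplit(label, "_", fixed = TRUE)[[1L]]
  model_spec("climate",
    temp_effect = if ("quadT" %in% parts) "quadratic" else
      if ("linT" %in% parts) "linear" else "none",
    precip_effect = if ("quadP" %in% parts) "quadratic" else
      if ("linP" %in% parts) "linear" else "none",
    lag = "L" %in% parts)
}

#' Enumerate the 32-model family
#'
#' 12 climate-only models (`{linT, quadT} x {no P, linP, quadP} x {+/- lag}`),
#' 4 human-only models (`logH`, `expH`, `linH`, `pH`), and 16 combined
#' models pairing each of 4 configured best-fitting climate specs with each
#' human trend.
#'
#' @param best_climate Labels of the 4 climate specs used to build the
#'   combined models.
#' @return Named list of 32 [model_spec()] objects with unique labels.
#' @export
enumerate_models <- function(best_climate = c("linT_linP", "quadT_linP",
                                              "linT_quadP", "linT_linP_L")) {
  if (length(best_climate) != 4L)
    stop("exactly 4 best-fitting climate specs are required")
  specs <- list()
  for (te in c("linear", "quadratic"))
    for (pe in c("none", "linear", "quadratic"))
      for (lg in c(FALSE, TRUE))
        specs <- c(specs, list(model_spec("climate", te, pe, lg)))
  for (ht in c("logistic", "exponential", "linear", "presence"))
    specs <- c(specs, list(model_spec("human", human_trend = ht)))
  climate_labels <- vapply(specs[1:12], `[[`, character(1), "label")
  missing <- setdiff(best_climate, climate_labels)
  if (length(missing))
    stop("unknown best-climate labels: ", paste(missing, collapse = ", "))
  for (cl in best_climate) {
    cs <- climate_spec_from_label(cl)
    for (ht in c("logistic", "exponential", "linear", "presence"))
      specs <- c(specs, list(model_spec("combined", cs$temp_effect,
                                        cs$precip_effect, cs$lag, ht)))
  }
  names(specs) <- vapply(specs, `[[`, character(1), "label")
  stopifnot(length(specs) == 32L, !anyDuplicated(names(specs)))
  specs
}

## covariate builder shared by fitting and hold-out prediction; `scaler`
## (means/sds keyed by column) is estimated when NULL and reused otherwise
make_covariates <- function(spec, climate, start_yr, end_yr, mid_yr,
                            arrival = NULL, scaler = NULL) {
  cols <- list(intercept = rep(1, length(mid_yr)))
  est <- is.null(scaler)
  if (est) scaler <- list()
  zcol <- function(name, v) {
    if (est) {
      sdv <- stats::sd(v)
      ## near-constant covariates collapse to an exact zero column
      degenerate <- sdv <= 1e-10 * max(1, abs(mean(v)))
      scaler[[name]] <<- c(mean = mean(v), sd = if (degenerate) Inf else sdv)
    }
    sc <- scaler[[name]]
    (v - sc["mean"]) / sc["sd"]
  }
  needs_climate <- spec$temp_effect != "none" || spec$precip_effect != "none" ||
    spec$lag
  if (needs_climate) {
    if (is.null(climate)) stop("spec needs a climate series")
    cw <- climate_at_windows(climate, start_yr, end_yr)
    if (spec$temp_effect != "none") {
      zT <- zcol("T", cw$temp)
      cols$T <- zT
      if (spec$temp_effect == "quadratic") cols$T2 <- zcol("T2", zT^2)
    }
    if (spec$precip_effect != "none") {
      zP <- zcol("P", cw$precip)
      cols$P <- zP
      if (spec$precip_effect == "quadratic") cols$P2 <- zcol("P2", zP^2)
    }
    if (spec$lag) {
      ## preceding (adjacent older) window; the oldest window lags itself
      m <- length(mid_yr)
      older <- c(seq_len(m)[-1L], m)
      cols$lagT <- zcol("lagT", cw$temp[older])
      cols$lagP <- zcol("lagP", cw$precip[older])
    }
  }
  if (spec$human_trend == "presence") {
    if (is.null(arrival)) stop("pH spec needs an arrival window")
    cols$pH <- human_presence_ramp(mid_yr, arrival[1L], arrival[2L])
  }
  list(X = do.call(cbind, cols), scaler = scaler)
}

#' Build the design table for one species and model spec
#'
#' One row per trajectory window whose midpoint falls inside `fit_range`
#' (windows are sorted young to old). The response is log10 window Ne;
#' climate covariates are window means standardised over the fitted
#' windows, quadratic terms are squares of the standardised linear terms
#' (themselves standardised), and the lag columns carry the adjacent older
#' window's climate (the oldest window lags itself). Nonlinear human trends
#' are not pre-computed: the likelihood consumes window midpoints and the
#' realm arrival bounds.
#'
#' @param traj An [ne_trajectory()].
#' @param spec A [model_spec()].
#' @param climate A [climate_series()] (required for climate terms).
#' @param arrival `c(earliest_yr, latest_yr)` arrival bounds for the
#'   species' realm (required for human trends).
#' @param fit_range `c(max_yr, min_yr)` years BP; default the last 742 kyr.
#' @return A list of class `model_design`.
#' @export
build_design <- function(traj, spec, climate = NULL, arrival = NULL,
                         fit_range = c(742000, 0)) {
  w <- trajectory_windows(traj)
  w <- w[w$mid_yr >= min(fit_range) & w$mid_yr <= max(fit_range), ]
  w <- w[order(w$mid_yr), ]
  if (spec$human_trend != "none" && is.null(arrival))
    stop("human-trend spec needs the realm arrival window")
  cv <- make_covariates(spec, climate, w$start_yr, w$end_yr, w$mid_yr,
                        arrival = arrival)
  structure(list(species_id = traj$species_id, spec = spec,
                 y = w$log10_ne, X = cv$X, mid_yr = w$mid_yr,
                 start_yr = w$start_yr, end_yr = w$end_yr,
                 arrival = arrival, scaler = cv$scaler, n = nrow(w)),
            class = "model_design")
}

## exact normal-inverse-gamma posterior draws for y ~ N(Xb, sigma^2);
## prior b | sigma^2 ~ N(0, sigma^2 V0), sigma^2 ~ InvGamma(a0, b0)
nig_draws <- function(X, y, S, a0 = 2, b0 = 0.02, pre = NULL) {
  p <- ncol(X); n <- length(y)
  if (is.null(pre)) pre <- nig_precompute(X)
  mn <- backsolve(pre$Un, backsolve(pre$Un, crossprod(X, y),
                                    transpose = TRUE))
  an <- a0 + n / 2
  bn <- b0 + 0.5 * (sum(y^2) - sum(mn * (pre$Mn %*% mn)))
  sigma2 <- 1 / stats::rgamma(S, shape = an, rate = bn)
  Zm <- matrix(stats::rnorm(S * p), p, S)
  B <- as.numeric(mn) + backsolve(pre$Un, Zm) * rep(sqrt(sigma2), each = p)
  list(beta = t(B), sigma = sqrt(sigma2), mn = as.numeric(mn))
}

nig_precompute <- function(X) {
  p <- ncol(X)
  v0_inv <- diag(c(1e-4, rep(0.01, p - 1L)), p)  # weak; looser intercept
  Mn <- v0_inv + crossprod(X)
  list(Mn = Mn, Un = chol(Mn))
}

## Gaussian log-likelihood, inlined for the samplers' hot loop
norm_loglik <- function(y, mu, sigma) {
  n <- length(y)
  -n * log(sigma) - 0.5 * sum(((y - mu) / sigma)^2) - n * 0.918938533204673
}

## pointwise log-likelihood matrix (draws x windows)
pointwise_loglik <- function(y, mu, sigma) {
  ## mu: n x S matrix; sigma length S
  S <- length(sigma)
  t(stats::dnorm(matrix(y, length(y), S), mu,
                 rep(sigma, each = length(y)), log = TRUE))
}

#' Fit one trajectory model
#'
#' Gaussian likelihood on log10 window Ne with mean = linear predictor plus
#' (for `logH`/`expH`/`linH`) a nonlinear human-suppression term (see
#' [human_trend_term()]). Linear specs (all climate-only models and `pH`)
#' are sampled exactly from their conjugate normal-inverse-gamma posterior;
#' nonlinear specs use Metropolis-within-Gibbs (conjugate draws of the
#' linear part, adaptive random-walk updates of the arrival time, rate and
#' drop, with a uniform prior on the arrival time over the realm window and
#' half-Normal(0,1) priors on rate and drop). The pointwise log-likelihood
#' is retained for [loo_score()].
#'
#' @param design A [build_design()] result (>= 6 windows).
#' @param mcmc An [mcmc_config()].
#' @return A `posterior_fit`: draws, pointwise log-likelihood, per-window
#'   posterior-median prediction, `mse`, convergence flag.
#' @export
fit_model <- function(design, mcmc = mcmc_config()) {
  if (design$n < 6L) stop("need at least 6 windows to fit")
  trend <- design$spec$human_trend
  if (trend %in% c("none", "presence")) {
    S <- mcmc$chains * mcmc$draws
    withr_seed(mcmc$seed, dr <- nig_draws(design$X, design$y, S))
    mu <- design$X %*% t(dr$beta)
    ll <- pointwise_loglik(design$y, mu, dr$sigma)
    pred <- apply(mu, 1L, stats::median)
    fit <- list(draws = list(beta = dr$beta, sigma = dr$sigma, theta = NULL),
                converged = TRUE, rhat = c(sigma = 1))
  } else {
    fit <- fit_human_mwg(design, mcmc)
    mu <- fit$mu
    ll <- fit$loglik
    pred <- apply(mu, 1L, stats::median)
  }
  structure(list(species_id = design$species_id, spec = design$spec,
                 y = design$y, mid_yr = design$mid_yr, draws = fit$draws,
                 loglik = ll, pred = pred,
                 mse = mean((design$y - pred)^2),
                 converged = fit$converged, rhat = fit$rhat,
                 design = design),
            class = "posterior_fit")
}

## Metropolis-within-Gibbs for the nonlinear human-trend models
fit_human_mwg <- function(design, mcmc) {
  y <- design$y; X <- design$X; n <- design$n
  trend <- c(logistic = "logistic", exponential = "exponential",
             linear = "linear")[design$spec$human_trend]
  earliest <- design$arrival[1L]; latest <- design$arrival[2L]
  p <- ncol(X)
  total <- mcmc$warmup + mcmc$draws
  S_keep <- mcmc$chains * mcmc$draws
  beta_k <- matrix(NA_real_, S_keep, p)
  sigma_k <- numeric(S_keep)
  theta_k <- matrix(NA_real_, S_keep, 3L,
                    dimnames = list(NULL, c("t_arr", "rate", "delta")))
  ll_k <- matrix(NA_real_, S_keep, n)
  mu_k <- matrix(NA_real_, n, S_keep)
  sig_ch <- matrix(NA_real_, mcmc$draws, mcmc$chains)
  del_ch <- matrix(NA_real_, mcmc$draws, mcmc$chains)
  ## specialised fast versions of human_trend_term for the hot loop
  mid <- design$mid_yr
  hterm <- switch(trend,
    logistic = function(th) -th[3L] / (1 + exp(-th[2L] * (th[1L] - mid) / 1e4)),
    exponential = function(th)
      -th[3L] * (1 - exp(-th[2L] * pmax((th[1L] - mid) / 1e4, 0))),
    linear = function(th) -pmin(th[3L], th[2L] * pmax((th[1L] - mid) / 1e4, 0)))
  for (ch in seq_len(mcmc$chains)) {
    withr_seed(mcmc$seed + 3000L * ch, {
      old_lvl <- mean(y[design$mid_yr >= stats::median(design$mid_yr)])
      new_lvl <- mean(y[seq_len(min(5L, n))])
      th <- c((earliest + latest) / 2, 0.5, max(0.1, old_lvl - new_lvl))
      h <- hterm(th)
      pre <- nig_precompute(X)
      scales <- c(0.5, 0.4, 0.4)
      for (it in seq_len(total)) {
        ## conjugate refresh of the linear part given the human term
        bdr <- nig_draws(X, y - h, 1L, pre = pre)
        beta <- as.numeric(bdr$beta[1L, ]); sigma <- bdr$sigma[1L]
        eta <- as.numeric(X %*% beta)
        loglik_th <- function(tht) norm_loglik(y, eta + hterm(tht), sigma)
        ll_cur <- loglik_th(th)
        ## arrival time: random walk on the logit of its window position
        u <- stats::qlogis((th[1L] - latest) / (earliest - latest))
        up <- u + stats::rnorm(1, 0, scales[1L])
        thp <- th; thp[1L] <- latest + stats::plogis(up) * (earliest - latest)
        lj <- function(v) log(v - latest) + log(earliest - v) # logit jacobian
        llp <- loglik_th(thp)
        acc1 <- log(stats::runif(1)) < llp - ll_cur + lj(thp[1L]) - lj(th[1L])
        if (acc1) { th <- thp; ll_cur <- llp }
        if (it <= mcmc$warmup) scales[1L] <- adapt_scale(scales[1L], acc1, it, 0.3)
        ## rate and drop: log random walks, half-Normal(0,1) priors
        for (j in 2:3) {
          thp <- th; thp[j] <- th[j] * exp(stats::rnorm(1, 0, scales[j]))
          llp <- loglik_th(thp)
          lr <- llp - ll_cur + log_half_normal(thp[j]) - log_half_normal(th[j]) +
            log(thp[j]) - log(th[j])
          accj <- log(stats::runif(1)) < lr
          if (accj) { th <- thp; ll_cur <- llp }
          if (it <= mcmc$warmup) scales[j] <- adapt_scale(scales[j], accj, it, 0.3)
        }
        h <- hterm(th)
        if (it > mcmc$warmup) {
          k <- (ch - 1L) * mcmc$draws + (it - mcmc$warmup)
          beta_k[k, ] <- beta; sigma_k[k] <- sigma; theta_k[k, ] <- th
          mu_k[, k] <- eta + h
          ll_k[k, ] <- stats::dnorm(y, mu_k[, k], sigma, log = TRUE)
          sig_ch[it - mcmc$warmup, ch] <- sigma
          del_ch[it - mcmc$warmup, ch] <- th[3L]
        }
      }
    })
  }
  rhat <- c(sigma = split_rhat(sig_ch), delta = split_rhat(del_ch))
  list(draws = list(beta = beta_k, sigma = sigma_k, theta = theta_k),
       loglik = ll_k, mu = mu_k, rhat = rhat,
       converged = all(rhat < 1.05))
}

#' @export
print.posterior_fit <- function(x, ...) {
  cat(sprintf("<posterior_fit> %s / %s: %d windows, mse %.4f\n",
              x$species_id, x$spec$label, length(x$y), x$mse))
  invisible(x)
}

#' Leave-one-out score of a fitted trajectory model
#'
#' Computes the expected log pointwise predictive density with the
#' conjugate linear part integrated out analytically: given the nonlinear
#' human-trend parameters, the leave-one-out predictive density of each
#' window is an exact Student-t from rank-one downdates of the
#' normal-inverse-gamma posterior. Linear specs (climate-only and `pH`)
#' therefore get *exact* LOO; nonlinear specs importance-sample only over
#' the three human-trend parameters, with Pareto-smoothed weights.
#' Marginalising the linear part removes the dimension-dependent optimism
#' that raw-draw importance sampling shows for richer models.
#'
#' @param fit A `posterior_fit`.
#' @return List: `elpd`, `se`, `pointwise`, `pareto_k`, `reliable`.
#' @export
loo_score <- function(fit) {
  design <- fit$design
  if (is.null(design)) {
    res <- psis_loo(fit$loglik)
    return(list(elpd = res$elpd, se = res$se, pointwise = res$pointwise,
                pareto_k = res$pareto_k, reliable = res$reliable))
  }
  theta <- fit$draws$theta
  ll <- marginal_pointwise_loglik(design, theta)
  if (is.null(theta)) {
    pointwise <- ll[1L, ]
    return(list(elpd = sum(pointwise),
                se = stats::sd(pointwise) * sqrt(length(pointwise)),
                pointwise = pointwise,
                pareto_k = rep(-Inf, length(pointwise)), reliable = TRUE))
  }
  res <- psis_loo(ll)
  list(elpd = res$elpd, se = res$se, pointwise = res$pointwise,
       pareto_k = res$pareto_k, reliable = res$reliable)
}

## log p(y_i | y_{-i}, theta_s) with the normal-inverse-gamma linear part
## integrated analytically (Student-t from rank-one downdates); one row per
## theta draw (a single row when theta is NULL)
marginal_pointwise_loglik <- function(design, theta = NULL,
                                      a0 = 2, b0 = 0.02) {
  X <- design$X; y <- design$y; n <- design$n; p <- ncol(X)
  v0_inv <- diag(c(1e-4, rep(0.01, p - 1L)), p)
  Mn <- v0_inv + crossprod(X)
  ## per-observation downdates A_i = (Mn - x_i x_i')^{-1}, stored flat for
  ## vectorised quadratic forms
  AiV <- matrix(NA_real_, n, p * p)
  H <- matrix(NA_real_, n, p)
  li <- numeric(n)
  for (i in seq_len(n)) {
    Ai <- solve(Mn - tcrossprod(X[i, ]))
    AiV[i, ] <- as.numeric(Ai)
    H[i, ] <- Ai %*% X[i, ]
    li[i] <- sum(X[i, ] * H[i, ])
  }
  a_i <- a0 + (n - 1) / 2
  trend <- c(logistic = "logistic", exponential = "exponential",
             linear = "linear")[design$spec$human_trend]
  S <- if (is.null(theta)) 1L else nrow(theta)
  ll <- matrix(NA_real_, S, n)
  for (s in seq_len(S)) {
    h <- if (is.null(theta)) 0 else
      human_trend_term(design$mid_yr, trend, t_arr = theta[s, "t_arr"],
                       k = theta[s, "rate"], delta = theta[s, "delta"],
                       b = theta[s, "rate"])
    r <- y - h
    Xtr <- as.numeric(crossprod(X, r))
    q <- as.numeric(AiV %*% as.numeric(tcrossprod(Xtr)))  # Xtr' A_i Xtr
    u <- as.numeric(H %*% Xtr)                            # x_i' A_i Xtr
    quad <- q - 2 * r * u + r^2 * li                      # b_i' A_i b_i
    b_i <- b0 + 0.5 * (sum(r^2) - r^2 - quad)
    mu <- u - li * r
    sc2 <- (b_i / a_i) * (1 + li)
    ll[s, ] <- stats::dt((r - mu) / sqrt(sc2), df = 2 * a_i, log = TRUE) -
      0.5 * log(sc2)
  }
  ll
}

#' Fit every spec to every species and rank by total LOO elpd
#'
#' Pipeline driver for the model-family comparison: builds the design for
#' each species x spec pair, fits, scores by PSIS-LOO, and totals elpd
#' across species per spec.
#'
#' @param trajs Named list of trajectories.
#' @param traits Traits table (supplies each species' realm).
#' @param climate A [climate_series()].
#' @param arrivals Arrival-window table (realm, earliest_yr, latest_yr).
#' @param specs List of [model_spec()]s (default [enumerate_models()]).
#' @param mcmc An [mcmc_config()].
#' @param fit_range Fit range in years BP.
#' @return List with `scores` (species x spec elpd matrix), `fits` (nested
#'   list, species then spec label), and the [rank_models()] ranking.
#' @export
fit_all_models <- function(trajs, traits, climate, arrivals,
                           specs = enumerate_models(),
                           mcmc = mcmc_config(), fit_range = c(742000, 0)) {
  fits <- lapply(names(trajs), function(sp) {
    realm <- traits$realm[match(sp, traits$species_id)]
    w <- arrivals[arrivals$realm == realm, ]
    if (nrow(w) != 1L) stop("no arrival window for realm ", realm)
    arrival <- c(w$earliest_yr, w$latest_yr)
    out <- lapply(specs, function(spec) {
      d <- build_design(trajs[[sp]], spec, climate = climate,
                        arrival = arrival, fit_range = fit_range)
      f <- fit_model(d, mcmc)
      f$loo <- loo_score(f)
      f
    })
    names(out) <- names(specs)
    out
  })
  names(fits) <- names(trajs)
  ranking <- rank_models(fits)
  scores <- sapply(names(specs), function(lb)
    vapply(fits, function(sf) sf[[lb]]$loo$elpd, numeric(1)))
  list(scores = scores, fits = fits, ranking = ranking)
}

#' Rank model specs by total LOO elpd across species
#'
#' @param fits Nested list: per species, per spec label, a `posterior_fit`
#'   with a `loo` element (as produced by [fit_all_models()]).
#' @return List: `table` (label, family, total elpd, se, rank, per-species
#'   mean), `best`, `best_by_class`, and `share_negative_trend` (share of
#'   species whose 95% HPDI of the best human model's net drop excludes 0).
#' @export
rank_models <- function(fits) {
  labels <- names(fits[[1L]])
  gaps <- unlist(lapply(names(fits), function(sp) {
    miss <- setdiff(labels, names(fits[[sp]]))
    if (length(miss)) paste0(sp, ": ", paste(miss, collapse = ",")) else NULL
  }))
  if (length(gaps))
    stop("missing species x spec fits: ", paste(gaps, collapse = "; "))
  elpd <- vapply(labels, function(lb)
    sum(vapply(fits, function(sf) sf[[lb]]$loo$elpd, numeric(1))), numeric(1))
  se <- vapply(labels, function(lb)
    sqrt(sum(vapply(fits, function(sf) sf[[lb]]$loo$se^2, numeric(1)))),
    numeric(1))
  family <- vapply(labels, function(lb)
    fits[[1L]][[lb]]$spec$family, character(1))
  tab <- data.frame(label = labels, family = family, elpd = elpd, se = se)
  tab <- tab[order(-tab$elpd), ]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  best_by_class <- vapply(split(tab, tab$family),
                          function(d) d$label[1L], character(1))
  ## share of species with clearly negative post-arrival trend under the
  ## best nonlinear human model (HPDI of -delta entirely below 0)
  human_tab <- tab[tab$family == "human" & tab$label != "pH", ]
  share_neg <- NA_real_
  if (nrow(human_tab)) {
    hb <- human_tab$label[1L]
    share_neg <- mean(vapply(fits, function(sf) {
      hp <- hpdi(-sf[[hb]]$draws$theta[, "delta"])
      hp[2L] < 0
    }, logical(1)))
  }
  list(table = tab, best = tab$label[1L], best_by_class = best_by_class,
       share_negative_trend = share_neg)
}

#' Fit on old windows, predict the recent past
#'
#' Fits a (typically climate-only) spec to windows with midpoints older
#' than `split_yr` (up to the fit-range maximum) and predicts log10 Ne for
#' the held-out younger windows from the posterior-median response,
#' re-using the training covariate standardisation. Squared errors are
#' aggregated into four 25-kyr intervals.
#'
#' @inheritParams build_design
#' @param split_yr Hold-out split, years BP (windows at or below are
#'   predicted).
#' @param mcmc An [mcmc_config()].
#' @param max_yr Oldest midpoint used for fitting.
#' @return List: `predictions` (per held-out window observed, predicted,
#'   squared error), `interval_mse` (named, `"75-100"` ... `"0-25"` kya),
#'   and the training `fit`.
#' @export
fit_predict_holdout <- function(traj, spec, climate = NULL, arrival = NULL,
                                split_yr = 1e5, mcmc = mcmc_config(),
                                max_yr = 742000) {
  train <- build_design(traj, spec, climate = climate, arrival = arrival,
                        fit_range = c(max_yr, split_yr * (1 + 1e-9)))
  w <- trajectory_windows(traj)
  hold <- w[w$mid_yr <= split_yr, ]
  if (nrow(hold) == 0L) stop("no held-out windows below the split")
  fit <- fit_model(train, mcmc)
  cv <- make_covariates(spec, climate, hold$start_yr, hold$end_yr,
                        hold$mid_yr, arrival = arrival,
                        scaler = train$scaler)
  mu <- cv$X %*% t(fit$draws$beta)
  if (!is.null(fit$draws$theta)) {
    trend <- c(logistic = "logistic", exponential = "exponential",
               linear = "linear")[spec$human_trend]
    for (s in seq_len(ncol(mu)))
      mu[, s] <- mu[, s] + human_trend_term(hold$mid_yr, trend,
        t_arr = fit$draws$theta[s, "t_arr"], k = fit$draws$theta[s, "rate"],
        delta = fit$draws$theta[s, "delta"], b = fit$draws$theta[s, "rate"])
  }
  pred <- apply(mu, 1L, stats::median)
  sqerr <- (hold$log10_ne - pred)^2
  brk <- c(0, 25000, 50000, 75000, 100001)
  lab <- c("0-25", "25-50", "50-75", "75-100")
  iv <- cut(hold$mid_yr, brk, labels = lab, right = FALSE)
  interval_mse <- tapply(sqerr, iv, mean)
  list(predictions = data.frame(species_id = traj$species_id,
                                mid_yr = hold$mid_yr,
                                observed = hold$log10_ne, predicted = pred,
                                sqerr = sqerr, interval = as.character(iv)),
       interval_mse = interval_mse, fit = fit)
}

#' Observed-vs-predicted contrasts per time interval
#'
#' Paired t-test across species of observed minus predicted mean log10 Ne
#' per interval, with Cohen's d (mean difference over the SD of paired
#' differences) and a 95% CI of the mean difference. The degrees of freedom
#' convention defaults to `n` (the reporting convention for these paired
#' contrasts); `"n-1"` gives the textbook value.
#'
#' @param obs_pred Data.frame with columns `species_id`, `interval`,
#'   `observed`, `predicted` (one row per species per interval).
#' @param df_convention `"n"` or `"n-1"`.
#' @return Data.frame: one row per interval with `t`, `df`, `p`,
#'   `cohens_d`, `ci_lo`, `ci_hi`, `mean_diff`, `n`.
#' @export
compare_windows <- function(obs_pred, df_convention = c("n", "n-1")) {
  df_convention <- match.arg(df_convention)
  out <- lapply(split(obs_pred, obs_pred$interval), function(d) {
    n <- nrow(d)
    if (n < 3L) stop("need at least 3 species per interval")
    dd <- d$observed - d$predicted
    sdd <- stats::sd(dd)
    df <- if (df_convention == "n") n else n - 1L
    if (sdd == 0) {  # identical pairs: a zero, not an indeterminate, effect
      tstat <- if (mean(dd) == 0) 0 else sign(mean(dd)) * Inf
    } else {
      tstat <- mean(dd) / (sdd / sqrt(n))
    }
    hw <- stats::qt(0.975, df) * sdd / sqrt(n)
    data.frame(interval = d$interval[1L], t = tstat, df = df,
               p = 2 * stats::pt(abs(tstat), df, lower.tail = FALSE),
               cohens_d = if (sdd == 0) if (mean(dd) == 0) 0 else
                 sign(mean(dd)) * Inf else mean(dd) / sdd,
               ci_lo = mean(dd) - hw, ci_hi = mean(dd) + hw,
               mean_diff = mean(dd), n = n)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Correlation between a human trajectory and the megafauna trend
#'
#' Evaluates the human Ne trajectory (log10) and the average megafauna
#' trend on a common log-spaced time grid inside `range` and returns
#' Pearson and Spearman correlations.
#'
#' @param human_traj An [ne_trajectory()] for *H. sapiens*.
#' @param mean_trend Data.frame from [average_trend()] (`time_yr`,
#'   `mean_log10_ne`).
#' @param range `c(from_yr, to_yr)` years BP (order free).
#' @param n_grid Number of grid points.
#' @return List with `pearson`, `spearman`, `n`.
#' @export
human_megafauna_correlation <- function(human_traj, mean_trend,
                                        range = c(1.5e6, 1.5e5),
                                        n_grid = 40) {
  lo <- max(min(range), human_traj$boundaries[1L], min(mean_trend$time_yr), 1)
  hi <- min(max(range), human_traj$boundaries[length(human_traj$boundaries)],
            max(mean_trend$time_yr))
  if (!(hi > lo)) stop("series do not overlap the requested range")
  grid <- 10^seq(log10(lo), log10(hi), length.out = n_grid)
  grid <- grid[grid < human_traj$boundaries[length(human_traj$boundaries)]]
  y1 <- log10(vapply(grid, function(g) evaluate_trajectory(human_traj, g),
                     numeric(1)))
  y2 <- stats::approx(log10(mean_trend$time_yr), mean_trend$mean_log10_ne,
                      xout = log10(grid), rule = 1)$y
  ok <- is.finite(y1) & is.finite(y2)
  if (sum(ok) < 5L) stop("fewer than 5 usable grid points")
  list(pearson = stats::cor(y1[ok], y2[ok]),
       spearman = stats::cor(y1[ok], y2[ok], method = "spearman"),
       n = sum(ok))
}
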