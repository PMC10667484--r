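#' Decline severity of a trajectory
#'
#' Severity is one minus the ratio of the lowest to the highest effective
#' size anywhere on the trajectory (temporal order ignored), i.e. the
#' fractional reduction from peak to trough. Ties are broken toward the most
#' recent occurrence.
#'
#' @param traj An [ne_trajectory()].
#' @return One-row data.frame: `species_id`, `ne_min`, `ne_max`, `severity`
#'   (in `[0, 1)`), `t_min_yr`, `t_max_yr` (interval midpoints, years BP, at
#'   which the extrema occur).
#' @export
decline_severity <- function(traj) {
  stopifnot(inherits(traj, "ne_trajectory"))
  w <- trajectory_windows(traj)
  ## ties toward the most recent time: windows are ordered young -> old,
  ## so the first index attaining an extremum is the most recent
  i_min <- which(w$ne == min(w$ne))[1L]
  i_max <- which(w$ne == max(w$ne))[1L]
  data.frame(species_id = traj$species_id,
             ne_min = w$ne[i_min], ne_max = w$ne[i_max],
             severity = 1 - w$ne[i_min] / w$ne[i_max],
             t_min_yr = w$mid_yr[i_min], t_max_yr = w$mid_yr[i_max])
}

#' Pooled Spearman correlation of Ne with time before present
#'
#' Rank correlation of effective size against window midpoint age, pooled
#' over all species' windows. A positive correlation means sizes were larger
#' in the past, i.e. a general decline toward the present.
#'
#' @param trajs List of [ne_trajectory()] objects.
#' @return List with `rho` and `p` (tie-corrected, normal approximation).
#' @export
spearman_ne_time <- function(trajs) {
  if (inherits(trajs, "ne_trajectory")) trajs <- list(trajs)
  pts <- do.call(rbind, lapply(trajs, trajectory_windows))
  if (is.null(pts) || nrow(pts) < 3L) stop("need at least 3 pooled points")
  ct <- suppressWarnings(
    stats::cor.test(pts$mid_yr, pts$ne, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' One representative species per genus
#'
#' Reduces a dataset to a single species per genus (the first `_`-separated
#' token of `species_id`), minimising shared evolutionary history. The
#' representative is the species with the most trajectory windows; ties (and
#' the case with no trajectories supplied) break alphabetically.
#'
#' @param traits Traits table.
#' @param trajs Optional named list of trajectories used for the
#'   window-count criterion.
#' @return The retained rows of `traits`.
#' @export
genus_subset <- function(traits, trajs = NULL) {
  ids <- traits$species_id
  bad <- which(!grepl("_", ids))
  if (length(bad))
    stop("unparseable species_id (no genus token) at row ", bad[1L],
         ": '", ids[bad[1L]], "'")
  genus <- vapply(strsplit(ids, "_", fixed = TRUE), `[[`, character(1), 1L)
  nwin <- if (is.null(trajs)) rep(0L, length(ids)) else
    vapply(ids, function(s)
      if (!is.null(trajs[[s]])) length(trajs[[s]]$ne) else 0L, integer(1))
  ord <- order(genus, -nwin, ids)
  keep <- ord[!duplicated(genus[ord])]
  traits[sort(keep), , drop = FALSE]
}

## per-species sufficient statistics for the hierarchical slope model;
## x is forward log-time centred within species
slope_model_stats <- function(trajs) {
  sp <- names(trajs)
  stats_list <- lapply(trajs, function(tr) {
    w <- trajectory_windows(tr)
    x <- -log10(pmax(w$mid_yr, 1))
    xc <- x - mean(x)
    y <- w$log10_ne
    list(n = length(y), ybar = mean(y), Syy = sum((y - mean(y))^2),
         Sxx = sum(xc^2), Sxy = sum(xc * y))
  })
  list(species_id = sp,
       n = vapply(stats_list, `[[`, numeric(1), "n"),
       ybar = vapply(stats_list, `[[`, numeric(1), "ybar"),
       Syy = vapply(stats_list, `[[`, numeric(1), "Syy"),
       Sxx = vapply(stats_list, `[[`, numeric(1), "Sxx"),
       Sxy = vapply(stats_list, `[[`, numeric(1), "Sxy"))
}

#' Bayesian hierarchical slope model with a body-mass effect
#'
#' Per-species regression of log10 Ne on forward log-time (so negative
#' slopes are declines toward the present), with species slopes partially
#' pooled around `alpha + beta * z(log10 mass)`:
#' \deqn{y_{ij} = a_i + s_i x_{ij} + e_{ij}, \quad e \sim N(0, \sigma^2)}
#' \deqn{s_i \sim N(\alpha + \beta z_i, \tau^2)}
#' Priors: flat on the species levels `a_i`, Normal(0,1) on `alpha` and
#' `beta` (the mass predictor is standardised), half-Normal(0,1) on the
#' scales. Sampling is by Gibbs updates for all location parameters and
#' adaptive random-walk Metropolis on the log scales.
#'
#' @param trajs Named list of [ne_trajectory()] objects (>= 3).
#' @param traits Traits table with `species_id` and `mass_kg`.
#' @param mcmc An [mcmc_config()].
#' @return A `slope_posterior`: reported draws of per-species slopes,
#'   `alpha`, `beta`, `sigma`, `tau`; split R-hat and ESS for `beta`;
#'   `converged` flag.
#' @export
fit_slope_model <- function(trajs, traits, mcmc = mcmc_config()) {
  trajs <- trajs[names(trajs) %in% traits$species_id]
  if (length(trajs) < 3L) stop("need at least 3 species with trajectories")
  st <- slope_model_stats(trajs)
  mass <- traits$mass_kg[match(st$species_id, traits$species_id)]
  if (stats::sd(log10(mass)) == 0)
    stop("mass is constant across species: the mass effect is unidentifiable")
  z <- as.numeric(scale(log10(mass)))
  res <- run_slope_chains(st, z, mcmc, C = NULL, lambda_fixed = NULL)
  res
}

#' Phylogenetic hierarchical slope model
#'
#' As [fit_slope_model()], but species-level slope residuals are correlated
#' through a Brownian-motion phylogenetic correlation matrix `C` (from the
#' tree's shared branch lengths), attenuated by Pagel's lambda:
#' `s ~ MVN(alpha + beta z, tau^2 (lambda C + (1 - lambda) I))`, with a
#' uniform prior on `lambda` (or `lambda_fixed` supplied, 0 giving the
#' independent-residual model).
#'
#' @inheritParams fit_slope_model
#' @param tree An [ape::phylo] tree with branch lengths whose tip labels
#'   cover the analysed species; species absent from the tree are excluded
#'   with a warning.
#' @param lambda_fixed Optional fixed lambda in `[0, 1]`.
#' @return A `slope_posterior` additionally carrying `lambda` draws.
#' @export
fit_phylo_slope_model <- function(trajs, traits, tree,
                                  mcmc = mcmc_config(), lambda_fixed = NULL) {
  if (is.null(tree$edge.length) || sum(tree$edge.length) == 0)
    stop("tree has no usable branch lengths")
  present <- names(trajs) %in% tree$tip.label
  if (any(!present)) {
    warning("species absent from tree excluded: ",
            paste(names(trajs)[!present], collapse = ", "))
    trajs <- trajs[present]
  }
  if (length(trajs) < 3L) stop("need at least 3 species on the tree")
  tree <- ape::keep.tip(tree, names(trajs))
  C <- ape::vcv(tree, corr = TRUE)[names(trajs), names(trajs)]
  st <- slope_model_stats(trajs)
  mass <- traits$mass_kg[match(st$species_id, traits$species_id)]
  if (stats::sd(log10(mass)) == 0)
    stop("mass is constant across species: the mass effect is unidentifiable")
  z <- as.numeric(scale(log10(mass)))
  run_slope_chains(st, z, mcmc, C = C, lambda_fixed = lambda_fixed)
}

## shared chain driver for the (phylogenetic) hierarchical slope model
run_slope_chains <- function(st, z, mcmc, C = NULL, lambda_fixed = NULL) {
  ns <- length(st$n)
  phylo <- !is.null(C)
  total <- mcmc$warmup + mcmc$draws
  keep_beta <- matrix(NA_real_, mcmc$draws, mcmc$chains)
  keep_alpha <- keep_beta; keep_sigma <- keep_beta; keep_tau <- keep_beta
  keep_lambda <- if (phylo) keep_beta else NULL
  keep_slopes <- vector("list", mcmc$chains)
  Z <- cbind(1, z)
  for (ch in seq_len(mcmc$chains)) {
    withr_seed(mcmc$seed + 1000L * ch, {
      s <- st$Sxy / pmax(st$Sxx, 1e-12)
      a <- st$ybar
      alpha <- mean(s); beta <- 0
      sigma <- 0.2; tau <- max(stats::sd(s), 0.05)
      lambda <- if (!is.null(lambda_fixed)) lambda_fixed else 0.5
      ls_scale <- 0.1; lt_scale <- 0.2; ll_scale <- 0.5
      slope_draws <- matrix(NA_real_, mcmc$draws, ns)
      if (phylo) {
        Om <- phylo_precision(C, lambda)
        ldet <- attr(Om, "ldet")
      }
      for (it in seq_len(total)) {
        ## species levels (flat prior; x centred so independent of s)
        a <- stats::rnorm(ns, st$ybar, sigma / sqrt(st$n))
        mu_s <- alpha + beta * z
        if (!phylo) {
          prec <- st$Sxx / sigma^2 + 1 / tau^2
          mean_s <- (st$Sxy / sigma^2 + mu_s / tau^2) / prec
          s <- stats::rnorm(ns, mean_s, 1 / sqrt(prec))
        } else {
          P <- diag(st$Sxx / sigma^2, ns) + Om / tau^2
          U <- chol(P)
          b <- st$Sxy / sigma^2 + as.numeric(Om %*% mu_s) / tau^2
          mean_s <- backsolve(U, backsolve(U, b, transpose = TRUE))
          s <- mean_s + backsolve(U, stats::rnorm(ns))
        }
        ## hyper-regression (alpha, beta) with N(0,1) priors
        if (!phylo) {
          M <- crossprod(Z) / tau^2 + diag(2)
          bb <- crossprod(Z, s) / tau^2
        } else {
          M <- t(Z) %*% Om %*% Z / tau^2 + diag(2)
          bb <- t(Z) %*% Om %*% s / tau^2
        }
        Uh <- chol(M)
        mh <- backsolve(Uh, backsolve(Uh, bb, transpose = TRUE))
        g <- mh + backsolve(Uh, stats::rnorm(2))
        alpha <- g[1L]; beta <- g[2L]
        ## residual scale sigma: adaptive RW Metropolis on the log scale
        sse <- sum(st$Syy + st$n * (st$ybar - a)^2 - 2 * s * st$Sxy +
                     s^2 * st$Sxx + 2 * a * 0)  # x centred: no cross term
        lp_sigma <- function(sg)
          -sum(st$n) * log(sg) - sse / (2 * sg^2) + log_half_normal(sg) + log(sg)
        prop <- sigma * exp(stats::rnorm(1, 0, ls_scale))
        acc <- log(stats::runif(1)) < lp_sigma(prop) - lp_sigma(sigma)
        if (acc) sigma <- prop
        if (it <= mcmc$warmup) ls_scale <- adapt_scale(ls_scale, acc, it)
        ## slope-scale tau
        r <- s - (alpha + beta * z)
        qf <- if (!phylo) sum(r^2) else as.numeric(t(r) %*% Om %*% r)
        lp_tau <- function(tu)
          -ns * log(tu) - qf / (2 * tu^2) + log_half_normal(tu) + log(tu)
        prop <- tau * exp(stats::rnorm(1, 0, lt_scale))
        acc <- log(stats::runif(1)) < lp_tau(prop) - lp_tau(tau)
        if (acc) tau <- prop
        if (it <= mcmc$warmup) lt_scale <- adapt_scale(lt_scale, acc, it)
        ## phylogenetic signal lambda (logit random walk, uniform prior)
        if (phylo && is.null(lambda_fixed)) {
          lp_lambda <- function(lam) {
            Oml <- phylo_precision(C, lam)
            -0.5 * attr(Oml, "ldet") -
              as.numeric(t(r) %*% Oml %*% r) / (2 * tau^2) +
              log(lam) + log(1 - lam)  # logit jacobian
          }
          eta <- stats::qlogis(lambda) + stats::rnorm(1, 0, ll_scale)
          lam_p <- stats::plogis(eta)
          acc <- log(stats::runif(1)) < lp_lambda(lam_p) - lp_lambda(lambda)
          if (acc) {
            lambda <- lam_p
            Om <- phylo_precision(C, lambda)
          }
          if (it <= mcmc$warmup) ll_scale <- adapt_scale(ll_scale, acc, it, 0.3)
        }
        if (it > mcmc$warmup) {
          k <- it - mcmc$warmup
          keep_beta[k, ch] <- beta; keep_alpha[k, ch] <- alpha
          keep_sigma[k, ch] <- sigma; keep_tau[k, ch] <- tau
          if (phylo) keep_lambda[k, ch] <- lambda
          slope_draws[k, ] <- s
        }
      }
      keep_slopes[[ch]] <- slope_draws
    })
  }
  rhat <- c(beta = split_rhat(keep_beta), alpha = split_rhat(keep_alpha),
            sigma = split_rhat(keep_sigma))
  slopes_all <- do.call(rbind, keep_slopes)
  colnames(slopes_all) <- st$species_id
  out <- list(
    species_id = st$species_id,
    slopes = report_subsample(slopes_all, mcmc$report_draws, mcmc$seed),
    beta = as.numeric(keep_beta), alpha = as.numeric(keep_alpha),
    sigma = as.numeric(keep_sigma), tau = as.numeric(keep_tau),
    lambda = if (phylo) as.numeric(keep_lambda) else NULL,
    rhat = rhat, ess_beta = ess_basic(keep_beta),
    converged = all(rhat < 1.01),
    n_draws = length(keep_beta)
  )
  if (max(rhat) >= 1.03)  # clear non-convergence; marginal cases only flag
    warning("chains flagged as non-converged (max split R-hat = ",
            round(max(rhat), 4), ")")
  class(out) <- "slope_posterior"
  out
}

phylo_precision <- function(C, lambda) {
  S <- lambda * C + diag(1 - lambda, nrow(C))
  U <- chol(S)
  Om <- chol2inv(U)
  attr(Om, "ldet") <- 2 * sum(log(diag(U)))
  Om
}

#' @export
print.slope_posterior <- function(x, ...) {
  hb <- hpdi(x$beta)
  cat(sprintf(paste0("<slope_posterior> %d species, %d draws; mass effect ",
                     "beta mean %.3f, 95%% HPDI [%.3f, %.3f]%s\n"),
              length(x$species_id), x$n_draws, mean(x$beta), hb[1L], hb[2L],
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Bayesian regression of decline severity on mass and extremum times
#'
#' Regresses logit(severity) on standardised log10 mass and the (years BP)
#' times at which each species hit its lowest and highest size. Severities
#' exactly 0 or 1 are winsorised to `(1e-6, 1 - 1e-6)`. Priors are
#' Normal(0,1) on the standardised coefficients and half-Normal(0,1) on the
#' residual scale; sampling is Gibbs on coefficients with Metropolis on the
#' scale. Predictors are ranked by absolute posterior-mean standardised
#' effect.
#'
#' @param severities Data.frame from [decline_severity()] rows.
#' @param traits Traits table with `species_id` and `mass_kg`.
#' @param mcmc An [mcmc_config()].
#' @return A `severity_posterior`: coefficient draws (columns `z_mass`,
#'   `z_t_min`, `z_t_max` plus intercept), `ranking`, posterior-mean `r2`.
#' @export
fit_severity_model <- function(severities, traits, mcmc = mcmc_config()) {
  if (nrow(severities) < 3L) stop("need at least 3 species")
  sv <- pmin(pmax(severities$severity, 1e-6), 1 - 1e-6)
  if (any(sv != severities$severity))
    message("winsorised ", sum(sv != severities$severity),
            " severities at the (0, 1) boundary")
  y <- stats::qlogis(sv)
  mass <- traits$mass_kg[match(severities$species_id, traits$species_id)]
  zs <- function(v) if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else v * 0
  X <- cbind(intercept = 1, z_mass = zs(log10(mass)),
             z_t_min = zs(severities$t_min_yr),
             z_t_max = zs(severities$t_max_yr))
  n <- length(y); p <- ncol(X)
  total <- mcmc$warmup + mcmc$draws
  coefs <- vector("list", mcmc$chains)
  sig_ch <- matrix(NA_real_, mcmc$draws, mcmc$chains)
  XtX <- crossprod(X); Xty <- crossprod(X, y)
  for (ch in seq_len(mcmc$chains)) {
    withr_seed(mcmc$seed + 2000L * ch, {
      b <- rep(0, p); sigma <- max(stats::sd(y), 0.1)
      sc <- 0.2
      keep <- matrix(NA_real_, mcmc$draws, p)
      for (it in seq_len(total)) {
        ## prior scale 10 on the intercept, 1 on standardised slopes
        M <- XtX / sigma^2 + diag(c(0.01, rep(1, p - 1L)))
        U <- chol(M)
        mb <- backsolve(U, backsolve(U, Xty / sigma^2, transpose = TRUE))
        b <- as.numeric(mb + backsolve(U, stats::rnorm(p)))
        sse <- sum((y - X %*% b)^2)
        lp <- function(sg) -n * log(sg) - sse / (2 * sg^2) +
          log_half_normal(sg, 3) + log(sg)
        prop <- sigma * exp(stats::rnorm(1, 0, sc))
        acc <- log(stats::runif(1)) < lp(prop) - lp(sigma)
        if (acc) sigma <- prop
        if (it <= mcmc$warmup) sc <- adapt_scale(sc, acc, it)
        if (it > mcmc$warmup) {
          keep[it - mcmc$warmup, ] <- b
          sig_ch[it - mcmc$warmup, ch] <- sigma
        }
      }
      coefs[[ch]] <- keep
    })
  }
  draws <- do.call(rbind, coefs)
  colnames(draws) <- colnames(X)
  bm <- colMeans(draws)
  fitted <- as.numeric(X %*% bm)
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  eff <- abs(bm[-1L])
  structure(list(
    coefs = report_subsample(draws, mcmc$report_draws, mcmc$seed),
    ranking = names(sort(eff, decreasing = TRUE)),
    r2 = r2, rhat_sigma = split_rhat(sig_ch)
  ), class = "severity_posterior")
}
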