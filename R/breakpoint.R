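#' Two-segment piecewise regression of log10 Ne on log time
#'
#' Fits a continuous two-segment linear model of log10 Ne against
#' "forward log-time" (`-log10` years BP, so that declines toward the
#' present have negative slope, the field's reporting convention) with the
#' breakpoint chosen to minimise the residual sum of squares. The search
#' profiles the breakpoint over midpoints between sorted unique abscissae
#' inside the search range, then refines the best candidate by continuous
#' one-dimensional optimisation, so noiseless two-segment inputs are
#' recovered exactly and the returned RSS is globally optimal on any grid.
#'
#' @param points Data.frame with columns `log10_t` (log10 years BP) and
#'   `log10_ne` (at least 6 rows).
#' @param search Breakpoint search range in years BP `c(min_yr, max_yr)`;
#'   defaults to the interior of the data support.
#' @param refine Refine the best grid candidate by continuous
#'   optimisation (disable for speed inside bootstrap loops).
#' @return An object of class `breakpoint_fit`: breakpoint (years BP and
#'   log10), the two slopes (`slope_pre` older, `slope_post` younger than
#'   the breakpoint, d log10 Ne per decade toward the present) with
#'   standard errors and p-values, intercept (fitted value at the
#'   breakpoint), `rss`, `n_points`, and a `flag` (`"ok"` or
#'   `"no breakpoint support"`).
#' @export
fit_piecewise <- function(points, search = NULL, refine = TRUE) {
  if (nrow(points) < 6L) stop("need at least 6 points")
  x <- -points$log10_t   # forward log-time
  y <- points$log10_ne
  if (length(unique(x)) < 3L) stop("degenerate x-values: cannot place a breakpoint")
  xr <- range(x)
  if (is.null(search)) {
    srch <- xr
  } else {
    srch <- sort(-log10(search))
    srch[1L] <- max(srch[1L], xr[1L]); srch[2L] <- min(srch[2L], xr[2L])
  }
  ux <- sort(unique(x))
  cand <- (ux[-1L] + ux[-length(ux)]) / 2
  cand <- cand[cand > srch[1L] & cand < srch[2L]]
  if (length(cand) == 0L) stop("search range excludes all breakpoint candidates")
  rss <- vapply(cand, function(p) piecewise_rss(x, y, p), numeric(1))
  j <- which.min(rss)
  psi <- cand[j]
  best <- rss[j]
  if (refine) {
    ## refine the brackets around the few best candidates: the global
    ## optimum can sit inside a gap whose midpoint is not the grid argmin
    for (jj in utils::head(order(rss), 5L)) {
      lo <- if (jj > 1L) cand[jj - 1L] else srch[1L]
      hi <- if (jj < length(cand)) cand[jj + 1L] else srch[2L]
      opt <- stats::optimize(function(p) piecewise_rss(x, y, p),
                             lower = lo, upper = hi, tol = 1e-10)
      if (opt$objective < best) { psi <- opt$minimum; best <- opt$objective }
    }
  }
  fit <- piecewise_ols(x, y, psi)
  slope_diff_p <- fit$p_diff
  flag <- if (!is.finite(slope_diff_p) || slope_diff_p > 0.05)
    "no breakpoint support" else "ok"
  structure(list(
    breakpoint_log10t = -psi, breakpoint_yr = 10^(-psi),
    slope_pre = fit$slope_pre, slope_post = fit$slope_post,
    intercept = fit$intercept,
    se_pre = fit$se_pre, se_post = fit$se_post,
    p_pre = fit$p_pre, p_post = fit$p_post,
    rss = fit$rss, n_points = length(y),
    x_range = xr, flag = flag, ci_yr = c(NA_real_, NA_real_)
  ), class = "breakpoint_fit")
}

piecewise_basis <- function(x, psi) cbind(1, x - psi, pmax(x - psi, 0))

piecewise_rss <- function(x, y, psi) {
  f <- stats::lm.fit(piecewise_basis(x, psi), y)
  sum(f$residuals^2)
}

piecewise_ols <- function(x, y, psi) {
  X <- piecewise_basis(x, psi)
  f <- stats::lm.fit(X, y)
  cf <- f$coefficients
  rss <- sum(f$residuals^2)
  df <- length(y) - 3L
  s2 <- rss / max(df, 1L)
  XtXi <- chol2inv(chol(crossprod(X)))
  V <- s2 * XtXi
  slope_pre <- cf[2L]                 # x < psi: older than the breakpoint
  slope_post <- cf[2L] + cf[3L]       # x > psi: younger
  se_pre <- sqrt(V[2L, 2L])
  se_post <- sqrt(V[2L, 2L] + V[3L, 3L] + 2 * V[2L, 3L])
  se_diff <- sqrt(V[3L, 3L])
  pt2 <- function(est, se) {
    if (se == 0) return(if (est == 0) 1 else 0)
    2 * stats::pt(abs(est / se), df = max(df, 1L), lower.tail = FALSE)
  }
  list(intercept = unname(cf[1L]), slope_pre = unname(slope_pre),
       slope_post = unname(slope_post), se_pre = se_pre, se_post = se_post,
       p_pre = pt2(slope_pre, se_pre), p_post = pt2(slope_post, se_post),
       p_diff = pt2(cf[3L], se_diff), rss = rss)
}

#' @export
print.breakpoint_fit <- function(x, ...) {
  cat(sprintf(paste0("<breakpoint_fit> break at %s yr BP ",
                     "(slopes pre %.3f, post %.3f; rss %.4g; %s)\n"),
              format(round(x$breakpoint_yr), big.mark = ","),
              x$slope_pre, x$slope_post, x$rss, x$flag))
  invisible(x)
}

#' Bootstrap confidence interval for the breakpoint
#'
#' Case-resampling bootstrap: rows of `points` are resampled with
#' replacement, the piecewise model refitted, and the percentile interval of
#' the breakpoint (in years BP) returned. Draws on which the model is
#' unfittable (fewer than 6 usable points or degenerate abscissae) are
#' rejected and redrawn; the interval is widened, if necessary, to contain
#' the point estimate.
#'
#' @inheritParams fit_piecewise
#' @param fit The [fit_piecewise()] fit being assessed.
#' @param n_boot Number of bootstrap draws (>= 200).
#' @param seed Integer seed.
#' @param level Interval level (default 0.95).
#' @return Numeric `c(low_yr, high_yr)`, with attributes `n_rejected`.
#' @export
breakpoint_ci <- function(points, fit, n_boot = 1000, seed = 1,
                          level = 0.95) {
  if (n_boot < 200) stop("n_boot must be at least 200")
  n <- nrow(points)
  bps <- numeric(n_boot)
  rejected <- 0L
  withr_seed(seed, {
    for (b in seq_len(n_boot)) {
      repeat {
        ix <- sample.int(n, n, replace = TRUE)
        res <- tryCatch(fit_piecewise(points[ix, , drop = FALSE],
                                      refine = FALSE),
                        error = function(e) NULL)
        if (!is.null(res)) break
        rejected <- rejected + 1L
      }
      bps[b] <- res$breakpoint_yr
    }
  })
  a <- (1 - level) / 2
  ci <- unname(stats::quantile(bps, c(a, 1 - a)))
  ci <- c(min(ci[1L], fit$breakpoint_yr), max(ci[2L], fit$breakpoint_yr))
  attr(ci, "n_rejected") <- rejected
  ci
}

#' Pooled piecewise fits by realm or globally
#'
#' Pools every species' window points (log10 midpoint time, log10 Ne)
#' within each group and fits one piecewise model per group. With
#' `grouping = "global"` all species form a single group. Groups with
#' fewer than 2 species are skipped with a warning. Points are pooled raw
#' (each window contributes equally); `weight = "species"` instead weights
#' each species' points by the inverse of its window count.
#'
#' @param trajs Named list of [ne_trajectory()] objects.
#' @param traits Traits table assigning `species_id` to `realm`.
#' @param grouping `"realm"` or `"global"`.
#' @param search Breakpoint search range, years BP (see [fit_piecewise()]).
#' @param weight `"none"` (pool raw points) or `"species"`.
#' @return Named list of `breakpoint_fit` objects.
#' @export
grouped_fits <- function(trajs, traits, grouping = c("realm", "global"),
                         search = NULL, weight = c("none", "species")) {
  grouping <- match.arg(grouping)
  weight <- match.arg(weight)
  pts <- pooled_points(trajs)
  pts$realm <- traits$realm[match(pts$species_id, traits$species_id)]
  groups <- if (grouping == "global") list(global = pts) else
    split(pts, pts$realm)
  out <- list()
  for (g in names(groups)) {
    d <- groups[[g]]
    if (length(unique(d$species_id)) < 2L) {
      warning("group '", g, "' has fewer than 2 species; skipped")
      next
    }
    if (weight == "species") {
      ## equalise species influence by replicating an inverse-count weight
      w <- 1 / table(d$species_id)[d$species_id]
      d <- d[rep(seq_len(nrow(d)), round(as.numeric(w) * 100)), ]
    }
    out[[g]] <- fit_piecewise(d[, c("log10_t", "log10_ne")], search = search)
  }
  out
}

## pooled (log10 mid-time, log10 ne) window points across species;
## the first window (midpoint possibly < 1 yr) is guarded by a 1-yr floor
pooled_points <- function(trajs) {
  do.call(rbind, lapply(trajs, function(tr) {
    w <- trajectory_windows(tr)
    data.frame(species_id = w$species_id,
               log10_t = log10(pmax(w$mid_yr, 1)),
               log10_ne = w$log10_ne)
  }))
}

#' Percent change of fitted population size between two times
#'
#' Evaluates the fitted piecewise model at two times and expresses the
#' change as a percent decrease: `100 (1 - 10^(fit(to) - fit(from)))`, so a
#' decline toward the present is positive.
#'
#' @param fit A `breakpoint_fit`.
#' @param from_yr,to_yr Years BP with `from_yr > to_yr >= 0` (from older to
#'   younger); both must lie inside the fitted support.
#' @return Percent decrease (negative values indicate an increase).
#' @export
segment_change <- function(fit, from_yr, to_yr) {
  if (!(from_yr > to_yr) || to_yr < 0)
    stop("need from_yr > to_yr >= 0 on the BP axis")
  f <- function(yr) {
    if (yr <= 0) stop("cannot evaluate the log-time model at 0 yr")
    x <- -log10(yr)
    if (x < fit$x_range[1L] - 1e-9 || x > fit$x_range[2L] + 1e-9)
      stop(sprintf("time %g yr outside fitted support", yr))
    psi <- -fit$breakpoint_log10t
    slope <- if (x <= psi) fit$slope_pre else fit$slope_post
    fit$intercept + slope * (x - psi)
  }
  100 * (1 - 10^(f(to_yr) - f(from_yr)))
}
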