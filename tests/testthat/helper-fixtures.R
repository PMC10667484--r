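## deterministic fixtures shared across test files

## points lying exactly on a continuous two-segment line in forward
## log-time: slope `pre` older than the breakpoint, `post` younger
two_segment_points <- function(break_yr = 5e4, pre = -0.03, post = -0.50,
                               level = 4.5, n = 40,
                               t_range = c(1e3, 2e6), noise_sd = 0,
                               seed = NULL) {
  lt <- seq(log10(t_range[1]), log10(t_range[2]), length.out = n)
  x <- -lt
  psi <- -log10(break_yr)
  y <- ifelse(x <= psi, level + pre * (x - psi), level + post * (x - psi))
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y + rnorm(n, 0, noise_sd)
  }
  data.frame(log10_t = lt, log10_ne = y)
}

## brute-force time-weighted mean of a step function by midpoint-rule
## integration on a fine uniform grid
riemann_mean <- function(boundaries, values, start_yr, end_yr,
                         n_steps = 2e6) {
  h <- (end_yr - start_yr) / n_steps
  ts <- start_yr + (seq_len(n_steps) - 0.5) * h
  idx <- findInterval(ts, boundaries)
  mean(values[idx])
}

## narrowest contiguous HPDI by exhaustive scan over all windows
hpdi_scan <- function(draws, prob = 0.95) {
  s <- sort(draws)
  n <- length(s)
  w <- ceiling(prob * n)
  if (w >= n) return(c(s[1], s[n]))
  best <- c(Inf, NA, NA)
  for (i in 1:(n - w + 1)) {
    width <- s[i + w - 1] - s[i]
    if (width < best[1]) best <- c(width, s[i], s[i + w - 1])
  }
  best[2:3]
}

## tiny deterministic trajectory used by unit examples
toy_trajectory <- function(ne = c(1000, 5000, 8000, 6000),
                           boundaries = c(0, 1e4, 1e5, 1e6, 3e6),
                           species_id = "Toyus_examplus") {
  ne_trajectory(species_id, boundaries, ne)
}
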