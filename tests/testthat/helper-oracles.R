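# Independent oracles used across tests. These deliberately avoid the
# package's own computational paths.

# Profiled-sigma log-likelihood of the normal-error Hill model maximized
# over a grid of (tp, log10_ga, gw). Vectorized via the identity
# RSS(tp) = sum(y^2) - 2 tp sum(y h) + tp^2 sum(h^2) with h the unit-top
# Hill shape, so a 50^3 grid is cheap.
grid_hill_loglik_max <- function(conc, resp, n_grid = 50) {
  pos <- conc > 0
  lc <- log10(conc[pos])
  tp_grid <- seq(1e-6, 1.5 * max(resp), length.out = n_grid)
  ga_grid <- seq(min(lc) - 2, max(lc) + 2, length.out = n_grid)
  gw_grid <- seq(0.3, 8, length.out = n_grid)
  pairs <- expand.grid(log10_ga = ga_grid, gw = gw_grid)
  n <- length(resp)
  # h: obs x pairs matrix of unit-top Hill shapes (0 at conc == 0)
  lg <- log(10) * outer(log10(pmax(conc, 1e-300)), pairs$log10_ga, function(a, b) b - a)
  h <- 1 / (1 + exp(sweep(lg, 2, pairs$gw, `*`)))
  h[conc == 0, ] <- 0
  A <- colSums(h^2)
  B <- colSums(resp * h)
  Cyy <- sum(resp^2)
  best <- -Inf
  for (tp in tp_grid) {
    rss <- Cyy - 2 * tp * B + tp^2 * A
    rss <- pmax(rss, 1e-300)
    ll <- -n / 2 * (log(2 * pi * rss / n) + 1)
    best <- max(best, max(ll))
  }
  best
}

# Brute-force two-pass quantile-of-quantiles: per region, quantile summary_p
# across assays of the per-assay quantile assay_q across individuals.
brute_multi_assay <- function(values_df, assay_q, summary_p) {
  # values_df: region_id, assay, value (per individual)
  regions <- unique(values_df$region_id)
  out <- data.frame()
  for (r in regions) {
    d <- values_df[values_df$region_id == r, ]
    assays <- unique(d$assay)
    aq <- vapply(assays, function(a) {
      stats::quantile(d$value[d$assay == a], assay_q, type = 7, names = FALSE)
    }, numeric(1))
    out <- rbind(out, data.frame(
      region_id = r,
      value = stats::quantile(aq, summary_p, type = 7, names = FALSE)
    ))
  }
  out
}

# Mean of a normal truncated below at 0 by numerical quadrature.
quadrature_truncnorm_mean <- function(mean, sd) {
  f <- function(x) x * stats::dnorm(x, mean, sd)
  mass <- 1 - stats::pnorm(0, mean, sd)
  stats::integrate(f, 0, mean + 12 * sd, rel.tol = 1e-10)$value / mass
}

# A tiny fully-loaded state for pipeline-level tests.
tiny_state <- function(seed = 11, n_regions = 3, n_chemicals = 3,
                       n_assays = 2, n_per_region = 15, degenerate = FALSE) {
  spec <- fixture_spec(n_regions = n_regions, n_chemicals = n_chemicals,
                       n_assays = n_assays, seed = seed)
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  write_fixtures(spec, dir, degenerate = degenerate)
  load_inputs(dir, risk_config(seed = seed, n_per_region = n_per_region))
}
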