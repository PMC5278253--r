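# Shared fixtures: small, fast configurations built in code.

small_config <- function(n = 2000L, seed = 1L, ...) {
  pop_config(n_individuals = n, rng_seed = seed, ...)
}

# a fitted trend + population + rates bundle at modest scale, memoised per
# test file run
small_world <- local({
  cache <- new.env()
  function(n = 5000L, seed = 11L, n_per_wave = 3000L) {
    key <- paste(n, seed, n_per_wave, sep = "_")
    if (!is.null(cache[[key]])) return(cache[[key]])
    cfg <- small_config(n, seed)
    waves <- generate_survey_waves(cfg, n_per_wave = n_per_wave)
    w <- list(cfg = cfg,
              waves = waves,
              model = fit_salt_trend(waves),
              pop = generate_population(cfg),
              rates = generate_rate_tables(cfg),
              params = risk_params())
    cache[[key]] <- w
    w
  }
})

# brute-force least-absolute-deviation line: the optimal LAD line passes
# through two data points; enumerate all pairs (independent oracle)
lad_brute_force <- function(x, y) {
  best <- Inf; best_b <- c(NA, NA)
  n <- length(x)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (x[i] == x[j]) next
    b1 <- (y[j] - y[i]) / (x[j] - x[i])
    b0 <- y[i] - b1 * x[i]
    obj <- sum(abs(y - b0 - b1 * x))
    if (obj < best) { best <- obj; best_b <- c(b0, b1) }
  }
  list(coef = best_b, objective = best)
}

pinball_objective <- function(x, y, b, tau) {
  r <- y - b[1] - b[2] * x
  mean(r * (tau - (r < 0)))
}
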