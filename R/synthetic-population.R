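#' Generate a synthetic population
#'
#' Draws `n_individuals` synthetic people with demographics, a persistent
#' salt quantile (rank), and co-risk-factors. Salt at any (year, quintile)
#' is the lognormal quantile of the individual's rank in that stratum-year
#' distribution, so trajectories are rank-preserving within individual
#' (perfectly autocorrelated), not independent annual draws. Individuals
#' with age below `age_range[1]` at `start_year` are future cohorts who
#' enter the simulation on reaching the minimum age (the population is
#' closed: no migration).
#'
#' @param cfg A [pop_config()] object.
#' @return A `data.table` (class `salt_population`), one row per individual:
#'   `id`, `birth_year`, `sex` ("M"/"F"), `qimd` (1 = least deprived),
#'   `salt_rank`, `sbp0` (baseline systolic BP, mmHg), `bmi`, `tchol`,
#'   `diabetes`, `smoker`, `ets`, `fruitveg`, `pa`. The config is attached
#'   as attribute `config`.
#' @export
generate_population <- function(cfg) {
  validate_pop_config(cfg)
  cols <- c("id", "birth_year", "sex", "qimd", "salt_rank", "sbp0", "bmi",
            "tchol", "diabetes", "smoker", "ets", "fruitveg", "pa")
  if (cfg$n_individuals == 0L) {
    pop <- data.table(id = integer(), birth_year = integer(),
                      sex = character(), qimd = integer(),
                      salt_rank = numeric(), sbp0 = numeric(),
                      bmi = numeric(), tchol = numeric(),
                      diabetes = integer(), smoker = integer(),
                      ets = integer(), fruitveg = numeric(), pa = numeric())
    setattr(pop, "class", c("salt_population", class(pop)))
    setattr(pop, "config", cfg)
    return(pop)
  }
  set.seed(cfg$rng_seed)
  n <- cfg$n_individuals
  horizon <- cfg$end_year - cfg$start_year
  # ages at start_year, extended below the minimum so cohorts keep entering
  ages <- seq.int(cfg$age_range[1] - horizon, cfg$age_range[2])
  w <- ifelse(ages <= 60, 1, exp(-0.06 * (ages - 60)))
  age0 <- sample(ages, n, replace = TRUE, prob = w)

  pop <- data.table(
    id = seq_len(n),
    birth_year = cfg$start_year - age0,
    sex = ifelse(runif(n) < cfg$sex_ratio, "M", "F"),
    qimd = sample.int(5L, n, replace = TRUE, prob = cfg$qimd_weights),
    salt_rank = pmin(pmax(runif(n), 1e-6), 1 - 1e-6)
  )
  pop[, bmi := pmax(15, rnorm(n, cfg$bmi$mean, cfg$bmi$sd))]
  pop[, tchol := pmax(2.5, rnorm(n, cfg$tchol$mean, cfg$tchol$sd))]
  pop[, diabetes := rbinom(n, 1L, cfg$diabetes_prev)]
  pop[, smoker := rbinom(n, 1L, cfg$smoking_prev)]
  pop[, ets := rbinom(n, 1L, cfg$ets_prev)]
  pop[, fruitveg := pmax(0, rnorm(n, cfg$fruitveg$mean, cfg$fruitveg$sd))]
  pop[, pa := pmin(7, pmax(0, rnorm(n, cfg$pa$mean, cfg$pa$sd)))]

  # SBP with positive dependence on salt, age and BMI
  ref_age <- pmax(age0, cfg$age_range[1])
  salt_ref <- salt_quantile_value(pop$salt_rank,
                                  salt_mean_at(cfg, cfg$start_year, pop$qimd),
                                  cfg$salt_cv)
  sp <- cfg$sbp
  pop[, sbp0 := sp$mean +
        sp$salt_coef * (salt_ref - salt_mean_at(cfg, cfg$start_year, 3L)) +
        sp$age_coef * (ref_age - 50) +
        sp$bmi_coef * (bmi - cfg$bmi$mean) +
        rnorm(n, 0, sp$sd)]
  setcolorder(pop, cols)
  setattr(pop, "class", c("salt_population", class(pop)))
  setattr(pop, "config", cfg)
  pop[]
}

#' Salt trajectories implied by the generator
#'
#' Evaluates each individual's rank in the stratum-year lognormal
#' distribution across years — the generator's "true" exposure, used to
#' build survey waves and as a reference in tests. The simulation pipeline
#' itself uses trajectories projected from a fitted [fit_salt_trend()]
#' model instead.
#'
#' @param pop A `salt_population`.
#' @param years Calendar years (columns of the result).
#' @param cfg Configuration; defaults to the one attached to `pop`.
#' @return Numeric matrix, individuals x years, column names the years.
#' @export
salt_trajectories <- function(pop, years, cfg = attr(pop, "config")) {
  out <- matrix(NA_real_, nrow(pop), length(years),
                dimnames = list(NULL, years))
  for (j in seq_along(years)) {
    m <- salt_mean_at(cfg, years[j], pop$qimd)
    out[, j] <- salt_quantile_value(pop$salt_rank, m, cfg$salt_cv)
  }
  out
}

#' Generate cross-sectional survey waves of salt intake
#'
#' Emulates nationally representative 24-hour-urine surveys: independent
#' cross-sections (not a panel), one per wave year, drawn from the same
#' stratum-year distributions as the population.
#'
#' @param cfg A [pop_config()] object.
#' @param wave_years Calendar years of the waves (default the four survey
#'   years 2001, 2006, 2008, 2011).
#' @param n_per_wave Individuals per wave.
#' @return `data.table` with columns `year`, `sex`, `qimd`, `salt`.
#' @export
generate_survey_waves <- function(cfg, wave_years = c(2001L, 2006L, 2008L, 2011L),
                                  n_per_wave = 10000L) {
  validate_pop_config(cfg)
  set.seed(cfg$rng_seed + 1L)
  waves <- lapply(wave_years, function(y) {
    qimd <- sample.int(5L, n_per_wave, replace = TRUE, prob = cfg$qimd_weights)
    dt <- data.table(
      year = as.integer(y),
      sex = ifelse(runif(n_per_wave) < cfg$sex_ratio, "M", "F"),
      qimd = qimd,
      salt = salt_quantile_value(pmin(pmax(runif(n_per_wave), 1e-6), 1 - 1e-6),
                                 salt_mean_at(cfg, y, qimd), cfg$salt_cv)
    )
    dt
  })
  rbindlist(waves)
}

#' Convert spot-urine-like values to 24-hour-equivalent draws
#'
#' Stochastic enhancement of a spot-like measurement into a
#' 24-hour-urine-equivalent value: a Gaussian-copula coupling preserves the
#' rank ordering of the input (with correlation `rank_corr`) while the
#' marginal is a lognormal with the calibration target mean and SD.
#'
#' @param spot Positive numeric vector of spot-like values.
#' @param calibration List with `mean`, `sd` (both of the 24-h-equivalent
#'   target distribution) and `rank_corr` in `[0, 1]` (default 0.7).
#' @param seed Optional integer seed.
#' @return Numeric vector of 24-h-equivalent salt values (g/day).
#' @export
synthesize_24h_salt <- function(spot, calibration, seed = NULL) {
  if (any(spot <= 0)) stop("spot-like values must be positive")
  if (is.null(calibration$mean) || calibration$mean <= 0)
    stop("calibration mean must be positive")
  if (is.null(calibration$sd) || calibration$sd < 0)
    stop("calibration sd must be non-negative")
  rho <- if (is.null(calibration$rank_corr)) 0.7 else calibration$rank_corr
  if (rho < 0 || rho > 1) stop("rank_corr must be in [0, 1]")
  n <- length(spot)
  if (calibration$sd == 0) return(rep(calibration$mean, n))
  if (!is.null(seed)) set.seed(seed)
  z_in <- qnorm((rank(spot, ties.method = "average") - 0.5) / n)
  z_out <- rho * z_in + sqrt(1 - rho^2) * rnorm(n)
  cv <- calibration$sd / calibration$mean
  sdlog <- sqrt(log(1 + cv^2))
  qlnorm(pnorm(z_out), meanlog = log(calibration$mean) - sdlog^2 / 2,
         sdlog = sdlog)
}

#' Write / read a population as CSV
#'
#' Long format has one row per individual-year with the generator salt
#' value; wide format one row per individual (the [generate_population()]
#' columns).
#'
#' @param pop A `salt_population`.
#' @param path File path.
#' @param format `"wide"` (default) or `"long"`.
#' @param years Years for the long format (default the config horizon).
#' @export
write_population <- function(pop, path, format = c("wide", "long"),
                             years = NULL) {
  format <- match.arg(format)
  cfg <- attr(pop, "config")
  if (format == "wide") {
    fwrite(pop, path)
  } else {
    if (is.null(years)) years <- cfg$start_year:cfg$end_year
    traj <- salt_trajectories(pop, years, cfg)
    long <- data.table(
      id = rep(pop$id, length(years)),
      year = rep(years, each = nrow(pop)),
      sex = rep(pop$sex, length(years)),
      qimd = rep(pop$qimd, length(years)),
      salt = as.vector(traj)
    )
    fwrite(long, path)
  }
  invisible(path)
}
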