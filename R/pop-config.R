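#' Configuration of the synthetic population generator
#'
#' Builds and validates the configuration object consumed by
#' [generate_population()], [generate_survey_waves()] and
#' [generate_rate_tables()]. Defaults describe an English-like
#' non-institutionalised adult population: mean daily salt intake
#' (24-hour-urine equivalent) anchored at 9.5 g/day in 2001 falling to
#' 8.1 g/day in 2011, declining log-linearly in time, with higher intake in
#' more deprived quintiles and a right-skewed (lognormal) marginal
#' distribution.
#'
#' @param n_individuals Number of synthetic individuals. The generated set
#'   includes future cohorts (individuals younger than `age_range[1]` at
#'   `start_year`) who activate on reaching the minimum age, so that the
#'   reporting window stays populated through `end_year`.
#' @param start_year,end_year Calendar years bounding the simulated horizon.
#' @param age_range Two integers, minimum and maximum simulated age (adults;
#'   events are *reported* for ages 30-84 regardless).
#' @param sex_ratio Proportion male.
#' @param qimd_weights Five proportions (must sum to 1) for deprivation
#'   quintiles 1 (least deprived) to 5 (most deprived).
#' @param salt_mean_by_year Named numeric vector of mean-salt anchors in
#'   g/day, names are calendar years. Between and beyond anchors the mean is
#'   interpolated/extrapolated linearly in `log(year - year0)` with
#'   `year0 = min(anchor year) - 1`, i.e. a logarithmic decline.
#' @param salt_qimd_gradient Difference in mean salt (g/day), most minus
#'   least deprived quintile; applied additively, centred on quintile 3.
#' @param salt_cv Coefficient of variation of the within-stratum salt
#'   distribution. Default 0.40, typical of single-collection 24-h urine
#'   surveys (cross-sectional SD inflated by day-to-day variation).
#' @param sbp List of systolic blood pressure generation parameters:
#'   `mean`, `sd` (residual), `salt_coef` (mmHg per g/day, cross-sectional),
#'   `age_coef` (mmHg per year over age 50), `bmi_coef` (mmHg per kg/m^2
#'   over 27).
#' @param bmi,tchol Lists with `mean` and `sd` for body-mass index and total
#'   cholesterol.
#' @param diabetes_prev,smoking_prev,ets_prev Prevalence of diabetes, current
#'   smoking and environmental tobacco smoke exposure.
#' @param fruitveg,pa Lists with `mean` and `sd` for fruit & vegetable
#'   portions/day and days/week with >= 30 min physical activity.
#' @param rate_params List controlling the synthetic baseline rate tables:
#'   `qimd_inc_gradient` (relative incidence increase per quintile step),
#'   `qimd_mort_gradient` (same for other-cause mortality) and
#'   `age_monotone` (enforce incidence non-decreasing in age).
#' @param rng_seed Integer seed; regenerating with the same config is
#'   bit-identical.
#'
#' @return A list of class `salt_pop_config`.
#' @export
pop_config <- function(n_individuals = 10000L,
                       start_year = 2001L,
                       end_year = 2030L,
                       age_range = c(19L, 99L),
                       sex_ratio = 0.5,
                       qimd_weights = rep(0.2, 5),
                       salt_mean_by_year = c("2001" = 9.5, "2011" = 8.1),
                       salt_qimd_gradient = 0.8,
                       salt_cv = 0.40,
                       sbp = list(mean = 122, sd = 12, salt_coef = 0.9,
                                  age_coef = 0.35, bmi_coef = 0.7),
                       bmi = list(mean = 27.2, sd = 4.6),
                       tchol = list(mean = 5.4, sd = 1.0),
                       diabetes_prev = 0.06,
                       smoking_prev = 0.22,
                       ets_prev = 0.20,
                       fruitveg = list(mean = 3.8, sd = 1.8),
                       pa = list(mean = 2.5, sd = 1.8),
                       rate_params = list(qimd_inc_gradient = 0.08,
                                          qimd_mort_gradient = 0.05,
                                          age_monotone = TRUE),
                       rng_seed = 1L) {
  cfg <- list(
    n_individuals = as.integer(n_individuals),
    start_year = as.integer(start_year),
    end_year = as.integer(end_year),
    age_range = as.integer(age_range),
    sex_ratio = sex_ratio,
    qimd_weights = qimd_weights,
    salt_mean_by_year = salt_mean_by_year,
    salt_qimd_gradient = salt_qimd_gradient,
    salt_cv = salt_cv,
    sbp = sbp, bmi = bmi, tchol = tchol,
    diabetes_prev = diabetes_prev,
    smoking_prev = smoking_prev,
    ets_prev = ets_prev,
    fruitveg = fruitveg, pa = pa,
    rate_params = rate_params,
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "salt_pop_config"
  validate_pop_config(cfg)
  cfg
}

validate_pop_config <- function(cfg) {
  stopifnot(inherits(cfg, "salt_pop_config"))
  if (is.na(cfg$n_individuals) || cfg$n_individuals < 0L)
    stop("n_individuals must be a non-negative integer")
  if (length(cfg$qimd_weights) != 5L || any(cfg$qimd_weights < 0))
    stop("qimd_weights must be 5 non-negative proportions")
  if (abs(sum(cfg$qimd_weights) - 1) > 1e-8)
    stop("qimd_weights must sum to 1")
  if (length(cfg$age_range) != 2L || cfg$age_range[1] >= cfg$age_range[2])
    stop("age_range must be ordered [min, max]")
  anchors <- cfg$salt_mean_by_year
  if (is.null(names(anchors)) || anyNA(as.integer(names(anchors))))
    stop("salt_mean_by_year must be named by calendar year")
  if (any(anchors <= 0))
    stop("salt anchors must be positive")
  if (cfg$salt_cv <= 0)
    stop("salt_cv must be positive")
  if (cfg$start_year >= cfg$end_year)
    stop("start_year must precede end_year")
  invisible(cfg)
}

#' Read a run configuration from a YAML file
#'
#' Flat key-value YAML; recognised keys are the arguments of [pop_config()]
#' (nested lists such as `sbp:` are supported by YAML mapping syntax).
#' Unknown keys raise an error rather than being ignored.
#'
#' @param path Path to the YAML configuration file.
#' @return A `salt_pop_config` object.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pop_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  if (!is.null(vals$salt_mean_by_year))
    vals$salt_mean_by_year <- unlist(vals$salt_mean_by_year)
  do.call(pop_config, vals)
}

# Mean salt (g/day) implied by the anchors at a given year: linear in
# log(year - year0), segment-wise between anchors, end segments extrapolated.
salt_trend_mean <- function(cfg, year) {
  anchors <- cfg$salt_mean_by_year
  ay <- as.integer(names(anchors))
  o <- order(ay)
  ay <- ay[o]; am <- unname(anchors[o])
  year0 <- ay[1] - 1L
  if (any(year <= year0))
    stop("year must exceed the trend origin (", year0, ")")
  x <- log(year - year0)
  if (length(ay) == 1L) return(rep(am, length(x)))
  ax <- log(ay - year0)
  idx <- pmin(pmax(findInterval(x, ax), 1L), length(ax) - 1L)
  slope <- (am[idx + 1L] - am[idx]) / (ax[idx + 1L] - ax[idx])
  am[idx] + slope * (x - ax[idx])
}

#' Target mean salt of a stratum-year under the generator
#'
#' The generator's own target: the anchor-interpolated logarithmic time
#' trend plus the additive deprivation gradient (centred on quintile 3).
#' Exposed so tests can compare sample moments against the value they were
#' generated from.
#'
#' @param cfg A `salt_pop_config`.
#' @param year Calendar year(s).
#' @param qimd Deprivation quintile(s) 1-5 (1 = least deprived).
#' @return Mean salt in g/day.
#' @export
salt_mean_at <- function(cfg, year, qimd = 3L) {
  m <- salt_trend_mean(cfg, year) + cfg$salt_qimd_gradient * (qimd - 3) / 4
  if (any(m <= 0)) stop("configured trend/gradient implies non-positive salt")
  m
}

# Lognormal quantile with mean m and coefficient of variation cv.
salt_quantile_value <- function(rank, m, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  qlnorm(rank, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}
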