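#' Cases and deaths prevented or postponed
#'
#' Counts first events and cause-specific deaths in each run within the
#' reporting period and age window, and differences them
#' (counterfactual minus policy): positive values mean the policy
#' prevented or postponed events. CHD and stroke are pooled into CVD;
#' gastric cancer is reported separately.
#'
#' @param counterfactual,policy `salt_sim` objects from paired runs of the
#'   same iteration (same population and seed).
#' @param period Two calendar years bounding the counting window
#'   (default the full simulated overlap).
#' @param age_range Reporting ages (default 30-84).
#' @param by Stratification columns of the event log (default `"qimd"`;
#'   use `c("qimd", "agegrp", "sex")` for standardisation inputs, with
#'   `agegrp` derived from the event age).
#' @param cfg Population config (needed when `"agegrp"` is requested).
#' @return `data.table` with columns `disease` ("cvd"/"gca"), `measure`
#'   ("cases"/"deaths"), the `by` columns, counterfactual and policy counts
#'   and `cpp` (their difference).
#' @export
cases_prevented <- function(counterfactual, policy, period = NULL,
                            age_range = c(30L, 84L), by = "qimd",
                            cfg = NULL) {
  stopifnot(inherits(counterfactual, "salt_sim"), inherits(policy, "salt_sim"))
  if (counterfactual$seed != policy$seed ||
      !identical(counterfactual$years, policy$years))
    stop("runs are not paired (mismatched seed or years)")
  if (is.null(period)) period <- range(counterfactual$years)

  count_one <- function(sim) {
    ev <- sim$events[year >= period[1] & year <= period[2] &
                       age >= age_range[1] & age <= age_range[2]]
    ev[, disease := fcase(event %in% c("chd", "stroke"), "cvd",
                          event == "gca", "gca",
                          event %in% c("death_chd", "death_stroke"), "cvd",
                          event == "death_gca", "gca",
                          default = NA_character_)]
    ev[, measure := fifelse(grepl("^death", event), "deaths", "cases")]
    ev <- ev[!is.na(disease)]
    if ("agegrp" %in% by) {
      if (is.null(cfg)) stop("cfg needed to derive age groups")
      ag <- age_groups(cfg)
      ev[, agegrp := ag$agegrp[agegrp_index(age, ag)]]
    }
    ev[, .(n_events = .N), by = c("disease", "measure", by)]
  }
  cf <- count_one(counterfactual)
  po <- count_one(policy)
  grid <- if (identical(by, "qimd")) data.table(qimd = 1:5) else
    unique(rbind(cf[, ..by], po[, ..by]))
  combos <- CJ(disease = c("cvd", "gca"), measure = c("cases", "deaths"),
               sorted = FALSE)
  combos[, `..k..` := 1L]
  grid <- copy(grid)[, `..k..` := 1L]
  full <- merge(combos, grid, by = "..k..",
                allow.cartesian = TRUE)[, `..k..` := NULL]
  setnames(cf, "n_events", "n_cf"); setnames(po, "n_events", "n_policy")
  out <- merge(merge(full, cf, by = c("disease", "measure", by), all.x = TRUE),
               po, by = c("disease", "measure", by), all.x = TRUE)
  out[is.na(n_cf), n_cf := 0L][is.na(n_policy), n_policy := 0L]
  out[, cpp := n_cf - n_policy]
  setorderv(out, c("disease", "measure", by))
  out[]
}

#' Direct age-sex standardisation of stratum counts
#'
#' Reweights the age-sex-specific rates within each deprivation quintile to
#' a common standard age-sex structure, returning the expected counts each
#' quintile would show if it had the standard structure.
#'
#' @param counts `data.table(qimd, agegrp, sex, n)` of observed counts.
#' @param pys `data.table(qimd, agegrp, sex, py)` of person-years (or
#'   population) denominators; zero denominators with non-zero counts are
#'   an error.
#' @param standard `data.table(agegrp, sex, weight)` common structure; by
#'   default the total `pys` across quintiles.
#' @return `data.table(qimd, standardised)` of standardised counts.
#' @export
direct_standardise <- function(counts, pys, standard = NULL) {
  counts <- as.data.table(counts); pys <- as.data.table(pys)
  if (is.null(standard))
    standard <- pys[, .(weight = sum(py)), by = .(agegrp, sex)]
  m <- merge(pys, counts, by = c("qimd", "agegrp", "sex"), all.x = TRUE)
  m[is.na(n), n := 0]
  if (any(m$py <= 0 & m$n > 0)) stop("zero person-years with non-zero counts")
  m[, rate := fifelse(py > 0, n / py, 0)]
  m <- merge(m, standard, by = c("agegrp", "sex"))
  m[, .(standardised = sum(rate * weight) / sum(weight) * sum(py)),
    by = qimd][order(qimd)]
}

#' Equity slope index across deprivation quintiles
#'
#' The slope-index-of-inequality convention: each quintile is placed at the
#' midpoint of its cumulative population share, ranked from least (rank 0)
#' to most (rank 1) deprived, and the quintile values are regressed on that
#' rank by weighted least squares (weights = quintile populations). The
#' reported slope is the fitted difference between rank 1 and rank 0, i.e.
#' most minus least deprived: a positive slope means more benefit accrues
#' to deprived areas (the policy reduces inequality).
#'
#' For the relative index, pass `relative = TRUE` and the counterfactual
#' stratum burdens: values become CPP as a percentage of the
#' counterfactual burden.
#'
#' @param values Numeric vector of 5 quintile values ordered QIMD 1 (least
#'   deprived) to 5 (most deprived); `NA`s allowed if >= 2 remain.
#' @param populations Quintile population sizes (weights); default equal.
#' @param relative Compute the relative index.
#' @param counterfactual Counterfactual burden per quintile (required when
#'   `relative = TRUE`).
#' @return The slope (a single number; for the relative index, in
#'   percentage points).
#' @export
equity_slope_index <- function(values, populations = rep(1, 5),
                               relative = FALSE, counterfactual = NULL) {
  if (length(values) != 5L) stop("values must have 5 quintiles")
  if (relative) {
    if (is.null(counterfactual)) stop("relative index needs counterfactual burdens")
    values <- 100 * values / counterfactual
  }
  ok <- !is.na(values)
  if (sum(ok) < 2L) stop("fewer than 2 non-missing quintiles")
  p <- populations / sum(populations[ok])
  cum <- cumsum(fifelse(ok, p, 0))
  x <- cum - p / 2
  fit <- lm(values[ok] ~ x[ok], weights = populations[ok])
  unname(coef(fit)[2])
}

#' Summarise a Monte Carlo distribution
#'
#' Median, first and third quartiles (type-7 interpolation) and the
#' probability of superiority `Ps`: the percentage of iterations in which
#' the value is strictly positive, i.e. at least one case/death was
#' prevented or postponed.
#'
#' @param x Per-iteration values (length >= 1).
#' @return Named list: `median`, `q25`, `q75`, `ps` (percent).
#' @export
summarise_mc <- function(x) {
  if (!length(x)) stop("empty input")
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(median = q[2], q25 = q[1], q75 = q[3], ps = 100 * mean(x > 0))
}
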