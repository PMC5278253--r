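#' Draw one Monte Carlo realisation of the risk parameters
#'
#' Second-order parameter uncertainty: each relative risk is drawn from a
#' lognormal whose 2.5/97.5 percentiles match the CI columns of the
#' effect-size table, and the ideal salt level from its PERT distribution.
#' Point estimates are used wherever a CI is absent.
#'
#' @param base A [risk_params()] object holding the point estimates.
#' @return A new `risk_params` realisation.
#' @export
draw_risk_params <- function(base = risk_params()) {
  es <- copy(base$effect_sizes)
  sdlog <- (log(es$ci_high) - log(es$ci_low)) / (2 * qnorm(0.975))
  es[, rr_per_unit := exp(rnorm(.N, log(rr_per_unit), sdlog))]
  out <- base
  out$effect_sizes <- es
  ip <- base$ideal_salt_pert
  out$ideal_salt <- sample_pert(1L, ip[1], ip[2], ip[3])
  out
}

#' Run the full second-order Monte Carlo experiment
#'
#' The orchestration loop: for each iteration, regenerate survey waves and
#' population (first-order sampling uncertainty), refit the salt trend,
#' draw risk parameters and scenario targets (second-order uncertainty),
#' run all scenarios with common random numbers, difference paired event
#' logs into CPP/DPP by deprivation quintile, and compute crude and
#' age-sex-standardised equity slope indices. Aggregation reports medians,
#' IQRs and probabilities of superiority across iterations.
#'
#' Scenario comparisons follow the analysis design: `current_policy` vs
#' `no_intervention` over the whole horizon, and `feasible` / `ideal` vs
#' `current_policy` restricted to `policy_period`.
#'
#' @param cfg A [pop_config()] (its `n_individuals` sets the scale).
#' @param n_iterations Number of Monte Carlo iterations (>= 1).
#' @param seed Master seed; the run is fully reproducible from
#'   `(cfg, seed)`.
#' @param scenarios Character vector of scenarios to run.
#' @param years Simulated horizon.
#' @param policy_period Reporting period for the structural-policy
#'   comparisons.
#' @param n_per_wave Survey wave size for the trend fit.
#' @param base_params Point-estimate [risk_params()].
#' @param out_dir Optional directory; per-iteration and summary CSVs are
#'   written there.
#' @param verbose Log per-iteration progress to stderr.
#' @return List of class `salt_experiment`: `summary` (medians, IQRs, Ps
#'   per quantity) and `iterations` (the raw per-iteration long table).
#' @export
run_experiment <- function(cfg, n_iterations = 20L, seed = 1L,
                           scenarios = c("no_intervention", "current_policy",
                                         "feasible", "ideal"),
                           years = 2003:2030,
                           policy_period = c(2016L, 2030L),
                           n_per_wave = 5000L,
                           base_params = risk_params(),
                           out_dir = NULL, verbose = TRUE) {
  if (n_iterations < 1L) stop("n_iterations must be >= 1")
  validate_pop_config(cfg)
  rows <- vector("list", n_iterations)
  for (i in seq_len(n_iterations)) {
    iter_seed <- (seed * 1009L + i * 7919L) %% .Machine$integer.max
    res <- tryCatch(
      run_iteration(cfg, iter_seed, scenarios, years, policy_period,
                    n_per_wave, base_params),
      error = function(e) stop("iteration ", i, " failed: ",
                               conditionMessage(e), call. = FALSE))
    res[, iteration := i]
    rows[[i]] <- res
    if (verbose) message("iteration ", i, "/", n_iterations, " done")
  }
  iters <- rbindlist(rows)
  summary <- iters[, {
    s <- summarise_mc(value)
    .(median = s$median, q25 = s$q25, q75 = s$q75, ps = s$ps)
  }, by = .(comparison, quantity)]
  out <- list(summary = summary, iterations = iters)
  class(out) <- "salt_experiment"
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fwrite(iters, file.path(out_dir, "iterations.csv"))
    fwrite(summary, file.path(out_dir, "summary.csv"))
  }
  out
}

run_iteration <- function(cfg, iter_seed, scenarios, years, policy_period,
                          n_per_wave, base_params) {
  icfg <- cfg
  icfg$rng_seed <- as.integer(iter_seed %% 1e9)
  set.seed(icfg$rng_seed)
  waves <- generate_survey_waves(icfg, n_per_wave = n_per_wave)
  model <- fit_salt_trend(waves)
  pop <- generate_population(icfg)
  rates <- generate_rate_tables(icfg)
  set.seed(icfg$rng_seed + 2L)
  params <- draw_risk_params(base_params)
  specs <- lapply(setNames(scenarios, scenarios), scenario_spec)
  draws <- lapply(specs, function(spec) {
    if (spec$rule != "target") return(NULL)
    tp <- spec$target_pert
    sample_pert(1L, tp[1], tp[2], tp[3])
  })
  sims <- list()
  for (sc in scenarios) {
    sims[[sc]] <- run_scenario(pop, specs[[sc]], params, rates, model,
                               years = years, seed = icfg$rng_seed + 3L,
                               target_draw = draws[[sc]])
  }
  comparisons <- list()
  if (all(c("no_intervention", "current_policy") %in% scenarios))
    comparisons$current_vs_none <- list(cf = "no_intervention",
                                        pol = "current_policy",
                                        period = range(years))
  for (sc in intersect(c("feasible", "ideal"), scenarios))
    if ("current_policy" %in% scenarios)
      comparisons[[paste0(sc, "_vs_current")]] <-
        list(cf = "current_policy", pol = sc, period = policy_period)

  out <- vector("list", length(comparisons))
  for (k in seq_along(comparisons)) {
    cmp <- comparisons[[k]]
    out[[k]] <- summarise_comparison(sims[[cmp$cf]], sims[[cmp$pol]],
                                     cmp$period, cfg, names(comparisons)[k])
  }
  rbindlist(out)
}

# One comparison -> long table of (comparison, quantity, value)
summarise_comparison <- function(cf_sim, pol_sim, period, cfg, label) {
  byq <- cases_prevented(cf_sim, pol_sim, period = period)
  fine <- cases_prevented(cf_sim, pol_sim, period = period,
                          by = c("qimd", "agegrp", "sex"), cfg = cfg)
  # person-years approximated by the counterfactual population structure at
  # the period midpoint (reporting ages only)
  ag <- age_groups(cfg)
  midy <- floor(mean(period))
  pop_cf <- attr_population_structure(cf_sim, cfg, midy)
  std <- pop_cf[, .(weight = sum(py)), by = .(agegrp, sex)]

  rows <- list()
  for (dis in c("cvd", "gca")) for (ms in c("cases", "deaths")) {
    sub <- byq[disease == dis & measure == ms][order(qimd)]
    vals <- sub$cpp
    burden <- sub$n_cf
    pops <- pop_cf[, .(py = sum(py)), by = qimd][order(qimd)]$py
    rows[[length(rows) + 1L]] <- data.table(
      quantity = c(paste0(dis, "_", ms, "_cpp_total"),
                   paste0(dis, "_", ms, "_cpp_q", 1:5),
                   paste0(dis, "_", ms, "_slope_abs"),
                   paste0(dis, "_", ms, "_slope_rel")),
      value = c(sum(vals), vals,
                equity_slope_index(vals, pops),
                equity_slope_index(vals, pops, relative = TRUE,
                                   counterfactual = pmax(burden, 1)))
    )
    # directly age-sex standardised slopes
    fsub <- fine[disease == dis & measure == ms,
                 .(qimd, agegrp, sex, n = cpp)]
    fburden <- fine[disease == dis & measure == ms,
                    .(qimd, agegrp, sex, n = n_cf)]
    std_cpp <- direct_standardise(fsub, pop_cf, std)
    std_burden <- direct_standardise(fburden, pop_cf, std)
    svals <- std_cpp$standardised[match(1:5, std_cpp$qimd)]
    sburd <- std_burden$standardised[match(1:5, std_burden$qimd)]
    rows[[length(rows) + 1L]] <- data.table(
      quantity = c(paste0(dis, "_", ms, "_slope_abs_std"),
                   paste0(dis, "_", ms, "_slope_rel_std")),
      value = c(equity_slope_index(svals, pops),
                equity_slope_index(svals, pops, relative = TRUE,
                                   counterfactual = pmax(sburd, 1)))
    )
  }
  out <- rbindlist(rows)
  out[, comparison := label]
  out[]
}

# population structure (person-counts by qimd/agegrp/sex) of a run at one
# year, restricted to the reporting ages; deaths up to that year are
# ignored (a documented approximation, used only as standardisation
# denominators and slope weights)
attr_population_structure <- function(sim, cfg, year,
                                      age_range = c(30L, 84L)) {
  ag <- age_groups(cfg)
  dt <- copy(sim$pop_info)
  dt[, age := year - birth_year]
  dt <- dt[age >= age_range[1] & age <= age_range[2]]
  dt[, agegrp := ag$agegrp[agegrp_index(age, ag)]]
  out <- dt[, .(py = .N), by = .(qimd, agegrp, sex)]
  # ensure every quintile appears
  miss <- setdiff(1:5, unique(out$qimd))
  if (length(miss))
    out <- rbind(out, data.table(qimd = miss, agegrp = ag$agegrp[1],
                                 sex = "M", py = 0L))
  out[]
}
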