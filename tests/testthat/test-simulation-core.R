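# year-stepping, competing risks, common random numbers, lag windows

zero_rates <- function(rates) {
  rt <- copy(rates)
  rt[, `:=`(incidence = 0, case_fatality = 0, mortality = 0)]
  rt
}

no_mortality <- function(rates) {
  rt <- copy(rates)
  rt[, `:=`(case_fatality = 0, mortality = 0)]
  rt
}

test_that("null dynamics: zero hazards give no events and pure aging", {
  w <- small_world(n = 1000L, seed = 2L, n_per_wave = 1000L)
  sim <- run_scenario(w$pop, scenario_spec("current_policy"), w$params,
                      zero_rates(w$rates), w$model, years = 2003:2008,
                      seed = 5)
  expect_identical(nrow(sim$events), 0L)
  expect_true(all(sim$yearly$deaths == 0))
  # active population grows only by entrants
  expect_equal(diff(sim$yearly$alive), sim$yearly$entrants[-1])
})

test_that("incident counts match the binomial oracle for identical individuals", {
  w <- small_world(n = 1000L, seed = 2L, n_per_wave = 1000L)
  pop <- copy(w$pop)
  # make all 1000 individuals identical clones
  for (col in setdiff(names(pop), "id")) set(pop, j = col, value = pop[[col]][1])
  setattr(pop, "class", class(w$pop))
  setattr(pop, "config", w$cfg)
  pop[, birth_year := 1950L]
  sim <- run_scenario(pop, scenario_spec("current_policy"), w$params,
                      no_mortality(w$rates), w$model, years = 2003:2003,
                      seed = 31, keep_probabilities = TRUE)
  p <- sim$probs$p$chd[1, 1]
  count <- sum(sim$events$event == "chd")
  interval <- qbinom(c(0.005, 0.995), 1000L, p)
  expect_gte(count, interval[1])
  expect_lte(count, interval[2])
})

test_that("runs are deterministic and respect the horizon", {
  w <- small_world(n = 2000L, seed = 3L, n_per_wave = 1000L)
  a <- run_scenario(w$pop, scenario_spec("current_policy"), w$params, w$rates,
                    w$model, years = 2003:2015, seed = 17)
  b <- run_scenario(w$pop, scenario_spec("current_policy"), w$params, w$rates,
                    w$model, years = 2003:2015, seed = 17)
  expect_identical(as.data.frame(a$events), as.data.frame(b$events))
  expect_true(all(a$events$year <= 2015 & a$events$year >= 2003))
})

test_that("event log honours first-event-only and terminal-death invariants", {
  w <- small_world(n = 20000L, seed = 13L)
  sim <- run_scenario(w$pop, scenario_spec("current_policy"), w$params,
                      w$rates, w$model, years = 2003:2030, seed = 23)
  ev <- sim$events
  dup <- ev[, .N, by = .(id, event)][N > 1]
  expect_identical(nrow(dup[event %in% c("chd", "stroke", "gca")]), 0L)
  deaths <- ev[grepl("^death", event)]
  expect_identical(anyDuplicated(deaths$id), 0L)
  # nothing happens after death
  last <- merge(ev, deaths[, .(id, dyear = year)], by = "id")
  expect_true(all(last$year <= last$dyear))
  # gca remission only 10+ years after onset
  rem <- merge(ev[event == "gca_remission", .(id, ryear = year)],
               ev[event == "gca", .(id, oyear = year)], by = "id")
  expect_true(all(rem$ryear - rem$oyear >= w$params$gca_remission))
})

test_that("accounting identity: alive(t+1) = alive(t) - deaths(t) + entrants(t+1)", {
  w <- small_world(n = 20000L, seed = 13L)
  sim <- run_scenario(w$pop, scenario_spec("current_policy"), w$params,
                      w$rates, w$model, years = 2003:2030, seed = 23)
  yl <- sim$yearly
  expect_equal(yl$alive[-1], yl$alive[-nrow(yl)] - yl$deaths[-nrow(yl)] +
                 yl$entrants[-1])
})

test_that("CRN coupling: lower-salt scenario's CVD event set is a subset", {
  # brute force on a small instance with mortality disabled, as the u < p
  # argument requires (deaths would otherwise truncate histories)
  w <- small_world(n = 100L, seed = 4L, n_per_wave = 2000L)
  rt <- no_mortality(w$rates)
  hi <- run_scenario(w$pop, scenario_spec("no_intervention"), w$params, rt,
                     w$model, years = 2003:2020, seed = 11)
  lo <- run_scenario(w$pop, scenario_spec("current_policy"), w$params, rt,
                     w$model, years = 2003:2020, seed = 11)
  for (dis in c("chd", "stroke")) {
    set_hi <- hi$events[event == dis, paste(id, year)]
    set_lo <- lo$events[event == dis, paste(id, year)]
    expect_true(all(set_lo %in% set_hi))
  }
})

test_that("lag windows: 2003-2015 salt changes hit CVD in 2008-2020, GCa in 2011-2023", {
  w <- small_world(n = 3000L, seed = 6L, n_per_wave = 2000L)
  traj <- project_salt_matrix(w$model, w$pop, 2001:2030)
  bumped <- traj
  cols <- as.character(2003:2015)
  bumped[, cols] <- bumped[, cols] + 1.5     # change confined to 2003-2015
  pa <- incidence_probabilities(traj, w$pop, w$params, w$rates, 2003:2030)
  pb <- incidence_probabilities(bumped, w$pop, w$params, w$rates, 2003:2030)
  yrs <- 2003:2030
  for (dis in c("chd", "stroke")) {
    diffs <- colSums(abs(pb$p[[dis]] - pa$p[[dis]])) > 1e-12
    expect_identical(yrs[diffs], 2008:2020)
  }
  dg <- colSums(abs(pb$p$gca - pa$p$gca)) > 1e-12
  expect_identical(yrs[dg], 2011:2023)
})

test_that("frozen salt leaves incidence paths driven by non-salt factors only", {
  w <- small_world(n = 2000L, seed = 8L, n_per_wave = 1000L)
  traj <- project_salt_matrix(w$model, w$pop, 2001:2015)
  frozen <- traj
  frozen[] <- traj[, 1]
  pr <- incidence_probabilities(frozen, w$pop, w$params, w$rates, 2003:2015)
  # constant exposure: the salt-attributable RR component is constant, so
  # within-individual probabilities change only through age-group hazards
  expect_equal(pr$rr$gca[, 1], pr$rr$gca[, ncol(pr$rr$gca)])
  expect_equal(pr$sbp[, 1], pr$sbp[, ncol(pr$sbp)])
})

test_that("death counts are roughly stationary without improvement and trends", {
  cfg <- small_config(20000L, seed = 19L,
                      salt_mean_by_year = c("2001" = 8.5, "2011" = 8.5))
  waves <- generate_survey_waves(cfg, n_per_wave = 2000L)
  model <- fit_salt_trend(waves)
  pop <- generate_population(cfg)
  rates <- generate_rate_tables(cfg)
  params <- risk_params(fatality_improvement = c(cvd = 0, gca = 0))
  sim <- run_scenario(pop, scenario_spec("current_policy"), params, rates,
                      model, years = 2003:2014, seed = 3)
  d <- sim$yearly$deaths
  first <- mean(d[1:6]); second <- mean(d[7:12])
  expect_lt(abs(second - first) / first, 0.25)
})
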