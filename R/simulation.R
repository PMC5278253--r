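#' Annual incidence probabilities implied by a set of trajectories
#'
#' The deterministic half of the simulation: converts salt trajectories
#' into per-individual, per-year probabilities of first CHD, stroke and
#' gastric cancer events. Salt reaches CVD through systolic blood pressure
#' with the CVD lag kernel (`sbp(y) = sbp0 + delta_sbp(lagged salt change
#' since the first simulated year)`) and gastric cancer directly with the
#' GCa kernel. Relative risks are log-linear above the ideal levels,
#' multiplied across risk factors, and baseline hazards are calibrated per
#' (age group, sex, QIMD) stratum so that mean `h0 * RR` reproduces the
#' rate-table incidence in the first simulated year; hazards convert to
#' probabilities as `1 - exp(-h0 * RR)`.
#'
#' Exposed separately from [run_scenario()] so properties such as
#' lag-window containment can be asserted on the probabilities themselves.
#'
#' @param traj Salt trajectory matrix (individuals x years, column names
#'   calendar years) covering at least two years before `sim_years[1]`.
#' @param pop The `salt_population`.
#' @param params A [risk_params()].
#' @param rates A rate table ([generate_rate_tables()]).
#' @param sim_years Years to be simulated.
#' @return List with `p` and `rr` (lists of matrices per disease,
#'   individuals x `sim_years`), `sbp` matrix, and `h0` (list of
#'   stratum arrays).
#' @export
incidence_probabilities <- function(traj, pop, params, rates, sim_years) {
  cfg <- attr(pop, "config")
  ag <- age_groups(cfg)
  years_all <- as.integer(colnames(traj))
  jsim <- match(sim_years, years_all)
  if (anyNA(jsim)) stop("trajectories do not cover the simulated years")

  k_cvd <- lag_kernel(params$lag_cvd, params$lag_sd_cvd)
  k_gca <- lag_kernel(params$lag_gca, params$lag_sd_gca)
  lag_cvd <- lag_matrix(traj, k_cvd)[, jsim, drop = FALSE]
  lag_gca <- lag_matrix(traj, k_gca)[, jsim, drop = FALSE]

  age_ref <- pmax(sim_years[1] - pop$birth_year, cfg$age_range[1])
  delta <- salt_to_sbp_delta(lag_cvd - lag_cvd[, 1], params$sbp_coefs,
                             age = age_ref, sbp = pop$sbp0)
  sbp <- pop$sbp0 + delta

  rr <- list(
    chd = relative_risk(sbp, rr_lookup(params, "chd", "sbp"),
                        params$ideal_sbp) * static_rr(pop, params, "chd"),
    stroke = relative_risk(sbp, rr_lookup(params, "stroke", "sbp"),
                           params$ideal_sbp) * static_rr(pop, params, "stroke"),
    gca = relative_risk(lag_gca, rr_lookup(params, "gca", "salt"),
                        params$ideal_salt) * static_rr(pop, params, "gca")
  )

  # stratum indices at the calibration (first simulated) year
  age1 <- sim_years[1] - pop$birth_year
  active1 <- age1 >= cfg$age_range[1]
  six <- match(pop$sex, c("M", "F"))
  h0 <- list()
  p <- list()
  for (dis in c("chd", "stroke", "gca")) {
    inc_arr <- rate_array(rates, ag, dis, "incidence")
    rrbar <- array(1, dim = dim(inc_arr), dimnames = dimnames(inc_arr))
    cal <- data.table(ai = agegrp_index(age1, ag), si = six, qi = pop$qimd,
                      rr = rr[[dis]][, 1])[active1 == TRUE]
    m <- cal[, .(rrbar = mean(rr)), by = .(ai, si, qi)]
    rrbar[cbind(m$ai, m$si, m$qi)] <- m$rrbar
    h0[[dis]] <- inc_arr / rrbar
    pm <- matrix(NA_real_, nrow(pop), length(sim_years),
                 dimnames = list(NULL, sim_years))
    for (j in seq_along(sim_years)) {
      ai <- agegrp_index(sim_years[j] - pop$birth_year, ag)
      h0v <- h0[[dis]][cbind(ai, six, pop$qimd)]
      pm[, j] <- 1 - exp(-h0v * rr[[dis]][, j])
    }
    if (any(pm < 0 | pm > 1)) stop("event probability outside [0, 1]")
    p[[dis]] <- pm
  }
  list(p = p, rr = rr, sbp = sbp, h0 = h0)
}

#' Run one scenario through the competing-risk microsimulation
#'
#' Advances the population year by year. Each living, active individual
#' draws independent Bernoulli events for first CHD, stroke and gastric
#' cancer (diseases develop independently; more than one may start in a
#' year), then mortality: a disease-specific fatality hazard for each
#' prevalent disease (base case fatality with secular improvement and the
#' deprivation gradient, multiplied by the same relative risk as
#' incidence) and other-cause mortality, resolved as competing causes with
#' a single recorded cause chosen proportionally to the hazards that
#' fired. All draws use the shared-uniform convention `u < p`: with a
#' common seed, lowering a probability can only remove events, never add
#' them, which is what makes paired scenario runs positively coupled
#' (common random numbers). Gastric cancer survivors reaching 10 years
#' after onset remit and stop drawing GCa fatality. Individuals enter on
#' reaching the minimum simulated age; the population is closed otherwise.
#'
#' @param pop A `salt_population`.
#' @param scenario A [scenario_spec()].
#' @param params A [risk_params()].
#' @param rates A rate table.
#' @param trend_model A fitted [fit_salt_trend()] model from which baseline
#'   trajectories are projected.
#' @param years Simulated calendar years (default 2003-2030).
#' @param seed Integer seed; runs are deterministic given
#'   `(pop, scenario, params, seed)` and paired scenario runs sharing a
#'   seed share their uniforms.
#' @param target_draw PERT draw for target-rule scenarios.
#' @param keep_probabilities Attach the probability matrices (memory-heavy;
#'   for diagnostics and property tests).
#' @param traj Optionally, a precomputed trajectory matrix to use instead
#'   of projecting + applying the scenario (must cover `years[1] - 2`
#'   onwards).
#' @return List of class `salt_sim`: `events` (the event log:
#'   `id, year, event, age, sex, qimd, scenario`), `yearly`
#'   (year, alive active at start, deaths, entrants), `scenario`, `years`,
#'   `salt` (the applied trajectory matrix) and optionally `probs`.
#' @export
run_scenario <- function(pop, scenario, params, rates, trend_model,
                         years = 2003:2030, seed = 1L, target_draw = NULL,
                         keep_probabilities = FALSE, traj = NULL) {
  cfg <- attr(pop, "config")
  stopifnot(inherits(scenario, "scenario_spec"))
  if (is.null(traj)) {
    traj_years <- max(trend_model$year0 + 1L, min(years) - 2L):max(years)
    baseline <- project_salt_matrix(trend_model, pop, traj_years)
    traj <- apply_scenario(baseline, scenario, pop, draw = target_draw)
  }
  probs <- incidence_probabilities(traj, pop, params, rates, years)
  ag <- age_groups(cfg)
  six <- match(pop$sex, c("M", "F"))
  n <- nrow(pop)

  cf_arr <- list(chd = rate_array(rates, ag, "chd", "case_fatality"),
                 stroke = rate_array(rates, ag, "stroke", "case_fatality"),
                 gca = rate_array(rates, ag, "gca", "case_fatality"))
  mort_arr <- rate_array(rates, ag, "other", "mortality")
  kmax <- length(years) - 1L
  mult <- list(
    chd = fatality_multiplier(kmax, params$fatality_improvement["cvd"],
                              params$improvement_decay),
    stroke = fatality_multiplier(kmax, params$fatality_improvement["cvd"],
                                 params$improvement_decay),
    gca = fatality_multiplier(kmax, params$fatality_improvement["gca"],
                              params$improvement_decay)
  )

  alive <- rep(TRUE, n)
  onset <- list(chd = rep(NA_integer_, n), stroke = rep(NA_integer_, n),
                gca = rep(NA_integer_, n))
  remitted <- rep(FALSE, n)
  ev_id <- list(); ev_year <- list(); ev_event <- list(); ev_age <- list()
  yearly <- data.table(year = years, alive = NA_integer_,
                       deaths = NA_integer_, entrants = NA_integer_)

  set.seed(seed)
  for (j in seq_along(years)) {
    y <- years[j]
    age <- y - pop$birth_year
    active <- alive & age >= cfg$age_range[1]
    yearly$alive[j] <- sum(active)
    yearly$entrants[j] <- sum(alive & age == cfg$age_range[1])
    u <- matrix(runif(8L * n), n, 8L)

    # first-event incidence (independent across diseases)
    for (d in seq_along(onset)) {
      dis <- names(onset)[d]
      new <- active & is.na(onset[[dis]]) & u[, d] < probs$p[[dis]][, j]
      if (any(new)) {
        onset[[dis]][new] <- y
        ev_id[[length(ev_id) + 1L]] <- pop$id[new]
        ev_year[[length(ev_year) + 1L]] <- rep(y, sum(new))
        ev_event[[length(ev_event) + 1L]] <- rep(dis, sum(new))
        ev_age[[length(ev_age) + 1L]] <- age[new]
      }
    }

    # gastric cancer remission at 10 years post onset
    rem <- active & !remitted & !is.na(onset$gca) &
      (y - onset$gca) >= params$gca_remission
    if (any(rem)) {
      remitted[rem] <- TRUE
      ev_id[[length(ev_id) + 1L]] <- pop$id[rem]
      ev_year[[length(ev_year) + 1L]] <- rep(y, sum(rem))
      ev_event[[length(ev_event) + 1L]] <- rep("gca_remission", sum(rem))
      ev_age[[length(ev_age) + 1L]] <- age[rem]
    }

    # competing mortality
    ai <- agegrp_index(age, ag)
    idx <- cbind(ai, six, pop$qimd)
    g <- ifelse(age > 70, params$qimd_fatality_gradient / 2,
                params$qimd_fatality_gradient)
    grad <- (1 + g)^(pop$qimd - 3)
    haz <- matrix(0, n, 4L)
    for (d in 1:3) {
      dis <- names(onset)[d]
      prev <- active & !is.na(onset[[dis]]) & onset[[dis]] <= y
      if (dis == "gca") prev <- prev & !remitted
      f <- pmin(cf_arr[[dis]][idx] * mult[[dis]][j] * grad, 1)
      haz[prev, d] <- f[prev] * probs$rr[[dis]][prev, j]
    }
    haz[active, 4L] <- mort_arr[idx][active]
    pdie <- 1 - exp(-haz)
    fired <- u[, 4:7] < pdie
    hf <- haz * fired
    tot <- rowSums(hf)
    dying <- tot > 0
    if (any(dying)) {
      r <- u[dying, 8L] * tot[dying]
      cum1 <- hf[dying, 1L]
      cum2 <- cum1 + hf[dying, 2L]
      cum3 <- cum2 + hf[dying, 3L]
      cause <- 1L + (r > cum1) + (r > cum2) + (r > cum3)
      lab <- c("death_chd", "death_stroke", "death_gca", "death_other")[cause]
      alive[dying] <- FALSE
      ev_id[[length(ev_id) + 1L]] <- pop$id[dying]
      ev_year[[length(ev_year) + 1L]] <- rep(y, sum(dying))
      ev_event[[length(ev_event) + 1L]] <- lab
      ev_age[[length(ev_age) + 1L]] <- age[dying]
    }
    yearly$deaths[j] <- sum(dying)
  }

  events <- data.table(id = as.integer(unlist(ev_id)),
                       year = as.integer(unlist(ev_year)),
                       event = as.character(unlist(ev_event)),
                       age = as.integer(unlist(ev_age)))
  events[, sex := pop$sex[match(id, pop$id)]]
  events[, qimd := pop$qimd[match(id, pop$id)]]
  events[, scenario := scenario$name]
  setorder(events, year, id)
  out <- list(events = events, yearly = yearly, scenario = scenario$name,
              years = years, n = n, seed = seed, salt = traj,
              pop_info = pop[, .(id, birth_year, sex, qimd)])
  if (keep_probabilities) out$probs <- probs
  class(out) <- "salt_sim"
  out
}

#' @export
print.salt_sim <- function(x, ...) {
  cat("<salt_sim> scenario:", x$scenario, " years:", min(x$years), "-",
      max(x$years), " individuals:", x$n, "\n")
  cat("  events:", nrow(x$events), " deaths:", sum(x$yearly$deaths), "\n")
  invisible(x)
}
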