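#' Counterfactual policy scenario specifications
#'
#' The four scenarios of the analysis:
#' \describe{
#'   \item{`no_intervention`}{salt frozen at its 2003 level for every
#'     individual (rule `freeze`).}
#'   \item{`current_policy`}{the fitted logarithmic decline continued
#'     unchanged (rule `trend`).}
#'   \item{`feasible`}{structural policies from 2016 drive the mean salt of
#'     ages 19-64 linearly to a PERT(5.8, 6.0, 7.0) g/day target by 2020
#'     (rule `target`).}
#'   \item{`ideal`}{mean salt of ages 19-64 reaches a PERT(1.5, 3.8, 6.0)
#'     g/day ideal level by 2025 (rule `target`).}
#' }
#' Target-rule reductions are proportional to each individual's excess over
#' the drawn target, so the intervention is more effective for higher
#' consumers and never pushes anyone below the target itself.
#'
#' @param name One of `"no_intervention"`, `"current_policy"`, `"feasible"`,
#'   `"ideal"`.
#' @param ... Overrides of the preset fields (`freeze_year`, `target_pert`
#'   as `c(min, mode, max)`, `target_year`, `policy_start`, `age_range`).
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(name = c("no_intervention", "current_policy",
                                   "feasible", "ideal"), ...) {
  name <- match.arg(name)
  spec <- switch(name,
    no_intervention = list(name = name, rule = "freeze", freeze_year = 2003L),
    current_policy = list(name = name, rule = "trend"),
    feasible = list(name = name, rule = "target",
                    target_pert = c(5.8, 6.0, 7.0), target_year = 2020L,
                    policy_start = 2016L, age_range = c(19L, 64L)),
    ideal = list(name = name, rule = "target",
                 target_pert = c(1.5, 3.8, 6.0), target_year = 2025L,
                 policy_start = 2016L, age_range = c(19L, 64L))
  )
  over <- list(...)
  spec[names(over)] <- over
  if (spec$rule == "target") {
    tp <- spec$target_pert
    if (!(tp[1] <= tp[2] && tp[2] <= tp[3]))
      stop("PERT parameters must satisfy min <= mode <= max")
    if (spec$target_year <= spec$policy_start)
      stop("target_year must follow policy_start")
  }
  class(spec) <- "scenario_spec"
  spec
}

#' Sample from a PERT distribution
#'
#' The PERT is the Beta distribution rescaled to `[min, max]` with shape
#' parameters implied by the mode and the standard shape constant 4:
#' `alpha = 1 + 4 (mode - min)/(max - min)`,
#' `beta  = 1 + 4 (max - mode)/(max - min)`, giving mean
#' `(min + 4 mode + max) / 6`.
#'
#' @param n Number of draws.
#' @param min,mode,max Distribution parameters, `min <= mode <= max`.
#' @param shape Shape constant (default 4).
#' @return Numeric vector of draws, always within `[min, max]`.
#' @export
sample_pert <- function(n, min, mode, max, shape = 4) {
  if (!(min <= mode && mode <= max))
    stop("PERT parameters must satisfy min <= mode <= max")
  if (min == max) return(rep(min, n))
  a <- 1 + shape * (mode - min) / (max - min)
  b <- 1 + shape * (max - mode) / (max - min)
  min + (max - min) * rbeta(n, a, b)
}

#' Apply a policy scenario to salt trajectories
#'
#' Transforms a matrix of baseline (current-policy) salt trajectories into
#' the counterfactual ones:
#' \itemize{
#' \item `trend`: unchanged.
#' \item `freeze`: every year at or after `freeze_year` takes the
#'   individual's `freeze_year` value.
#' \item `target`: from `policy_start`, the mean of the in-window age group
#'   follows a linear path from its baseline value down to the drawn target
#'   by `target_year` (held there afterwards); each individual's reduction
#'   is `lambda(year) * max(0, salt - target)` with `lambda` solved so the
#'   group mean meets the path (clamped to `[0, 1]`). Individuals aging in
#'   are treated from that year on; individuals aging out of the window
#'   stay on the intervention (structural policies act through the food
#'   supply, so an achieved dietary change persists and deepens with the
#'   policy), though `lambda` is always calibrated on the in-window mean.
#' }
#' Applying the same scenario twice is idempotent, and no trajectory is
#' ever made negative.
#'
#' @param traj Baseline salt matrix, individuals x years, column names the
#'   calendar years (as from [project_salt_matrix()]).
#' @param spec A [scenario_spec()].
#' @param pop The `salt_population` the rows of `traj` refer to.
#' @param draw The sampled PERT target (g/day) for target-rule scenarios;
#'   one draw per Monte Carlo iteration.
#' @return Modified trajectory matrix, same shape as `traj`.
#' @export
apply_scenario <- function(traj, spec, pop, draw = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  years <- as.integer(colnames(traj))
  if (spec$rule == "trend") return(traj)

  if (spec$rule == "freeze") {
    j0 <- match(spec$freeze_year, years)
    if (is.na(j0)) stop("freeze_year not covered by trajectories")
    out <- traj
    if (j0 < ncol(out)) out[, (j0 + 1L):ncol(out)] <- out[, j0]
    return(out)
  }

  # target rule
  if (is.null(draw)) stop("target-rule scenario requires a PERT draw")
  tp <- spec$target_pert
  if (draw < tp[1] || draw > tp[3]) stop("draw outside PERT support")
  out <- traj
  ages0 <- spec$age_range
  treated <- logical(nrow(traj))
  js <- which(years >= spec$policy_start)
  if (!length(js)) return(out)
  j_start <- js[1]
  age_start <- years[j_start] - pop$birth_year
  w0 <- age_start >= ages0[1] & age_start <= ages0[2]
  m0 <- mean(traj[w0, j_start])
  for (j in js) {
    y <- years[j]
    frac <- min(1, (y - spec$policy_start) /
                   (spec$target_year - spec$policy_start))
    m_des <- m0 + (draw - m0) * frac
    age <- y - pop$birth_year
    w <- age >= ages0[1] & age <= ages0[2]
    b <- traj[, j]
    excess <- pmax(b - draw, 0)
    me <- mean(excess[w])
    needed <- mean(b[w]) - m_des
    lambda <- if (me > 0) min(1, max(0, needed / me)) else 0
    # lambda is calibrated on the in-window mean, but the reformulated food
    # supply keeps applying to ever-treated individuals who age out
    treated <- treated | w
    el <- w | (treated & age > ages0[2])
    out[el, j] <- b[el] - lambda * excess[el]
  }
  out
}
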