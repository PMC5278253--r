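#' Age groups used by the rate tables
#'
#' First group spans the minimum simulated age up to 29, then 5-year bands
#' to the maximum age.
#'
#' @param cfg A [pop_config()] object.
#' @return `data.table` with `agegrp` (label), `lo`, `hi`, `mid`.
#' @export
age_groups <- function(cfg) {
  lo <- c(cfg$age_range[1], seq.int(30L, cfg$age_range[2], 5L))
  hi <- c(lo[-1] - 1L, cfg$age_range[2])
  data.table(agegrp = paste0(lo, "-", hi), lo = lo, hi = hi,
             mid = (lo + hi) / 2)
}

# index of the age group containing each age (capped at the last band)
agegrp_index <- function(age, ag) {
  pmin(pmax(findInterval(age, ag$lo), 1L), nrow(ag))
}

#' Generate synthetic baseline epidemiological rate tables
#'
#' Stand-ins for the real incidence / case-fatality / mortality calibration
#' inputs (which are out of scope to ingest): smooth Gompertz-like age
#' curves at England-plausible magnitudes for first coronary heart disease
#' (`chd`), stroke, gastric cancer (`gca`) and other-cause death (`other`),
#' with configurable sex and deprivation gradients. Deterministic given the
#' configuration. Incidence and mortality are annual rates per person-year;
#' `case_fatality` is the annual death rate among prevalent cases at the
#' table's base year. Values are rounded to 8 decimals so the CSV
#' round-trip is exact.
#'
#' @param cfg A [pop_config()] object (`cfg$rate_params` controls the
#'   deprivation gradients and age monotonicity).
#' @return `data.table` with columns `disease`, `agegrp`, `sex`, `qimd`,
#'   `incidence`, `case_fatality`, `mortality`.
#' @export
generate_rate_tables <- function(cfg) {
  validate_pop_config(cfg)
  ag <- age_groups(cfg)
  rp <- cfg$rate_params
  grid <- CJ(disease = c("chd", "stroke", "gca", "other"),
             agegrp = ag$agegrp, sex = c("M", "F"), qimd = 1:5, sorted = FALSE)
  grid <- merge(grid, ag[, .(agegrp, mid)], by = "agegrp", sort = FALSE)
  qmult <- (1 + rp$qimd_inc_gradient)^(grid$qimd - 3)
  qmort <- (1 + rp$qimd_mort_gradient)^(grid$qimd - 3)
  male <- grid$sex == "M"
  mid <- grid$mid

  inc <- numeric(nrow(grid))
  cf <- numeric(nrow(grid))
  mort <- numeric(nrow(grid))

  i <- grid$disease == "chd"
  inc[i] <- 4e-4 * exp(0.09 * (mid[i] - 50)) * ifelse(male[i], 1.5, 0.8) * qmult[i]
  cf[i] <- 0.03 * exp(0.045 * (mid[i] - 50))
  i <- grid$disease == "stroke"
  inc[i] <- 2.5e-4 * exp(0.095 * (mid[i] - 50)) * ifelse(male[i], 1.2, 0.9) * qmult[i]
  cf[i] <- 0.06 * exp(0.04 * (mid[i] - 50))
  i <- grid$disease == "gca"
  inc[i] <- 3e-5 * exp(0.085 * (mid[i] - 50)) * ifelse(male[i], 1.7, 0.7) * qmult[i]
  cf[i] <- 0.25 * exp(0.01 * (mid[i] - 50))
  i <- grid$disease == "other"
  mort[i] <- 6e-4 * exp(0.088 * (mid[i] - 45)) * ifelse(male[i], 1.3, 0.85) * qmort[i]

  grid[, incidence := pmin(inc, 0.5)]
  grid[, case_fatality := pmin(cf, 0.8)]
  grid[, mortality := pmin(mort, 0.7)]
  grid[, mid := NULL]

  if (isTRUE(rp$age_monotone)) {
    lev <- ag$agegrp
    grid[, agegrp := factor(agegrp, levels = lev)]
    setorder(grid, disease, sex, qimd, agegrp)
    grid[, incidence := cummax(incidence), by = .(disease, sex, qimd)]
    grid[, mortality := cummax(mortality), by = .(disease, sex, qimd)]
    grid[, agegrp := as.character(agegrp)]
  }
  grid[, `:=`(incidence = round(incidence, 8),
              case_fatality = round(case_fatality, 8),
              mortality = round(mortality, 8))]
  setcolorder(grid, c("disease", "agegrp", "sex", "qimd", "incidence",
                      "case_fatality", "mortality"))
  bad <- grid[incidence < 0 | incidence > 1 | case_fatality < 0 |
                case_fatality > 1 | mortality < 0 | mortality > 1]
  if (nrow(bad)) stop("rate outside [0, 1]")
  grid[]
}

#' @rdname generate_rate_tables
#' @param rates A rate table as returned by `generate_rate_tables()`.
#' @param path CSV file path.
#' @export
write_rate_tables <- function(rates, path) {
  fwrite(rates[, .(disease, agegrp, sex, qimd, incidence, case_fatality,
                   mortality)], path)
  invisible(path)
}

#' @rdname generate_rate_tables
#' @export
read_rate_tables <- function(path) {
  rt <- fread(path, colClasses = list(character = c("disease", "agegrp", "sex"),
                                      integer = "qimd"))
  need <- c("disease", "agegrp", "sex", "qimd", "incidence", "case_fatality",
            "mortality")
  if (!all(need %in% names(rt))) stop("missing rate table columns")
  # rates are stored at 8 decimals; re-round so the text round-trip is exact
  # even when the CSV parser lands one ulp off the writer's double
  rt[, `:=`(incidence = round(incidence, 8),
            case_fatality = round(case_fatality, 8),
            mortality = round(mortality, 8))]
  rt[]
}

# rate table -> array[agegrp, sex, qimd] for one disease/column
rate_array <- function(rates, ag, dis, col) {
  sub <- rates[disease == dis]
  arr <- array(NA_real_, dim = c(nrow(ag), 2L, 5L),
               dimnames = list(ag$agegrp, c("M", "F"), 1:5))
  idx <- cbind(match(sub$agegrp, ag$agegrp), match(sub$sex, c("M", "F")),
               sub$qimd)
  arr[idx] <- sub[[col]]
  if (anyNA(arr)) stop("rate table does not cover all strata for ", dis)
  arr
}
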