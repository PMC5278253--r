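#' Fit the salt time trend by quantile regression
#'
#' Fits, separately for each (sex, QIMD) stratum and each quantile level
#' tau, the linear model `salt ~ intercept + slope * log(year - year0)` by
#' minimising the pinball (check) loss, i.e. quantile regression on a
#' logarithmic time scale. `year0` defaults to 2000 so the 2001 wave maps
#' to `log(1) = 0`. Crossing of fitted quantile curves is remedied at
#' evaluation time by rearrangement (sorting the fitted quantiles).
#'
#' The minimiser is a Nelder-Mead polish of an OLS-based start; with only
#' two free parameters this reproduces the exact linear-programming
#' solution to well below sampling error (and is verified against a
#' brute-force least-absolute-deviation oracle in the test suite).
#'
#' @param waves `data.table` with columns `year`, `sex`, `qimd`, `salt`
#'   (as from [generate_survey_waves()]).
#' @param taus Strictly increasing quantile levels.
#' @param year0 Reference year of the logarithmic time transform.
#' @return Object of class `salt_trend`: a list with `coefs`
#'   (`data.table(tau, sex, qimd, intercept, slope)`), `taus`, `year0`.
#' @export
fit_salt_trend <- function(waves, taus = c(0.05, 0.25, 0.5, 0.75, 0.95),
                           year0 = 2000L) {
  waves <- as.data.table(waves)
  if (!all(c("year", "sex", "qimd", "salt") %in% names(waves)))
    stop("waves must have columns year, sex, qimd, salt")
  if (length(unique(waves$year)) < 2L)
    stop("at least two waves with distinct years are required")
  if (any(waves$salt <= 0)) stop("salt values must be positive")
  if (is.unsorted(taus, strictly = TRUE) || any(taus <= 0) || any(taus >= 1))
    stop("taus must be strictly increasing in (0, 1)")
  if (any(waves$year <= year0)) stop("all wave years must exceed year0")

  strata <- unique(waves[, .(sex, qimd)])
  coefs <- vector("list", nrow(strata) * length(taus))
  k <- 0L
  for (s in seq_len(nrow(strata))) {
    sub <- waves[sex == strata$sex[s] & qimd == strata$qimd[s]]
    if (nrow(sub) == 0L) stop("empty stratum: ", strata$sex[s], "/",
                              strata$qimd[s])
    x <- log(sub$year - year0)
    for (tau in taus) {
      fit <- pinball_fit(x, sub$salt, tau)
      k <- k + 1L
      coefs[[k]] <- data.table(tau = tau, sex = strata$sex[s],
                               qimd = strata$qimd[s],
                               intercept = fit[1], slope = fit[2])
    }
  }
  out <- list(coefs = rbindlist(coefs), taus = taus, year0 = as.integer(year0))
  class(out) <- "salt_trend"
  out
}

# two-parameter quantile regression via Nelder-Mead on the pinball loss
pinball_fit <- function(x, y, tau) {
  loss <- function(b) {
    r <- y - b[1] - b[2] * x
    mean(r * (tau - (r < 0)))
  }
  b0 <- coef(lm(y ~ x))
  # shift the OLS intercept so the tau-quantile of residuals is zero
  b0[1] <- b0[1] + quantile(y - b0[1] - b0[2] * x, tau, names = FALSE)
  fit <- optim(b0, loss, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  # restart once from the solution; guards against premature collapse
  fit <- optim(fit$par, loss, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  unname(fit$par)
}

#' Evaluate fitted quantile curves
#'
#' Returns the rearranged (sorted, non-crossing) fitted quantiles of one
#' stratum at the given years, floored at a small positive value.
#'
#' @param model A `salt_trend`.
#' @param sex,qimd Stratum.
#' @param years Calendar years.
#' @return Matrix `length(taus) x length(years)`.
#' @export
predict_quantiles <- function(model, sex, qimd, years) {
  stopifnot(inherits(model, "salt_trend"))
  if (any(years <= model$year0)) stop("years must exceed year0")
  sx <- sex; qm <- qimd
  cf <- model$coefs[sex == sx & qimd == qm][order(tau)]
  if (nrow(cf) != length(model$taus)) stop("stratum not in model")
  x <- log(years - model$year0)
  q <- outer(cf$intercept, rep(1, length(x))) + outer(cf$slope, x)
  q <- apply(q, 2L, sort)                      # rearrangement
  if (is.null(dim(q))) q <- matrix(q, nrow = length(model$taus))
  pmax(q, 0.05)
}

#' Project individual salt intake from the fitted trend
#'
#' Interpolates each individual's persistent quantile (rank) linearly
#' between adjacent fitted tau curves evaluated at the requested year, with
#' linear tail extension beyond the outermost taus; output floored at
#' 0.05 g/day so projections stay strictly positive. Rank order within a
#' stratum is preserved for all years.
#'
#' @param model A `salt_trend`.
#' @param quantile Individual rank(s) in (0, 1).
#' @param sex,qimd Stratum (vectors recycled against `quantile`).
#' @param year Calendar year (scalar or vector recycled likewise).
#' @return Salt in g/day.
#' @export
project_salt <- function(model, quantile, sex, qimd, year) {
  if (any(quantile <= 0 | quantile >= 1))
    stop("quantile must lie strictly inside (0, 1)")
  n <- max(length(quantile), length(sex), length(qimd), length(year))
  quantile <- rep_len(quantile, n); sex <- rep_len(sex, n)
  qimd <- rep_len(qimd, n); year <- rep_len(year, n)
  out <- numeric(n)
  dt <- data.table(i = seq_len(n), quantile, sex, qimd, year)
  for (grp in split(dt, by = c("sex", "qimd", "year"))) {
    qv <- predict_quantiles(model, grp$sex[1], grp$qimd[1], grp$year[1])[, 1]
    out[grp$i] <- interp_rank(grp$quantile, model$taus, qv)
  }
  pmax(out, 0.05)
}

# linear interpolation of rank u on the (taus, values) grid with linear
# tail extension using the outermost segments
interp_rank <- function(u, taus, values) {
  k <- length(taus)
  idx <- pmin(pmax(findInterval(u, taus), 1L), k - 1L)
  values[idx] + (u - taus[idx]) *
    (values[idx + 1L] - values[idx]) / (taus[idx + 1L] - taus[idx])
}

#' Project salt trajectories for a whole population
#'
#' Vectorised [project_salt()] across a population and a span of years.
#'
#' @param model A `salt_trend`.
#' @param pop A `salt_population`.
#' @param years Calendar years (columns).
#' @return Matrix individuals x years (column names the years).
#' @export
project_salt_matrix <- function(model, pop, years) {
  out <- matrix(NA_real_, nrow(pop), length(years),
                dimnames = list(NULL, years))
  idx <- split(seq_len(nrow(pop)), list(pop$sex, pop$qimd), drop = TRUE)
  for (g in idx) {
    qv <- predict_quantiles(model, pop$sex[g[1]], pop$qimd[g[1]], years)
    for (j in seq_along(years))
      out[g, j] <- interp_rank(pop$salt_rank[g], model$taus, qv[, j])
  }
  pmax(out, 0.05)
}

#' Serialise / deserialise a fitted trend model
#'
#' CSV with columns `tau`, `sex`, `qimd`, `intercept`, `slope`, `year0`.
#'
#' @param model A `salt_trend`.
#' @param path CSV file path.
#' @export
write_salt_trend <- function(model, path) {
  out <- copy(model$coefs)[, `:=`(year0 = model$year0)]
  fwrite(out, path)
  invisible(path)
}

#' @rdname write_salt_trend
#' @export
read_salt_trend <- function(path) {
  cf <- fread(path, colClasses = list(character = "sex"))
  out <- list(coefs = cf[, .(tau, sex, qimd, intercept, slope)],
              taus = sort(unique(cf$tau)), year0 = cf$year0[1])
  class(out) <- "salt_trend"
  out
}
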