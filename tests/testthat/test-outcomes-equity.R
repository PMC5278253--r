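# CPP/DPP differencing, standardisation, equity slopes, MC summaries

make_sim <- function(events, seed = 1L, years = 2003:2015) {
  ev <- as.data.table(events)
  structure(list(events = ev, years = years, seed = seed, n = 100L,
                 pop_info = data.table(id = 1:100, birth_year = 1950L,
                                       sex = "M", qimd = 1L)),
            class = "salt_sim")
}

ev_row <- function(id, year, event, age = 60L, sex = "M", qimd = 1L)
  data.table(id = id, year = year, event = event, age = age, sex = sex,
             qimd = qimd, scenario = "x")

test_that("cases_prevented: self-difference, subtraction and additivity", {
  ev <- rbindlist(list(ev_row(1:10, 2010L, "chd"),
                       ev_row(11:13, 2011L, "gca", qimd = 3L)))
  sim <- make_sim(ev)
  z <- cases_prevented(sim, sim)
  expect_true(all(z$cpp == 0))
  expect_identical(nrow(z), 20L)      # 2 diseases x 2 measures x 5 quintiles

  pol <- make_sim(ev[1:7])            # 7 CVD cases instead of 10, 0 gca
  out <- cases_prevented(sim, pol)
  expect_equal(out[disease == "cvd" & measure == "cases" & qimd == 1, cpp], 3)
  expect_equal(out[disease == "gca" & measure == "cases" & qimd == 3, cpp], 3)
  expect_equal(out[measure == "cases", sum(cpp)], 6)
  # stratum sum equals the total of an unstratified count
  expect_equal(sum(out$cpp),
               sum(out[, .(s = sum(cpp)), by = .(disease, measure)]$s))
  # pairing is enforced
  bad <- make_sim(ev, seed = 99L)
  expect_error(cases_prevented(sim, bad), "not paired")
})

test_that("reporting window filters by age and period", {
  ev <- rbindlist(list(ev_row(1L, 2010L, "chd", age = 25L),   # too young
                       ev_row(2L, 2010L, "chd", age = 90L),   # too old
                       ev_row(3L, 2002L, "chd", age = 60L),   # out of period
                       ev_row(4L, 2010L, "chd", age = 60L)))
  sim <- make_sim(ev)
  none <- make_sim(ev[0])
  out <- cases_prevented(sim, none, period = c(2003L, 2015L))
  expect_equal(out[disease == "cvd" & measure == "cases", sum(cpp)], 1)
})

test_that("direct standardisation: trivial cases and a 2x2 hand example", {
  # identical age-sex structure across quintiles -> standardised = crude
  pys <- CJ(qimd = 1:5, agegrp = c("a", "b"), sex = "M")[, py := rep(c(100, 200), 5)]
  counts <- copy(pys)[, n := rep(c(5, 10), 5)][, py := NULL]
  std <- direct_standardise(counts, pys)
  expect_equal(std$standardised, rep(15, 5))

  # one QIMD standardised to its own structure is unchanged
  own <- pys[qimd == 2, .(agegrp, sex, weight = py)]
  std2 <- direct_standardise(counts[qimd == 2], pys[qimd == 2], own)
  expect_equal(std2$standardised, 15)

  # hand-computed 2-age-group example: rates (.1, .05) vs (.2, .1),
  # standard weights (1, 1) -> expected counts per 2 persons: .15 vs .3,
  # scaled to each stratum's own total person-years (300)
  pys2 <- data.table(qimd = rep(1:2, each = 2), agegrp = rep(c("a", "b"), 2),
                     sex = "M", py = c(100, 200, 200, 100))
  cnt2 <- data.table(qimd = rep(1:2, each = 2), agegrp = rep(c("a", "b"), 2),
                     sex = "M", n = c(10, 10, 40, 10))
  stdp <- data.table(agegrp = c("a", "b"), sex = "M", weight = c(1, 1))
  out <- direct_standardise(cnt2, pys2, stdp)
  expect_equal(out[qimd == 1, standardised], (0.1 + 0.05) / 2 * 300)
  expect_equal(out[qimd == 2, standardised], (0.2 + 0.1) / 2 * 300)
  expect_error(direct_standardise(cnt2, copy(pys2)[, py := 0], stdp), "zero")
})

test_that("equity slope index: analytic cases", {
  expect_equal(equity_slope_index(rep(7, 5)), 0)
  # equal populations, linear gradient: least squares on x = .1 ... .9
  expect_equal(equity_slope_index(c(0, 50, 100, 150, 200)), 250)
  expect_equal(equity_slope_index(rev(c(0, 50, 100, 150, 200))), -250)
  # linearity: slope of a sum is the sum of slopes
  a <- c(3, 9, 2, 8, 1); b <- c(0, 4, 4, 2, 10)
  expect_equal(equity_slope_index(a + b),
               equity_slope_index(a) + equity_slope_index(b))
  # relative index: values as % of counterfactual burden
  expect_equal(equity_slope_index(c(10, 10, 10, 10, 20), relative = TRUE,
                                  counterfactual = rep(100, 5)),
               equity_slope_index(c(10, 10, 10, 10, 20) ))
  expect_error(equity_slope_index(c(1, NA, NA, NA, NA)), "fewer than 2")
  expect_error(equity_slope_index(1:4), "5 quintiles")
})

test_that("unequal populations weight the slope regression", {
  v <- c(0, 50, 100, 150, 200)
  pops <- c(1000, 1000, 1000, 1000, 5000)
  # midpoints shift with cumulative population shares; still exact for a
  # linear-in-x response evaluated on those shares
  p <- pops / sum(pops)
  x <- cumsum(p) - p / 2
  vlin <- 100 * x          # exactly linear in the rank variable
  expect_equal(equity_slope_index(vlin, pops), 100)
})

test_that("summarise_mc: quartiles and probability of superiority", {
  s <- summarise_mc(c(-1, 1, 2, 3))
  expect_equal(s$median, 1.5)
  expect_equal(s$ps, 75)
  expect_equal(s$q25, quantile(c(-1, 1, 2, 3), 0.25, names = FALSE))
  expect_equal(summarise_mc(c(2, 5, 9))$ps, 100)
  one <- summarise_mc(4.2)
  expect_equal(one$median, 4.2)
  expect_equal(one$q25, 4.2)
  expect_equal(one$q75, 4.2)
  expect_error(summarise_mc(numeric(0)), "empty")
})
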