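test_that("season start is the rank-3 mature-cow calving", {
  cv <- data.frame(calf_id = c("a", "b", "c", "d"),
                   birth_date = as.Date("2015-04-01") + c(0, 1, 2, 3),
                   dam_age = c(5, 4, 6, 2))
  expect_equal(seasonStart(cv), as.Date("2015-04-03"))
  # all mature cows calving the same day: that day
  cv2 <- data.frame(calf_id = c("a", "b", "c"),
                    birth_date = as.Date("2015-04-07"), dam_age = 4)
  expect_equal(seasonStart(cv2), as.Date("2015-04-07"))
  # heifer calvings never count toward the rank
  cv3 <- cv; cv3$dam_age <- 2
  expect_error(seasonStart(cv3), "season start undefined")
})

test_that("season start equals a brute-force filter-sort-index oracle on
           mixed heifer/mature records", {
  set.seed(31)
  for (i in 1:10) {
    n <- 30
    cv <- data.frame(
      calf_id = sprintf("c%02d", sample(n)),
      birth_date = as.Date("2016-04-01") + sample(0:60, n, replace = TRUE),
      dam_age = sample(2:9, n, replace = TRUE))
    oracle <- function(x, matureAge, rank) {
      x <- x[x$dam_age >= matureAge, ]
      sort(x$birth_date)[rank]
    }
    expect_equal(seasonStart(cv, 3, 3), oracle(cv, 3, 3))
    expect_equal(seasonStart(cv, 4, 5), oracle(cv, 4, 5))
  }
})

test_that("cycle bins are half-open with pre-start births clamped and
           flagged", {
  start <- as.Date("2015-04-03")
  hb <- HerdBook(data.frame(
    id = c("D1", "C1", "C2", "C3"),
    sex = c("F", "F", "M", "F"),
    birth_date = c(as.Date("2010-04-01"), start + 20, start + 21,
                   start - 2),
    dam_id = c(NA, "D1", "D1", "D1"),
    group = c(NA, 1L, 1L, 1L), year = c(NA, 2014L, 2014L, 2014L)))
  starts <- data.frame(group = 1L, year = 2014L, season_start = start)
  cyc <- assignCycles(hb, starts)
  expect_equal(cyc$cycle, c(1L, 2L, 1L))
  expect_equal(cyc$clamped, c(FALSE, FALSE, TRUE))
})

test_that("an 85-day season spans five 21-day cycles", {
  start <- as.Date("2017-04-01")
  hb <- HerdBook(data.frame(
    id = c("D1", sprintf("C%d", 1:5)),
    sex = c("F", rep("M", 5)),
    birth_date = c(as.Date("2010-04-01"), start + c(0, 21, 42, 63, 84)),
    dam_id = c(NA, rep("D1", 5)),
    group = c(NA, rep(1L, 5)), year = c(NA, rep(2016L, 5))))
  starts <- data.frame(group = 1L, year = 2016L, season_start = start)
  expect_equal(assignCycles(hb, starts)$cycle, 1:5)
})

test_that("cycle assignment is invariant to a common date translation", {
  sim <- simulateHerd(smallParams(seed = 4))
  st <- seasonStartTable(sim$herd)
  c1 <- assignCycles(sim$herd, st)
  shifted <- sim$herd
  shifted@animals$birth_date <- shifted@animals$birth_date + 365
  st2 <- st
  st2$season_start <- st2$season_start + 365
  c2 <- assignCycles(shifted, st2)
  expect_identical(c1$cycle, c2$cycle)
  expect_identical(c1$clamped, c2$clamped)
})

test_that("the heifer group falls back to the herd-wide season start", {
  sim <- simulateHerd(smallParams(seed = 4))
  st <- seasonStartTable(sim$herd)
  expect_true(all(st$fallback[st$group == 4]))
  expect_false(any(st$fallback[st$group %in% 1:2]))
  sth <- seasonStartTable(sim$herd, scope = "herd")
  expect_equal(length(unique(sth$season_start[sth$year == sth$year[1]])), 1)
})

test_that("cycle shares sum to 100 per group-year and flag the 60%
           benchmark", {
  asg <- data.frame(calf_id = sprintf("c%d", 1:8),
                    group = 1L, year = 2014L,
                    cycle = c(1, 1, 1, 2, 1, 1, 1, 2))
  d <- cycleDistribution(asg)
  expect_equal(sum(d$distribution$pct), 100)
  expect_equal(d$benchmarkFlags$first_cycle_pct, 75)
  expect_true(d$benchmarkFlags$meets_benchmark)
  unif <- data.frame(calf_id = sprintf("c%d", 1:8), group = 1L,
                     year = 2014L, cycle = rep(1:4, 2))
  d2 <- cycleDistribution(unif)
  expect_equal(d2$distribution$pct, rep(25, 4))
  expect_false(d2$benchmarkFlags$meets_benchmark)
})

test_that("simulated first-cycle shares track the configured conception
           process", {
  # conditional cycle-of-conception distribution implied by the per-cycle
  # conception probabilities (vigor effect switched off)
  p <- smallParams(seed = 8,
                   vsEffectSlopes = c(afc_days = 0, avg_ww_kg = 0,
                                      conception_rate = 0,
                                      lifetime_kg = 0))
  sim <- simulateHerd(p)
  cyc <- sim$truth$cycles$cycle
  probs <- p@conceptionProbs
  open <- cumprod(c(1, 1 - probs))[seq_along(probs)]
  cond <- open * probs / sum(open * probs)
  for (k in 1:4) {
    ph <- mean(cyc == k)
    se <- sqrt(cond[k] * (1 - cond[k]) / length(cyc))
    expect_lt(abs(ph - cond[k]), 3 * se + 1e-9)
  }
})
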