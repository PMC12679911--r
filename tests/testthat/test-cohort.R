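test_that("cohort derived cells reproduce the published accounting", {
  # 29 of 74 retained 2015 heifers still calving four years on
  expect_equal(round(pctRemaining(29, 74), 1), 39.2)
  # 6 of 7 bottom-stratum 2016 heifers
  expect_equal(round(pctRemaining(6, 7)), 86)
  expect_equal(round(pctRemaining(13, 38), 1), 34.2)
  expect_equal(round(pctRemaining(22, 33)), 67)
  expect_equal(round(pctRemaining(23, 46)), 50)
  expect_true(is.na(pctRemaining(0, 0)))
  # 16 grand calves over 4 sires at 205.94 kg each
  expect_equal(totalKgWeanedPerSire(205.94, 16, 4), 823.76)
  # the one-decimal-rounded average is what the table arithmetic uses:
  # 27/4 = 6.75 -> 6.8; 196.63 x 6.8 = 1337.08
  expect_equal(round(totalKgWeanedPerSire(196.63, 27, 4), 2), 1337.08)
  expect_equal(totalKgWeanedPerSire(196.63, 27, 4, roundedAverage = FALSE),
               196.63 * 6.75)
  expect_equal(round(totalKgWeanedPerSire(194.78, 81, 8), 2), 1967.28)
  expect_equal(round(totalKgWeanedPerSire(192.48, 52, 4), 2), 2502.24)
  expect_equal(round(totalKgWeanedPerSire(207.92, 74, 6), 2), 2557.42)
  expect_equal(round(totalKgWeanedPerSire(196.91, 81, 4), 2), 3997.27)
})

test_that("first-calving wean rates reproduce the published cohort
           percentages", {
  expect_equal(firstCalvingWeanRate(54, 74), 73)
  expect_equal(firstCalvingWeanRate(68, 86), 79)
  expect_equal(firstCalvingWeanRate(0, 10), 0)
  expect_warning(out <- firstCalvingWeanRate(3, 0), "undefined")
  expect_true(is.na(out))
})

test_that("the cohort table conserves counts across strata and keeps
           grand calves inside retained-daughter families", {
  sim <- simulateHerd(simParams(nYears = 5, seed = 16))
  pr <- assignParentage(sim$herd, sim$genotypes)
  herd <- applyParentage(sim$herd, pr)
  bt <- bpiTable(pr, herd)
  ct <- buildCohortTable(herd, bt, heiferYears = 2015L, nFollowYears = 2)
  strata <- ct[ct$stratum != "Total", ]
  total <- ct[ct$stratum == "Total", ]
  for (cl in c("n_sires", "n_daughters_sired", "n_daughters_retained",
               grep("^calves_", names(ct), value = TRUE),
               "total_calves_weaned")) {
    expect_equal(sum(strata[[cl]]), total[[cl]])
  }
  # derived cells follow their definitions
  half_up <- function(x) floor(10 * x + 0.5) / 10   # table convention
  for (i in seq_len(nrow(strata))) {
    expect_equal(strata$avg_grandcalves_per_sire[i],
                 half_up(strata$total_calves_weaned[i] /
                           strata$n_sires[i]))
    expect_equal(strata$total_kg_weaned_per_sire[i],
                 strata$avg_ww_per_calf[i] *
                   strata$avg_grandcalves_per_sire[i])
  }
  # every grand calf has a retained daughter of the cohort as its dam
  a <- herdAnimals(herd)
  ret <- a$id[!is.na(a$year) & a$year == 2015 & a$sex == "F" &
                !is.na(a$retained) & a$retained]
  grand <- a[!is.na(a$dam_id) & a$dam_id %in% ret, ]
  expect_gte(sum(strata$total_calves_weaned), 0)
  expect_lte(sum(strata[[grep("^calves_", names(ct), value = TRUE)[1]]]),
             nrow(grand))
})

test_that("a stratum with no retained daughters reports zero production", {
  hb <- HerdBook(
    data.frame(
      id = c("D1", sprintf("S%d", 1:4), sprintf("H%d", 1:4)),
      sex = c("F", rep("M", 4), rep("F", 4)),
      birth_date = c(as.Date("2010-04-01"), rep(as.Date("2012-04-01"), 4),
                     rep(as.Date("2015-04-10"), 4)),
      dam_id = c(rep(NA, 5), rep("D1", 4)),
      assigned_sire_id = c(rep(NA, 5), sprintf("S%d", 1:4)),
      group = c(rep(NA, 5), rep(1L, 4)),
      year = c(rep(NA, 5), rep(2014L, 4)),
      retained = c(rep(NA, 5), FALSE, TRUE, TRUE, TRUE)),
    services = data.frame(sire_id = sprintf("S%d", 1:4), group = 1L,
                          year = 2014L))
  bt <- data.frame(sire_id = sprintf("S%d", 1:4), group = 1L,
                   year = 2014L, bpi = c(0.2, 0.8, 1.2, 1.9))
  ct <- buildCohortTable(hb, bt, heiferYears = 2014L, nFollowYears = 2)
  row <- ct[ct$stratum == "Bottom25", ]
  expect_equal(row$n_sires, 1)
  expect_equal(row$n_daughters_sired, 1)
  expect_equal(row$n_daughters_retained, 0)
  expect_equal(row$total_calves_weaned, 0)
  expect_equal(row$total_kg_weaned_per_sire, 0)
})

test_that("first-cycle linkage R-squared matches its definition", {
  # collinear points explain everything
  col <- data.frame(sire_id = 1:4, stratum = "Top25",
                    pct_daughters_c1 = c(10, 20, 30, 40),
                    pct_grandcalves_c1 = c(15, 25, 35, 45))
  expect_equal(firstCycleLinkage(col)$r_squared, 1)
  # flat response explains nothing
  flat <- col
  flat$pct_grandcalves_c1 <- 50
  expect_equal(firstCycleLinkage(flat)$r_squared, 0)
  # 5-point fixture against the by-hand sum-of-squares identity
  x <- c(20, 35, 50, 65, 80)
  y <- c(30, 32, 55, 60, 78)
  fit <- lm(y ~ x)
  r2_hand <- 1 - sum(residuals(fit)^2) / sum((y - mean(y))^2)
  five <- data.frame(sire_id = 1:5, stratum = "Average50",
                     pct_daughters_c1 = x, pct_grandcalves_c1 = y)
  expect_equal(firstCycleLinkage(five)$r_squared, r2_hand)
  # below 3 sires the statistic is flagged undefined
  two <- five[1:2, ]
  expect_true(is.na(firstCycleLinkage(two)$r_squared))
})

test_that("per-sire first-cycle shares are percentages of daughters and
           grand calves", {
  sim <- simulateHerd(smallParams(seed = 20))
  pr <- assignParentage(sim$herd, sim$genotypes)
  herd <- applyParentage(sim$herd, pr)
  st <- seasonStartTable(herd)
  cyc <- assignCycles(herd, st)
  sh <- firstCycleShares(herd, cyc, heiferYears = 2014L)
  expect_true(all(sh$pct_daughters_c1 >= 0 & sh$pct_daughters_c1 <= 100))
  expect_true(all(sh$n_daughters >= 1))
})
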