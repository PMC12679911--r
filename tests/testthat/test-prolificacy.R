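test_that("BPI reproduces the printed breeding-group extremes", {
  # study-wide maximum: 49 of 113 matched calves among 8 sires
  expect_equal(round(bpi(49, 113, 8), 2), 3.47)
  # a 10-calf minimum among 126 calves and 5 sires prints as 0.4
  expect_equal(round(bpi(10, 126, 5), 1), 0.4)
  expect_equal(round(bpi(1, 136, 6), 2), 0.04)
  expect_equal(round(bpi(38, 136, 6), 1), 1.7)
  expect_equal(round(bpi(51, 121, 6), 1), 2.5)
  expect_equal(round(bpi(4, 121, 6), 1), 0.2)
  # a sire at exactly the equal share indexes 1
  expect_equal(bpi(20, 100, 5), 1)
  expect_error(bpi(1, 0, 5), "undefined")
  expect_error(bpi(1, 10, 0), "undefined")
})

test_that("BPI is scale-invariant and conserves m within a group-year", {
  n <- c(3, 9, 18)
  expect_equal(sum(bpi(n, sum(n), 3)), 3)
  expect_equal(bpi(n, sum(n), 3), bpi(2 * n, 2 * sum(n), 3))
})

test_that("first-cycle BPI substitutes first-cycle counts and flags empty
           cycles", {
  expect_equal(bpiFirstCycle(5, 20, 4), 1)
  expect_warning(out <- bpiFirstCycle(0, 0, 4), "undefined")
  expect_true(is.na(out))
})

test_that("the BPI table counts only matched calves and collapses to the
           overall BPI when every calf is first-cycle", {
  hb <- toyHerd()
  pr <- data.frame(calf_id = c("C1", "C2"), group = 1L, year = 2014L,
                   assigned_sire_id = c("S1", NA),
                   status = c("matched", "no_sire_match"))
  cyc <- data.frame(calf_id = c("C1", "C2"), cycle = c(1L, 1L))
  bt <- bpiTable(pr, hb, cyc)
  expect_equal(nrow(bt), 2)          # both rostered sires get a record
  expect_equal(bt$N, c(1L, 1L))      # the unmatched calf is excluded
  expect_equal(bt$n[bt$sire_id == "S1"], 1L)
  expect_equal(bt$n[bt$sire_id == "S2"], 0L)
  expect_equal(bt$bpi[bt$sire_id == "S2"], 0)
  expect_equal(bt$bpi, bt$bpi_first) # all matched calves in cycle 1
  expect_equal(sum(bt$bpi), unique(bt$m))
})

test_that("group-year BPI sums to the sire count on simulated herds", {
  sim <- simulateHerd(smallParams(seed = 2))
  pr <- assignParentage(sim$herd, sim$genotypes)
  bt <- bpiTable(pr, sim$herd)
  sums <- aggregate(bpi ~ group + year, bt, sum)
  ms <- aggregate(m ~ group + year, bt, unique)
  expect_equal(sums$bpi, as.numeric(ms$m))
})

test_that("rank stratification splits quartiles deterministically with
           id tie-breaks", {
  s <- stratifySires(sprintf("S%d", 1:8), rep(1, 8))
  expect_equal(as.integer(table(s$stratum)), c(2L, 4L, 2L))
  # equal BPI: ranks resolved by sire id
  expect_equal(s$stratum[s$sire_id %in% c("S1", "S2")],
               factor(c("Bottom25", "Bottom25"),
                      levels = levels(s$stratum)))
  expect_equal(s$stratum[s$sire_id %in% c("S7", "S8")],
               factor(c("Top25", "Top25"), levels = levels(s$stratum)))
  # strata partition the sire set
  expect_false(anyNA(s$stratum))
  # 14 sires split 4/6/4, as in a 14-sire cohort year
  s14 <- stratifySires(sprintf("S%02d", 1:14), seq(0.1, 2.7, 0.2))
  expect_equal(as.integer(table(s14$stratum)), c(4L, 6L, 4L))
  expect_warning(s3 <- stratifySires(c("a", "b", "c"), 1:3),
                 "fewer than 4")
  expect_equal(nrow(s3), 3)
})

test_that("repeatability is the Spearman correlation between use-years", {
  rec <- data.frame(
    sire_id = rep(sprintf("S%d", 1:5), each = 2),
    year = rep(c(2014L, 2015L), 5),
    bpi = c(0.2, 0.3, 0.5, 0.6, 1.0, 1.1, 1.5, 1.6, 2.0, 2.1))
  set.seed(1)
  r <- bpiRepeatability(rec, nPerm = 499)
  expect_equal(r$rho[r$use_year_pair == "1-2"], 1)
  rev_rec <- rec
  rev_rec$bpi[rev_rec$year == 2015] <- rev(rec$bpi[rec$year == 2015])
  set.seed(1)
  r2 <- bpiRepeatability(rev_rec, nPerm = 499)
  expect_equal(r2$rho[r2$use_year_pair == "1-2"], -1)
})

test_that("Spearman rho equals the definitional rank-difference formula
           on a 5-pair fixture", {
  x <- c(0.3, 1.2, 0.8, 2.1, 0.5)
  y <- c(0.4, 1.0, 1.1, 1.9, 0.2)
  d <- rank(x) - rank(y)
  rho_def <- 1 - 6 * sum(d^2) / (5 * (5^2 - 1))
  rec <- data.frame(sire_id = rep(sprintf("S%d", 1:5), each = 2),
                    year = rep(c(2014L, 2015L), 5),
                    bpi = as.numeric(rbind(x, y)))
  set.seed(2)
  r <- bpiRepeatability(rec, nPerm = 499)
  expect_equal(r$rho[r$use_year_pair == "1-2"], rho_def)
  # cross-check against the library implementation
  expect_equal(rho_def, unname(cor(x, y, method = "spearman")))
})

test_that("simulated sires with static weights repeat their ranking
           across years", {
  sim <- simulateHerd(simParams(nYears = 3, seed = 6))
  pr <- assignParentage(sim$herd, sim$genotypes)
  bt <- bpiTable(pr, sim$herd)
  set.seed(3)
  r <- bpiRepeatability(bt, nPerm = 999)
  r12 <- r[r$use_year_pair == "1-2", ]
  expect_gt(r12$rho, 0.3)
  expect_lt(r12$p_value, 0.05)
})

test_that("age summary partitions records into yearling, two-year-old and
           mature classes", {
  rec <- data.frame(sire_id = "S1", bpi = 0.5, sire_age = 1)
  s <- sireAgeSummary(rec)
  expect_equal(s$mean_bpi[s$age_class == "1"], 0.5)
  expect_equal(s$sd_bpi[s$age_class == "1"], 0)
  rec2 <- data.frame(sire_id = sprintf("S%d", 1:6), bpi = seq(0.2, 2.2, 0.4),
                     sire_age = c(1, 1, 2, 2, 3, 6))
  s2 <- sireAgeSummary(rec2)
  expect_equal(sum(s2$n), 6L)
  expect_equal(s2$n, c(2L, 2L, 2L))
})

test_that("age classes show no BPI difference when weights are
           age-independent", {
  set.seed(17)
  n <- 300
  rec <- data.frame(sire_id = sprintf("S%d", 1:n),
                    bpi = rlnorm(n, 0, 0.3),
                    sire_age = sample(1:6, n, replace = TRUE))
  s <- sireAgeSummary(rec)
  for (i in 1:2) {
    for (j in (i + 1):3) {
      se <- sqrt(s$sd_bpi[i]^2 / s$n[i] + s$sd_bpi[j]^2 / s$n[j])
      expect_lt(abs(s$mean_bpi[i] - s$mean_bpi[j]), 3 * se)
    }
  }
})
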