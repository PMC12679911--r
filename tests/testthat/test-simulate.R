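test_that("founder pools respect their composition constraints", {
  set.seed(19)
  f <- simulateBreedCompositions(simParams(), nSires = 40, nDams = 30,
                                 purebredFraction = 0.5)
  fr <- breedFractions(f$composition)
  vs <- vigorScore(f$composition)
  pure <- names(f$pool)[f$pool == "purebred"]
  comp <- names(f$pool)[f$pool == "composite"]
  # one breed at >= 0.8 caps retained heterozygosity below 1 - 0.8^2
  expect_true(all(apply(fr[pure, ], 1, max) >= 0.8))
  expect_true(all(vs[pure] < 0.36))
  # composites: no breed above 0.35, at least 5 contributing breeds
  expect_true(all(apply(fr[comp, ], 1, max) <= 0.35))
  expect_true(all(rowSums(fr[comp, ] > 0.01) >= 5))
  expect_equal(unname(rowSums(fr)), rep(1, nrow(fr)))
  # six equal breeds attain the closed-form score
  expect_equal(vigorScore(rep(1 / 6, 6)), 1 - 6 * (1 / 6)^2)
  expect_equal(vigorScore(rep(1 / 6, 6)), 0.8333333, tolerance = 1e-6)
})

test_that("offspring composition is the component-wise parental mean", {
  d <- c(A = 0.7, B = 0.2, C = 0.1)
  s <- c(A = 0.1, B = 0.3, C = 0.6)
  expect_equal(childComposition(d, s), c(A = 0.4, B = 0.25, C = 0.35))
  expect_equal(sum(childComposition(d, s)), 1)
})

test_that("Mendelian transmission is exact for homozygous parents", {
  p <- simParams(breeds = c("REF", "ALT"), nSnps = 30,
                 breedAlleleFreqs = matrix(
                   c(rep(0, 30), rep(1, 30)), nrow = 2, byrow = TRUE,
                   dimnames = list(c("REF", "ALT"), NULL)))
  comp <- matrix(c(1, 0, 0, 1), nrow = 2, byrow = TRUE,
                 dimnames = list(c("P0", "P2"), c("REF", "ALT")))
  ped <- data.frame(id = c("K11", "K22"),
                    dam_id = c("P0", "P2"), sire_id = c("P2", "P2"))
  set.seed(1)
  gp <- simulateGenotypes(BreedComposition(comp), p, ped)
  g <- genotypeCalls(gp)
  expect_true(all(g[, "P0"] == 0))
  expect_true(all(g[, "P2"] == 2))
  # (0,2) parents always give a heterozygote; (2,2) always a 2
  expect_true(all(g[, "K11"] == 1))
  expect_true(all(g[, "K22"] == 2))
})

test_that("founder allele frequencies match the configured values within
           binomial error", {
  set.seed(23)
  L <- 20
  fr <- matrix(runif(L, 0.25, 0.75), nrow = 1,
               dimnames = list("B1", sprintf("s%02d", 1:L)))
  p <- simParams(breeds = c("B1", "B2"), nSnps = L,
                 breedAlleleFreqs = rbind(fr, B2 = fr[1, ]))
  n <- 500
  comp <- matrix(c(1, 0), nrow = n, ncol = 2, byrow = TRUE,
                 dimnames = list(sprintf("A%03d", 1:n), c("B1", "B2")))
  gp <- simulateGenotypes(BreedComposition(comp), p)
  phat <- altAlleleFreq(gp)
  se <- sqrt(fr[1, ] * (1 - fr[1, ]) / (2 * n))
  expect_true(all(abs(phat - fr[1, ]) < 3 * se))
})

test_that("equal prolificacy weights give equal expected calf shares", {
  set.seed(29)
  p <- simParams(vsEffectSlopes = c(afc_days = 0, avg_ww_kg = 0,
                                    conception_rate = 0, lifetime_kg = 0))
  nd <- 1100
  dams <- data.frame(id = sprintf("D%04d", 1:nd), group = 1L, vs = 0.65)
  sires <- data.frame(id = sprintf("S%d", 1:4), group = 1L, weight = 1)
  comp <- matrix(0.5, nrow = nd + 4, ncol = 2,
                 dimnames = list(c(dams$id, sires$id), c("A", "B")))
  season <- simulateBreedingSeason(p, 2014L, dams, sires, comp)
  tab <- table(season$calves$true_sire_id)
  N <- nrow(season$calves)
  expect_gt(N, 900)
  se <- sqrt(0.25 * 0.75 / N)
  for (s in sires$id) {
    expect_lt(abs(tab[[s]] / N - 0.25), 3 * se)
  }
})

test_that("a 9:1 weight split yields expected BPIs of 1.8 and 0.2", {
  set.seed(37)
  p <- simParams(vsEffectSlopes = c(afc_days = 0, avg_ww_kg = 0,
                                    conception_rate = 0, lifetime_kg = 0))
  nd <- 1100
  dams <- data.frame(id = sprintf("D%04d", 1:nd), group = 1L, vs = 0.65)
  sires <- data.frame(id = c("BIG", "SMALL"), group = 1L,
                      weight = c(9, 1))
  comp <- matrix(0.5, nrow = nd + 2, ncol = 2,
                 dimnames = list(c(dams$id, sires$id), c("A", "B")))
  season <- simulateBreedingSeason(p, 2014L, dams, sires, comp)
  N <- nrow(season$calves)
  nBig <- sum(season$calves$true_sire_id == "BIG")
  se <- 2 * sqrt(0.9 * 0.1 / N)     # m * multinomial SE of the share
  expect_lt(abs(bpi(nBig, N, 2) - 1.8), 3 * se)
  expect_lt(abs(bpi(N - nBig, N, 2) - 0.2), 3 * se)
})

test_that("zero conception probability yields an empty season and a
           sireless group errors", {
  p <- simParams(conceptionProbs = rep(0, 4),
                 vsEffectSlopes = c(afc_days = 0, avg_ww_kg = 0,
                                    conception_rate = 0, lifetime_kg = 0))
  dams <- data.frame(id = c("D1", "D2"), group = 1L, vs = 0.65)
  sires <- data.frame(id = "S1", group = 1L, weight = 1)
  comp <- matrix(0.5, 3, 2, dimnames = list(c("D1", "D2", "S1"),
                                            c("A", "B")))
  set.seed(1)
  season <- simulateBreedingSeason(p, 2014L, dams, sires, comp)
  expect_equal(nrow(season$calves), 0)
  expect_error(
    simulateBreedingSeason(p, 2014L, dams,
                           data.frame(id = "S1", group = 2L, weight = 1),
                           comp),
    "no sires")
})

test_that("retention applies togglable rules then keeps the heaviest
           fraction, logging every exclusion", {
  hb <- HerdBook(data.frame(
    id = c("D1", sprintf("H%d", 1:6)),
    sex = "F",
    birth_date = c(as.Date("2010-04-01"),
                   rep(as.Date("2015-04-10"), 6)),
    dam_id = c(NA, rep("D1", 6)),
    group = c(NA, rep(1L, 6)), year = c(NA, rep(2014L, 6)),
    weaning_weight = c(NA, 230, 220, 210, 200, 190, NA)))
  cyc <- data.frame(calf_id = sprintf("H%d", 1:6),
                    cycle = c(1, 3, 1, 2, 1, 1))
  # post-2019 rule set: third-cycle heifers culled before ranking
  p <- simParams(retentionRules = "third_cycle", retentionFraction = 0.5)
  r <- simulateRetention(hb, p, cyc)
  a <- herdAnimals(r$herd)
  expect_equal(r$log$reason[r$log$id == "H2"], "third_cycle")
  expect_equal(r$log$reason[r$log$id == "H6"], "not_weaned")
  # 4 eligible remain, keep round(0.5 * 4) = 2 heaviest: H1, H3
  expect_equal(sort(a$id[!is.na(a$retained) & a$retained]),
               c("H1", "H3"))
  # all rules off at fraction 1: every weaned heifer is retained
  p2 <- simParams(retentionFraction = 1)
  r2 <- simulateRetention(hb, p2)
  a2 <- herdAnimals(r2$herd)
  expect_equal(sum(a2$retained, na.rm = TRUE), 5)
  # retention count is round(fraction x eligible)
  p3 <- simParams(retentionFraction = 0.6)
  r3 <- simulateRetention(hb, p3)
  expect_equal(sum(herdAnimals(r3$herd)$retained, na.rm = TRUE),
               round(0.6 * 5))
})

test_that("every calf's true sire comes from its group-year roster and the
           herd book is internally consistent", {
  sim <- simulateHerd(smallParams(seed = 14))
  a <- herdAnimals(sim$herd)
  sv <- sireServices(sim$herd)
  calves <- a[!is.na(a$dam_id), ]
  key <- paste(calves$true_sire_id, calves$group, calves$year)
  roster_key <- paste(sv$sire_id, sv$group, sv$year)
  expect_true(all(key %in% roster_key))
  expect_true(validObject(sim$herd))
  # compositions cover every animal and sum to 1
  fr <- breedFractions(sim$compositions)
  expect_setequal(rownames(fr), a$id)
  expect_equal(max(abs(rowSums(fr) - 1)), 0, tolerance = 1e-9)
})
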