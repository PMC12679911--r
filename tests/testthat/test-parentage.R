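test_that("opposing-homozygote counting matches its definition", {
  expect_equal(countOpposingHomozygotes(c(0, 1, 2), c(0, 1, 2)), 0)
  expect_equal(countOpposingHomozygotes(2, 0), 1)
  expect_equal(countOpposingHomozygotes(c(0, NA, 2), c(2, 2, NA)), 1)
  expect_error(countOpposingHomozygotes(c(0, 1), 0), "length")
})

test_that("vectorized opposing-homozygote count equals a naive locus loop", {
  set.seed(21)
  naive <- function(a, b) {
    n <- 0L
    for (l in seq_along(a)) {
      if (is.na(a[l]) || is.na(b[l])) next
      if ((a[l] == 0 && b[l] == 2) || (a[l] == 2 && b[l] == 0)) n <- n + 1L
    }
    n
  }
  for (i in 1:20) {
    a <- sample(c(0L, 1L, 2L, NA), 100, replace = TRUE)
    b <- sample(c(0L, 1L, 2L, NA), 100, replace = TRUE)
    expect_identical(countOpposingHomozygotes(a, b), naive(a, b))
  }
})

test_that("a lone compatible candidate is matched", {
  g <- matrix(c(0L, 1L, 2L, 0L, 1L, 2L), nrow = 3,
              dimnames = list(NULL, c("calf", "sire")))
  gp <- GenotypePanel(g)
  r <- assignSire("calf", "sire", gp, basePanelSize = 3)
  expect_equal(r$assigned_sire_id, "sire")
  expect_equal(r$status, "matched")
  expect_error(assignSire("calf", character(0), gp), "empty candidate")
})

test_that("indistinguishable candidates end as no sire match after
           extension", {
  g <- matrix(rep(c(0L, 1L, 2L, 1L), 30), nrow = 120)
  g <- cbind(g[, 1], g[, 1], g[, 1])
  colnames(g) <- c("calf", "twinA", "twinB")
  gp <- GenotypePanel(g)
  r <- assignSire("calf", c("twinA", "twinB"), gp,
                  basePanelSize = 100, extensionSize = 20)
  expect_equal(r$status, "no_sire_match")
  expect_true(is.na(r$assigned_sire_id))
  expect_equal(r$panel_size_used, 120)
})

test_that("assignment is invariant to candidate ordering", {
  set.seed(5)
  sim <- simulateHerd(smallParams(seed = 5))
  a <- herdAnimals(sim$herd)
  calf <- a$id[!is.na(a$dam_id)][1]
  sv <- sireServices(sim$herd)
  cand <- sv$sire_id[sv$group == a$group[a$id == calf] &
                       sv$year == a$year[a$id == calf]]
  r1 <- assignSire(calf, cand, sim$genotypes)
  r2 <- assignSire(calf, rev(cand), sim$genotypes)
  r3 <- assignSire(calf, sample(cand), sim$genotypes)
  expect_identical(r1$assigned_sire_id, r2$assigned_sire_id)
  expect_identical(r1$assigned_sire_id, r3$assigned_sire_id)
})

test_that("error-free simulated genotypes recover the true sire", {
  sim <- simulateHerd(smallParams(seed = 9))
  pr <- assignParentage(sim$herd, sim$genotypes)
  a <- herdAnimals(sim$herd)
  truth <- a$true_sire_id[match(pr$calf_id, a$id)]
  matched <- !is.na(pr$assigned_sire_id)
  expect_gt(mean(pr$assigned_sire_id[matched] == truth[matched]), 0.999)
  vs <- verificationSummary(pr)
  expect_equal(vs$matched + vs$unmatched, vs$tested)
})

test_that("verification summary counts tested, matched and unmatched", {
  r <- data.frame(status = c(rep("matched", 8),
                             "ambiguous_resolved_by_extension",
                             "no_sire_match"))
  expect_equal(verificationSummary(r), list(tested = 10L, matched = 9L,
                                            unmatched = 1L))
  empty <- data.frame(status = character(0))
  expect_equal(verificationSummary(empty),
               list(tested = 0L, matched = 0L, unmatched = 0L))
})

test_that("random non-sire exclusion matches the closed-form
           no-opposing-homozygote probability", {
  # two unrelated Hardy-Weinberg animals at alt frequency p share no
  # opposing homozygote at a locus with probability 1 - 2 p^2 q^2
  set.seed(13)
  L <- 10L
  freqs <- matrix(runif(L, 0.3, 0.7), nrow = 1,
                  dimnames = list("B1", sprintf("snp%03d", 1:L)))
  p <- simParams(breeds = c("B1", "B2"), nSnps = L,
                 breedAlleleFreqs = rbind(freqs, B2 = freqs[1, ]))
  n <- 4000
  comp <- matrix(c(1, 0), nrow = n, ncol = 2, byrow = TRUE,
                 dimnames = list(sprintf("A%04d", 1:n), c("B1", "B2")))
  gp <- simulateGenotypes(BreedComposition(comp), p)
  g <- genotypeCalls(gp)
  i1 <- seq(1, n, by = 2); i2 <- seq(2, n, by = 2)
  oh0 <- vapply(seq_along(i1), function(k)
    countOpposingHomozygotes(g[, i1[k]], g[, i2[k]]) == 0, logical(1))
  pq <- freqs[1, ] * (1 - freqs[1, ])
  closed <- prod(1 - 2 * pq^2)
  se <- sqrt(closed * (1 - closed) / length(oh0))
  expect_lt(abs(mean(oh0) - closed), 3 * se)
})
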