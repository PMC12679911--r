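## Synthetic multi-sire herd simulator with known ground truth.
##
## The generator emulates the structure of a western-Canadian cow-calf
## operation running 4 multi-sire breeding groups per year over 6 breeding
## seasons: two mature-cow groups, one 3-year-old group and one
## replacement-heifer group, bull:cow ratios around 1:20-1:27, a calving
## season of up to four 21-day cycles, heterogeneous static per-bull siring
## propensities, breed-composition inheritance as the parental mean,
## Mendelian SNP transmission from breed-specific allele frequencies, and
## weaning-weight / conception responses to the dam's vigor score.

.DEFAULT_BREEDS <- c("Angus", "Hereford", "Gelbvieh", "Limousin",
                     "Simmental", "Charolais", "Shorthorn", "Jersey",
                     "Indeterminate")

#' SimParams: synthetic herd generator settings
#'
#' Defaults are the study conditions the pipeline is designed for: 6
#' breeding years, four groups (6/150, 6/150, 3/70 and 4/80 sires/dams,
#' i.e. bull:cow ratios 1:20 to 1:25), a four-cycle 21-day calving season,
#' per-cycle baseline conception probabilities declining from 0.62 to 0.45
#' (about two thirds of calves in the first cycle), lognormal static
#' prolificacy weights, a 120-SNP panel (100 verification loci plus 20
#' extension loci), and per-+10%-vigor-score trait slopes at the estimated
#' values: -0.7 d age at first calving, +1.74 kg weaning weight, +2
#' percentage points conception, +60.3 kg lifetime productivity.
#'
#' @slot nYears number of breeding seasons.
#' @slot groups list of group specs, each `list(name, nSires, nDams, damAges)`.
#' @slot nCycles cycles in the calving season.
#' @slot conceptionProbs per-cycle baseline conception probability for a dam
#'   still open at that cycle, at the reference vigor score.
#' @slot vsEffectSlopes named numeric, trait change per +0.10 vigor score:
#'   `afc_days`, `avg_ww_kg`, `conception_rate`, `lifetime_kg`.
#' @slot vsRef vigor score at which baselines apply.
#' @slot prolificacyWeights optional fixed per-bull weights; drawn
#'   lognormal(0, `prolificacySdLog`) when empty.
#' @slot prolificacySdLog sd(log) of drawn prolificacy weights.
#' @slot yearlingFactor multiplier on a yearling bull's effective weight.
#' @slot breeds breed names; last entry is the indeterminate remainder.
#' @slot breedAlleleFreqs breeds x loci alternate-allele frequencies; drawn
#'   Uniform(0.2, 0.8) when empty.
#' @slot nSnps loci on the simulated panel.
#' @slot genotypeErrorRate per-allele flip probability.
#' @slot retentionFraction fraction of eligible heifer calves retained.
#' @slot retentionRules character subset of
#'   `c("third_cycle", "not_weaned")`: togglable culling criteria applied
#'   before the top-fraction selection.
#' @slot wwBaseline,wwSigma weaning-weight baseline (kg) and Gaussian noise.
#' @slot afcSigma,lifetimeSigma trait noise for the direct trait generator.
#' @slot birthWeightMean,birthWeightSigma birth weight distribution (kg).
#' @slot weaningProb probability a born calf survives to weaning.
#' @slot cowCullProb annual background culling probability for a cow.
#' @slot openCullProb culling probability for a cow that failed to conceive.
#' @slot maxCowAge cows older than this are culled.
#' @slot seed RNG seed for [simulateHerd()].
#'
#' @name SimParams-class
#' @aliases SimParams-class
#' @exportClass SimParams
setClass("SimParams", representation(
  nYears = "integer", groups = "list", nCycles = "integer",
  conceptionProbs = "numeric", vsEffectSlopes = "numeric", vsRef = "numeric",
  prolificacyWeights = "numeric", prolificacySdLog = "numeric",
  yearlingFactor = "numeric", breeds = "character",
  breedAlleleFreqs = "matrix", nSnps = "integer",
  genotypeErrorRate = "numeric", retentionFraction = "numeric",
  retentionRules = "character", wwBaseline = "numeric", wwSigma = "numeric",
  afcSigma = "numeric", lifetimeSigma = "numeric",
  birthWeightMean = "numeric", birthWeightSigma = "numeric",
  weaningProb = "numeric", cowCullProb = "numeric", openCullProb = "numeric",
  maxCowAge = "integer", seed = "integer"
))

setValidity("SimParams", function(object) {
  msg <- character(0)
  if (length(object@breeds) < 2) msg <- c(msg, "at least 2 breeds required")
  if (length(object@prolificacyWeights) > 0 &&
      any(object@prolificacyWeights <= 0)) {
    msg <- c(msg, "prolificacy weights must be > 0")
  }
  if (any(object@conceptionProbs < 0 | object@conceptionProbs > 1)) {
    msg <- c(msg, "conception probabilities must be in [0, 1]")
  }
  if (length(object@conceptionProbs) != object@nCycles) {
    msg <- c(msg, "need one conception probability per cycle")
  }
  if (nrow(object@breedAlleleFreqs) > 0) {
    if (any(object@breedAlleleFreqs < 0 | object@breedAlleleFreqs > 1)) {
      msg <- c(msg, "allele frequencies must be in [0, 1]")
    }
  }
  for (g in object@groups) {
    if (g$nSires < 1) msg <- c(msg, "each group needs at least one sire")
  }
  for (s in c("genotypeErrorRate", "retentionFraction", "weaningProb",
              "cowCullProb", "openCullProb")) {
    v <- slot(object, s)
    if (v < 0 || v > 1) msg <- c(msg, sprintf("%s must be in [0, 1]", s))
  }
  if (length(msg) == 0) TRUE else msg
})

#' Construct simulator settings
#'
#' See [SimParams-class] for the meaning and defaults of every field.
#'
#' @param nYears,groups,nCycles,conceptionProbs,vsEffectSlopes,vsRef see
#'   [SimParams-class].
#' @param prolificacyWeights,prolificacySdLog,yearlingFactor,breeds see
#'   [SimParams-class].
#' @param breedAlleleFreqs,nSnps,genotypeErrorRate,retentionFraction see
#'   [SimParams-class].
#' @param retentionRules,wwBaseline,wwSigma,afcSigma,lifetimeSigma see
#'   [SimParams-class].
#' @param birthWeightMean,birthWeightSigma,weaningProb,cowCullProb see
#'   [SimParams-class].
#' @param openCullProb,maxCowAge,seed see [SimParams-class].
#' @return A validated [SimParams-class].
#' @examples
#' p <- simParams(nYears = 2, seed = 11)
#' p
#' @export
simParams <- function(nYears = 6L,
                      groups = list(
                        list(name = 1L, nSires = 6L, nDams = 150L,
                             damAges = 4:8),
                        list(name = 2L, nSires = 6L, nDams = 150L,
                             damAges = 4:8),
                        list(name = 3L, nSires = 3L, nDams = 70L,
                             damAges = 3L),
                        list(name = 4L, nSires = 4L, nDams = 80L,
                             damAges = 2L)),
                      nCycles = 4L,
                      conceptionProbs = c(0.62, 0.55, 0.50, 0.45),
                      vsEffectSlopes = c(afc_days = -0.7,
                                         avg_ww_kg = 1.74,
                                         conception_rate = 0.02,
                                         lifetime_kg = 60.3),
                      vsRef = 0.65,
                      prolificacyWeights = numeric(0),
                      prolificacySdLog = 0.8,
                      yearlingFactor = 0.55,
                      breeds = .DEFAULT_BREEDS,
                      breedAlleleFreqs = matrix(numeric(0), nrow = 0,
                                                ncol = 0),
                      nSnps = 120L,
                      genotypeErrorRate = 0,
                      retentionFraction = 0.5,
                      retentionRules = character(0),
                      wwBaseline = 190, wwSigma = 15,
                      afcSigma = 10, lifetimeSigma = 150,
                      birthWeightMean = 38, birthWeightSigma = 4,
                      weaningProb = 0.95,
                      cowCullProb = 0.10, openCullProb = 0.85,
                      maxCowAge = 12L,
                      seed = 1L) {
  new("SimParams",
      nYears = as.integer(nYears), groups = groups,
      nCycles = as.integer(nCycles), conceptionProbs = conceptionProbs,
      vsEffectSlopes = vsEffectSlopes, vsRef = vsRef,
      prolificacyWeights = prolificacyWeights,
      prolificacySdLog = prolificacySdLog, yearlingFactor = yearlingFactor,
      breeds = breeds, breedAlleleFreqs = breedAlleleFreqs,
      nSnps = as.integer(nSnps), genotypeErrorRate = genotypeErrorRate,
      retentionFraction = retentionFraction,
      retentionRules = retentionRules,
      wwBaseline = wwBaseline, wwSigma = wwSigma, afcSigma = afcSigma,
      lifetimeSigma = lifetimeSigma, birthWeightMean = birthWeightMean,
      birthWeightSigma = birthWeightSigma, weaningProb = weaningProb,
      cowCullProb = cowCullProb, openCullProb = openCullProb,
      maxCowAge = as.integer(maxCowAge), seed = as.integer(seed))
}

#' @rdname SimParams-class
#' @param object a `SimParams`
#' @export
setMethod("show", "SimParams", function(object) {
  gs <- vapply(object@groups, function(g)
    sprintf("%d:%d/%d", g$name, g$nSires, g$nDams), character(1))
  cat(sprintf("SimParams: %d years; groups (sires/dams) %s; %d-cycle season\n",
              object@nYears, paste(gs, collapse = " "), object@nCycles))
  cat(sprintf("  %d SNPs, allele-flip error %.3g; retention fraction %.2f; seed %d\n",
              object@nSnps, object@genotypeErrorRate,
              object@retentionFraction, object@seed))
  invisible(NULL)
})

## Dirichlet draws via normalized gammas.
.rdirichlet <- function(n, alpha) {
  x <- matrix(rgamma(n * length(alpha), shape = alpha), nrow = n,
              byrow = TRUE)
  x / rowSums(x)
}

.ensureAlleleFreqs <- function(params) {
  if (nrow(params@breedAlleleFreqs) > 0) {
    return(params@breedAlleleFreqs)
  }
  f <- matrix(runif(length(params@breeds) * params@nSnps, 0.2, 0.8),
              nrow = length(params@breeds),
              dimnames = list(params@breeds,
                              sprintf("snp%03d", seq_len(params@nSnps))))
  f
}

## Purebred-like founder: one dominant breed at >= 0.8, remainder spread
## thinly over three other breeds and the indeterminate component.
.rPurebredComposition <- function(n, breeds, dominant = breeds[1]) {
  k <- length(breeds)
  out <- matrix(0, nrow = n, ncol = k, dimnames = list(NULL, breeds))
  dom <- runif(n, 0.80, 0.92)
  others <- setdiff(breeds, dominant)
  for (i in seq_len(n)) {
    minor <- c(sample(others[-length(others)], 3), breeds[k])
    out[i, dominant] <- dom[i]
    out[i, minor] <- (1 - dom[i]) * as.vector(.rdirichlet(1, rep(0.6, 4)))
  }
  out
}

## Composite-like founder: >= 5 breeds, none above maxFraction, small
## indeterminate remainder. Rejection-resamples rows violating the cap.
.rCompositeComposition <- function(n, breeds, maxFraction = 0.35,
                                   nComponent = 6) {
  k <- length(breeds)
  comp_breeds <- breeds[seq_len(min(nComponent, k - 1))]
  out <- matrix(0, nrow = n, ncol = k, dimnames = list(NULL, breeds))
  ind <- runif(n, 0.01, 0.06)
  for (i in seq_len(n)) {
    repeat {
      x <- as.vector(.rdirichlet(1, rep(3, length(comp_breeds))))
      if (max(x) * (1 - ind[i]) <= maxFraction) break
    }
    out[i, comp_breeds] <- x * (1 - ind[i])
    out[i, k] <- ind[i]
  }
  out
}

#' Simulate founder breed compositions
#'
#' Draws two founder bull pools -- purebred-like (one breed at 0.80-0.92,
#' like the straightbred Angus sires of the study herd) and composite-like
#' (at least five breeds, none above 0.35, like composite Beef Booster
#' bulls) -- and a dam pool drawn as per-animal mixtures between the two.
#'
#' @param params a [SimParams-class].
#' @param nSires,nDams pool sizes.
#' @param purebredFraction fraction of sires that are purebred-like.
#' @param sireIds,damIds optional animal ids.
#' @return list with `composition` (a [BreedComposition-class] over all
#'   founders) and `pool` (named character: `"purebred"`, `"composite"`, or
#'   `"dam"`).
#' @examples
#' set.seed(1)
#' f <- simulateBreedCompositions(simParams(), nSires = 4, nDams = 6)
#' vigorScore(f$composition)
#' @export
simulateBreedCompositions <- function(params, nSires, nDams,
                                      purebredFraction = 0.25,
                                      sireIds = NULL, damIds = NULL) {
  breeds <- params@breeds
  if (length(breeds) < 2) stop("breed list must have at least 2 entries")
  nPure <- round(purebredFraction * nSires)
  nComp <- nSires - nPure
  mats <- list()
  pools <- character(0)
  if (nPure > 0) {
    mats <- c(mats, list(.rPurebredComposition(nPure, breeds)))
    pools <- c(pools, rep("purebred", nPure))
  }
  if (nComp > 0) {
    mats <- c(mats, list(.rCompositeComposition(nComp, breeds)))
    pools <- c(pools, rep("composite", nComp))
  }
  if (nDams > 0) {
    lam <- runif(nDams, 0.2, 0.8)
    dm <- lam * .rPurebredComposition(nDams, breeds) +
      (1 - lam) * .rCompositeComposition(nDams, breeds)
    mats <- c(mats, list(dm))
    pools <- c(pools, rep("dam", nDams))
  }
  f <- do.call(rbind, mats)
  if (is.null(sireIds)) sireIds <- sprintf("S%03d", seq_len(nSires))
  if (is.null(damIds)) damIds <- sprintf("D%04d", seq_len(nDams))
  rownames(f) <- c(sireIds, damIds)
  names(pools) <- rownames(f)
  list(composition = BreedComposition(f), pool = pools)
}

#' Offspring breed composition
#'
#' The component-wise mean of the two parental composition vectors: each
#' parent transmits half its genome, so expected fractional ancestry is the
#' parental average.
#'
#' @param dam,sire numeric composition vectors over the same breed set.
#' @return numeric vector summing to 1.
#' @export
childComposition <- function(dam, sire) {
  stopifnot(length(dam) == length(sire))
  (dam + sire) / 2
}

#' Simulate SNP genotypes for founders and pedigreed offspring
#'
#' Founder genotypes are drawn per locus as Binomial(2, p) where p is the
#' composition-weighted average of the breed-specific alternate-allele
#' frequencies. Offspring receive one allele from each parent (Mendelian
#' transmission: a parent with genotype g transmits the alternate allele
#' with probability g/2). Genotyping error flips each allele independently
#' with probability `genotypeErrorRate`.
#'
#' @param compositions a [BreedComposition-class] covering every founder
#'   (animals without both parents in `pedigree`).
#' @param params a [SimParams-class]; `breedAlleleFreqs` is drawn at
#'   Uniform(0.2, 0.8) if not supplied.
#' @param pedigree optional data.frame (`id`, `dam_id`, `sire_id`) of
#'   offspring, ordered so that parents precede their offspring.
#' @return A [GenotypePanel-class] over founders and offspring.
#' @examples
#' set.seed(1)
#' p <- simParams(nSnps = 10)
#' f <- simulateBreedCompositions(p, nSires = 2, nDams = 2)
#' ped <- data.frame(id = "C1", dam_id = "D0001", sire_id = "S001")
#' gp <- simulateGenotypes(f$composition, p, ped)
#' @export
simulateGenotypes <- function(compositions, params, pedigree = NULL) {
  freqs <- .ensureAlleleFreqs(params)
  comp <- breedFractions(compositions)
  missing_breeds <- setdiff(colnames(comp), rownames(freqs))
  if (length(missing_breeds) > 0) {
    stop(sprintf("no allele frequencies for breed(s): %s",
                 paste(missing_breeds, collapse = ", ")))
  }
  freqs <- freqs[colnames(comp), , drop = FALSE]
  L <- ncol(freqs)
  founders <- rownames(comp)
  if (!is.null(pedigree)) founders <- setdiff(founders, pedigree$id)
  ids <- c(founders, if (!is.null(pedigree)) pedigree$id)
  a1 <- matrix(0L, nrow = L, ncol = length(ids),
               dimnames = list(colnames(freqs), ids))
  a2 <- a1
  p_founder <- t(comp[founders, , drop = FALSE] %*% freqs)  # L x founders
  a1[, founders] <- rbinom(length(p_founder), 1, p_founder)
  a2[, founders] <- rbinom(length(p_founder), 1, p_founder)
  if (!is.null(pedigree)) {
    for (i in seq_len(nrow(pedigree))) {
      kid <- pedigree$id[i]
      gd <- a1[, pedigree$dam_id[i]] + a2[, pedigree$dam_id[i]]
      gs <- a1[, pedigree$sire_id[i]] + a2[, pedigree$sire_id[i]]
      a1[, kid] <- rbinom(L, 1, gd / 2)
      a2[, kid] <- rbinom(L, 1, gs / 2)
    }
  }
  e <- params@genotypeErrorRate
  if (e > 0) {
    f1 <- matrix(rbinom(length(a1), 1, e), nrow = L)
    f2 <- matrix(rbinom(length(a2), 1, e), nrow = L)
    a1 <- abs(a1 - f1)
    a2 <- abs(a2 - f2)
  }
  GenotypePanel(a1 + a2)
}

## Vigor scores for a composition matrix (rows)
.rowVigor <- function(f) 1 - rowSums(f^2)

#' Simulate one multi-sire breeding season
#'
#' Each dam still open at cycle c conceives with probability
#' `conceptionProbs[c]` shifted by her vigor score (the configured
#' conception slope per +0.10 VS, centred at `vsRef`). The sire of each
#' conception is drawn from her group's bulls with probability proportional
#' to their effective prolificacy weights. Births are placed uniformly
#' inside the conception cycle's 21-day window of the following spring's
#' calving season; weaning weight responds to the dam's vigor score with
#' the configured slope plus Gaussian noise.
#'
#' @param params a [SimParams-class].
#' @param year breeding year label (calves are born the next calendar
#'   spring).
#' @param dams data.frame with `id`, `group`, `vs` (vigor score).
#' @param sires data.frame with `id`, `group`, `weight` (effective
#'   prolificacy weight, > 0).
#' @param compositions breeds-fraction matrix covering all dams and sires
#'   (rownames are ids); calf compositions are the parental means.
#' @return list with `calves` (data.frame: `id`, `sex`, `birth_date`,
#'   `dam_id`, `true_sire_id`, `group`, `year`, `cycle`, `birth_weight`,
#'   `weaning_weight`) and `compositions` (matrix for the calves).
#' @export
simulateBreedingSeason <- function(params, year, dams, sires, compositions) {
  for (g in unique(dams$group)) {
    if (sum(sires$group == g) == 0) {
      stop(sprintf("group %s has no sires", g))
    }
  }
  slope_conc <- params@vsEffectSlopes[["conception_rate"]] * 10
  slope_ww <- params@vsEffectSlopes[["avg_ww_kg"]] * 10
  anchor <- as.Date(sprintf("%d-04-01", year + 1))
  calves <- NULL
  calf_comp <- NULL
  for (g in unique(dams$group)) {
    dg <- dams[dams$group == g, , drop = FALSE]
    sg <- sires[sires$group == g, , drop = FALSE]
    nd <- nrow(dg)
    if (nd == 0) next
    padj <- outer(dg$vs - params@vsRef, rep(slope_conc, params@nCycles)) +
      matrix(params@conceptionProbs, nrow = nd, ncol = params@nCycles,
             byrow = TRUE)
    padj <- pmin(pmax(padj, 0), 1)
    u <- matrix(runif(nd * params@nCycles), nrow = nd)
    hit <- u < padj
    cyc <- apply(hit, 1, function(z) if (any(z)) which(z)[1] else NA_integer_)
    conceived <- which(!is.na(cyc))
    if (length(conceived) == 0) next
    sire_id <- sg$id[sample.int(nrow(sg), length(conceived), replace = TRUE,
                                prob = sg$weight)]
    cc <- cyc[conceived]
    bd <- anchor + 21L * (cc - 1L) + sample.int(21L, length(cc),
                                                replace = TRUE) - 1L
    dvs <- dg$vs[conceived]
    sex <- ifelse(runif(length(cc)) < 0.5, "F", "M")
    weaned <- runif(length(cc)) < params@weaningProb
    ww <- params@wwBaseline + slope_ww * (dvs - params@vsRef) +
      rnorm(length(cc), 0, params@wwSigma)
    ww[!weaned] <- NA_real_
    cf <- data.frame(
      id = NA_character_, sex = sex, birth_date = bd,
      dam_id = dg$id[conceived], true_sire_id = sire_id,
      group = g, year = year, cycle = cc,
      birth_weight = rnorm(length(cc), params@birthWeightMean,
                           params@birthWeightSigma),
      weaning_weight = ww, stringsAsFactors = FALSE
    )
    comp_g <- (compositions[cf$dam_id, , drop = FALSE] +
                 compositions[cf$true_sire_id, , drop = FALSE]) / 2
    calves <- rbind(calves, cf)
    calf_comp <- rbind(calf_comp, comp_g)
  }
  if (is.null(calves)) {
    calves <- data.frame(id = character(0), sex = character(0),
                         birth_date = as.Date(character(0)),
                         dam_id = character(0), true_sire_id = character(0),
                         group = integer(0), year = integer(0),
                         cycle = integer(0), birth_weight = numeric(0),
                         weaning_weight = numeric(0))
    calf_comp <- compositions[0, , drop = FALSE]
  } else {
    ## deterministic ids in birth order
    o <- order(calves$birth_date, calves$dam_id)
    calves <- calves[o, , drop = FALSE]
    calf_comp <- calf_comp[o, , drop = FALSE]
    calves$id <- sprintf("C%d-%03d", year, seq_len(nrow(calves)))
    rownames(calves) <- NULL
    rownames(calf_comp) <- calves$id
  }
  list(calves = calves, compositions = calf_comp)
}

#' Apply replacement-heifer retention rules
#'
#' Applies the configured togglable culling criteria to the heifer calves
#' of each year, then retains the top `retentionFraction` of the remaining
#' eligible heifers by weaning weight (the "weigh and keep the top
#' females" rule). Criteria currently supported: `"third_cycle"` (a heifer
#' born in calving cycle 3 or later is culled, the post-2019 rule) and
#' `"not_weaned"` (always applied implicitly: a heifer without a weaning
#' weight is not eligible). Every exclusion is logged with a reason code.
#'
#' @param herd a [HerdBook-class].
#' @param params a [SimParams-class] (`retentionRules`,
#'   `retentionFraction`).
#' @param cycleAssignments optional data.frame (`calf_id`, `cycle`) from
#'   [assignCycles()] or simulator truth, required for the `third_cycle`
#'   rule.
#' @return list with `herd` (the HerdBook with `retained` filled in for
#'   heifer calves) and `log` (data.frame `id`, `year`, `reason` with codes
#'   `not_weaned`, `third_cycle`, `low_weaning_weight`, `retained`).
#' @export
simulateRetention <- function(herd, params, cycleAssignments = NULL) {
  a <- herdAnimals(herd)
  log <- NULL
  if ("third_cycle" %in% params@retentionRules &&
      is.null(cycleAssignments)) {
    stop("the third_cycle rule needs cycle assignments")
  }
  for (y in sort(unique(a$year[!is.na(a$year)]))) {
    heifers <- which(a$year == y & a$sex == "F" & !is.na(a$dam_id))
    if (length(heifers) == 0) next
    elig <- heifers
    notweaned <- elig[is.na(a$weaning_weight[elig])]
    elig <- setdiff(elig, notweaned)
    addlog <- function(ids, reason) {
      if (length(ids) == 0) return(NULL)
      data.frame(id = a$id[ids], year = y, reason = reason)
    }
    log <- rbind(log, addlog(notweaned, "not_weaned"))
    if ("third_cycle" %in% params@retentionRules) {
      cyc <- cycleAssignments$cycle[match(a$id[elig],
                                          cycleAssignments$calf_id)]
      third <- elig[!is.na(cyc) & cyc >= 3]
      log <- rbind(log, addlog(third, "third_cycle"))
      elig <- setdiff(elig, third)
    }
    nkeep <- round(params@retentionFraction * length(elig))
    o <- elig[order(-a$weaning_weight[elig], a$id[elig])]
    keep <- o[seq_len(min(nkeep, length(o)))]
    drop <- setdiff(elig, keep)
    log <- rbind(log, addlog(drop, "low_weaning_weight"),
                 addlog(keep, "retained"))
    a$retained[heifers] <- FALSE
    a$retained[keep] <- TRUE
  }
  herd@animals <- a
  validObject(herd)
  list(herd = herd, log = log)
}

#' Simulate a complete multi-year herd with ground truth
#'
#' Runs the full generator: founder compositions and genotypes, a bull pool
#' with static prolificacy weights and age structure, `nYears` breeding
#' seasons with dams assigned to groups by age (2-year-old replacement
#' heifers in group 4, 3-year-olds in group 3, mature cows split over
#' groups 1 and 2), heifer retention with the configured rules, annual
#' culling of open and aged cows, and Mendelian genotype transmission to
#' every calf.
#'
#' @param params a [SimParams-class]; `params@seed` fixes all randomness.
#' @return list with components `herd` (a [HerdBook-class] with true sires
#'   and a service roster), `genotypes` (a [GenotypePanel-class]),
#'   `compositions` (a [BreedComposition-class] over all animals), `truth`
#'   (list: `weights` named per-bull raw weights, `effectiveWeights`
#'   data.frame per sire x group-year, `slopes`, `cycles` data.frame of
#'   true conception cycles, `seasonAnchor` dates), and `retentionLog`.
#' @examples
#' sim <- simulateHerd(simParams(nYears = 1, seed = 3))
#' sim$herd
#' @export
simulateHerd <- function(params) {
  set.seed(params@seed)
  startYear <- 2014L
  freqs <- .ensureAlleleFreqs(params)
  params@breedAlleleFreqs <- freqs
  nSiresTotal <- sum(vapply(params@groups, function(g) g$nSires, integer(1)))
  nDamsTotal <- sum(vapply(params@groups, function(g) g$nDams, integer(1)))

  ## ---- founder bulls (with replacements for later years) and dams
  nBulls <- nSiresTotal + ceiling(0.4 * nSiresTotal * params@nYears)
  founders <- simulateBreedCompositions(
    params, nSires = nBulls, nDams = nDamsTotal,
    sireIds = sprintf("S%03d", seq_len(nBulls)),
    damIds = sprintf("D%04d", seq_len(nDamsTotal)))
  comp <- breedFractions(founders$composition)
  bullIds <- sprintf("S%03d", seq_len(nBulls))
  if (length(params@prolificacyWeights) > 0) {
    w <- rep_len(params@prolificacyWeights, nBulls)
  } else {
    w <- rlnorm(nBulls, 0, params@prolificacySdLog)
  }
  names(w) <- bullIds
  bulls <- data.frame(
    id = bullIds, weight = w,
    birth_cal_year = NA_integer_, active = FALSE, yearsUsed = 0L,
    stringsAsFactors = FALSE)
  ## initial actives: a realistic age mix
  bulls$active[seq_len(nSiresTotal)] <- TRUE
  bulls$birth_cal_year[seq_len(nSiresTotal)] <-
    startYear - sample(c(1L, 2L, 3L, 4L), nSiresTotal, replace = TRUE,
                       prob = c(0.2, 0.35, 0.3, 0.15))
  nextBull <- nSiresTotal + 1L

  ## ---- founder dams, with ages per group spec
  damIds <- sprintf("D%04d", seq_len(nDamsTotal))
  dam_group <- integer(0)
  dam_age <- integer(0)
  for (g in params@groups) {
    dam_group <- c(dam_group, rep(g$name, g$nDams))
    dam_age <- c(dam_age, sample(rep(g$damAges, length.out = g$nDams)))
  }
  dams <- data.frame(
    id = damIds, birth_cal_year = (startYear + 1L) - dam_age,
    g12 = sample(1:2, nDamsTotal, replace = TRUE), active = TRUE,
    disposal_year = NA_integer_, stringsAsFactors = FALSE)
  dams$g12[dam_group %in% c(1L, 2L)] <- dam_group[dam_group %in% c(1L, 2L)]
  dam_vs <- .rowVigor(comp[damIds, , drop = FALSE])
  names(dam_vs) <- damIds

  services <- NULL
  all_calves <- NULL
  calf_comp_all <- comp[0, , drop = FALSE]
  pedigree <- NULL
  retention_log <- NULL
  eff_weights <- NULL
  groupsByName <- setNames(params@groups,
                           vapply(params@groups, function(g)
                             as.character(g$name), character(1)))

  for (y in seq(startYear, length.out = params@nYears)) {
    calving_year <- y + 1L
    ## assign active dams to groups by age at calving
    act <- dams[dams$active, , drop = FALSE]
    age <- calving_year - act$birth_cal_year
    grp <- ifelse(age <= 2, 4L, ifelse(age == 3, 3L, act$g12))
    season_dams <- data.frame(id = act$id, group = grp,
                              vs = dam_vs[act$id],
                              stringsAsFactors = FALSE)
    ## bull pool maintenance: retire, then recruit to required counts
    if (y > startYear) {
      age_b <- y - bulls$birth_cal_year
      retire <- bulls$active &
        (bulls$yearsUsed >= 4L | age_b > 6L |
           runif(nrow(bulls)) < 0.25)
      bulls$active[retire] <- FALSE
      need <- nSiresTotal - sum(bulls$active)
      while (need > 0 && nextBull <= nBulls) {
        bulls$active[nextBull] <- TRUE
        bulls$birth_cal_year[nextBull] <- y - sample(1:2, 1)
        nextBull <- nextBull + 1L
        need <- need - 1L
      }
    }
    actives <- which(bulls$active)
    ## random assignment of active bulls to groups at required counts
    pool <- sample(actives)
    season_sires <- NULL
    for (g in params@groups) {
      take <- pool[seq_len(min(g$nSires, length(pool)))]
      pool <- setdiff(pool, take)
      age_b <- y - bulls$birth_cal_year[take]
      effw <- bulls$weight[take] *
        ifelse(age_b <= 1, params@yearlingFactor, 1)
      season_sires <- rbind(season_sires, data.frame(
        id = bulls$id[take], group = g$name, weight = effw,
        stringsAsFactors = FALSE))
    }
    bulls$yearsUsed[bulls$id %in% season_sires$id] <-
      bulls$yearsUsed[bulls$id %in% season_sires$id] + 1L
    services <- rbind(services, data.frame(
      sire_id = season_sires$id, group = season_sires$group, year = y))
    eff_weights <- rbind(eff_weights, data.frame(
      sire_id = season_sires$id, group = season_sires$group, year = y,
      weight = season_sires$weight))

    season <- simulateBreedingSeason(params, y, season_dams, season_sires,
                                     rbind(comp, calf_comp_all))
    cf <- season$calves
    all_calves <- rbind(all_calves, cf)
    calf_comp_all <- rbind(calf_comp_all, season$compositions)
    if (nrow(cf) > 0) {
      pedigree <- rbind(pedigree, data.frame(
        id = cf$id, dam_id = cf$dam_id, sire_id = cf$true_sire_id))
      dam_vs <- c(dam_vs, setNames(.rowVigor(season$compositions), cf$id))
    }

    ## cull: open dams, background rate, age limit
    open <- dams$active & !(dams$id %in% cf$dam_id)
    cull <- dams$active &
      ((open & runif(nrow(dams)) < params@openCullProb) |
         runif(nrow(dams)) < params@cowCullProb |
         (calving_year - dams$birth_cal_year) >= params@maxCowAge)
    dams$active[cull] <- FALSE
    dams$disposal_year[cull] <- y

    ## heifer retention decided at weaning; retained heifers enter the
    ## dam pool and will breed as 2-year-olds in year y + 2
    hf <- cf[cf$sex == "F", , drop = FALSE]
    if (nrow(hf) > 0) {
      elig <- hf[!is.na(hf$weaning_weight), , drop = FALSE]
      dropped <- hf[is.na(hf$weaning_weight), , drop = FALSE]
      if (nrow(dropped) > 0) {
        retention_log <- rbind(retention_log, data.frame(
          id = dropped$id, year = y, reason = "not_weaned"))
      }
      if ("third_cycle" %in% params@retentionRules && nrow(elig) > 0) {
        third <- elig$cycle >= 3
        if (any(third)) {
          retention_log <- rbind(retention_log, data.frame(
            id = elig$id[third], year = y, reason = "third_cycle"))
        }
        elig <- elig[!third, , drop = FALSE]
      }
      nkeep <- round(params@retentionFraction * nrow(elig))
      o <- elig[order(-elig$weaning_weight, elig$id), , drop = FALSE]
      keep <- o$id[seq_len(min(nkeep, nrow(o)))]
      drop_ids <- setdiff(elig$id, keep)
      if (length(drop_ids) > 0) {
        retention_log <- rbind(retention_log, data.frame(
          id = drop_ids, year = y, reason = "low_weaning_weight"))
      }
      if (length(keep) > 0) {
        retention_log <- rbind(retention_log, data.frame(
          id = keep, year = y, reason = "retained"))
        dams <- rbind(dams, data.frame(
          id = keep, birth_cal_year = calving_year,
          g12 = sample(1:2, length(keep), replace = TRUE),
          active = TRUE, disposal_year = NA_integer_))
      }
    }
  }

  ## ---- assemble the herd book
  used_bulls <- bulls[!is.na(bulls$birth_cal_year), , drop = FALSE]
  founder_rows <- data.frame(
    id = c(damIds, used_bulls$id),
    sex = c(rep("F", length(damIds)), rep("M", nrow(used_bulls))),
    birth_date = as.Date(sprintf("%d-04-15",
      c(dams$birth_cal_year[match(damIds, dams$id)],
        used_bulls$birth_cal_year))),
    dam_id = NA_character_, true_sire_id = NA_character_,
    stringsAsFactors = FALSE)
  retained_ids <- retention_log$id[retention_log$reason == "retained"]
  calf_rows <- data.frame(
    id = all_calves$id, sex = all_calves$sex,
    birth_date = all_calves$birth_date, dam_id = all_calves$dam_id,
    true_sire_id = all_calves$true_sire_id, group = all_calves$group,
    year = all_calves$year, birth_weight = all_calves$birth_weight,
    weaning_weight = all_calves$weaning_weight,
    retained = ifelse(all_calves$sex == "F",
                      all_calves$id %in% retained_ids, NA),
    stringsAsFactors = FALSE)
  calf_rows$disposal_year <- dams$disposal_year[match(calf_rows$id, dams$id)]
  founder_rows$disposal_year <- dams$disposal_year[match(founder_rows$id,
                                                         dams$id)]
  herd <- HerdBook(rbind(
    cbind(founder_rows[, c("id", "sex", "birth_date", "dam_id",
                           "true_sire_id")],
          assigned_sire_id = NA_character_, group = NA_integer_,
          year = NA_integer_, birth_weight = NA_real_,
          weaning_weight = NA_real_, retained = NA,
          disposal_year = founder_rows$disposal_year),
    cbind(calf_rows[, c("id", "sex", "birth_date", "dam_id",
                        "true_sire_id")],
          assigned_sire_id = NA_character_,
          group = calf_rows$group, year = calf_rows$year,
          birth_weight = calf_rows$birth_weight,
          weaning_weight = calf_rows$weaning_weight,
          retained = calf_rows$retained,
          disposal_year = calf_rows$disposal_year)),
    services = services)

  all_comp <- rbind(comp[c(damIds, used_bulls$id), , drop = FALSE],
                    calf_comp_all)
  genotypes <- simulateGenotypes(BreedComposition(all_comp), params,
                                 pedigree)
  truth <- list(
    weights = w, effectiveWeights = eff_weights,
    slopes = params@vsEffectSlopes,
    cycles = data.frame(calf_id = all_calves$id, group = all_calves$group,
                        year = all_calves$year, cycle = all_calves$cycle),
    startYear = startYear)
  list(herd = herd, genotypes = genotypes,
       compositions = BreedComposition(all_comp), truth = truth,
       retentionLog = retention_log)
}

#' Simulate per-heifer vigor-score trait responses with injected slopes
#'
#' Direct generator of heifer-level records for the four regressed traits,
#' with exactly the configured linear effect per +0.10 vigor score: age at
#' first calving (Gaussian noise), average calf weaning weight (Gaussian),
#' conception (Bernoulli through a linear probability), and lifetime
#' productivity as cumulative weaned kg (Gaussian). Used to verify that the
#' regression stage recovers known slopes.
#'
#' @param n number of heifers.
#' @param slopes named numeric per +0.10 VS (defaults: the estimated
#'   values -0.7 d AFC, +1.74 kg WW, +0.02 conception, +60.3 kg lifetime).
#' @param params a [SimParams-class] supplying noise scales and `vsRef`.
#' @param baselines named numeric trait values at `vsRef`.
#' @return data.frame with columns `vs`, `afc_days`, `avg_ww_kg`,
#'   `conception`, `lifetime_kg`.
#' @examples
#' set.seed(1)
#' tr <- simulateVigorTraits(200)
#' slopePer10pct(tr$vs, tr$avg_ww_kg)
#' @export
simulateVigorTraits <- function(n,
                                slopes = c(afc_days = -0.7,
                                           avg_ww_kg = 1.74,
                                           conception_rate = 0.02,
                                           lifetime_kg = 60.3),
                                params = simParams(),
                                baselines = c(afc_days = 740,
                                              avg_ww_kg = 190,
                                              conception_rate = 0.85,
                                              lifetime_kg = 600)) {
  vs <- stats::rbeta(n, 5.9, 3.2)
  dv <- vs - params@vsRef
  p <- pmin(pmax(baselines[["conception_rate"]] +
                   slopes[["conception_rate"]] * 10 * dv, 0.01), 0.99)
  data.frame(
    vs = vs,
    afc_days = baselines[["afc_days"]] + slopes[["afc_days"]] * 10 * dv +
      rnorm(n, 0, params@afcSigma),
    avg_ww_kg = baselines[["avg_ww_kg"]] + slopes[["avg_ww_kg"]] * 10 * dv +
      rnorm(n, 0, params@wwSigma),
    conception = rbinom(n, 1, p),
    lifetime_kg = baselines[["lifetime_kg"]] +
      slopes[["lifetime_kg"]] * 10 * dv + rnorm(n, 0, params@lifetimeSigma)
  )
}
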