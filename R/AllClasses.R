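#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#' @importFrom S4Vectors DataFrame
#' @importFrom stats aggregate ave coef complete.cases cor lm median pnorm
#'   quantile rbeta rbinom rgamma rlnorm rnorm runif sd setNames
#' @importFrom utils head read.csv read.delim read.table write.csv
#'   write.table
NULL

## ---------------------------------------------------------------------------
## HerdBook
## ---------------------------------------------------------------------------

.HERDBOOK_COLS <- c(
  "id", "sex", "birth_date", "dam_id", "true_sire_id", "assigned_sire_id",
  "group", "year", "birth_weight", "weaning_weight", "retained",
  "disposal_year"
)

#' HerdBook: the longitudinal animal registry
#'
#' An S4 container for the herd book of a cow-calf operation: one row per
#' animal (cows, bulls and calves), with pedigree links, birth dates and
#' weights, breeding-group membership and retention/disposal records, plus a
#' service roster listing which sires served which breeding group in which
#' year (the candidate lists for parentage testing).
#'
#' @slot animals `data.frame` with columns `id`, `sex` (`"F"`/`"M"`),
#'   `birth_date` (`Date`), `dam_id`, `true_sire_id` (simulation ground
#'   truth, `NA` for field data), `assigned_sire_id` (DNA-verified sire),
#'   `group` (breeding group 1-4 the animal was born into), `year`
#'   (breeding year of that group), `birth_weight` (kg), `weaning_weight`
#'   (kg; `NA` means the calf was not weaned), `retained` (logical),
#'   `disposal_year`.
#' @slot services `data.frame` with columns `sire_id`, `group`, `year`: the
#'   multi-sire breeding-pasture roster.
#'
#' @name HerdBook-class
#' @aliases HerdBook-class
#' @exportClass HerdBook
setClass("HerdBook",
  representation(animals = "data.frame", services = "data.frame")
)

setValidity("HerdBook", function(object) {
  a <- object@animals
  msg <- character(0)
  missing_cols <- setdiff(.HERDBOOK_COLS, names(a))
  if (length(missing_cols) > 0) {
    return(sprintf("missing animal columns: %s",
                   paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(a$id)) {
    msg <- c(msg, sprintf("duplicated animal ids: %s",
      paste(unique(a$id[duplicated(a$id)]), collapse = ", ")))
  }
  if (!inherits(a$birth_date, "Date")) {
    msg <- c(msg, "birth_date must be a Date")
  }
  if (!all(a$sex %in% c("F", "M"))) {
    msg <- c(msg, "sex must be 'F' or 'M'")
  }
  for (pcol in c("dam_id", "true_sire_id")) {
    ref <- a[[pcol]]
    bad <- which(!is.na(ref) & !(ref %in% a$id))
    if (length(bad) > 0) {
      msg <- c(msg, sprintf("rows %s: %s references an unknown animal",
                            paste(head(bad, 5), collapse = ","), pcol))
    }
    idx <- match(ref, a$id)
    ok <- is.na(idx)
    cmp <- which(!ok)
    late <- cmp[!(a$birth_date[cmp] > a$birth_date[idx[cmp]])]
    if (length(late) > 0) {
      msg <- c(msg, sprintf(
        "rows %s: calf birth_date not after its %s birth_date",
        paste(head(late, 5), collapse = ","), pcol))
    }
  }
  s <- object@services
  if (nrow(s) > 0 && !all(c("sire_id", "group", "year") %in% names(s))) {
    msg <- c(msg, "services needs columns sire_id, group, year")
  }
  if (length(msg) == 0) TRUE else msg
})

#' Construct a HerdBook
#'
#' @param animals data.frame of animal records (see [HerdBook-class]);
#'   missing optional columns are filled with `NA`.
#' @param services data.frame sire service roster (`sire_id`, `group`,
#'   `year`); may be empty.
#' @return A validated [HerdBook-class] object.
#' @examples
#' hb <- HerdBook(data.frame(
#'   id = c("D1", "S1", "C1"), sex = c("F", "M", "F"),
#'   birth_date = as.Date(c("2012-04-01", "2013-04-01", "2015-04-10")),
#'   dam_id = c(NA, NA, "D1"), true_sire_id = c(NA, NA, "S1")
#' ))
#' nAnimals(hb)
#' @export
HerdBook <- function(animals,
                     services = data.frame(sire_id = character(0),
                                           group = integer(0),
                                           year = integer(0))) {
  defaults <- list(
    dam_id = NA_character_, true_sire_id = NA_character_,
    assigned_sire_id = NA_character_, group = NA_integer_,
    year = NA_integer_, birth_weight = NA_real_, weaning_weight = NA_real_,
    retained = NA, disposal_year = NA_integer_
  )
  for (col in names(defaults)) {
    if (is.null(animals[[col]])) animals[[col]] <- defaults[[col]]
  }
  animals <- animals[, .HERDBOOK_COLS]
  animals$id <- as.character(animals$id)
  for (col in c("dam_id", "true_sire_id", "assigned_sire_id")) {
    animals[[col]] <- as.character(animals[[col]])
  }
  rownames(animals) <- NULL
  new("HerdBook", animals = animals, services = services)
}

#' @describeIn HerdBook-class number of animal records
#' @param x,object a `HerdBook`
#' @export
setGeneric("nAnimals", function(x) standardGeneric("nAnimals"))

#' @rdname HerdBook-class
#' @export
setMethod("nAnimals", "HerdBook", function(x) nrow(x@animals))

#' @describeIn HerdBook-class the animal record table
#' @export
setGeneric("herdAnimals", function(x) standardGeneric("herdAnimals"))

#' @rdname HerdBook-class
#' @export
setMethod("herdAnimals", "HerdBook", function(x) x@animals)

#' @describeIn HerdBook-class the sire service roster
#' @export
setGeneric("sireServices", function(x) standardGeneric("sireServices"))

#' @rdname HerdBook-class
#' @export
setMethod("sireServices", "HerdBook", function(x) x@services)

#' @rdname HerdBook-class
#' @export
setMethod("show", "HerdBook", function(object) {
  a <- object@animals
  cat(sprintf("HerdBook: %d animals (%d F / %d M), %d calves with a dam\n",
              nrow(a), sum(a$sex == "F"), sum(a$sex == "M"),
              sum(!is.na(a$dam_id))))
  if (nrow(object@services) > 0) {
    cat(sprintf("  service roster: %d sire x group-year entries (%d sires)\n",
                nrow(object@services),
                length(unique(object@services$sire_id))))
  }
  yrs <- sort(unique(a$year[!is.na(a$year)]))
  if (length(yrs) > 0) {
    cat(sprintf("  breeding years: %s\n", paste(yrs, collapse = ", ")))
  }
  invisible(NULL)
})

## ---------------------------------------------------------------------------
## GenotypePanel
## ---------------------------------------------------------------------------

#' GenotypePanel: biallelic SNP calls for parentage verification
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with a single
#' `"calls"` assay: loci in rows, animals in columns, genotypes coded as the
#' number of copies of the alternate allele (0/1/2, `NA` = no call).
#' `colData` carries the per-animal missing-call rate.
#'
#' @name GenotypePanel-class
#' @aliases GenotypePanel-class
#' @exportClass GenotypePanel
setClass("GenotypePanel", contains = "SummarizedExperiment")

setValidity("GenotypePanel", function(object) {
  if (!"calls" %in% SummarizedExperiment::assayNames(object)) {
    return("needs a 'calls' assay")
  }
  g <- SummarizedExperiment::assay(object, "calls")
  if (!all(g %in% c(0L, 1L, 2L) | is.na(g))) {
    return("genotype calls must be 0, 1, 2 or NA")
  }
  if (is.null(colnames(g)) || anyDuplicated(colnames(g))) {
    return("animal (column) names must be present and unique")
  }
  TRUE
})

#' Construct a GenotypePanel
#'
#' @param calls integer matrix of genotypes, loci x animals, coded 0/1/2/NA
#'   as copies of the alternate allele. An animals x loci matrix is accepted
#'   and transposed when `animalsInRows = TRUE`.
#' @param animalsInRows logical; set `TRUE` if `calls` is animals x loci.
#' @return A [GenotypePanel-class].
#' @examples
#' g <- matrix(c(0L, 1L, 2L, 2L, 1L, 0L), nrow = 3,
#'             dimnames = list(paste0("snp", 1:3), c("A1", "A2")))
#' gp <- GenotypePanel(g)
#' missingRate(gp)
#' @export
GenotypePanel <- function(calls, animalsInRows = FALSE) {
  if (animalsInRows) calls <- t(calls)
  if (is.null(rownames(calls))) {
    rownames(calls) <- sprintf("snp%03d", seq_len(nrow(calls)))
  }
  storage.mode(calls) <- "integer"
  miss <- colMeans(is.na(calls))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(calls = calls),
    colData = S4Vectors::DataFrame(animal_id = colnames(calls),
                                   missing_rate = miss)
  )
  obj <- new("GenotypePanel", se)
  all_missing <- colnames(calls)[miss >= 1]
  if (length(all_missing) > 0) {
    warning(sprintf("animal(s) with all genotypes missing: %s",
                    paste(all_missing, collapse = ", ")))
  }
  obj
}

#' @describeIn GenotypePanel-class the loci x animals genotype matrix
#' @param x,object a `GenotypePanel`
#' @export
setGeneric("genotypeCalls", function(x) standardGeneric("genotypeCalls"))

#' @rdname GenotypePanel-class
#' @export
setMethod("genotypeCalls", "GenotypePanel",
          function(x) SummarizedExperiment::assay(x, "calls"))

#' @describeIn GenotypePanel-class per-animal missing-call rate
#' @export
setGeneric("missingRate", function(x) standardGeneric("missingRate"))

#' @rdname GenotypePanel-class
#' @export
setMethod("missingRate", "GenotypePanel", function(x) {
  setNames(x$missing_rate, x$animal_id)
})

#' @describeIn GenotypePanel-class per-locus alternate-allele frequency
#'   estimated from the calls (allele counts over non-missing animals)
#' @export
setGeneric("altAlleleFreq", function(x) standardGeneric("altAlleleFreq"))

#' @rdname GenotypePanel-class
#' @export
setMethod("altAlleleFreq", "GenotypePanel", function(x) {
  g <- genotypeCalls(x)
  rowSums(g, na.rm = TRUE) / (2 * rowSums(!is.na(g)))
})

#' @rdname GenotypePanel-class
#' @export
setMethod("show", "GenotypePanel", function(object) {
  g <- genotypeCalls(object)
  cat(sprintf("GenotypePanel: %d loci x %d animals, %.1f%% missing calls\n",
              nrow(g), ncol(g), 100 * mean(is.na(g))))
  invisible(NULL)
})

## ---------------------------------------------------------------------------
## BreedComposition
## ---------------------------------------------------------------------------

#' BreedComposition: genomic breed fractions per animal
#'
#' Per-animal fractional ancestry over named founder breeds plus an
#' `Indeterminate` remainder. Each row sums to 1 (within 1e-9), matching the
#' accounting of commercial genomic breed-composition panels, where any
#' ancestry not attributable to the recognized breeds is reported as an
#' indeterminate percentage.
#'
#' @slot fractions numeric matrix, animals x components; rownames are animal
#'   ids; the last column is conventionally `Indeterminate`.
#'
#' @name BreedComposition-class
#' @aliases BreedComposition-class
#' @exportClass BreedComposition
setClass("BreedComposition", representation(fractions = "matrix"))

setValidity("BreedComposition", function(object) {
  f <- object@fractions
  msg <- character(0)
  if (is.null(rownames(f)) || anyDuplicated(rownames(f))) {
    msg <- c(msg, "animal (row) names must be present and unique")
  }
  if (is.null(colnames(f))) msg <- c(msg, "breed (column) names required")
  if (any(f < -1e-9 | f > 1 + 1e-9)) {
    msg <- c(msg, "fractions must lie in [0, 1]")
  }
  bad <- which(abs(rowSums(f) - 1) > 1e-9)
  if (length(bad) > 0) {
    msg <- c(msg, sprintf("rows not summing to 1: %s",
                          paste(head(rownames(f)[bad], 5), collapse = ", ")))
  }
  if (length(msg) == 0) TRUE else msg
})

#' Construct a BreedComposition
#'
#' @param fractions animals x breeds matrix of ancestry fractions, rows
#'   summing to 1; rownames are animal ids.
#' @return A [BreedComposition-class].
#' @examples
#' bc <- BreedComposition(matrix(c(0.5, 0.25, 0.25), nrow = 1,
#'   dimnames = list("A1", c("Angus", "Hereford", "Gelbvieh"))))
#' vigorScore(bc)
#' @export
BreedComposition <- function(fractions) {
  new("BreedComposition", fractions = as.matrix(fractions))
}

#' @describeIn BreedComposition-class the animals x breeds fraction matrix
#' @param x,object a `BreedComposition`
#' @export
setGeneric("breedFractions", function(x) standardGeneric("breedFractions"))

#' @rdname BreedComposition-class
#' @export
setMethod("breedFractions", "BreedComposition", function(x) x@fractions)

#' @rdname BreedComposition-class
#' @export
setMethod("show", "BreedComposition", function(object) {
  f <- object@fractions
  cat(sprintf("BreedComposition: %d animals x %d components (%s)\n",
              nrow(f), ncol(f),
              paste(head(colnames(f), 5), collapse = ", ")))
  invisible(NULL)
})

## ---------------------------------------------------------------------------
## RunConfig
## ---------------------------------------------------------------------------

#' RunConfig: pipeline constants
#'
#' Holds the tunable constants of the analysis pipeline: the 21-day cycle
#' length, the mature-cow definition and rank used for the season start
#' rule, the empirical BPI quartile descriptors, the 60% first-cycle
#' benchmark, the suggested 75% vigor-score cutoff, and the published
#' per-10%-vigor-score benchmark slopes.
#'
#' @slot cycleLengthDays length of a calving cycle (days, default 21).
#' @slot matureAgeYears minimum dam age (whole years at calving) to count as
#'   a mature cow (default 3).
#' @slot firstCycleStartRank the season starts at this many mature-cow
#'   calvings (default 3).
#' @slot bpiBottomCutoff,bpiTopCutoff empirical BPI quartile descriptors
#'   (defaults 0.4 and 1.4); stratification itself is rank-based.
#' @slot firstCycleBenchmark recommended first-cycle calf share (default
#'   0.60).
#' @slot vsCutoff suggested vigor-score selection cutoff (default 0.75).
#' @slot benchmarkSlopes named numeric, trait units per +10% vigor score:
#'   `avg_ww_kg` +1.33, `afc_days` -2, `conception_rate` +0.02,
#'   `lifetime_kg` +35.7.
#' @slot rngSeed integer seed for the pipeline.
#'
#' @name RunConfig-class
#' @aliases RunConfig-class
#' @exportClass RunConfig
setClass("RunConfig", representation(
  cycleLengthDays = "integer",
  matureAgeYears = "integer",
  firstCycleStartRank = "integer",
  bpiBottomCutoff = "numeric",
  bpiTopCutoff = "numeric",
  firstCycleBenchmark = "numeric",
  vsCutoff = "numeric",
  benchmarkSlopes = "numeric",
  rngSeed = "integer"
))

setValidity("RunConfig", function(object) {
  msg <- character(0)
  if (object@cycleLengthDays <= 0) msg <- c(msg, "cycleLengthDays must be > 0")
  if (object@bpiTopCutoff < object@bpiBottomCutoff) {
    msg <- c(msg, "bpiTopCutoff must be >= bpiBottomCutoff")
  }
  for (s in c("firstCycleBenchmark", "vsCutoff")) {
    v <- slot(object, s)
    if (v < 0 || v > 1) msg <- c(msg, sprintf("%s must be in [0, 1]", s))
  }
  if (length(msg) == 0) TRUE else msg
})

#' Construct a RunConfig
#'
#' @param cycleLengthDays,matureAgeYears,firstCycleStartRank,bpiBottomCutoff
#'   see [RunConfig-class].
#' @param bpiTopCutoff,firstCycleBenchmark,vsCutoff,benchmarkSlopes,rngSeed
#'   see [RunConfig-class].
#' @return A validated [RunConfig-class].
#' @examples
#' cfg <- runConfig(rngSeed = 7)
#' cfg
#' @export
runConfig <- function(cycleLengthDays = 21L,
                      matureAgeYears = 3L,
                      firstCycleStartRank = 3L,
                      bpiBottomCutoff = 0.4,
                      bpiTopCutoff = 1.4,
                      firstCycleBenchmark = 0.60,
                      vsCutoff = 0.75,
                      benchmarkSlopes = c(avg_ww_kg = 1.33,
                                          afc_days = -2,
                                          conception_rate = 0.02,
                                          lifetime_kg = 35.7),
                      rngSeed = 1L) {
  new("RunConfig",
      cycleLengthDays = as.integer(cycleLengthDays),
      matureAgeYears = as.integer(matureAgeYears),
      firstCycleStartRank = as.integer(firstCycleStartRank),
      bpiBottomCutoff = bpiBottomCutoff,
      bpiTopCutoff = bpiTopCutoff,
      firstCycleBenchmark = firstCycleBenchmark,
      vsCutoff = vsCutoff,
      benchmarkSlopes = benchmarkSlopes,
      rngSeed = as.integer(rngSeed))
}

#' @rdname RunConfig-class
#' @param object a `RunConfig`
#' @export
setMethod("show", "RunConfig", function(object) {
  cat("RunConfig:\n")
  cat(sprintf("  cycle length %d d; mature age >= %d y; season start at mature calving #%d\n",
              object@cycleLengthDays, object@matureAgeYears,
              object@firstCycleStartRank))
  cat(sprintf("  BPI quartile descriptors %.2g / %.2g; first-cycle benchmark %.0f%%; VS cutoff %.0f%%\n",
              object@bpiBottomCutoff, object@bpiTopCutoff,
              100 * object@firstCycleBenchmark, 100 * object@vsCutoff))
  cat("  benchmark slopes per +10% VS:",
      paste(sprintf("%s=%+.3g", names(object@benchmarkSlopes),
                    object@benchmarkSlopes), collapse = ", "), "\n")
  invisible(NULL)
})

#' Read a RunConfig from YAML
#'
#' Keys mirror the arguments of [runConfig()]; absent keys keep defaults,
#' unknown keys raise an error.
#'
#' @param path path to a YAML file.
#' @return A [RunConfig-class].
#' @export
readRunConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(runConfig))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  if (!is.null(vals$benchmarkSlopes)) {
    vals$benchmarkSlopes <- unlist(vals$benchmarkSlopes)
  }
  do.call(runConfig, vals)
}
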