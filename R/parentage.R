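## SNP-exclusion sire verification.
##
## Parentage is assigned by opposing-homozygote counting against the
## candidate sires of the dam's breeding group: a locus where calf and
## candidate are homozygous for different alleles is Mendelian-impossible
## without genotyping error. Candidates within the mismatch tolerance on
## the 100-locus base panel are "compatible"; ambiguity triggers a re-test
## on extension loci; calves with no single surviving candidate are
## classified "no sire match". Dam genotypes are not used (dams are known
## from calving records).

#' Count opposing homozygotes between two genotype vectors
#'
#' The number of loci where one animal carries 0 and the other 2 copies of
#' the alternate allele. Loci with a missing call in either animal are
#' skipped.
#'
#' @param calf,candidate equal-length genotype vectors coded 0/1/2/`NA`.
#' @return integer count.
#' @examples
#' countOpposingHomozygotes(c(0, 1, 2), c(0, 1, 2))  # 0
#' countOpposingHomozygotes(2, 0)                    # 1
#' @export
countOpposingHomozygotes <- function(calf, candidate) {
  if (length(calf) != length(candidate)) {
    stop("genotype vectors differ in length")
  }
  sum((calf == 0 & candidate == 2) | (calf == 2 & candidate == 0),
      na.rm = TRUE)
}

#' Assign a sire to one calf by exclusion
#'
#' Candidates with at most `maxMismatches` opposing homozygotes on the base
#' panel (the first `basePanelSize` loci, in panel order) are compatible.
#' Exactly one compatible candidate is a match. If several survive, the
#' comparison is repeated on base plus the next `extensionSize` loci; a
#' residual tie is broken by the fewest mismatches, and if still tied (or
#' no candidate survives) the calf is classified `no_sire_match`. The
#' result does not depend on the order candidates are supplied in.
#'
#' @param calfId calf animal id (must be a column of `panel`).
#' @param candidates candidate sire ids, drawn from the dam's breeding
#'   group's service roster.
#' @param panel a [GenotypePanel-class].
#' @param basePanelSize loci in the base verification panel (default 100,
#'   capped at the panel size).
#' @param extensionSize additional loci for ambiguous cases (default 20).
#' @param maxMismatches opposing-homozygote tolerance (default 1, i.e. one
#'   tolerated genotyping error per 100 loci).
#' @return list of class `ParentageResult`: `calf_id`,
#'   `assigned_sire_id` (`NA` when unmatched), `n_candidates`,
#'   `opposing_homozygote_counts` (named integer, on the panel finally
#'   used), `panel_size_used`, `status` (`"matched"`, `"no_sire_match"`,
#'   `"ambiguous_resolved_by_extension"`).
#' @export
assignSire <- function(calfId, candidates, panel, basePanelSize = 100,
                       extensionSize = 20, maxMismatches = 1) {
  if (length(candidates) == 0) stop("empty candidate list")
  g <- genotypeCalls(panel)
  candidates <- sort(unique(as.character(candidates)))
  stopifnot(calfId %in% colnames(g), all(candidates %in% colnames(g)))
  nb <- min(basePanelSize, nrow(g))
  base <- seq_len(nb)
  ohb <- vapply(candidates, function(s)
    countOpposingHomozygotes(g[base, calfId], g[base, s]), integer(1))
  compatible <- candidates[ohb <= maxMismatches]
  res <- list(calf_id = calfId, assigned_sire_id = NA_character_,
              n_candidates = length(candidates),
              opposing_homozygote_counts = ohb,
              panel_size_used = nb, status = "no_sire_match")
  if (length(compatible) == 1) {
    res$assigned_sire_id <- compatible
    res$status <- "matched"
  } else if (length(compatible) > 1) {
    ext <- seq_len(min(nb + extensionSize, nrow(g)))
    ohe <- vapply(candidates, function(s)
      countOpposingHomozygotes(g[ext, calfId], g[ext, s]), integer(1))
    res$opposing_homozygote_counts <- ohe
    res$panel_size_used <- length(ext)
    surv <- candidates[candidates %in% compatible &
                         ohe[candidates] <= maxMismatches]
    if (length(surv) >= 1) {
      best <- surv[ohe[surv] == min(ohe[surv])]
      if (length(best) == 1) {
        res$assigned_sire_id <- best
        res$status <- "ambiguous_resolved_by_extension"
      }
    }
  }
  class(res) <- "ParentageResult"
  res
}

#' @export
print.ParentageResult <- function(x, ...) {
  cat(sprintf("ParentageResult: calf %s -> %s (%s; %d candidates, %d loci)\n",
              x$calf_id,
              ifelse(is.na(x$assigned_sire_id), "none", x$assigned_sire_id),
              x$status, x$n_candidates, x$panel_size_used))
  invisible(x)
}

#' Assign sires for every calf in a herd book
#'
#' For each calf whose dam's breeding group-year has a service roster and
#' that is genotyped, runs [assignSire()] against that group-year's
#' candidate sires.
#'
#' @param herd a [HerdBook-class] with a service roster.
#' @param panel a [GenotypePanel-class].
#' @param ... passed to [assignSire()] (`basePanelSize`, `extensionSize`,
#'   `maxMismatches`).
#' @return data.frame with one row per tested calf: `calf_id`, `group`,
#'   `year`, `assigned_sire_id`, `n_candidates`, `min_oh`,
#'   `panel_size_used`, `status`.
#' @examples
#' sim <- simulateHerd(simParams(nYears = 1, seed = 5))
#' pr <- assignParentage(sim$herd, sim$genotypes)
#' verificationSummary(pr)
#' @export
assignParentage <- function(herd, panel, ...) {
  a <- herdAnimals(herd)
  sv <- sireServices(herd)
  g <- genotypeCalls(panel)
  calves <- a[!is.na(a$dam_id) & !is.na(a$group) & !is.na(a$year) &
                a$id %in% colnames(g), , drop = FALSE]
  out <- vector("list", nrow(calves))
  for (i in seq_len(nrow(calves))) {
    cand <- sv$sire_id[sv$group == calves$group[i] &
                         sv$year == calves$year[i]]
    cand <- cand[cand %in% colnames(g)]
    if (length(cand) == 0) next
    r <- assignSire(calves$id[i], cand, panel, ...)
    out[[i]] <- data.frame(
      calf_id = r$calf_id, group = calves$group[i], year = calves$year[i],
      assigned_sire_id = r$assigned_sire_id,
      n_candidates = r$n_candidates,
      min_oh = min(r$opposing_homozygote_counts),
      panel_size_used = r$panel_size_used, status = r$status,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(calf_id = character(0), group = integer(0),
                      year = integer(0), assigned_sire_id = character(0),
                      n_candidates = integer(0), min_oh = integer(0),
                      panel_size_used = integer(0), status = character(0))
  }
  rownames(res) <- NULL
  res
}

#' Summarize verification outcomes
#'
#' @param results data.frame from [assignParentage()] (or anything with a
#'   `status` column).
#' @return list `tested`, `matched`, `unmatched`; matched + unmatched =
#'   tested. Extension-resolved calves count as matched.
#' @examples
#' verificationSummary(data.frame(status = c("matched", "no_sire_match")))
#' @export
verificationSummary <- function(results) {
  matched <- sum(results$status %in%
                   c("matched", "ambiguous_resolved_by_extension"))
  list(tested = nrow(results), matched = matched,
       unmatched = nrow(results) - matched)
}

#' Fill assigned sires into a herd book
#'
#' @param herd a [HerdBook-class].
#' @param results data.frame from [assignParentage()].
#' @return the herd with `assigned_sire_id` set for matched calves.
#' @export
applyParentage <- function(herd, results) {
  a <- herdAnimals(herd)
  idx <- match(results$calf_id, a$id)
  a$assigned_sire_id[idx] <- results$assigned_sire_id
  herd@animals <- a
  validObject(herd)
  herd
}
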