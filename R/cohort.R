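## Retained-daughter cohort accounting.
##
## Tracks each sire stratum's DNA-attributed daughters from a birth-year
## cohort through several calving seasons: retention, calves born per
## year, percent of retained daughters still calving in the final year,
## total grand calves weaned, grand calves per sire, and weaned kg per
## sire. Daughters are attributed to sires by verified parentage, never by
## herd-book sire fields.

#' Percent of retained daughters remaining
#'
#' `100 * lastYearCalvers / retained`: the share of a retained cohort
#' still producing (calving) in the final tabulated year.
#'
#' @param lastYearCalvers daughters that calved in the final year.
#' @param retained daughters originally retained.
#' @return percent (full precision).
#' @examples
#' round(pctRemaining(29, 74), 1)  # 39.2
#' @export
pctRemaining <- function(lastYearCalvers, retained) {
  if (retained == 0) return(NA_real_)
  100 * lastYearCalvers / retained
}

## table-style commercial rounding: half away from zero, not half to even
.roundHalfUp <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Weaned kg of grand calves per sire
#'
#' Average weaning weight per grand calf multiplied by the average number
#' of grand calves per sire. With `roundedAverage = TRUE` (default) the
#' grand-calf average is first rounded to one decimal, reproducing
#' standard cohort-table accounting (e.g. 196.63 kg x 6.8 = 1337.08 kg);
#' set it to `FALSE` for the full-precision product.
#'
#' @param avgWwPerCalf mean weaning weight of the stratum's grand calves
#'   (kg).
#' @param totalCalvesWeaned grand calves weaned.
#' @param nSires sires in the stratum.
#' @param roundedAverage use the one-decimal-rounded grand-calf average.
#' @return kg.
#' @export
totalKgWeanedPerSire <- function(avgWwPerCalf, totalCalvesWeaned, nSires,
                                 roundedAverage = TRUE) {
  avg <- totalCalvesWeaned / nSires
  if (roundedAverage) avg <- .roundHalfUp(avg, 1)
  avgWwPerCalf * avg
}

#' First-calving wean rate
#'
#' Percent of a retained heifer cohort that weaned a calf at first
#' calving, rounded to a whole percent.
#'
#' @param firstYearCalves calves produced in the cohort's first calving
#'   year.
#' @param retained heifers retained.
#' @return integer percent, `NA` (flagged by warning) when nothing was
#'   retained.
#' @examples
#' firstCalvingWeanRate(54, 74)  # 73
#' firstCalvingWeanRate(68, 86)  # 79
#' @export
firstCalvingWeanRate <- function(firstYearCalves, retained) {
  if (retained == 0) {
    warning("wean rate undefined: no retained heifers")
    return(NA_real_)
  }
  round(100 * firstYearCalves / retained)
}

#' Build the retained-daughter cohort table
#'
#' For each heifer birth-year cohort: ranks the sires that produced those
#' heifers into BPI strata ([stratifySires()], on their BPI in the
#' cohort's breeding year), then accounts per stratum for daughters sired
#' and retained, their calves born per calendar year over the follow-up
#' window, percent remaining (calvers in the final year over retained),
#' total grand calves weaned, grand calves per sire, average weaning
#' weight per weaned grand calf, and weaned kg per sire. A `Total` row per
#' cohort sums the count columns.
#'
#' @param herd a [HerdBook-class] with `assigned_sire_id` and `retained`
#'   filled (see [applyParentage()], [simulateRetention()]).
#' @param bpiRecords data.frame from [bpiTable()].
#' @param heiferYears breeding years whose heifer crops to follow.
#' @param nFollowYears calendar years of calf production tabulated per
#'   cohort, starting 2 years after the cohort's birth (default 4).
#' @param roundedAverage see [totalKgWeanedPerSire()].
#' @return data.frame with one row per (cohort, stratum) plus `Total`
#'   rows: `heifer_year`, `stratum`, `avg_bpi`, `n_sires`,
#'   `n_daughters_sired`, `n_daughters_retained`, `calves_<year>` columns,
#'   `pct_remaining`, `total_calves_weaned`, `avg_grandcalves_per_sire`,
#'   `avg_ww_per_calf`, `total_kg_weaned_per_sire`.
#' @export
buildCohortTable <- function(herd, bpiRecords, heiferYears,
                             nFollowYears = 4, roundedAverage = TRUE) {
  a <- herdAnimals(herd)
  a$birth_cal_year <- as.integer(format(a$birth_date, "%Y"))
  ## one shared follow-up window across cohorts, anchored at the earliest
  ## cohort's first possible calving year
  years <- seq(min(heiferYears) + 3L, length.out = nFollowYears)
  out <- NULL
  for (hy in heiferYears) {
    heifers <- a[!is.na(a$year) & a$year == hy & a$sex == "F" &
                   !is.na(a$assigned_sire_id), , drop = FALSE]
    if (nrow(heifers) == 0) next
    sires <- sort(unique(heifers$assigned_sire_id))
    b <- bpiRecords[bpiRecords$year == hy &
                      bpiRecords$sire_id %in% sires, , drop = FALSE]
    sire_bpi <- tapply(b$bpi, b$sire_id, mean)
    sire_bpi <- sire_bpi[!is.na(sire_bpi)]
    strata <- stratifySires(names(sire_bpi), as.numeric(sire_bpi))
    cohort_rows <- NULL
    for (lv in levels(strata$stratum)) {
      ss <- strata$sire_id[strata$stratum == lv]
      dtr <- heifers[heifers$assigned_sire_id %in% ss, , drop = FALSE]
      ret <- dtr[!is.na(dtr$retained) & dtr$retained, , drop = FALSE]
      grand <- a[!is.na(a$dam_id) & a$dam_id %in% ret$id &
                   a$birth_cal_year %in% years, , drop = FALSE]
      by_year <- vapply(years, function(yy)
        sum(grand$birth_cal_year == yy), integer(1))
      last_calvers <- length(unique(
        grand$dam_id[grand$birth_cal_year == years[length(years)]]))
      weaned <- grand[!is.na(grand$weaning_weight), , drop = FALSE]
      n_s <- length(ss)
      avg_ww <- if (nrow(weaned) > 0) mean(weaned$weaning_weight) else 0
      row <- data.frame(
        heifer_year = hy, stratum = lv,
        avg_bpi = if (n_s > 0) mean(sire_bpi[ss]) else NA_real_,
        n_sires = n_s, n_daughters_sired = nrow(dtr),
        n_daughters_retained = nrow(ret), stringsAsFactors = FALSE)
      for (j in seq_along(years)) {
        row[[sprintf("calves_%d", years[j])]] <- by_year[j]
      }
      row$pct_remaining <- if (nrow(ret) > 0)
        pctRemaining(last_calvers, nrow(ret)) else NA_real_
      row$total_calves_weaned <- nrow(weaned)
      row$avg_grandcalves_per_sire <- if (n_s > 0)
        .roundHalfUp(nrow(weaned) / n_s, 1) else NA_real_
      row$avg_ww_per_calf <- avg_ww
      row$total_kg_weaned_per_sire <- if (n_s > 0)
        totalKgWeanedPerSire(avg_ww, nrow(weaned), n_s, roundedAverage)
        else NA_real_
      cohort_rows <- rbind(cohort_rows, row)
    }
    tot <- cohort_rows[1, , drop = FALSE]
    tot$stratum <- "Total"
    tot$avg_bpi <- NA_real_
    for (cl in c("n_sires", "n_daughters_sired", "n_daughters_retained",
                 grep("^calves_", names(cohort_rows), value = TRUE),
                 "total_calves_weaned")) {
      tot[[cl]] <- sum(cohort_rows[[cl]])
    }
    ret_all <- tot$n_daughters_retained
    grand_all <- a[!is.na(a$dam_id) &
                     a$dam_id %in% heifers$id[!is.na(heifers$retained) &
                                                heifers$retained] &
                     a$birth_cal_year == years[length(years)], ,
                   drop = FALSE]
    tot$pct_remaining <- if (ret_all > 0)
      pctRemaining(length(unique(grand_all$dam_id)), ret_all) else NA_real_
    tot$avg_grandcalves_per_sire <- NA_real_
    tot$avg_ww_per_calf <- NA_real_
    tot$total_kg_weaned_per_sire <- NA_real_
    out <- rbind(out, cohort_rows, tot)
  }
  rownames(out) <- NULL
  out
}

#' Per-stratum linkage between first-cycle daughters and grand calves
#'
#' For each sire: the percentage of his daughters born in the first
#' 21-day cycle and the percentage of his grand calves born in the first
#' cycle; per stratum, the ordinary least-squares R-squared of grandcalf
#' percentage on daughter percentage. High-BPI sires showing a strong
#' linkage means first-cycle calving propagates across generations.
#'
#' @param perSire data.frame with `sire_id`, `stratum`,
#'   `pct_daughters_c1`, `pct_grandcalves_c1`.
#' @return data.frame `stratum`, `n_sires`, `r_squared` (`NA`, flagged,
#'   below 3 sires).
#' @export
firstCycleLinkage <- function(perSire) {
  out <- NULL
  for (lv in unique(perSire$stratum)) {
    sub <- perSire[perSire$stratum == lv, , drop = FALSE]
    sub <- sub[complete.cases(sub[, c("pct_daughters_c1",
                                      "pct_grandcalves_c1")]), ,
               drop = FALSE]
    r2 <- NA_real_
    if (nrow(sub) >= 3) {
      if (sd(sub$pct_grandcalves_c1) == 0) {
        r2 <- 0            # flat response: nothing to explain
      } else if (sd(sub$pct_daughters_c1) == 0) {
        r2 <- NA_real_     # degenerate predictor
      } else {
        fit <- lm(pct_grandcalves_c1 ~ pct_daughters_c1, data = sub)
        r2 <- suppressWarnings(summary(fit))$r.squared
      }
    }
    out <- rbind(out, data.frame(stratum = lv, n_sires = nrow(sub),
                                 r_squared = r2))
  }
  out
}

#' Per-sire first-cycle shares of daughters and grand calves
#'
#' Companion to [firstCycleLinkage()]: computes, for the sires of given
#' heifer cohorts, the percent of their daughters born in cycle 1 and the
#' percent of their retained daughters' calves born in cycle 1.
#'
#' @param herd a [HerdBook-class] with assigned sires and retention flags.
#' @param cycles data.frame from [assignCycles()].
#' @param heiferYears breeding years of the daughter cohorts.
#' @return data.frame `sire_id`, `n_daughters`, `pct_daughters_c1`,
#'   `n_grandcalves`, `pct_grandcalves_c1`.
#' @export
firstCycleShares <- function(herd, cycles, heiferYears) {
  a <- herdAnimals(herd)
  cyc <- setNames(cycles$cycle, cycles$calf_id)
  heifers <- a[!is.na(a$year) & a$year %in% heiferYears & a$sex == "F" &
                 !is.na(a$assigned_sire_id), , drop = FALSE]
  out <- NULL
  for (s in sort(unique(heifers$assigned_sire_id))) {
    d <- heifers[heifers$assigned_sire_id == s, , drop = FALSE]
    dc <- cyc[d$id]
    ret <- d$id[!is.na(d$retained) & d$retained]
    gc <- a[!is.na(a$dam_id) & a$dam_id %in% ret, , drop = FALSE]
    gcc <- cyc[gc$id]
    out <- rbind(out, data.frame(
      sire_id = s, n_daughters = nrow(d),
      pct_daughters_c1 = 100 * mean(dc == 1, na.rm = TRUE),
      n_grandcalves = nrow(gc),
      pct_grandcalves_c1 = if (nrow(gc) > 0)
        100 * mean(gcc == 1, na.rm = TRUE) else NA_real_))
  }
  out
}
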