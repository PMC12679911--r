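## 21-day calving-cycle bookkeeping.
##
## Following standardized performance analysis practice, the first 21-day
## calving period starts when the 3rd mature cow (3 years old and older)
## of the season calves. Calves are then binned into half-open 21-day
## windows; a calf born exactly 21 days after the start belongs to cycle 2.

#' Season start date by the rank-k mature-cow rule
#'
#' The date of the `rank`-th calving (chronological order, same-day ties
#' ordered by calf id) by a dam aged at least `matureAge` whole years at
#' calving.
#'
#' @param calvings data.frame with `calf_id`, `birth_date` (`Date`),
#'   `dam_age` (years).
#' @param matureAge minimum mature dam age (default 3).
#' @param rank which mature-cow calving starts the season (default 3).
#' @return a `Date`.
#' @examples
#' cv <- data.frame(calf_id = c("a", "b", "c"),
#'                  birth_date = as.Date("2015-04-01") + 0:2,
#'                  dam_age = c(5, 4, 6))
#' seasonStart(cv)  # day 3
#' @export
seasonStart <- function(calvings, matureAge = 3, rank = 3) {
  m <- calvings[calvings$dam_age >= matureAge, , drop = FALSE]
  if (nrow(m) < rank) {
    stop(sprintf(
      "season start undefined: %d mature-cow calvings, need %d",
      nrow(m), rank))
  }
  m <- m[order(m$birth_date, m$calf_id), , drop = FALSE]
  m$birth_date[rank]
}

#' Season start per breeding group-year
#'
#' Applies [seasonStart()] within each group-year of the herd book. Dam
#' age at calving is in whole calendar years (calving year minus dam birth
#' year). Group-years with too few mature-cow calvings (the
#' replacement-heifer group has none by construction) fall back to the
#' herd-wide start of that calving year, flagged; with
#' `scope = "herd"` a single start per calving year is used throughout.
#'
#' @param herd a [HerdBook-class].
#' @param config a [RunConfig-class] (mature age, rank).
#' @param scope `"group"` (default) or `"herd"`.
#' @return data.frame `group`, `year`, `season_start`, `fallback`
#'   (logical: herd-wide start used).
#' @export
seasonStartTable <- function(herd, config = runConfig(),
                             scope = c("group", "herd")) {
  scope <- match.arg(scope)
  a <- herdAnimals(herd)
  calves <- a[!is.na(a$dam_id) & !is.na(a$year), , drop = FALSE]
  dam_by <- as.integer(format(
    a$birth_date[match(calves$dam_id, a$id)], "%Y"))
  calvings <- data.frame(
    calf_id = calves$id, birth_date = calves$birth_date,
    dam_age = as.integer(format(calves$birth_date, "%Y")) - dam_by,
    group = calves$group, year = calves$year)
  gy <- unique(calvings[, c("group", "year")])
  gy <- gy[order(gy$year, gy$group), , drop = FALSE]
  herd_start <- function(yr) {
    seasonStart(calvings[calvings$year == yr, , drop = FALSE],
                config@matureAgeYears, config@firstCycleStartRank)
  }
  out <- NULL
  for (i in seq_len(nrow(gy))) {
    sub <- calvings[calvings$group == gy$group[i] &
                      calvings$year == gy$year[i], , drop = FALSE]
    fallback <- FALSE
    st <- if (scope == "herd") {
      fallback <- TRUE
      herd_start(gy$year[i])
    } else {
      tryCatch(seasonStart(sub, config@matureAgeYears,
                           config@firstCycleStartRank),
               error = function(e) {
                 fallback <<- TRUE
                 herd_start(gy$year[i])
               })
    }
    out <- rbind(out, data.frame(group = gy$group[i], year = gy$year[i],
                                 season_start = st, fallback = fallback))
  }
  out
}

#' Assign calves to 21-day calving cycles
#'
#' Half-open bins: cycle `1 + floor((birth - start) / cycleLength)` for
#' births on or after the season start. Births before the start (possible
#' for early heifer calvings under the rank-3 rule) clamp to cycle 1 and
#' are flagged.
#'
#' @param herd a [HerdBook-class].
#' @param starts data.frame from [seasonStartTable()] (`group`, `year`,
#'   `season_start`).
#' @param cycleLength days per cycle (default 21).
#' @return data.frame `calf_id`, `group`, `year`, `season_start`, `cycle`,
#'   `clamped`.
#' @examples
#' sim <- simulateHerd(simParams(nYears = 1, seed = 2))
#' st <- seasonStartTable(sim$herd)
#' cyc <- assignCycles(sim$herd, st)
#' table(cyc$cycle)
#' @export
assignCycles <- function(herd, starts, cycleLength = 21) {
  a <- herdAnimals(herd)
  calves <- a[!is.na(a$dam_id) & !is.na(a$year), , drop = FALSE]
  key <- paste(calves$group, calves$year)
  skey <- paste(starts$group, starts$year)
  st <- starts$season_start[match(key, skey)]
  keep <- !is.na(st)
  calves <- calves[keep, , drop = FALSE]
  st <- st[keep]
  off <- as.integer(calves$birth_date - st)
  cyc <- 1L + floor(off / cycleLength)
  clamped <- off < 0
  cyc[clamped] <- 1L
  data.frame(calf_id = calves$id, group = calves$group,
             year = calves$year, season_start = st, cycle = as.integer(cyc),
             clamped = clamped)
}

#' Calving-cycle distribution per group-year
#'
#' Percentage of calves in each cycle per group-year (summing to 100
#' within a group-year) and a flag for whether the first-cycle share meets
#' the benchmark (60% of the calf crop in the first 21 days is the
#' commonly recommended target).
#'
#' @param assignments data.frame from [assignCycles()].
#' @param benchmark first-cycle share target (default 0.60).
#' @return list with `distribution` (data.frame `group`, `year`, `cycle`,
#'   `n`, `pct`) and `benchmarkFlags` (data.frame `group`, `year`,
#'   `first_cycle_pct`, `meets_benchmark`).
#' @export
cycleDistribution <- function(assignments, benchmark = 0.60) {
  if (nrow(assignments) == 0) {
    warning("no cycle assignments")
    return(list(distribution = NULL, benchmarkFlags = NULL))
  }
  tab <- aggregate(list(n = assignments$calf_id),
                   by = list(group = assignments$group,
                             year = assignments$year,
                             cycle = assignments$cycle),
                   FUN = length)
  tot <- aggregate(list(total = tab$n),
                   by = list(group = tab$group, year = tab$year), FUN = sum)
  tab <- merge(tab, tot)
  tab$pct <- 100 * tab$n / tab$total
  tab <- tab[order(tab$year, tab$group, tab$cycle),
             c("group", "year", "cycle", "n", "pct")]
  rownames(tab) <- NULL
  f1 <- tab[tab$cycle == 1, , drop = FALSE]
  flags <- merge(tot[, c("group", "year")],
                 f1[, c("group", "year", "pct")], all.x = TRUE)
  flags$pct[is.na(flags$pct)] <- 0
  names(flags)[names(flags) == "pct"] <- "first_cycle_pct"
  flags$meets_benchmark <- flags$first_cycle_pct >= 100 * benchmark
  flags <- flags[order(flags$year, flags$group), , drop = FALSE]
  rownames(flags) <- NULL
  list(distribution = tab, benchmarkFlags = flags)
}
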