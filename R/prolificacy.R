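## Bull Prolificacy Index (BPI).
##
## BPI = n / (N / m): the number of calves DNA-attributed to a sire,
## divided by the equal-share expectation given N total matched calves and
## m sires in the breeding pasture. BPI 1.0 means the sire met his expected
## contribution; within a group-year BPI sums to m exactly. Only calves
## with a verified sire enter n and N.

#' Bull Prolificacy Index
#'
#' @param n calves attributed to the sire (matched only).
#' @param N total matched calves in the breeding group-year.
#' @param m sires in the breeding group-year.
#' @return `n * m / N` at full precision; rounding is a display concern.
#' @examples
#' bpi(10, 126, 5)   # prints as 0.4
#' bpi(49, 113, 8)   # the study-range maximum, prints as 3.47
#' @export
bpi <- function(n, N, m) {
  if (any(N == 0) || any(m == 0)) {
    stop("BPI undefined: N and m must be positive")
  }
  stopifnot(all(n >= 0), all(n <= N))
  n * m / N
}

#' First-21-day Bull Prolificacy Index
#'
#' The BPI formula with n and N replaced by first-cycle counts; m (sires
#' in the pasture) is unchanged.
#'
#' @param nFirst sire's matched calves born in the first cycle.
#' @param NFirst all matched first-cycle calves in the group-year.
#' @param m sires in the group-year.
#' @return ratio, or `NA` with a warning when the group-year had no
#'   first-cycle calves (undefined, flagged rather than silently zero).
#' @export
bpiFirstCycle <- function(nFirst, NFirst, m) {
  if (NFirst == 0) {
    warning("first-cycle BPI undefined: no first-cycle calves")
    return(NA_real_)
  }
  bpi(nFirst, NFirst, m)
}

#' Per-sire, per-group-year BPI table
#'
#' One record per sire x group-year served, with overall and first-cycle
#' BPI. N counts only sire-verified calves; unmatched calves are excluded
#' from both n and N. m is the number of sires on the group-year's service
#' roster; a matched sire absent from the roster (a mid-season
#' replacement) is added to that group-year's sire count with a warning.
#'
#' @param parentage data.frame from [assignParentage()] (or any frame with
#'   `calf_id`, `group`, `year`, `assigned_sire_id`, `status`).
#' @param herd a [HerdBook-class] (service roster; sire birth dates for
#'   ages).
#' @param cycles optional data.frame from [assignCycles()]; first-cycle
#'   columns are `NA` when omitted.
#' @return data.frame: `sire_id`, `group`, `year`, `n`, `N`, `m`, `bpi`,
#'   `n_first`, `N_first`, `bpi_first`, `sire_age`.
#' @examples
#' sim <- simulateHerd(simParams(nYears = 1, seed = 5))
#' pr <- assignParentage(sim$herd, sim$genotypes)
#' bt <- bpiTable(pr, sim$herd)
#' aggregate(bpi ~ group, bt, sum)  # equals m per group
#' @export
bpiTable <- function(parentage, herd, cycles = NULL) {
  sv <- sireServices(herd)
  a <- herdAnimals(herd)
  matched <- parentage[!is.na(parentage$assigned_sire_id), , drop = FALSE]
  if (!is.null(cycles)) {
    matched$cycle <- cycles$cycle[match(matched$calf_id, cycles$calf_id)]
  } else {
    matched$cycle <- NA_integer_
  }
  gys <- unique(rbind(sv[, c("group", "year")],
                      matched[, c("group", "year")]))
  gys <- gys[order(gys$year, gys$group), , drop = FALSE]
  out <- NULL
  for (i in seq_len(nrow(gys))) {
    g <- gys$group[i]; y <- gys$year[i]
    roster <- sv$sire_id[sv$group == g & sv$year == y]
    mg <- matched[matched$group == g & matched$year == y, , drop = FALSE]
    extra <- setdiff(unique(mg$assigned_sire_id), roster)
    if (length(extra) > 0) {
      warning(sprintf(
        "group %s year %s: matched sire(s) %s not on the service roster; added",
        g, y, paste(extra, collapse = ", ")))
      roster <- c(roster, extra)
    }
    N <- nrow(mg)
    m <- length(roster)
    if (m == 0) next
    Nf <- sum(mg$cycle == 1, na.rm = TRUE)
    has_cycles <- !is.null(cycles)
    for (s in sort(roster)) {
      n <- sum(mg$assigned_sire_id == s)
      nf <- sum(mg$assigned_sire_id == s & mg$cycle == 1, na.rm = TRUE)
      sire_by <- as.integer(format(a$birth_date[match(s, a$id)], "%Y"))
      out <- rbind(out, data.frame(
        sire_id = s, group = g, year = y, n = n, N = N, m = m,
        bpi = if (N > 0) bpi(n, N, m) else NA_real_,
        n_first = if (has_cycles) nf else NA_integer_,
        N_first = if (has_cycles) Nf else NA_integer_,
        bpi_first = if (has_cycles && Nf > 0) bpi(nf, Nf, m) else NA_real_,
        sire_age = y - sire_by, stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

#' Stratify sires into bottom 25% / average 50% / top 25% by BPI
#'
#' Rank-based: sires are sorted by BPI (ties broken by sire id) and split
#' into the bottom quartile, middle half and top quartile by rank, the
#' quartile size being `round(n / 4)`. The published 0.4 / 1.4 cutoffs are
#' empirical descriptors of those quartiles, not classification rules.
#' Fewer than 4 sires yields a single stratum with a warning.
#'
#' @param sireIds character sire ids.
#' @param bpiValues matching BPI values (one per sire; average a sire's
#'   records first if he has several).
#' @return data.frame `sire_id`, `bpi`, `stratum` (factor `Bottom25`,
#'   `Average50`, `Top25`); attribute `summary` holds per-stratum size and
#'   average BPI.
#' @examples
#' s <- stratifySires(paste0("S", 1:8), c(0.1, 0.3, 0.8, 0.9, 1, 1.1, 1.6, 2))
#' attr(s, "summary")
#' @export
stratifySires <- function(sireIds, bpiValues) {
  stopifnot(length(sireIds) == length(bpiValues),
            !anyDuplicated(sireIds))
  n <- length(sireIds)
  o <- order(bpiValues, sireIds)
  if (n < 4) {
    warning("fewer than 4 sires: single stratum")
    stratum <- factor(rep("Average50", n),
                      levels = c("Bottom25", "Average50", "Top25"))
  } else {
    nq <- round(n / 4)
    lab <- rep("Average50", n)
    lab[seq_len(nq)] <- "Bottom25"
    lab[seq(n - nq + 1, n)] <- "Top25"
    stratum <- factor(character(n),
                      levels = c("Bottom25", "Average50", "Top25"))
    stratum[o] <- lab
  }
  out <- data.frame(sire_id = sireIds, bpi = bpiValues, stratum = stratum,
                    stringsAsFactors = FALSE)
  smry <- aggregate(bpi ~ stratum, data = out, FUN = mean, drop = FALSE)
  names(smry)[2] <- "avg_bpi"
  smry$n_sires <- as.integer(table(out$stratum))
  attr(out, "summary") <- smry
  out
}

#' Across-year repeatability of sire BPI
#'
#' Spearman rank correlation between a sire's BPI in his first year of use
#' and each later use-year (use-year = ordinal year of service, not
#' calendar year), with a permutation p-value. A sire with several records
#' in one year (serving two groups) contributes his mean BPI for that
#' year.
#'
#' @param records data.frame from [bpiTable()].
#' @param nPerm permutations for the p-value (default 1999; uses the
#'   current RNG stream).
#' @return data.frame `use_year_pair`, `n_sires`, `rho`, `p_value`;
#'   pairs with fewer than 3 sires are reported with `NA` rho (flagged).
#' @export
bpiRepeatability <- function(records, nPerm = 1999) {
  peryear <- aggregate(bpi ~ sire_id + year, data = records, FUN = mean)
  peryear <- peryear[order(peryear$sire_id, peryear$year), , drop = FALSE]
  peryear$use_year <- stats::ave(peryear$year, peryear$sire_id,
                                 FUN = seq_along)
  maxu <- max(peryear$use_year)
  out <- NULL
  for (k in seq(2, max(2, maxu))) {
    a <- peryear[peryear$use_year == 1, c("sire_id", "bpi")]
    b <- peryear[peryear$use_year == k, c("sire_id", "bpi")]
    mrg <- merge(a, b, by = "sire_id")
    ns <- nrow(mrg)
    if (ns < 3) {
      out <- rbind(out, data.frame(use_year_pair = sprintf("1-%d", k),
                                   n_sires = ns, rho = NA_real_,
                                   p_value = NA_real_))
      next
    }
    rho <- cor(mrg$bpi.x, mrg$bpi.y, method = "spearman")
    perm <- replicate(nPerm,
      cor(mrg$bpi.x, sample(mrg$bpi.y), method = "spearman"))
    p <- (1 + sum(abs(perm) >= abs(rho) - 1e-12)) / (nPerm + 1)
    out <- rbind(out, data.frame(use_year_pair = sprintf("1-%d", k),
                                 n_sires = ns, rho = rho, p_value = p))
  }
  out
}

#' BPI descriptive statistics by sire age class
#'
#' Mean, SD, median and count of BPI per sire age class: yearlings,
#' 2-year-olds, and mature bulls (3 years and older). Descriptive only --
#' no inferential model is fitted.
#'
#' @param records data.frame from [bpiTable()] with `sire_age`.
#' @return data.frame `age_class`, `n`, `mean_bpi`, `sd_bpi`,
#'   `median_bpi`.
#' @export
sireAgeSummary <- function(records) {
  r <- records[!is.na(records$sire_age) & !is.na(records$bpi), ,
               drop = FALSE]
  cls <- cut(r$sire_age, breaks = c(-Inf, 1, 2, Inf),
             labels = c("1", "2", ">=3"))
  out <- data.frame(age_class = levels(cls))
  out$n <- as.integer(table(cls))
  out$mean_bpi <- as.numeric(tapply(r$bpi, cls, mean))
  out$sd_bpi <- as.numeric(tapply(r$bpi, cls,
                                  function(x) if (length(x) > 1) sd(x) else 0))
  out$median_bpi <- as.numeric(tapply(r$bpi, cls, median))
  out
}
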