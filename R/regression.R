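## Per-10%-vigor-score trait regressions.
##
## Simple linear regressions of fertility and production traits on vigor
## score, reported per +10 percentage points of vigor score and compared
## with the published benchmark constants (+1.33 kg weaning weight, -2 d
## age at first calving, +2 points conception rate, +35.7 kg lifetime
## productivity per +10% VS). Conception is fitted as a linear probability
## model to match the linear framing; no multiple-testing correction is
## applied across the four traits (raw p-values are reported).

#' Linear trait slope per +10% vigor score
#'
#' Ordinary least-squares slope of `trait` on vigor score, scaled to a
#' +0.10 change in VS, with standard error and a two-sided t-test
#' p-value. Vigor scores supplied in percent (detected when values exceed
#' 1.5) are normalized to fractions first, so percent and fraction inputs
#' give identical slopes. With `binned = TRUE` the regression is fitted on
#' the per-0.10-VS-bin trait means instead of animal-level records.
#'
#' @param vs vigor scores (fractions, or percents which are rescaled).
#' @param trait trait values (for conception, 0/1 outcomes or per-bin
#'   proportions).
#' @param traitName label carried into the output.
#' @param binned fit on 0.10-wide bin means.
#' @return one-row data.frame of class `SlopeEstimate`: `trait`,
#'   `slope_per_10pct`, `std_error`, `p_value`, `n`.
#' @examples
#' vs <- seq(0.3, 0.9, length.out = 20)
#' slopePer10pct(vs, 100 + 17.4 * vs)  # exact line: slope 1.74, SE 0
#' @export
slopePer10pct <- function(vs, trait, traitName = "trait", binned = FALSE) {
  stopifnot(length(vs) == length(trait))
  keep <- complete.cases(vs, trait)
  vs <- vs[keep]; trait <- trait[keep]
  if (length(vs) < 3) stop("need at least 3 observations")
  if (max(vs) > 1.5) vs <- vs / 100
  if (sd(vs) == 0) stop("zero vigor-score variance: slope undefined")
  if (binned) {
    b <- binByVigor(vs)
    agg <- aggregate(trait, by = list(bin = b$vs_bin), FUN = mean)
    mid <- aggregate(vs, by = list(bin = b$vs_bin), FUN = mean)
    vs <- mid$x; trait <- agg$x
    if (length(vs) < 3) stop("need at least 3 occupied bins")
  }
  fit <- lm(trait ~ vs)
  ## summary.lm warns on noiseless fits; the degenerate case is handled below
  sfit <- suppressWarnings(summary(fit))
  sm <- sfit$coefficients
  slope <- sm["vs", "Estimate"]
  se <- sm["vs", "Std. Error"]
  p <- sm["vs", "Pr(>|t|)"]
  if (!is.finite(se) || sfit$sigma < 1e-10) {
    ## noiseless data: lm's t-test is 0/0; report the limits
    se <- 0
    p <- if (abs(slope) < 1e-12) 1 else 0
  }
  if (abs(slope) < 1e-12 && se == 0) p <- 1
  out <- data.frame(trait = traitName, slope_per_10pct = 0.10 * slope,
                    std_error = 0.10 * se, p_value = p,
                    n = length(trait), stringsAsFactors = FALSE)
  class(out) <- c("SlopeEstimate", class(out))
  out
}

#' Compare estimated slopes to published benchmark constants
#'
#' @param estimates data.frame of stacked [slopePer10pct()] rows; `trait`
#'   labels must match the benchmark names.
#' @param benchmarks named numeric, trait units per +10% VS (defaults from
#'   [runConfig()]: `avg_ww_kg` +1.33, `afc_days` -2, `conception_rate`
#'   +0.02, `lifetime_kg` +35.7).
#' @return data.frame `trait`, `slope_per_10pct`, `benchmark`,
#'   `difference` (estimate minus benchmark), `direction_agrees` (sign
#'   match; a zero estimate never agrees with a nonzero benchmark).
#'   Traits without a benchmark are dropped with a warning.
#' @examples
#' est <- data.frame(trait = "afc_days", slope_per_10pct = -0.7,
#'                   std_error = 0.6, p_value = 0.26, n = 100)
#' compareToBenchmarks(est)
#' @export
compareToBenchmarks <- function(estimates,
                                benchmarks = runConfig()@benchmarkSlopes) {
  miss <- setdiff(estimates$trait, names(benchmarks))
  if (length(miss) > 0) {
    warning(sprintf("no benchmark for trait(s): %s; row(s) omitted",
                    paste(miss, collapse = ", ")))
    estimates <- estimates[estimates$trait %in% names(benchmarks), ,
                           drop = FALSE]
  }
  bm <- benchmarks[estimates$trait]
  data.frame(
    trait = estimates$trait,
    slope_per_10pct = estimates$slope_per_10pct,
    benchmark = as.numeric(bm),
    difference = estimates$slope_per_10pct - as.numeric(bm),
    direction_agrees = sign(estimates$slope_per_10pct) == sign(bm) &
      estimates$slope_per_10pct != 0,
    stringsAsFactors = FALSE)
}

#' Sensitivity of the slope to a vigor-score selection cutoff
#'
#' Refits the regression excluding records above the cutoff (75% is the
#' suggested economically sufficient vigor score) and reports both fits
#' and their difference: a plateau above the cutoff shows up as a
#' truncated slope exceeding the full-data slope.
#'
#' @param vs,trait as in [slopePer10pct()].
#' @param cutoff vigor-score cutoff (default 0.75).
#' @param traitName label.
#' @return list `full`, `truncated` (SlopeEstimate rows), `difference`
#'   (truncated minus full slope), `n_above`, `trivial` (TRUE, flagged,
#'   when no record exceeds the cutoff so the fits are identical).
#' @export
vsCutoffSensitivity <- function(vs, trait, cutoff = 0.75,
                                traitName = "trait") {
  if (max(vs) > 1.5) vs <- vs / 100
  full <- slopePer10pct(vs, trait, traitName)
  above <- vs > cutoff
  if (!any(above)) {
    return(list(full = full, truncated = full, difference = 0,
                n_above = 0L, trivial = TRUE))
  }
  if (sum(!above) < 3) stop("too few records at or below the cutoff")
  trunc <- slopePer10pct(vs[!above], trait[!above], traitName)
  list(full = full, truncated = trunc,
       difference = trunc$slope_per_10pct - full$slope_per_10pct,
       n_above = sum(above), trivial = FALSE)
}

#' Fit all four vigor-score trait regressions
#'
#' Convenience wrapper fitting [slopePer10pct()] for age at first calving,
#' average weaning weight per calf, conception and lifetime productivity
#' on a heifer-level table such as [simulateVigorTraits()] output, and
#' comparing them to the benchmarks.
#'
#' @param records data.frame with `vs` and any of `afc_days`,
#'   `avg_ww_kg`, `conception`, `lifetime_kg`.
#' @param benchmarks see [compareToBenchmarks()].
#' @param binned see [slopePer10pct()].
#' @return list `estimates` (stacked SlopeEstimate rows) and `comparison`
#'   (benchmark table).
#' @export
vigorTraitRegressions <- function(records,
                                  benchmarks = runConfig()@benchmarkSlopes,
                                  binned = FALSE) {
  traits <- c(afc_days = "afc_days", avg_ww_kg = "avg_ww_kg",
              conception_rate = "conception", lifetime_kg = "lifetime_kg")
  est <- NULL
  for (nm in names(traits)) {
    col <- traits[[nm]]
    if (!col %in% names(records)) next
    if (sum(complete.cases(records$vs, records[[col]])) < 3) next
    est <- rbind(est, slopePer10pct(records$vs, records[[col]], nm,
                                    binned = binned))
  }
  if (is.null(est)) {
    warning("no trait with at least 3 complete records; nothing fitted")
    return(list(estimates = NULL, comparison = NULL))
  }
  list(estimates = est, comparison = compareToBenchmarks(est, benchmarks))
}
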