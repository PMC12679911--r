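## Genomic vigor score (retained heterozygosity) and breed-composition
## arithmetic.

.checkFractions <- function(p, tol = 1e-6) {
  if (any(p < -tol | p > 1 + tol)) {
    stop("breed fractions must lie in [0, 1]")
  }
  if (abs(sum(p) - 1) > tol) {
    stop(sprintf("breed fractions must sum to 1 (got %.6f)", sum(p)))
  }
}

#' Genomic vigor score (retained heterozygosity)
#'
#' `1 - sum(P_i^2)` over an animal's fractional breed composition: 0 for a
#' purebred, approaching `1 - 1/k` for k equally contributing breeds. A
#' crossbred of 50/25/25% over three breeds scores 0.625 (reported as
#' 62.5%). The score is a proxy for retained heterosis: the probability
#' that the two ancestry draws at a locus come from different founder
#' breeds.
#'
#' By default the indeterminate remainder is treated as one pseudo-breed
#' component inside the sum, which keeps the fractions summing to 1 and
#' matches the accounting in which one minus the named-breed total is the
#' indeterminate proportion. Set `includeIndeterminate = FALSE` to drop it
#' and renormalize over named breeds only.
#'
#' @param x a numeric fraction vector summing to 1, or a
#'   [BreedComposition-class] (one score per animal).
#' @param ... passed to methods.
#' @return numeric in `[0, 1 - 1/k]`.
#' @examples
#' vigorScore(c(0.5, 0.25, 0.25))   # 0.625
#' vigorScore(c(A = 1))             # purebred: 0
#' @export
setGeneric("vigorScore", function(x, ...) standardGeneric("vigorScore"))

#' @rdname vigorScore
#' @param tol tolerance on the sum-to-one check.
#' @export
setMethod("vigorScore", "numeric", function(x, tol = 1e-6) {
  .checkFractions(x, tol)
  1 - sum(x^2)
})

#' @rdname vigorScore
#' @param includeIndeterminate logical; keep the `Indeterminate` column as
#'   a pseudo-breed (default) or drop it and renormalize.
#' @export
setMethod("vigorScore", "BreedComposition",
          function(x, includeIndeterminate = TRUE) {
  f <- breedFractions(x)
  if (!includeIndeterminate && "Indeterminate" %in% colnames(f)) {
    f <- f[, setdiff(colnames(f), "Indeterminate"), drop = FALSE]
    s <- rowSums(f)
    s[s == 0] <- 1  # fully indeterminate animal: score 0 by convention
    f <- f / s
  }
  setNames(1 - rowSums(f^2), rownames(f))
})

#' Back-calculate a dam's breed composition from calf and sire
#'
#' A calf's genomic breed composition is the parental mean, so the dam's is
#' `2 * calf - sire`, component-wise. Because field compositions are
#' estimates, individual components can come out slightly negative; those
#' are clamped to zero and the vector renormalized to sum 1, with the
#' repair flagged. On exact parental-mean trios the inversion is exact and
#' no clamping occurs.
#'
#' @param calf,sire numeric composition vectors over the same breed set
#'   (names, when present, must match).
#' @return numeric composition vector with attribute `clamped` (logical).
#' @examples
#' d <- inferDamComposition(c(A = 0.5, B = 0.5), c(A = 1, B = 0))
#' d                       # pure B
#' attr(d, "clamped")      # FALSE
#' @export
inferDamComposition <- function(calf, sire) {
  if (length(calf) != length(sire)) {
    stop("calf and sire compositions must cover the same breed set")
  }
  if (!is.null(names(calf)) && !is.null(names(sire)) &&
      !identical(names(calf), names(sire))) {
    stop("calf and sire breed sets differ")
  }
  .checkFractions(calf)
  .checkFractions(sire)
  d <- 2 * calf - sire
  clamped <- any(d < -1e-9)
  d[d < 0] <- 0
  if (sum(d) == 0) stop("degenerate inversion: all components clamped")
  d <- d / sum(d)
  attr(d, "clamped") <- clamped
  d
}

#' Infer dam compositions for a set of trios
#'
#' Vectorized wrapper around [inferDamComposition()] for matched calf/sire
#' pairs drawn from a [BreedComposition-class].
#'
#' @param compositions a [BreedComposition-class] containing all calves and
#'   sires.
#' @param calfIds,sireIds equal-length id vectors pairing each calf with
#'   its verified sire.
#' @return list with `composition` (a [BreedComposition-class] of inferred
#'   dams, rownames are calf ids) and `clamped` (named logical).
#' @export
inferDamCompositions <- function(compositions, calfIds, sireIds) {
  stopifnot(length(calfIds) == length(sireIds))
  f <- breedFractions(compositions)
  out <- matrix(NA_real_, nrow = length(calfIds), ncol = ncol(f),
                dimnames = list(calfIds, colnames(f)))
  clamped <- logical(length(calfIds))
  for (i in seq_along(calfIds)) {
    d <- inferDamComposition(f[calfIds[i], ], f[sireIds[i], ])
    clamped[i] <- attr(d, "clamped")
    out[i, ] <- d
  }
  names(clamped) <- calfIds
  list(composition = BreedComposition(out), clamped = clamped)
}

#' Bin animals by vigor score
#'
#' Half-open bins `[a, a + width)` over `[0, 1]`, with the top bin closed
#' so a score of exactly 1 still lands in a bin. A score of 0.70 falls in
#' the 0.70-0.80 bin; 0.6999 falls in 0.60-0.70.
#'
#' @param vs numeric vigor scores in `[0, 1]` (a named vector keeps ids).
#' @param width bin width (default 0.10).
#' @return data.frame with `animal_id`, `vigor_score`, `vs_bin` (factor
#'   with labels like `"0.70-0.80"`); attribute `summary` holds per-bin
#'   counts and mean scores.
#' @examples
#' binByVigor(c(a = 0.70, b = 0.6999))$vs_bin
#' @export
binByVigor <- function(vs, width = 0.10) {
  stopifnot(width > 0)
  nb <- ceiling(1 / width - 1e-9)
  breaks <- round((0:nb) * width, 9)   # exact decimal edges
  breaks[nb + 1] <- max(1, breaks[nb + 1])
  labels <- sprintf("%.2f-%.2f", breaks[-length(breaks)], breaks[-1])
  idx <- findInterval(vs, breaks, rightmost.closed = TRUE)
  bin <- factor(labels[idx], levels = labels)
  out <- data.frame(
    animal_id = if (!is.null(names(vs))) names(vs) else
      as.character(seq_along(vs)),
    vigor_score = as.numeric(vs), vs_bin = bin)
  if (nrow(out) == 0) {
    attr(out, "summary") <- data.frame(vs_bin = factor(labels,
                                                       levels = labels),
                                       vigor_score = NA_real_, n = 0L)
    return(out)
  }
  smry <- aggregate(vigor_score ~ vs_bin, data = out, FUN = mean,
                    drop = FALSE)
  smry$n <- as.integer(table(out$vs_bin))
  attr(out, "summary") <- smry
  out
}
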