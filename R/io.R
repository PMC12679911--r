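## File formats: herd-book CSV, genotype matrix-TSV and PED/MAP,
## breed-composition CSV. CSV is the canonical herd-book format; genotypes
## accept two dialects because parentage labs return different artifacts.

#' Read a herd book from CSV
#'
#' The CSV must carry the documented header (`id`, `sex`, `birth_date`,
#' `dam_id`, `true_sire_id`, `assigned_sire_id`, `group`, `year`,
#' `birth_weight`, `weaning_weight`, `retained`, `disposal_year`); dates
#' are ISO-8601. Rows violating registry invariants (duplicate ids,
#' dangling or chronologically impossible parent references) are rejected
#' with row-indexed messages.
#'
#' @param path herd-book CSV.
#' @param servicesPath optional CSV of the sire service roster
#'   (`sire_id`, `group`, `year`).
#' @return A [HerdBook-class].
#' @export
readHerdBook <- function(path, servicesPath = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("id", "sex", "birth_date"), names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("herd-book format error: missing column(s) %s",
                 paste(missing_cols, collapse = ", ")))
  }
  for (col in names(df)) {       # blank cells are missing values
    if (is.character(df[[col]])) df[[col]][df[[col]] == ""] <- NA
  }
  df$birth_date <- as.Date(df$birth_date)
  if (anyNA(df$birth_date)) {
    stop(sprintf("herd-book format error: unparseable birth_date in row(s) %s",
                 paste(head(which(is.na(df$birth_date)), 5),
                       collapse = ", ")))
  }
  if (!is.null(df$retained)) df$retained <- as.logical(df$retained)
  services <- if (!is.null(servicesPath)) {
    read.csv(servicesPath, stringsAsFactors = FALSE)
  } else {
    data.frame(sire_id = character(0), group = integer(0),
               year = integer(0))
  }
  HerdBook(df, services)
}

#' Write a herd book to CSV
#'
#' @param herd a [HerdBook-class].
#' @param path output CSV for the animal records.
#' @param servicesPath optional output CSV for the service roster.
#' @return `path`, invisibly.
#' @export
writeHerdBook <- function(herd, path, servicesPath = NULL) {
  write.csv(herdAnimals(herd), path, row.names = FALSE, quote = FALSE,
            na = "")
  if (!is.null(servicesPath)) {
    write.csv(sireServices(herd), servicesPath, row.names = FALSE,
              quote = FALSE, na = "")
  }
  invisible(path)
}

.checkGenoCodes <- function(m) {
  bad <- !(m %in% c(0, 1, 2) | is.na(m))
  if (any(bad)) {
    stop(sprintf(
      "genotype format error: value(s) outside 0/1/2/missing (e.g. %s)",
      paste(head(unique(m[bad]), 3), collapse = ", ")))
  }
}

#' Read a genotype panel
#'
#' Two dialects: `"matrix-tsv"` -- a TSV with animals in rows, loci in
#' columns, a leading `animal_id` column, genotypes coded 0/1/2 copies of
#' the alternate allele (blank or NA = missing); `"ped-map"` -- a
#' PLINK-style .ped/.map pair where each locus contributes two allele
#' columns coded `A` (reference) / `B` (alternate), `0 0` = missing. Both
#' dialects yield the same panel for the same data. Animals with every
#' call missing are flagged with a warning.
#'
#' @param path the TSV, or the `.ped` file (the `.map` is expected
#'   alongside).
#' @param dialect `"matrix-tsv"` or `"ped-map"`.
#' @return A [GenotypePanel-class].
#' @export
readGenotypes <- function(path, dialect = c("matrix-tsv", "ped-map")) {
  dialect <- match.arg(dialect)
  if (dialect == "matrix-tsv") {
    df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    if (!"animal_id" %in% names(df)) {
      stop("genotype format error: missing animal_id column")
    }
    ids <- as.character(df$animal_id)
    m <- as.matrix(df[, setdiff(names(df), "animal_id"), drop = FALSE])
    .checkGenoCodes(m)
    rownames(m) <- ids
    GenotypePanel(m, animalsInRows = TRUE)
  } else {
    mapPath <- sub("\\.ped$", ".map", path)
    if (identical(mapPath, path)) mapPath <- paste0(path, ".map")
    map <- read.table(mapPath, stringsAsFactors = FALSE)
    loci <- map[[2]]
    ped <- read.table(path, stringsAsFactors = FALSE,
                      colClasses = "character")
    if (ncol(ped) != 6 + 2 * length(loci)) {
      stop(sprintf(
        "genotype format error: .ped has %d columns, expected %d for %d loci",
        ncol(ped), 6 + 2 * length(loci), length(loci)))
    }
    ids <- ped[[2]]
    al <- as.matrix(ped[, -(1:6), drop = FALSE])
    bad <- !(al %in% c("A", "B", "0"))
    if (any(bad)) {
      stop(sprintf("genotype format error: allele code(s) %s",
                   paste(head(unique(al[bad]), 3), collapse = ", ")))
    }
    a1 <- al[, seq(1, ncol(al), by = 2), drop = FALSE]
    a2 <- al[, seq(2, ncol(al), by = 2), drop = FALSE]
    g <- (a1 == "B") + (a2 == "B")
    g[a1 == "0" | a2 == "0"] <- NA
    rownames(g) <- ids
    colnames(g) <- loci
    GenotypePanel(g, animalsInRows = TRUE)
  }
}

#' Write a genotype panel
#'
#' @param panel a [GenotypePanel-class].
#' @param path output path: the TSV, or the `.ped` (the `.map` is written
#'   alongside).
#' @param dialect `"matrix-tsv"` or `"ped-map"`.
#' @return `path`, invisibly.
#' @export
writeGenotypes <- function(panel, path,
                           dialect = c("matrix-tsv", "ped-map")) {
  dialect <- match.arg(dialect)
  g <- t(genotypeCalls(panel))   # animals x loci
  if (dialect == "matrix-tsv") {
    df <- data.frame(animal_id = rownames(g), g, check.names = FALSE)
    write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                na = "")
  } else {
    mapPath <- sub("\\.ped$", ".map", path)
    if (identical(mapPath, path)) mapPath <- paste0(path, ".map")
    map <- data.frame(chr = 1, snp = colnames(g), cm = 0,
                      bp = seq_len(ncol(g)))
    write.table(map, mapPath, sep = "\t", row.names = FALSE,
                col.names = FALSE, quote = FALSE)
    al <- matrix("0", nrow = nrow(g), ncol = 2 * ncol(g))
    for (j in seq_len(ncol(g))) {
      gj <- g[, j]
      al[, 2 * j - 1] <- ifelse(is.na(gj), "0", ifelse(gj >= 1, "B", "A"))
      al[, 2 * j] <- ifelse(is.na(gj), "0", ifelse(gj == 2, "B", "A"))
    }
    ped <- cbind(FID = "F0", IID = rownames(g), PAT = "0", MAT = "0",
                 SEX = "0", PHENO = "-9", al)
    write.table(ped, path, sep = " ", row.names = FALSE,
                col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read breed compositions from CSV
#'
#' One row per animal: an `animal_id` column plus one column per breed
#' (conventionally ending with `Indeterminate`), fractions summing to 1.
#'
#' @param path CSV path.
#' @return A [BreedComposition-class].
#' @export
readBreedCompositions <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"animal_id" %in% names(df)) {
    stop("composition format error: missing animal_id column")
  }
  m <- as.matrix(df[, setdiff(names(df), "animal_id"), drop = FALSE])
  rownames(m) <- df$animal_id
  BreedComposition(m)
}

#' Write breed compositions to CSV
#'
#' @param compositions a [BreedComposition-class].
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
writeBreedCompositions <- function(compositions, path) {
  f <- breedFractions(compositions)
  df <- data.frame(animal_id = rownames(f), f, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
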