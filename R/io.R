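## File readers/writers. Two genotype dialects are supported: a plain matrix
## CSV (header of marker ids, first column animal id, cells 0/1/2/NA — the
## canonical fixture format) and PLINK-style .ped/.map (whitespace separated,
## two allele columns per marker, allele code 0 = missing). Pedigrees and
## phenotypes are CSV/TSV with named columns; unknown-parent sentinel "0".

#' Read a pedigree file
#'
#' @param path CSV or TSV file with columns \code{animal}, \code{sire},
#'   \code{dam} (any order; extra columns ignored).
#' @param dialect \code{"csv"} or \code{"tsv"}.
#' @return A \code{\linkS4class{Pedigree}}; records are topologically
#'   reordered if needed, duplicates and cycles are errors.
#' @export
readPedigree <- function(path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("pedigree file not found: %s", path))
  d <- read.table(path, header = TRUE, sep = if (dialect == "csv") "," else "\t",
                  stringsAsFactors = FALSE, colClasses = "character")
  need <- c("animal", "sire", "dam")
  if (!all(need %in% names(d)))
    stop(sprintf("pedigree file must name columns %s",
                 paste(need, collapse = ", ")))
  pedigree(d$animal, d$sire, d$dam)
}

#' Write a pedigree to CSV
#'
#' @param ped a \code{Pedigree}.
#' @param path output file.
#' @return \code{path}, invisibly. Unknown parents are written as "0".
#' @export
writePedigree <- function(ped, path) {
  stopifnot(is(ped, "Pedigree"))
  d <- pedigreeTable(ped)[, c("animal", "sire", "dam")]
  d$sire[is.na(d$sire)] <- UNKNOWN_PARENT
  d$dam[is.na(d$dam)] <- UNKNOWN_PARENT
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read genotypes
#'
#' @param path for \code{"matrix-csv"}: the CSV file; for \code{"plink"}: the
#'   basename or \code{.ped} path of a \code{.ped}/\code{.map} pair.
#' @param dialect \code{"matrix-csv"} or \code{"plink"}.
#' @return A \code{\linkS4class{GenotypePanel}}. Markers with more than two
#'   observed alleles are an error naming the marker; a mismatch between
#'   marker counts in the \code{.ped} and \code{.map} files is an error.
#' @export
readGenotypes <- function(path, dialect = c("matrix-csv", "plink")) {
  dialect <- match.arg(dialect)
  if (dialect == "matrix-csv") readGenotypesMatrix(path)
  else readGenotypesPlink(path)
}

readGenotypesMatrix <- function(path) {
  if (!file.exists(path)) stop(sprintf("genotype file not found: %s", path))
  d <- read.csv(path, header = TRUE, stringsAsFactors = FALSE,
                check.names = FALSE)
  ids <- as.character(d[[1L]])
  calls <- as.matrix(d[, -1L, drop = FALSE])
  storage.mode(calls) <- "double"
  bad <- colnames(calls)[apply(calls, 2L, function(x)
    any(!is.na(x) & !(x %in% 0:2)))]
  if (length(bad))
    stop(sprintf("marker '%s' has calls outside {0, 1, 2, NA}", bad[1L]))
  rownames(calls) <- ids
  genotypePanel(calls)
}

readGenotypesPlink <- function(path) {
  base <- sub("\\.ped$", "", path)
  pedFile <- paste0(base, ".ped")
  mapFile <- paste0(base, ".map")
  if (!file.exists(pedFile)) stop(sprintf("genotype file not found: %s", pedFile))
  if (!file.exists(mapFile)) stop(sprintf("map file not found: %s", mapFile))
  map <- read.table(mapFile, header = FALSE, stringsAsFactors = FALSE)
  names(map)[1:4] <- c("chr", "marker", "cm", "pos")
  ped <- read.table(pedFile, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  nMark <- nrow(map)
  if (ncol(ped) != 6L + 2L * nMark)
    stop(sprintf(paste0("marker count mismatch: .map lists %d markers but ",
                        ".ped has %d allele columns"),
                 nMark, ncol(ped) - 6L))
  ids <- ped[[2L]]
  alt <- matrix(0L, nrow(ped), nMark)
  miss <- matrix(0L, nrow(ped), nMark)
  for (j in seq_len(nMark)) {
    a1 <- ped[[6L + 2L * j - 1L]]
    a2 <- ped[[6L + 2L * j]]
    obs <- c(a1, a2)
    alleles <- sort(unique(obs[obs != "0"]))
    if (length(alleles) > 2L)
      stop(sprintf("marker '%s' has more than two alleles (%s)",
                   map$marker[j], paste(alleles, collapse = ", ")))
    ## ref = alphabetically first allele, alt = second (deterministic). A
    ## marker with a single observed allele reads as monomorphic-reference
    ## when that allele is "A" (the writer's reference label), otherwise as
    ## monomorphic-alternate, so writer round-trips are lossless.
    altAllele <- if (length(alleles) == 2L) alleles[2L]
                 else if (length(alleles) == 1L && alleles != "A") alleles
                 else ""
    miss[, j] <- (a1 == "0") + (a2 == "0")
    alt[, j] <- (a1 == altAllele) + (a2 == altAllele)
  }
  dimnames(alt) <- dimnames(miss) <- list(ids, map$marker)
  mp <- data.frame(marker = map$marker, chr = as.character(map$chr),
                   pos = as.numeric(map$pos), stringsAsFactors = FALSE)
  calls <- alt
  calls[miss == 2L] <- NA_integer_
  genotypePanel(calls, map = mp, missingAlleles = miss)
}

#' Write genotypes
#'
#' @param panel a \code{GenotypePanel}.
#' @param path output path; for \code{"plink"} the basename (\code{.ped} and
#'   \code{.map} are appended).
#' @param dialect \code{"matrix-csv"} or \code{"plink"}. The matrix dialect
#'   cannot represent half-missing calls; PLINK writes alleles as A (ref) and
#'   B (alt) with 0 for each unobserved slot.
#' @return \code{path}, invisibly.
#' @export
writeGenotypes <- function(panel, path, dialect = c("matrix-csv", "plink")) {
  stopifnot(is(panel, "GenotypePanel"))
  dialect <- match.arg(dialect)
  if (dialect == "matrix-csv") {
    if (any(panel@miss == 1L))
      stop("matrix-csv cannot represent half-missing calls")
    calls <- genotypeCalls(panel)
    d <- data.frame(animal = rownames(calls), calls, check.names = FALSE,
                    stringsAsFactors = FALSE)
    write.csv(d, path, row.names = FALSE, quote = FALSE, na = "NA")
  } else {
    base <- sub("\\.ped$", "", path)
    map <- panel@map
    write.table(data.frame(map$chr, map$marker, 0, map$pos),
                paste0(base, ".map"), row.names = FALSE, col.names = FALSE,
                quote = FALSE, sep = "\t")
    n <- nrow(panel@alt)
    m <- ncol(panel@alt)
    cols <- vector("list", 2L * m)
    for (j in seq_len(m)) {
      alt <- panel@alt[, j]
      miss <- panel@miss[, j]
      ## distribute alt copies then ref copies over the observed slots
      a1 <- ifelse(alt >= 1L, "B", "A")
      a2 <- ifelse(alt == 2L, "B", "A")
      a2[miss >= 1L] <- "0"
      a1[miss == 2L] <- "0"
      ## half-missing with one alt allele observed: keep B in slot 1
      cols[[2L * j - 1L]] <- a1
      cols[[2L * j]] <- a2
    }
    d <- data.frame(FID = rownames(panel@alt), IID = rownames(panel@alt),
                    PAT = 0, MAT = 0, SEX = 0, PHENO = -9, cols,
                    stringsAsFactors = FALSE)
    write.table(d, paste0(base, ".ped"), row.names = FALSE,
                col.names = FALSE, quote = FALSE, sep = " ")
  }
  invisible(path)
}

#' Read a phenotype table
#'
#' @param path CSV/TSV with columns \code{animal}, \code{value},
#'   \code{family}, \code{cage} plus any fixed-effect/covariate columns.
#'   Empty or \code{NA} values mark unobserved traits.
#' @param dialect \code{"csv"} or \code{"tsv"}.
#' @return A \code{\linkS4class{PhenotypeTable}}.
#' @export
readPhenotypes <- function(path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("phenotype file not found: %s", path))
  d <- read.table(path, header = TRUE, sep = if (dialect == "csv") "," else "\t",
                  stringsAsFactors = FALSE)
  d$value <- as.numeric(d$value)
  phenotypeTable(d)
}

#' Write a phenotype table to CSV
#'
#' @param pheno a \code{PhenotypeTable}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writePhenotypes <- function(pheno, path) {
  stopifnot(is(pheno, "PhenotypeTable"))
  write.csv(phenoData(pheno), path, row.names = FALSE, quote = FALSE,
            na = "NA")
  invisible(path)
}

#' Write a relationship matrix to CSV for inspection
#'
#' @param rel a \code{RelationshipMatrix}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeRelationship <- function(rel, path) {
  stopifnot(is(rel, "RelationshipMatrix"))
  d <- data.frame(animal = rel@animals, rel@A, check.names = FALSE)
  colnames(d)[-1L] <- rel@animals
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
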