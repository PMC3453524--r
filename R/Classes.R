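## S4 containers. Constructors (lower-case camel) validate and normalise;
## slots are never meant to be touched directly.

UNKNOWN_PARENT <- "0"

## ---------------------------------------------------------------- Pedigree

#' Pedigree of animals
#'
#' Animal/sire/dam triples stored in topological order (every parent precedes
#' its offspring). Unknown parents are \code{NA}. The full-sib family id of
#' an animal is derived from its (sire, dam) pair; founders have family
#' \code{NA}.
#'
#' @slot animal character vector of unique animal ids, topologically ordered.
#' @slot sire,dam character vectors; \code{NA} when unknown.
#' @slot family character vector of derived family ids (\code{NA} for
#'   founders).
#' @export
setClass("Pedigree",
         representation(animal = "character", sire = "character",
                        dam = "character", family = "character"))

setValidity("Pedigree", function(object) {
  n <- length(object@animal)
  if (length(object@sire) != n || length(object@dam) != n ||
      length(object@family) != n)
    return("animal, sire, dam and family must have equal length")
  if (anyDuplicated(object@animal))
    return(sprintf("duplicate animal id '%s'",
                   object@animal[duplicated(object@animal)][1L]))
  pos <- seq_len(n)
  names(pos) <- object@animal
  for (p in c(object@sire, object@dam)) {
    if (!is.na(p) && is.na(pos[p]))
      return(sprintf("parent '%s' is not listed as an animal", p))
  }
  sp <- pos[object@sire]; dp <- pos[object@dam]
  if (any(sp >= pos, na.rm = TRUE) || any(dp >= pos, na.rm = TRUE))
    return("pedigree is not topologically ordered (parent after offspring)")
  TRUE
})

#' Construct a Pedigree
#'
#' Normalises unknown-parent sentinels (\code{"0"}, \code{""}, \code{NA}) to
#' \code{NA}, reorders records topologically, and derives full-sib family ids
#' from (sire, dam) pairs. Fails on duplicate ids, parents that are not
#' listed as animals, and cyclic pedigrees (one cycle is reported).
#'
#' @param animal,sire,dam character vectors of equal length.
#' @return A \code{\linkS4class{Pedigree}}.
#' @examples
#' ped <- pedigree(c("o", "s", "d"), c("s", "0", "0"), c("d", "0", "0"))
#' animals(ped)
#' @export
pedigree <- function(animal, sire, dam) {
  animal <- as.character(animal)
  sire <- normalizeParent(sire)
  dam <- normalizeParent(dam)
  if (length(sire) != length(animal) || length(dam) != length(animal))
    stop("animal, sire and dam must have equal length")
  if (anyDuplicated(animal))
    stop(sprintf("duplicate animal id '%s' in pedigree",
                 animal[duplicated(animal)][1L]))
  miss <- setdiff(c(sire, dam), c(animal, NA))
  if (length(miss))
    stop(sprintf("parent id '%s' is not listed as an animal", miss[1L]))
  ord <- topoOrderPedigree(animal, sire, dam)
  fam <- ifelse(is.na(sire) & is.na(dam), NA_character_,
                paste(ifelse(is.na(sire), UNKNOWN_PARENT, sire),
                      ifelse(is.na(dam), UNKNOWN_PARENT, dam), sep = ":"))
  new("Pedigree", animal = animal[ord], sire = sire[ord], dam = dam[ord],
      family = fam[ord])
}

normalizeParent <- function(x) {
  x <- as.character(x)
  x[x %in% c(UNKNOWN_PARENT, "", ".", "NA")] <- NA_character_
  x
}

## Kahn topological sort; on failure reports one cycle.
topoOrderPedigree <- function(animal, sire, dam) {
  n <- length(animal)
  idx <- seq_len(n)
  names(idx) <- animal
  si <- unname(idx[sire]); di <- unname(idx[dam])
  indeg <- (!is.na(si)) + (!is.na(di))
  kids <- vector("list", n)
  for (i in idx) {
    for (p in c(si[i], di[i]))
      if (!is.na(p)) kids[[p]] <- c(kids[[p]], i)
  }
  out <- integer(0)
  queue <- idx[indeg == 0L]
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    out <- c(out, i)
    for (k in kids[[i]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(out) < n) {
    left <- setdiff(idx, out)
    cyc <- findOneCycle(left[1L], si, di, animal)
    stop(sprintf("cyclic pedigree: %s", paste(cyc, collapse = " -> ")))
  }
  out
}

findOneCycle <- function(start, si, di, animal) {
  path <- integer(0)
  i <- start
  seen <- integer(0)
  repeat {
    if (i %in% path) {
      cyc <- path[which(path == i)[1L]:length(path)]
      return(animal[c(cyc, i)])
    }
    path <- c(path, i)
    nxt <- c(si[i], di[i])
    nxt <- nxt[!is.na(nxt)]
    ## follow a parent that is itself stuck in the cycle
    i <- if (length(nxt)) nxt[1L] else break
  }
  animal[path]
}

#' @describeIn animals animal ids in topological order
#' @export
setMethod("animals", "Pedigree", function(x) x@animal)

#' Parents and family of a pedigree as a data.frame
#'
#' @param ped a \code{Pedigree}.
#' @return \code{data.frame} with columns \code{animal}, \code{sire},
#'   \code{dam}, \code{family}.
#' @export
pedigreeTable <- function(ped) {
  stopifnot(is(ped, "Pedigree"))
  data.frame(animal = ped@animal, sire = ped@sire, dam = ped@dam,
             family = ped@family, stringsAsFactors = FALSE)
}

setMethod("show", "Pedigree", function(object) {
  nf <- sum(is.na(object@sire) & is.na(object@dam))
  cat(sprintf("Pedigree: %d animals (%d founders, %d full-sib families)\n",
              length(object@animal), nf,
              length(unique(stats::na.omit(object@family)))))
})

## ----------------------------------------------------------- GenotypePanel

#' SNP genotype panel
#'
#' Calls are stored as the alternate-allele count among observed allele slots
#' (\code{alt}) plus the number of unobserved allele slots (\code{miss}), so
#' half-missing calls from per-allele file formats are representable. A
#' conventional 0/1/2/NA dosage view is available via
#' \code{\link{genotypeCalls}}.
#'
#' @slot alt integer matrix (animals x markers), alt-allele counts.
#' @slot miss integer matrix, unobserved allele slots per call (0, 1 or 2).
#' @slot map data.frame with columns \code{marker}, \code{chr}, \code{pos}.
#' @slot freq numeric vector of observed alt-allele frequencies (\code{NA}
#'   when a marker has no observed alleles).
#' @export
setClass("GenotypePanel",
         representation(alt = "matrix", miss = "matrix", map = "data.frame",
                        freq = "numeric"))

setValidity("GenotypePanel", function(object) {
  d <- dim(object@alt)
  if (!identical(d, dim(object@miss)))
    return("alt and miss matrices must have identical dimensions")
  if (nrow(object@map) != d[2L])
    return("marker map rows must match the number of markers")
  if (length(object@freq) != d[2L])
    return("freq length must match the number of markers")
  if (!all(c("marker", "chr", "pos") %in% names(object@map)))
    return("map needs columns marker, chr, pos")
  if (anyDuplicated(object@map$marker))
    return("duplicate marker ids in map")
  if (any(object@map$pos < 0))
    return("positions must be non-negative")
  for (ch in unique(object@map$chr)) {
    p <- object@map$pos[object@map$chr == ch]
    if (any(diff(p) <= 0))
      return(sprintf("positions not strictly increasing on chromosome %s", ch))
  }
  if (any(object@miss < 0L | object@miss > 2L))
    return("miss entries must be 0, 1 or 2")
  if (any(object@alt < 0L) || any(object@alt + object@miss > 2L))
    return("alt + miss must not exceed 2 allele slots")
  ok <- !is.na(object@freq)
  if (any(object@freq[ok] < 0 | object@freq[ok] > 1))
    return("allele frequencies must lie in [0, 1]")
  TRUE
})

#' Construct a GenotypePanel from dosage calls
#'
#' @param calls numeric/integer matrix (animals x markers) with values in
#'   \{0, 1, 2, NA\}; rownames are animal ids, colnames marker ids.
#' @param map optional marker map \code{data.frame(marker, chr, pos)}; by
#'   default a single chromosome with 1 Mb spacing.
#' @param missingAlleles optional integer matrix of unobserved allele slots;
#'   defaults to 2 wherever \code{calls} is \code{NA}, 0 elsewhere.
#' @return A \code{\linkS4class{GenotypePanel}} with observed alt-allele
#'   frequencies computed over non-missing allele slots only.
#' @examples
#' gp <- genotypePanel(matrix(c(0, 1, 2, NA), 2, 2,
#'                            dimnames = list(c("a1", "a2"), c("m1", "m2"))))
#' alleleFreq(gp)
#' @export
genotypePanel <- function(calls, map = NULL, missingAlleles = NULL) {
  calls <- as.matrix(calls)
  if (is.null(rownames(calls)))
    rownames(calls) <- paste0("animal", seq_len(nrow(calls)))
  if (is.null(colnames(calls)))
    colnames(calls) <- paste0("m", seq_len(ncol(calls)))
  if (is.null(missingAlleles)) {
    miss <- matrix(0L, nrow(calls), ncol(calls))
    miss[is.na(calls)] <- 2L
  } else {
    miss <- matrix(as.integer(missingAlleles), nrow(calls), ncol(calls))
  }
  alt <- calls
  alt[is.na(alt)] <- 0
  bad <- which(!(alt %in% 0:2) | alt + miss > 2)
  if (length(bad))
    stop("calls must be 0, 1, 2 or NA (consistent with missing alleles)")
  storage.mode(alt) <- "integer"
  dimnames(miss) <- dimnames(alt) <- dimnames(calls)
  if (is.null(map)) {
    map <- data.frame(marker = colnames(calls), chr = "1",
                      pos = 1e6 * seq_len(ncol(calls)),
                      stringsAsFactors = FALSE)
  }
  map$marker <- as.character(map$marker)
  map$chr <- as.character(map$chr)
  obsSlots <- colSums(2L - miss)
  freq <- ifelse(obsSlots > 0, colSums(alt) / pmax(obsSlots, 1L), NA_real_)
  names(freq) <- colnames(calls)
  new("GenotypePanel", alt = alt, miss = miss, map = map, freq = freq)
}

#' @describeIn animals animal ids (rownames of the call matrix)
#' @export
setMethod("animals", "GenotypePanel", function(x) rownames(x@alt))

#' @describeIn markers marker ids in map order
#' @export
setMethod("markers", "GenotypePanel", function(x) x@map$marker)

#' @describeIn markerMap the marker map
#' @export
setMethod("markerMap", "GenotypePanel", function(x) x@map)

#' @describeIn alleleFreq observed alt-allele frequencies
#' @export
setMethod("alleleFreq", "GenotypePanel", function(x) x@freq)

#' @describeIn genotypeCalls dosage view with NA for any unobserved slot
#' @export
setMethod("genotypeCalls", "GenotypePanel", function(x) {
  calls <- x@alt
  calls[x@miss > 0L] <- NA_integer_
  calls
})

setMethod("show", "GenotypePanel", function(object) {
  nm <- sum(object@miss > 0L)
  cat(sprintf(paste0("GenotypePanel: %d animals x %d markers on %d",
                     " chromosome(s); %d call(s) with missing alleles\n"),
              nrow(object@alt), ncol(object@alt),
              length(unique(object@map$chr)), nm))
})

#' Drop markers unusable by the default analysis
#'
#' Removes markers whose allele frequency is undefined (no observed calls)
#' and, optionally, monomorphic markers.
#'
#' @param panel a \code{GenotypePanel}.
#' @param monomorphic also drop markers with frequency 0 or 1.
#' @return A \code{GenotypePanel} restricted to the retained markers.
#' @export
dropUninformative <- function(panel, monomorphic = FALSE) {
  stopifnot(is(panel, "GenotypePanel"))
  keep <- !is.na(panel@freq)
  if (monomorphic)
    keep <- keep & panel@freq > 0 & panel@freq < 1
  subsetPanel(panel, which(keep))
}

subsetPanel <- function(panel, j) {
  new("GenotypePanel",
      alt = panel@alt[, j, drop = FALSE],
      miss = panel@miss[, j, drop = FALSE],
      map = panel@map[j, , drop = FALSE],
      freq = panel@freq[j])
}

## ---------------------------------------------------------- DesignEncoding

#' Marker design encoding
#'
#' The column matrix linking animals to marker alleles used by the genomic
#' models. Modes: \code{"dosage"} (one centred column per marker, value =
#' alt count minus twice the alt frequency), \code{"allele"} (two columns per
#' marker counting copies of the reference and alternate allele), and
#' \code{"allele3"} (three columns, the third counting unobserved allele
#' slots, used for the missing-as-third-allele analysis).
#'
#' @slot X numeric matrix (animals x coded columns).
#' @slot mode encoding mode.
#' @slot colMarker integer vector mapping each column to its marker (1-based).
#' @slot markers character vector of marker ids.
#' @export
setClass("DesignEncoding",
         representation(X = "matrix", mode = "character",
                        colMarker = "integer", markers = "character"))

setValidity("DesignEncoding", function(object) {
  if (ncol(object@X) != length(object@colMarker))
    return("colMarker must map every column")
  if (length(object@markers) < max(c(0L, object@colMarker)))
    return("colMarker indexes beyond the marker list")
  if (!object@mode %in% c("dosage", "allele", "allele3"))
    return("mode must be dosage, allele or allele3")
  TRUE
})

#' @describeIn markers marker ids behind the encoding
#' @export
setMethod("markers", "DesignEncoding", function(x) x@markers)

#' @describeIn animals animal ids (rownames of the design matrix)
#' @export
setMethod("animals", "DesignEncoding", function(x) rownames(x@X))

setMethod("show", "DesignEncoding", function(object) {
  cat(sprintf("DesignEncoding: mode '%s', %d animals x %d columns (%d markers)\n",
              object@mode, nrow(object@X), ncol(object@X),
              length(object@markers)))
})

## ---------------------------------------------------------- PhenotypeTable

#' Phenotype records
#'
#' One row per animal with the trait value (\code{NA} allowed: such animals
#' are carried as unobserved and can be predicted), full-sib family id, cage
#' id, and any number of categorical fixed-effect columns and numeric
#' covariate columns.
#'
#' @slot data data.frame with at least columns \code{animal}, \code{value},
#'   \code{family}, \code{cage}.
#' @export
setClass("PhenotypeTable", representation(data = "data.frame"))

setValidity("PhenotypeTable", function(object) {
  need <- c("animal", "value", "family", "cage")
  if (!all(need %in% names(object@data)))
    return(sprintf("phenotype table needs columns %s",
                   paste(need, collapse = ", ")))
  if (anyDuplicated(object@data$animal))
    return("duplicate animal id in phenotype table")
  if (!is.numeric(object@data$value))
    return("trait values must be numeric")
  TRUE
})

#' Construct a PhenotypeTable
#'
#' @param data data.frame with columns \code{animal}, \code{value},
#'   \code{family}, \code{cage} plus optional fixed-effect/covariate columns.
#' @return A \code{\linkS4class{PhenotypeTable}}.
#' @export
phenotypeTable <- function(data) {
  data <- as.data.frame(data)
  data$animal <- as.character(data$animal)
  new("PhenotypeTable", data = data)
}

#' Underlying data.frame of a PhenotypeTable
#'
#' @param x a \code{PhenotypeTable}.
#' @return The phenotype \code{data.frame}.
#' @export
phenoData <- function(x) {
  stopifnot(is(x, "PhenotypeTable"))
  x@data
}

#' @describeIn animals animal ids of the phenotype records
#' @export
setMethod("animals", "PhenotypeTable", function(x) x@data$animal)

setMethod("show", "PhenotypeTable", function(object) {
  d <- object@data
  cat(sprintf(paste0("PhenotypeTable: %d animals (%d with records), ",
                     "%d families, %d cages\n"),
              nrow(d), sum(!is.na(d$value)), length(unique(d$family)),
              length(unique(d$cage))))
})

## ------------------------------------------------------ RelationshipMatrix

#' Additive genetic relationship matrix
#'
#' Dense numerator relationship matrix A from the tabular method, together
#' with its sparse inverse from Henderson's rules with inbreeding
#' accounted for, in pedigree (topological) order.
#'
#' @slot A symmetric numeric matrix.
#' @slot Ainv sparse symmetric inverse (\code{dgCMatrix}).
#' @slot animals animal ids (row/column order).
#' @slot inbreeding per-animal inbreeding coefficients (diag(A) - 1).
#' @export
setClass("RelationshipMatrix",
         representation(A = "matrix", Ainv = "ANY", animals = "character",
                        inbreeding = "numeric"))

setValidity("RelationshipMatrix", function(object) {
  n <- length(object@animals)
  if (!identical(dim(object@A), c(n, n)))
    return("A dimension must match animal count")
  if (any(abs(object@A - t(object@A)) > 1e-8))
    return("A must be symmetric")
  d <- diag(object@A)
  if (any(d < 1 - 1e-8) || any(d > 2 + 1e-8))
    return("diagonal of A must lie in [1, 2]")
  TRUE
})

#' @describeIn animals animal ids in matrix order
#' @export
setMethod("animals", "RelationshipMatrix", function(x) x@animals)

#' @describeIn inbreeding inbreeding coefficients from diag(A) - 1
#' @export
setMethod("inbreeding", "RelationshipMatrix",
          function(x) setNames(x@inbreeding, x@animals))

setMethod("show", "RelationshipMatrix", function(object) {
  cat(sprintf(paste0("RelationshipMatrix: %d animals, mean inbreeding %.4f,",
                     " sparse inverse with %d non-zeros\n"),
              length(object@animals), mean(object@inbreeding),
              length(object@Ainv@x)))
})

## --------------------------------------------------------------- ModelSpec

#' Model specification
#'
#' Which genetic terms are fitted and under what prior. \code{pi1} is the
#' known prior fraction of markers with a substantial effect: \code{pi1 = 1}
#' gives the non-mixture model (all scaling factors positive
#' truncated-normal); \code{pi1 < 1} gives the two-component mixture in which
#' the remaining markers fall in a fixed near-zero variance component whose
#' variance is 1 percent of the phenotypic variance divided by the marker
#' count.
#'
#' @slot modelClass \code{"polygenic"}, \code{"genomic"} or \code{"combined"}.
#' @slot pi1 prior substantial fraction in (0, 1].
#' @slot fixedEffects names of categorical fixed-effect columns.
#' @slot covariates names of numeric covariate columns.
#' @slot includeCage fit the cage random effect.
#' @slot encodingMode marker encoding expected by the fit.
#' @export
setClass("ModelSpec",
         representation(modelClass = "character", pi1 = "numeric",
                        fixedEffects = "character", covariates = "character",
                        includeCage = "logical", encodingMode = "character"))

setValidity("ModelSpec", function(object) {
  if (!object@modelClass %in% c("polygenic", "genomic", "combined"))
    return("modelClass must be polygenic, genomic or combined")
  if (object@pi1 <= 0 || object@pi1 > 1)
    return("pi1 must lie in (0, 1]")
  TRUE
})

#' Construct a ModelSpec
#'
#' @param model model class: \code{"polygenic"}, \code{"genomic"} or
#'   \code{"combined"}.
#' @param pi1 prior fraction of markers with a substantial effect, in
#'   (0, 1]. Typical settings are 1, 0.7, 0.4, 0.1, 0.075, 0.05, 0.025 but
#'   any value in (0, 1] is accepted.
#' @param fixedEffects character vector of categorical fixed-effect column
#'   names in the phenotype table.
#' @param covariates character vector of numeric covariate column names.
#' @param includeCage fit cage as a random effect (default \code{TRUE}).
#' @param encodingMode marker encoding mode (see
#'   \code{\link{encodeDesign}}).
#' @return A \code{\linkS4class{ModelSpec}}.
#' @examples
#' modelSpec("genomic", pi1 = 0.025, fixedEffects = "sex", covariates = "x")
#' @export
modelSpec <- function(model = c("polygenic", "genomic", "combined"),
                      pi1 = 1, fixedEffects = character(0),
                      covariates = character(0), includeCage = TRUE,
                      encodingMode = "dosage") {
  model <- match.arg(model)
  new("ModelSpec", modelClass = model, pi1 = as.numeric(pi1),
      fixedEffects = as.character(fixedEffects),
      covariates = as.character(covariates),
      includeCage = isTRUE(includeCage), encodingMode = encodingMode)
}

setMethod("show", "ModelSpec", function(object) {
  cat(sprintf("ModelSpec: %s model, pi1 = %g, cage %s\n", object@modelClass,
              object@pi1, if (object@includeCage) "included" else "excluded"))
})

## ----------------------------------------------------------- PosteriorDraws

#' Stored MCMC samples
#'
#' Thinned post-burn-in draws of all downstream quantities: scalar chain
#' states (general mean and variance components), fixed-effect solutions,
#' per-column total marker effects (scaling factor times base effect, the
#' identifiable product), mixture indicators, and posterior-mean genetic
#' values per animal.
#'
#' @slot modelClass fitted model class.
#' @slot pi1 prior substantial fraction used.
#' @slot varG0 fixed spike variance (\code{NA} for non-genomic fits).
#' @slot scalars matrix (samples x \{mu, varE, varU, varC, varG1\}).
#' @slot b matrix of fixed-effect/covariate draws (samples x columns).
#' @slot beta matrix of per-column marker effects (samples x columns).
#' @slot s matrix of per-marker scaling-factor draws (samples x markers).
#' @slot delta integer matrix of mixture indicators (samples x markers).
#' @slot markers marker ids; \code{colMarker} maps beta columns to markers.
#' @slot colMarker integer vector.
#' @slot uMean named posterior-mean polygenic values over all pedigree
#'   animals (length 0 when the model has no polygenic term).
#' @slot gMean named posterior-mean genomic values over all encoded animals
#'   (length 0 when the model has no genomic term).
#' @slot design list describing the fixed-effect design (for phenotype
#'   correction).
#' @slot chain list of chain metadata: iterations, burnin, thin, seed,
#'   stored, warnings.
#' @export
setClass("PosteriorDraws",
         representation(modelClass = "character", pi1 = "numeric",
                        varG0 = "numeric", scalars = "matrix", b = "matrix",
                        beta = "matrix", s = "matrix", delta = "matrix",
                        markers = "character", colMarker = "integer",
                        uMean = "numeric", gMean = "numeric",
                        design = "list", chain = "list"))

setMethod("show", "PosteriorDraws", function(object) {
  cm <- colMeans(object@scalars)
  cat(sprintf("PosteriorDraws: %s model, pi1 = %g, %d stored samples\n",
              object@modelClass, object@pi1, nrow(object@scalars)))
  cat(sprintf("  chain: %d iterations, %d burn-in, thinning %d, seed %s\n",
              object@chain$iterations, object@chain$burnin,
              object@chain$thin, format(object@chain$seed)))
  cat(sprintf("  posterior means: mu = %.3f, varE = %.3f, varU = %.3f, varC = %.3f\n",
              cm["mu"], cm["varE"], cm["varU"], cm["varC"]))
  if (length(object@chain$warnings))
    cat("  warnings:", paste(object@chain$warnings, collapse = "; "), "\n")
})

## ----------------------------------------------------------------- SplitPlan

#' Cross-validation split plan
#'
#' Two independent rounds of five disjoint validation sets over the eligible
#' animals (animals from families with at least two phenotyped members), ten
#' train/validation pairs in total at a 1:5 validation-to-training ratio.
#'
#' @slot mode \code{"within"} or \code{"between"} family.
#' @slot splits list of ten \code{list(train =, validation =)} id sets.
#' @slot eligible eligible animal ids.
#' @slot phenotyped all phenotyped animal ids.
#' @slot seed integer seed used.
#' @slot eligibleFraction realized fraction of phenotyped animals eligible.
#' @export
setClass("SplitPlan",
         representation(mode = "character", splits = "list",
                        eligible = "character", phenotyped = "character",
                        seed = "integer", eligibleFraction = "numeric"))

setMethod("show", "SplitPlan", function(object) {
  nv <- vapply(object@splits, function(s) length(s$validation), integer(1))
  cat(sprintf(paste0("SplitPlan: %s-family, %d splits, %d eligible of %d ",
                     "phenotyped (%.0f%%), validation sizes %d-%d\n"),
              object@mode, length(object@splits), length(object@eligible),
              length(object@phenotyped), 100 * object@eligibleFraction,
              min(nv), max(nv)))
})

## ------------------------------------------------------------------ PAResult

#' Predictive-ability result
#'
#' Per-split Pearson correlations between predicted breeding values and
#' fixed-effect-corrected phenotypes of validation animals, with their mean
#' and standard error over splits.
#'
#' @slot table data.frame with columns \code{split}, \code{n}, \code{pa}.
#' @slot mean,se mean and standard error of \code{pa} across splits.
#' @slot mode split mode the plan used.
#' @export
setClass("PAResult",
         representation(table = "data.frame", mean = "numeric",
                        se = "numeric", mode = "character"))

setMethod("show", "PAResult", function(object) {
  cat(sprintf("PAResult: %s-family CV, mean PA %.3f (SE %.3f) over %d splits\n",
              object@mode, object@mean, object@se, nrow(object@table)))
})

## -------------------------------------------------------------- VarianceReport

#' Variance-component and heritability report
#'
#' Posterior means and central 95 percent credible intervals for the genomic
#' variance, polygenic variance, cage and residual variances, the phenotypic
#' variance (their per-sample sum), and the heritabilities
#' \code{h2u = varU / varP} and \code{h2a = varA / varP}.
#'
#' @slot table data.frame with columns \code{component}, \code{mean},
#'   \code{lower}, \code{upper}.
#' @slot perSample matrix of per-sample component values (samples x
#'   components).
#' @export
setClass("VarianceReport",
         representation(table = "data.frame", perSample = "matrix"))

setMethod("show", "VarianceReport", function(object) {
  cat("VarianceReport (posterior mean [95% central interval]):\n")
  t <- object@table
  for (i in seq_len(nrow(t))) {
    if (is.na(t$mean[i])) next
    cat(sprintf("  %-5s %8.3f [%8.3f, %8.3f]\n", t$component[i], t$mean[i],
                t$lower[i], t$upper[i]))
  }
})

## ----------------------------------------------------------- SimulationConfig

#' Synthetic-population configuration
#'
#' Parameters of the heterogeneous-stock-style simulator: eight founder
#' strains crossed and taken through pseudo-random mating burn-in, a recorded
#' three-generation pedigree of full-sib families with cages nested in
#' family, and a trait built from QTL effects, a pedigree polygenic term,
#' cage effects, sex and one continuous covariate. See \code{\link{simConfig}}.
#'
#' @slot params named list of parameters.
#' @export
setClass("SimulationConfig", representation(params = "list"))

setMethod("show", "SimulationConfig", function(object) {
  p <- object@params
  cat(sprintf(paste0("SimulationConfig: %d strains, %d burn-in generations ",
                     "(%d breeders), %d families, %d markers / %d chrom, ",
                     "h2(QTL) %.2f + h2(poly) %.2f, cage %.2f\n"),
              p$nFounderStrains, p$nBurnGenerations, p$burnPopSize,
              p$nFamilies, p$nMarkers, p$nChromosomes, p$h2QTL, p$h2Polygenic,
              p$cageFraction))
})

## ------------------------------------------------------------- TruePopulation

#' Simulated population with recorded truth
#'
#' @slot pedigree the recorded \code{Pedigree}.
#' @slot panel the \code{GenotypePanel} over all recorded animals.
#' @slot phenotypes the \code{PhenotypeTable} (offspring generation only).
#' @slot qtl data.frame of planted QTLs: marker, index, effect.
#' @slot trueValues data.frame per phenotyped animal: \code{u} (polygenic),
#'   \code{g} (genomic), \code{bv = u + g}.
#' @slot varComponents named numeric vector of target and realized variance
#'   components.
#' @slot config the \code{SimulationConfig} used.
#' @export
setClass("TruePopulation",
         representation(pedigree = "Pedigree", panel = "GenotypePanel",
                        phenotypes = "PhenotypeTable", qtl = "data.frame",
                        trueValues = "data.frame", varComponents = "numeric",
                        config = "SimulationConfig"))

setMethod("show", "TruePopulation", function(object) {
  cat(sprintf(paste0("TruePopulation: %d pedigree animals, %d phenotyped, ",
                     "%d markers, %d QTLs\n"),
              length(animals(object@pedigree)),
              nrow(object@trueValues), ncol(object@panel@alt),
              nrow(object@qtl)))
})
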