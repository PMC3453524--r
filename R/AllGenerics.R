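#' Animal identifiers of an object
#'
#' @param x a \code{Pedigree}, \code{GenotypePanel},
#'   \code{RelationshipMatrix} or \code{PhenotypeTable}.
#' @return Character vector of animal ids.
#' @export
setGeneric("animals", function(x) standardGeneric("animals"))

#' Marker identifiers of an object
#'
#' @param x a \code{GenotypePanel} or \code{DesignEncoding}.
#' @return Character vector of marker ids.
#' @export
setGeneric("markers", function(x) standardGeneric("markers"))

#' Marker map of a genotype panel
#'
#' @param x a \code{GenotypePanel}.
#' @return \code{data.frame} with columns \code{marker}, \code{chr},
#'   \code{pos} (1-based base pairs).
#' @export
setGeneric("markerMap", function(x) standardGeneric("markerMap"))

#' Observed alternate-allele frequencies
#'
#' Frequencies are computed over observed allele slots only; markers with no
#' observed alleles have frequency \code{NA}.
#'
#' @param x a \code{GenotypePanel}.
#' @return Named numeric vector in \code{[0, 1]} (or \code{NA}).
#' @export
setGeneric("alleleFreq", function(x) standardGeneric("alleleFreq"))

#' Genotype calls as alt-allele dosages
#'
#' @param x a \code{GenotypePanel}.
#' @return Integer matrix (animals x markers) with values 0/1/2 and \code{NA}
#'   wherever any allele slot of the call is unobserved.
#' @export
setGeneric("genotypeCalls", function(x) standardGeneric("genotypeCalls"))

#' Per-animal inbreeding coefficients
#'
#' @param x a \code{RelationshipMatrix}.
#' @return Named numeric vector (diagonal of A minus 1).
#' @export
setGeneric("inbreeding", function(x) standardGeneric("inbreeding"))

#' Posterior-mean genetic values per animal
#'
#' @param draws a \code{PosteriorDraws} object.
#' @param which one of \code{"polygenic"} (pedigree-based \code{u}),
#'   \code{"genomic"} (marker-based \code{g}) or \code{"total"}
#'   (\code{u + g}, combined model only).
#' @return Named numeric vector of posterior means.
#' @export
setGeneric("geneticValues", function(draws, which = c("polygenic", "genomic",
  "total")) standardGeneric("geneticValues"))

#' Posterior probability of a substantial marker effect
#'
#' The per-marker mean of the mixture indicator over stored samples, clamped
#' to \code{[1/(2S), 1 - 1/(2S)]} with \code{S} the stored sample count so
#' that prior-to-posterior odds remain finite.
#'
#' @param draws a \code{PosteriorDraws} object from a mixture fit
#'   (\code{pi1 < 1}).
#' @return Named numeric vector of clamped inclusion probabilities, with the
#'   unclamped estimates in attribute \code{"raw"} and the clamp half-width in
#'   attribute \code{"clamp"}.
#' @export
setGeneric("markerInclusionProb",
           function(draws) standardGeneric("markerInclusionProb"))
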