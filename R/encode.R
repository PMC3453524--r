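## Genotype encodings, Hardy-Weinberg imputation, phenotype transforms.

#' Impute missing genotype calls under Hardy-Weinberg equilibrium
#'
#' Every unobserved allele slot is drawn as a Bernoulli trial with success
#' probability equal to the marker's observed alternate-allele frequency (a
#' fully missing call is therefore drawn from the Hardy-Weinberg genotype
#' probabilities p^2 / 2p(1-p) / (1-p)^2 with p the alt frequency, via
#' uniform random numbers). Reproducible given the seed.
#'
#' @param panel a \code{GenotypePanel}; every marker must have at least one
#'   observed allele (drop undefined markers first, see
#'   \code{\link{dropUninformative}}).
#' @param seed integer seed.
#' @return A complete \code{GenotypePanel} (no missing allele slots);
#'   observed calls are untouched. Frequencies are recomputed over the now
#'   complete calls.
#' @export
imputeHWE <- function(panel, seed) {
  stopifnot(is(panel, "GenotypePanel"))
  if (anyNA(panel@freq)) {
    bad <- names(panel@freq)[is.na(panel@freq)][1L]
    stop(sprintf(paste0("marker '%s' has no observed calls; remove it ",
                        "before imputation (see dropUninformative)"), bad))
  }
  if (!any(panel@miss > 0L)) return(panel)
  set.seed(as.integer(seed))
  alt <- panel@alt
  miss <- panel@miss
  idx <- which(miss > 0L, arr.ind = TRUE)
  ## draw slots marker by marker so the draw count per marker is stable
  for (j in unique(idx[, "col"])) {
    rows <- idx[idx[, "col"] == j, "row"]
    nslots <- miss[rows, j]
    p <- panel@freq[j]
    draws <- runif(sum(nslots)) < p
    slot <- factor(rep(seq_along(rows), nslots), levels = seq_along(rows))
    alt[rows, j] <- alt[rows, j] +
      as.integer(vapply(split(draws, slot), sum, numeric(1)))
    miss[rows, j] <- 0L
  }
  calls <- alt
  dimnames(calls) <- dimnames(panel@alt)
  genotypePanel(calls, map = panel@map)
}

#' Encode genotypes as a model design matrix
#'
#' @param panel a \code{GenotypePanel}.
#' @param mode \code{"dosage"}: one column per marker, value = alt-allele
#'   count minus twice the alt frequency (column means are zero);
#'   \code{"allele"}: two columns per marker counting copies of the
#'   reference and alternate allele (each animal's columns sum to 2);
#'   \code{"allele3"}: three columns, the third counting unobserved allele
#'   slots (the missing-as-third-allele analysis; columns still sum to 2).
#'   \code{"dosage"} and \code{"allele"} require a complete panel (impute
#'   first).
#' @return A \code{\linkS4class{DesignEncoding}}.
#' @examples
#' gp <- genotypePanel(matrix(c(0, 1, 2, 1), 2, 2,
#'                            dimnames = list(c("a1", "a2"), c("m1", "m2"))))
#' encodeDesign(gp, "allele")
#' @export
encodeDesign <- function(panel, mode = c("dosage", "allele", "allele3")) {
  stopifnot(is(panel, "GenotypePanel"))
  mode <- match.arg(mode)
  n <- nrow(panel@alt)
  m <- ncol(panel@alt)
  if (mode %in% c("dosage", "allele") && any(panel@miss > 0L))
    stop(sprintf("mode '%s' requires a complete panel; impute missing calls first",
                 mode))
  if (mode == "dosage") {
    X <- sweep(panel@alt + 0, 2L, 2 * panel@freq)
    colnames(X) <- markers(panel)
    colMarker <- seq_len(m)
  } else if (mode == "allele") {
    X <- matrix(0, n, 2L * m)
    X[, seq(1L, 2L * m, by = 2L)] <- 2L - panel@alt
    X[, seq(2L, 2L * m, by = 2L)] <- panel@alt
    colnames(X) <- paste0(rep(markers(panel), each = 2L), c("_ref", "_alt"))
    colMarker <- rep(seq_len(m), each = 2L)
  } else {
    X <- matrix(0, n, 3L * m)
    X[, seq(1L, 3L * m, by = 3L)] <- 2L - panel@alt - panel@miss
    X[, seq(2L, 3L * m, by = 3L)] <- panel@alt
    X[, seq(3L, 3L * m, by = 3L)] <- panel@miss
    colnames(X) <- paste0(rep(markers(panel), each = 3L),
                          c("_ref", "_alt", "_mis"))
    colMarker <- rep(seq_len(m), each = 3L)
  }
  rownames(X) <- rownames(panel@alt)
  new("DesignEncoding", X = X, mode = mode, colMarker = as.integer(colMarker),
      markers = markers(panel))
}

#' Transform phenotype values
#'
#' Elementwise normalising transform followed by multiplication with a scale
#' factor (used to avoid rounding issues on very small or large scales).
#'
#' @param values numeric vector.
#' @param transform one of \code{"identity"}, \code{"cube-root"} (requires
#'   values >= 0), \code{"sqrt-plus-one"} (requires values >= -1),
#'   \code{"cube"}.
#' @param scaleFactor positive multiplier applied after the transform.
#' @return Transformed numeric vector.
#' @examples
#' transformPhenotype(27, "cube-root")   # 3
#' transformPhenotype(8, "sqrt-plus-one")  # 3
#' @export
transformPhenotype <- function(values,
                               transform = c("identity", "cube-root",
                                             "sqrt-plus-one", "cube"),
                               scaleFactor = 1) {
  transform <- match.arg(transform)
  values <- as.numeric(values)
  if (!is.numeric(scaleFactor) || length(scaleFactor) != 1L || scaleFactor <= 0)
    stop("scaleFactor must be a single positive number")
  ok <- !is.na(values)
  if (transform == "cube-root" && any(values[ok] < 0))
    stop(sprintf("cube-root transform undefined at index %d (value %g < 0)",
                 which(ok & values < 0)[1L], values[which(ok & values < 0)[1L]]))
  if (transform == "sqrt-plus-one" && any(values[ok] < -1))
    stop(sprintf("sqrt-plus-one transform undefined at index %d (value %g < -1)",
                 which(ok & values < -1)[1L],
                 values[which(ok & values < -1)[1L]]))
  out <- switch(transform,
                "identity" = values,
                "cube-root" = values^(1 / 3),
                "sqrt-plus-one" = sqrt(values + 1),
                "cube" = values^3)
  out * scaleFactor
}
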