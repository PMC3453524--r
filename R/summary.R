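## Variance components, genomic variance and heritabilities from draws.

#' Genomic variance of one sample of marker effects
#'
#' The empirical variance across animals of the genomic values
#' \code{g = X beta} for one posterior sample. This equals the sum of the
#' per-marker contributions to the genetic variance plus all covariances due
#' to linkage disequilibrium, with allele frequencies entering through the
#' empirical column covariances — identically the quadratic form
#' \code{t(beta) C beta} with \code{C} the empirical covariance of the
#' encoding columns.
#'
#' @param beta numeric vector of per-column marker effects (one sample);
#'   length must match the encoding's columns.
#' @param encoding a \code{DesignEncoding}.
#' @return The genomic variance (a single number; sample variance with
#'   denominator n - 1 across animals).
#' @export
genomicVarianceDraw <- function(beta, encoding) {
  stopifnot(is(encoding, "DesignEncoding"))
  if (length(beta) != ncol(encoding@X))
    stop(sprintf("beta has length %d but the encoding has %d columns",
                 length(beta), ncol(encoding@X)))
  var(drop(encoding@X %*% beta))
}

#' Summarize posterior draws into a variance report
#'
#' Per stored sample the genomic variance \code{varA} is computed from that
#' sample's marker effects via \code{\link{genomicVarianceDraw}}, the
#' phenotypic variance \code{varP} is the sum of the sample's components
#' (\code{varA + varU + varC + varE}; absent components contribute 0), and
#' the heritabilities are \code{h2u = varU / varP} and
#' \code{h2a = varA / varP}, so every heritability draw is bounded in [0, 1]
#' by construction. Reported are posterior means and central 95 percent
#' credible intervals.
#'
#' @param draws a \code{PosteriorDraws}.
#' @param encoding the \code{DesignEncoding} used in the fit; required for
#'   genomic and combined models.
#' @return A \code{\linkS4class{VarianceReport}}. Components absent from the
#'   model are reported as \code{NA} rows (e.g. \code{h2a} for the polygenic
#'   model).
#' @export
summarizeDraws <- function(draws, encoding = NULL) {
  stopifnot(is(draws, "PosteriorDraws"))
  S <- nrow(draws@scalars)
  if (S == 0L) stop("no stored samples to summarize")
  hasG <- length(draws@markers) > 0L
  hasU <- length(draws@uMean) > 0L
  if (hasG && is.null(encoding))
    stop("a genomic model needs its DesignEncoding to compute the genomic variance")
  varE <- draws@scalars[, "varE"]
  varU <- if (hasU) draws@scalars[, "varU"] else rep(0, S)
  varC <- draws@scalars[, "varC"]
  if (hasG) {
    if (ncol(encoding@X) != ncol(draws@beta))
      stop("encoding does not match the draws' marker columns")
    G <- encoding@X %*% t(draws@beta)           # animals x samples
    n <- nrow(G)
    m1 <- colMeans(G)
    varA <- (colSums(G * G) - n * m1^2) / (n - 1)
  } else {
    varA <- rep(0, S)
  }
  varP <- varA + varU + varC + varE
  h2u <- varU / varP
  h2a <- varA / varP
  perSample <- cbind(varA = varA, varU = varU, varC = varC, varE = varE,
                     varP = varP, h2u = h2u, h2a = h2a)
  qs <- function(x) quantile(x, c(0.025, 0.975), names = FALSE)
  row <- function(name, x, present = TRUE) {
    if (!present)
      return(data.frame(component = name, mean = NA_real_, lower = NA_real_,
                        upper = NA_real_))
    q <- qs(x)
    data.frame(component = name, mean = mean(x), lower = q[1L], upper = q[2L])
  }
  table <- rbind(row("varA", varA, hasG), row("varU", varU, hasU),
                 row("varC", varC), row("varE", varE), row("varP", varP),
                 row("h2u", h2u, hasU), row("h2a", h2a, hasG))
  rownames(table) <- NULL
  new("VarianceReport", table = table, perSample = perSample)
}

#' Write a variance report as CSV
#'
#' One row per component with model label and mixture percentage, mirroring
#' the layout of a variance-component table.
#'
#' @param report a \code{VarianceReport}.
#' @param path output file.
#' @param model,pi1 labels recorded in the CSV.
#' @return \code{path}, invisibly.
#' @export
writeVarianceReport <- function(report, path, model = "", pi1 = NA) {
  stopifnot(is(report, "VarianceReport"))
  d <- cbind(model = model, mixture = pi1, report@table)
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
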