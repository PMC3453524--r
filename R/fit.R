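## Model fitting: R-side orchestration around the compiled Gibbs kernel.

#' Chain control settings
#'
#' @param iterations total Gibbs iterations.
#' @param burnin discarded initial iterations.
#' @param thin store every \code{thin}-th post-burn-in state.
#' @param seed integer seed; the whole chain is reproducible from it.
#' @param fixVariances named list fixing variance components at known values
#'   instead of sampling them; names among \code{varE}, \code{varU},
#'   \code{varC}, \code{varG1}. Used for oracle checks against closed-form
#'   solutions.
#' @param sFixed freeze every scaling factor at this value (diagnostic;
#'   \code{NA} = sample).
#' @param deltaFixed freeze every mixture indicator at 1 (diagnostic).
#' @param priorOnly disable the likelihood so the chain reproduces the prior
#'   (validation of the sampler's prior draws); variances are held fixed.
#' @param startVariances named list of starting values for sampled variances.
#' @return A list of settings for \code{\link{fitBayes}}.
#' @export
chainControl <- function(iterations = 50000, burnin = 10000, thin = 10,
                         seed = 1, fixVariances = list(), sFixed = NA_real_,
                         deltaFixed = FALSE, priorOnly = FALSE,
                         startVariances = list()) {
  stopifnot(iterations > burnin, burnin >= 0, thin >= 1)
  list(iterations = as.integer(iterations), burnin = as.integer(burnin),
       thin = as.integer(thin), seed = as.integer(seed),
       fixVariances = fixVariances, sFixed = as.numeric(sFixed),
       deltaFixed = isTRUE(deltaFixed), priorOnly = isTRUE(priorOnly),
       startVariances = startVariances)
}

## Treatment-coded fixed-effect design over the observed rows; levels and
## covariate centres are taken from observed rows only and kept for later
## phenotype correction.
buildFixedDesign <- function(d, obs, fixedEffects, covariates) {
  cols <- list()
  meta <- list(fixedEffects = fixedEffects, covariates = covariates,
               levels = list(), centers = numeric(0))
  for (f in fixedEffects) {
    if (!f %in% names(d)) stop(sprintf("fixed effect '%s' not in phenotype table", f))
    lv <- sort(unique(as.character(d[[f]][obs])))
    meta$levels[[f]] <- lv
    for (l in lv[-1L])
      cols[[paste0(f, ":", l)]] <- as.numeric(d[[f]] == l)
  }
  for (cv in covariates) {
    if (!cv %in% names(d)) stop(sprintf("covariate '%s' not in phenotype table", cv))
    ctr <- mean(d[[cv]][obs])
    meta$centers[cv] <- ctr
    cols[[cv]] <- d[[cv]] - ctr
  }
  X <- if (length(cols)) do.call(cbind, cols) else matrix(0, nrow(d), 0L)
  colnames(X) <- names(cols)
  meta$colnames <- colnames(X)
  list(X = X, meta = meta)
}

#' Fit a breeding-value model by Gibbs sampling
#'
#' Fits one of three model classes to phenotype records: the polygenic
#' animal model \code{y = mu + X1 b + X2 c + Z u + e} with
#' \code{u ~ N(0, A varU)}; the genomic multi-marker model
#' \code{y = mu + X1 b + X2 c + Q a s + e} in which each marker's base
#' effects \code{a ~ N(0, 1)} are multiplied by a scaling factor \code{s}
#' carrying a positive truncated-normal prior (non-mixture, \code{pi1 = 1})
#' or a two-component mixture prior (\code{pi1 < 1}: substantial component
#' \code{TN>=0(0, varG1)} with probability \code{pi1}, near-zero component
#' \code{N(0, varG0)} otherwise, where \code{varG0} is fixed at 1 percent of
#' the phenotypic variance divided by the marker count); or the combined
#' model with both genetic terms.
#'
#' The update cycle is: normal full conditionals for the mean and fixed
#' effects (flat priors); cage effects; single-site polygenic updates using
#' the sparse A-inverse; per marker a joint (indicator, scaling) block update
#' with the scaling factor integrated analytically (the substantial
#' component's marginal likelihood includes the truncated-normal normalising
#' factor), then the scaling factor from its component full conditional and
#' the base effects from normal full conditionals; and scaled-inverse
#' chi-square updates (flat on the variance) for the sampled variances.
#'
#' Animals with \code{NA} phenotype contribute no residual term but keep
#' their polygenic value (linked through A) and genomic value (from their
#' genotypes) — this is how validation animals are predicted.
#'
#' @param spec a \code{\link{modelSpec}}.
#' @param pheno a \code{PhenotypeTable} (or data.frame coercible to one).
#' @param encoding a \code{DesignEncoding}; required for genomic and
#'   combined models. May cover more animals than are phenotyped.
#' @param relationship a \code{RelationshipMatrix}; required for polygenic
#'   and combined models.
#' @param chain a \code{\link{chainControl}} list.
#' @return A \code{\linkS4class{PosteriorDraws}}.
#' @export
fitBayes <- function(spec, pheno, encoding = NULL, relationship = NULL,
                     chain = chainControl()) {
  stopifnot(is(spec, "ModelSpec"))
  if (is.data.frame(pheno)) pheno <- phenotypeTable(pheno)
  stopifnot(is(pheno, "PhenotypeTable"))
  hasG <- spec@modelClass %in% c("genomic", "combined")
  hasU <- spec@modelClass %in% c("polygenic", "combined")
  if (hasG && is.null(encoding))
    stop(sprintf("model class '%s' requires a marker DesignEncoding",
                 spec@modelClass))
  if (hasU && is.null(relationship))
    stop(sprintf("model class '%s' requires a RelationshipMatrix",
                 spec@modelClass))
  d <- phenoData(pheno)
  obs <- which(!is.na(d$value))
  if (length(obs) < 3L) stop("need at least 3 phenotyped animals")
  y <- d$value[obs]

  fd <- buildFixedDesign(d, obs, spec@fixedEffects, spec@covariates)
  X <- fd$X[obs, , drop = FALSE]
  if (ncol(X) && any(colSums(X != 0) == 0))
    stop("a fixed-effect column has no observed records")

  hasCage <- isTRUE(spec@includeCage)
  if (hasCage) {
    cagef <- factor(d$cage[obs])
    cageIdx <- as.integer(cagef) - 1L
    nCage <- nlevels(cagef)
  } else {
    cageIdx <- rep(-1L, length(obs))
    nCage <- 0L
  }

  if (hasG) {
    stopifnot(is(encoding, "DesignEncoding"))
    rows <- match(d$animal[obs], rownames(encoding@X))
    if (anyNA(rows))
      stop(sprintf("animal '%s' has no genotypes in the encoding",
                   d$animal[obs][is.na(rows)][1L]))
    Wobs <- encoding@X[rows, , drop = FALSE]
    colMarker0 <- encoding@colMarker - 1L
    nMark <- length(encoding@markers)
  } else {
    Wobs <- matrix(0, length(obs), 0L)
    colMarker0 <- integer(0)
    nMark <- 0L
  }

  if (hasU) {
    stopifnot(is(relationship, "RelationshipMatrix"))
    anim0 <- match(d$animal[obs], relationship@animals) - 1L
    if (anyNA(anim0))
      stop(sprintf("animal '%s' is not in the pedigree relationship matrix",
                   d$animal[obs][is.na(anim0)][1L]))
    Ai <- relationship@Ainv
    AiP <- Ai@p; AiI <- Ai@i; AiX <- Ai@x
    N <- length(relationship@animals)
  } else {
    anim0 <- integer(0)
    AiP <- 0L; AiI <- integer(0); AiX <- numeric(0)
    N <- 0L
  }

  varP <- var(y)
  varG0 <- if (hasG) 0.01 * varP / nMark else NA_real_
  fv <- chain$fixVariances
  sv <- chain$startVariances
  pick <- function(name, default) {
    if (!is.null(fv[[name]])) as.numeric(fv[[name]])
    else if (!is.null(sv[[name]])) as.numeric(sv[[name]])
    else default
  }
  opts <- list(
    varE0 = pick("varE", 0.5 * varP),
    varC0 = pick("varC", 0.1 * varP),
    varU0 = pick("varU", 0.3 * varP),
    varG10 = pick("varG1",
                  if (hasG) 0.5 * varP / max(1, spec@pi1 * nMark) else 1),
    fixVarE = !is.null(fv$varE) || chain$priorOnly,
    fixVarC = !is.null(fv$varC) || chain$priorOnly,
    fixVarU = !is.null(fv$varU) || chain$priorOnly,
    fixVarG1 = !is.null(fv$varG1) || chain$priorOnly,
    sFix = chain$sFixed, deltaFix = chain$deltaFixed,
    priorOnly = chain$priorOnly, minVar = 1e-10)

  set.seed(chain$seed)
  res <- gibbs_core(y, X, cageIdx, nCage, Wobs, colMarker0, nMark, anim0, N,
                    AiP, AiI, AiX, hasU, hasG, hasCage,
                    spec@pi1, if (hasG) varG0 else 1,
                    chain$iterations, chain$burnin, chain$thin, opts)

  S <- res$stored
  scalars <- res$scalars
  colnames(scalars) <- c("mu", "varE", "varU", "varC", "varG1")
  bDraws <- res$b[, seq_len(ncol(X)), drop = FALSE]
  colnames(bDraws) <- colnames(X)
  if (hasG) {
    betaDraws <- res$beta
    colnames(betaDraws) <- colnames(encoding@X)
    deltaDraws <- res$delta
    colnames(deltaDraws) <- encoding@markers
    sDraws <- res$s
    colnames(sDraws) <- encoding@markers
    gMean <- drop(encoding@X %*% colMeans(betaDraws))
    names(gMean) <- rownames(encoding@X)
    markerIds <- encoding@markers
    colMk <- encoding@colMarker
  } else {
    betaDraws <- matrix(0, S, 0L)
    sDraws <- matrix(0, S, 0L)
    deltaDraws <- matrix(0L, S, 0L)
    gMean <- numeric(0)
    markerIds <- character(0)
    colMk <- integer(0)
  }
  uMean <- if (hasU) setNames(as.numeric(res$uMean), relationship@animals)
           else numeric(0)
  warnings <- character(0)
  if (hasG && spec@pi1 < 1 && res$nZeroSubstantial > 0.5 * res$nPostBurnin)
    warnings <- sprintf(
      "substantial component empty in %d of %d post-burn-in iterations",
      res$nZeroSubstantial, res$nPostBurnin)

  new("PosteriorDraws", modelClass = spec@modelClass, pi1 = spec@pi1,
      varG0 = varG0, scalars = scalars, b = bDraws, beta = betaDraws,
      s = sDraws, delta = deltaDraws, markers = markerIds, colMarker = colMk,
      uMean = uMean, gMean = gMean, design = fd$meta,
      chain = list(iterations = chain$iterations, burnin = chain$burnin,
                   thin = chain$thin, seed = chain$seed, stored = S,
                   warnings = warnings))
}

#' @describeIn markerInclusionProb clamped per-marker posterior inclusion
#'   probabilities from the stored mixture indicators
#' @export
setMethod("markerInclusionProb", "PosteriorDraws", function(draws) {
  if (draws@pi1 >= 1)
    stop("inclusion probabilities require a mixture model (pi1 < 1)")
  S <- nrow(draws@delta)
  if (S == 0L) stop("no stored samples")
  raw <- colMeans(draws@delta)
  clamp <- 1 / (2 * S)
  p1 <- pmin(pmax(raw, clamp), 1 - clamp)
  names(p1) <- draws@markers
  attr(p1, "raw") <- setNames(raw, draws@markers)
  attr(p1, "clamp") <- clamp
  p1
})

#' @describeIn geneticValues posterior-mean genetic values; requesting a
#'   component absent from the fitted model is an error
#' @export
setMethod("geneticValues", "PosteriorDraws", function(draws, which) {
  which <- match.arg(which, c("polygenic", "genomic", "total"))
  hasU <- length(draws@uMean) > 0L
  hasG <- length(draws@gMean) > 0L
  if (which == "polygenic") {
    if (!hasU) stop(sprintf("model class '%s' has no polygenic component",
                            draws@modelClass))
    draws@uMean
  } else if (which == "genomic") {
    if (!hasG) stop(sprintf("model class '%s' has no genomic component",
                            draws@modelClass))
    draws@gMean
  } else {
    if (!hasU || !hasG)
      stop("total genetic values require the combined model")
    draws@gMean + draws@uMean[names(draws@gMean)]
  }
})
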