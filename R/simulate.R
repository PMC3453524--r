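## Heterogeneous-stock-style population simulator: eight founder strains,
## pseudo-random-mating burn-in generating LD, a recorded three-generation
## pedigree of full-sib families, cages nested in family, and a trait with
## configurable QTL, polygenic, cage and residual variance.

#' Simulation configuration
#'
#' Defaults mirror a heterogeneous-stock mouse population: 8 founder
#' strains, 50 generations
#' of pseudo-random mating (200 breeders per generation during burn-in), 175
#' full-sib families in one recorded offspring generation with parents and
#' grandparents, family sizes Poisson(11) truncated at 2, on average 3.1
#' cages per family. The marker panel, trait architecture and variance
#' fractions are configurable; defaults are a desk-scale panel of 1,000 SNPs
#' on 5 chromosomes of 100 Mb and a mid-range trait (QTL heritability 0.3,
#' polygenic heritability 0.2, cage fraction 0.2).
#'
#' @param ... overrides of the default parameters: \code{nFounderStrains},
#'   \code{nBurnGenerations}, \code{burnPopSize}, \code{nFamilies},
#'   \code{offspringPerFamily} (\code{NA} = Poisson(\code{offspringLambda})
#'   truncated at 2), \code{offspringLambda}, \code{cagesPerFamilyMean},
#'   \code{nMarkers}, \code{nChromosomes}, \code{chromLength} (bp),
#'   \code{recombRate} (cM/Mb, Haldane map function), \code{nQTL},
#'   \code{qtlEffectDist} (\code{"gamma"} reflected, shape \code{qtlShape},
#'   or \code{"normal"}), \code{qtlShape}, \code{h2QTL}, \code{h2Polygenic},
#'   \code{cageFraction}, \code{sexEffect}, \code{covariateSlope},
#'   \code{mu}, \code{varP}.
#' @return A \code{\linkS4class{SimulationConfig}}.
#' @examples
#' simConfig(nFamilies = 20, nMarkers = 100)
#' @export
simConfig <- function(...) {
  p <- list(nFounderStrains = 8, nBurnGenerations = 50, burnPopSize = 200,
            nFamilies = 175, offspringPerFamily = NA, offspringLambda = 11,
            cagesPerFamilyMean = 3.1, nMarkers = 1000, nChromosomes = 5,
            chromLength = 1e8, recombRate = 0.5, nQTL = 20,
            qtlEffectDist = "gamma", qtlShape = 0.4, h2QTL = 0.3,
            h2Polygenic = 0.2, cageFraction = 0.2, sexEffect = 5,
            covariateSlope = 2, mu = 50, varP = 100)
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown))
    stop(sprintf("unknown simulation parameter '%s'", unknown[1L]))
  p[names(over)] <- over
  fr <- c(p$h2QTL, p$h2Polygenic, p$cageFraction)
  if (any(fr < 0) || sum(fr) >= 1)
    stop("variance fractions must be non-negative and sum to less than 1")
  if (p$nQTL > p$nMarkers) stop("nQTL cannot exceed nMarkers")
  if (p$nFounderStrains < 2) stop("need at least 2 founder strains")
  new("SimulationConfig", params = p)
}

#' Simulate the recorded pedigree
#'
#' Three recorded generations: for each full-sib family two parents, each
#' the offspring of its own grandparent couple (4 distinct grandparents per
#' family, recorded as founders), plus the phenotyped offspring. Family
#' sizes follow the configured distribution.
#'
#' @param config a \code{\link{simConfig}}.
#' @param seed integer seed (drives family sizes).
#' @return A \code{\linkS4class{Pedigree}}.
#' @export
simulatePedigree <- function(config, seed) {
  stopifnot(is(config, "SimulationConfig"))
  p <- config@params
  if (p$nFamilies < 1) stop("need at least one family")
  if (p$burnPopSize < 8)
    stop("mating design impossible: need at least 8 burn-in breeders")
  set.seed(as.integer(seed))
  F <- p$nFamilies
  if (is.na(p$offspringPerFamily)) {
    sizes <- rpois(F, p$offspringLambda)
    while (any(sizes < 2L))                      # truncation at 2
      sizes[sizes < 2L] <- rpois(sum(sizes < 2L), p$offspringLambda)
  } else {
    sizes <- rep(as.integer(p$offspringPerFamily), F)
  }
  gp <- sprintf("GP%05d", seq_len(4L * F))
  pa <- sprintf("P%05d", seq_len(2L * F))
  off <- sprintf("O%05d", seq_len(sum(sizes)))
  animal <- c(gp, pa, off)
  sire <- c(rep(NA_character_, 4L * F),
            gp[4L * seq_len(F) - 3L], gp[4L * seq_len(F) - 1L],
            rep(pa[2L * seq_len(F) - 1L], sizes))
  dam <- c(rep(NA_character_, 4L * F),
            gp[4L * seq_len(F) - 2L], gp[4L * seq_len(F)],
            rep(pa[2L * seq_len(F)], sizes))
  ## interleave parent columns: sires of families then dams were appended in
  ## blocks above; reorder parents to P1..P(2F) ids with correct parents
  sire[(4L * F) + seq_len(2L * F)] <-
    c(rbind(gp[4L * seq_len(F) - 3L], gp[4L * seq_len(F) - 1L]))
  dam[(4L * F) + seq_len(2L * F)] <-
    c(rbind(gp[4L * seq_len(F) - 2L], gp[4L * seq_len(F)]))
  sire[(6L * F) + seq_len(sum(sizes))] <- rep(pa[2L * seq_len(F) - 1L], sizes)
  dam[(6L * F) + seq_len(sum(sizes))] <- rep(pa[2L * seq_len(F)], sizes)
  pedigree(animal, sire, dam)
}

## Adjacent-marker recombination fractions under the Haldane map function;
## chromosome boundaries recombine freely.
recombFractions <- function(map, ratePerMb) {
  m <- nrow(map)
  if (m < 2L) return(numeric(0))
  dMorgan <- diff(map$pos) / 1e6 * ratePerMb / 100
  r <- 0.5 * (1 - exp(-2 * dMorgan))
  r[map$chr[-1L] != map$chr[-m]] <- 0.5
  r
}

## Vectorised meioses: one gamete per entry of parentIdx from haplotype
## matrices hapA/hapB (individuals x markers).
drawGametes <- function(hapA, hapB, parentIdx, rAdj) {
  n <- length(parentIdx)
  m <- ncol(hapA)
  start <- rbinom(n, 1L, 0.5)
  if (m > 1L) {
    xo <- matrix(runif(n * (m - 1L)) <
                   matrix(rAdj, n, m - 1L, byrow = TRUE), n, m - 1L)
    cs <- if (m == 2L) matrix(as.integer(xo), n, 1L)
          else t(apply(xo, 1L, cumsum))
    strand <- (start + cbind(0L, cs)) %% 2L
  } else {
    strand <- matrix(start, n, 1L)
  }
  gam <- hapA[parentIdx, , drop = FALSE]
  hb <- hapB[parentIdx, , drop = FALSE]
  sel <- strand == 1L
  gam[sel] <- hb[sel]
  gam
}

#' Simulate LD-bearing genotypes along the recorded pedigree
#'
#' Founder strain haplotypes are drawn per strain (strains are fixed for
#' one of the two alleles at every marker), crossed into a burn-in
#' population that undergoes the configured generations of pseudo-random
#' mating with Haldane recombination (this generates the linkage
#' disequilibrium), and gene dropping through the recorded pedigree then
#' yields genotypes for every recorded animal. Mendelian consistency holds
#' by construction.
#'
#' @param ped the recorded \code{Pedigree} from
#'   \code{\link{simulatePedigree}}.
#' @param config a \code{\link{simConfig}}.
#' @param seed integer seed.
#' @return A \code{\linkS4class{GenotypePanel}} over all recorded animals
#'   (no missing calls). An error is raised if no marker remains
#'   polymorphic (increase founder diversity or marker count).
#' @export
simulateGenotypes <- function(ped, config, seed) {
  stopifnot(is(ped, "Pedigree"), is(config, "SimulationConfig"))
  p <- config@params
  set.seed(as.integer(seed))
  m <- p$nMarkers
  perChr <- diff(round(seq(0, m, length.out = p$nChromosomes + 1L)))
  map <- do.call(rbind, lapply(seq_len(p$nChromosomes), function(ch) {
    k <- perChr[ch]
    data.frame(marker = character(k), chr = as.character(ch),
               pos = round(seq(p$chromLength / (k + 1L), p$chromLength *
                               k / (k + 1L), length.out = k)),
               stringsAsFactors = FALSE)
  }))
  map$marker <- sprintf("snp%05d", seq_len(m))
  rAdj <- recombFractions(map, p$recombRate)

  strains <- matrix(rbinom(p$nFounderStrains * m, 1L, 0.5),
                    p$nFounderStrains, m)
  nB <- p$burnPopSize
  pick <- t(replicate(nB, sample.int(p$nFounderStrains, 2L)))
  hapA <- strains[pick[, 1L], , drop = FALSE]
  hapB <- strains[pick[, 2L], , drop = FALSE]
  for (g in seq_len(p$nBurnGenerations)) {
    sires <- sample.int(nB, nB, replace = TRUE)
    dams <- sample.int(nB, nB, replace = TRUE)
    while (any(sires == dams)) {
      i <- sires == dams
      dams[i] <- sample.int(nB, sum(i), replace = TRUE)
    }
    newA <- drawGametes(hapA, hapB, sires, rAdj)
    newB <- drawGametes(hapA, hapB, dams, rAdj)
    hapA <- newA
    hapB <- newB
  }

  ids <- ped@animal
  N <- length(ids)
  idx <- setNames(seq_len(N), ids)
  founder <- is.na(ped@sire) & is.na(ped@dam)
  pedA <- matrix(0L, N, m)
  pedB <- matrix(0L, N, m)
  ## recorded founders: one further round of random mating from the burn-in
  ## population, so they share its LD structure without being clones
  nF <- sum(founder)
  fs <- sample.int(nB, nF, replace = TRUE)
  fd <- sample.int(nB, nF, replace = TRUE)
  while (any(fs == fd)) {
    i <- fs == fd
    fd[i] <- sample.int(nB, sum(i), replace = TRUE)
  }
  pedA[founder, ] <- drawGametes(hapA, hapB, fs, rAdj)
  pedB[founder, ] <- drawGametes(hapA, hapB, fd, rAdj)
  ## gene dropping by pedigree depth so each level is one vectorised call
  depth <- pedigreeDepth(ped)
  for (lev in sort(unique(depth[depth > 0L]))) {
    rows <- which(depth == lev)
    si <- idx[ped@sire[rows]]
    di <- idx[ped@dam[rows]]
    pedA[rows, ] <- drawGametes(pedA, pedB, si, rAdj)
    pedB[rows, ] <- drawGametes(pedA, pedB, di, rAdj)
  }
  calls <- pedA + pedB
  dimnames(calls) <- list(ids, map$marker)
  fr <- colMeans(calls) / 2
  if (!any(fr > 0 & fr < 1))
    stop(paste0("no polymorphic markers survived the burn-in; increase ",
                "founder diversity, marker count or reduce burn-in drift"))
  genotypePanel(calls, map = map)
}

## Depth of each animal in the pedigree (founders 0).
pedigreeDepth <- function(ped) {
  idx <- setNames(seq_along(ped@animal), ped@animal)
  depth <- integer(length(ped@animal))
  for (i in seq_along(ped@animal)) {
    s <- ped@sire[i]; d <- ped@dam[i]
    ds <- if (!is.na(s)) depth[idx[s]] else -1L
    dd <- if (!is.na(d)) depth[idx[d]] else -1L
    depth[i] <- max(ds, dd) + 1L
  }
  depth
}

#' Simulate a trait over a genotyped pedigree
#'
#' Builds phenotypes for the offspring generation as the sum of a general
#' mean, a sex effect, one continuous covariate, cage effects drawn per cage
#' (cages nested within family), QTL effects times dosage (effects rescaled
#' so the realized genomic variance among offspring equals the configured
#' QTL heritability times the phenotypic variance), a polygenic deviation
#' simulated by pedigree gene flow (founder values N(0, varU), offspring
#' half the parent average plus Mendelian sampling N(0, varU / 2)) that is
#' independent of the marker panel by construction, and a normal residual.
#'
#' @param ped the recorded \code{Pedigree}.
#' @param panel a \code{GenotypePanel} covering all phenotyped animals.
#' @param config a \code{\link{simConfig}}.
#' @param seed integer seed.
#' @return A \code{\linkS4class{TruePopulation}} with the phenotypes, the
#'   planted QTLs and effects, true genetic values and variance components.
#' @export
simulateTrait <- function(ped, panel, config, seed) {
  stopifnot(is(ped, "Pedigree"), is(panel, "GenotypePanel"),
            is(config, "SimulationConfig"))
  p <- config@params
  depth <- pedigreeDepth(ped)
  offIds <- ped@animal[depth == max(depth)]
  if (max(depth) == 0L) stop("pedigree has no offspring generation")
  rows <- match(offIds, animals(panel))
  if (anyNA(rows))
    stop(sprintf("panel does not cover phenotyped animal '%s'",
                 offIds[is.na(rows)][1L]))
  set.seed(as.integer(seed))
  n <- length(offIds)
  varCage <- p$cageFraction * p$varP
  varU <- p$h2Polygenic * p$varP
  varQTL <- p$h2QTL * p$varP
  varE <- p$varP - varCage - varU - varQTL

  calls <- panel@alt[rows, , drop = FALSE]
  qtl <- data.frame(marker = character(0), index = integer(0),
                    effect = numeric(0), stringsAsFactors = FALSE)
  g <- numeric(n)
  if (p$nQTL > 0L && varQTL > 0) {
    frOff <- colMeans(calls) / 2
    elig <- which(frOff >= 0.05 & frOff <= 0.95)
    if (length(elig) < p$nQTL)
      stop(sprintf(paste0("variance targets unreachable: only %d markers are ",
                          "polymorphic enough to carry the %d requested QTLs"),
                   length(elig), p$nQTL))
    qidx <- sort(elig[sample.int(length(elig), p$nQTL)])
    raw <- if (p$qtlEffectDist == "normal") rnorm(p$nQTL)
           else sample(c(-1, 1), p$nQTL, replace = TRUE) *
                rgamma(p$nQTL, shape = p$qtlShape, scale = 1)
    graw <- drop(calls[, qidx, drop = FALSE] %*% raw)
    if (var(graw) <= 0)
      stop("variance targets unreachable: planted QTLs carry no variance")
    eff <- raw * sqrt(varQTL / var(graw))
    g <- drop(calls[, qidx, drop = FALSE] %*% eff)
    g <- g - mean(g)
    qtl <- data.frame(marker = markers(panel)[qidx], index = qidx,
                      effect = eff, stringsAsFactors = FALSE)
  }

  ## polygenic gene flow along the recorded pedigree
  idx <- setNames(seq_along(ped@animal), ped@animal)
  u <- numeric(length(ped@animal))
  if (varU > 0) {
    for (i in seq_along(ped@animal)) {
      s <- ped@sire[i]; d <- ped@dam[i]
      if (is.na(s) && is.na(d)) {
        u[i] <- rnorm(1L, 0, sqrt(varU))
      } else {
        us <- if (!is.na(s)) u[idx[s]] else 0
        ud <- if (!is.na(d)) u[idx[d]] else 0
        u[i] <- 0.5 * (us + ud) + rnorm(1L, 0, sqrt(varU / 2))
      }
    }
  }
  uOff <- u[idx[offIds]]

  fam <- ped@family[idx[offIds]]
  cage <- character(n)
  for (f in unique(fam)) {
    mem <- which(fam == f)
    nc <- 1L + rpois(1L, max(p$cagesPerFamilyMean - 1, 0))
    cage[mem] <- sprintf("%s_c%d", f, sample.int(nc, length(mem),
                                                 replace = TRUE))
  }
  cageLevels <- unique(cage)
  cageEff <- setNames(rnorm(length(cageLevels), 0, sqrt(varCage)), cageLevels)

  sex <- sample(c("F", "M"), n, replace = TRUE)
  x <- rnorm(n)
  y <- p$mu + p$sexEffect * (sex == "M") + p$covariateSlope * x +
       cageEff[cage] + g + uOff + rnorm(n, 0, sqrt(varE))

  pheno <- phenotypeTable(data.frame(
    animal = offIds, value = as.numeric(y), family = fam, cage = cage,
    sex = sex, x = x, stringsAsFactors = FALSE))
  trueValues <- data.frame(animal = offIds, u = uOff, g = g, bv = uOff + g,
                           stringsAsFactors = FALSE)
  vc <- c(varP = p$varP, varQTL = varQTL, varU = varU, varCage = varCage,
          varE = varE, realizedVarG = var(g), realizedVarU = var(uOff),
          realizedVarBV = var(uOff + g), realizedVarPheno = var(as.numeric(y)))
  new("TruePopulation", pedigree = ped, panel = panel, phenotypes = pheno,
      qtl = qtl, trueValues = trueValues, varComponents = vc,
      config = config)
}

#' Simulate a complete population
#'
#' Convenience wrapper chaining \code{\link{simulatePedigree}} (seed),
#' \code{\link{simulateGenotypes}} (seed + 1) and \code{\link{simulateTrait}}
#' (seed + 2).
#'
#' @param config a \code{\link{simConfig}}.
#' @param seed integer base seed.
#' @return A \code{\linkS4class{TruePopulation}}.
#' @export
simulatePopulation <- function(config = simConfig(), seed = 1) {
  ped <- simulatePedigree(config, seed)
  panel <- simulateGenotypes(ped, config, seed + 1)
  simulateTrait(ped, panel, config, seed + 2)
}

#' Write a simulated population to disk
#'
#' Writes the same pedigree/genotype/phenotype formats the readers consume,
#' plus a truth CSV of QTL indices, effects and variance components.
#'
#' @param pop a \code{TruePopulation}.
#' @param dir output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
writePopulation <- function(pop, dir) {
  stopifnot(is(pop, "TruePopulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(pedigree = file.path(dir, "pedigree.csv"),
             genotypes = file.path(dir, "genotypes.csv"),
             phenotypes = file.path(dir, "phenotypes.csv"),
             truth = file.path(dir, "truth.csv"))
  writePedigree(pop@pedigree, files["pedigree"])
  writeGenotypes(pop@panel, files["genotypes"])
  writePhenotypes(pop@phenotypes, files["phenotypes"])
  vc <- pop@varComponents
  truth <- rbind(
    data.frame(kind = "qtl", name = pop@qtl$marker, value = pop@qtl$effect),
    data.frame(kind = "variance", name = names(vc), value = as.numeric(vc)))
  write.csv(truth, files["truth"], row.names = FALSE, quote = FALSE)
  invisible(files)
}
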