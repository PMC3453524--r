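# Fixture builders shared across the suite. Everything is generated in code;
# no data files.

# Random multi-generation pedigree: founders plus `extra` animals whose
# parents are drawn from everyone born before them (creates inbreeding).
randomPedigree <- function(nFounders = 20, extra = 80, seed = 1) {
  set.seed(seed)
  ids <- sprintf("A%04d", seq_len(nFounders + extra))
  sire <- rep(NA_character_, nFounders + extra)
  dam <- rep(NA_character_, nFounders + extra)
  for (i in nFounders + seq_len(extra)) {
    par <- sample(i - 1L, 2L)
    sire[i] <- ids[par[1L]]
    dam[i] <- ids[par[2L]]
  }
  pedigree(ids, sire, dam)
}

# Random genotype panel of 0/1/2 calls with an optional fraction of fully
# missing calls.
randomPanel <- function(n = 10, m = 20, seed = 1, missing = 0) {
  set.seed(seed)
  calls <- matrix(rbinom(n * m, 2L, runif(m, 0.1, 0.9)[rep(seq_len(m),
                                                           each = n)]),
                  n, m, dimnames = list(sprintf("an%03d", seq_len(n)),
                                        sprintf("mk%03d", seq_len(m))))
  if (missing > 0) {
    drop <- which(runif(n * m) < missing)
    calls[drop] <- NA_integer_
  }
  genotypePanel(calls)
}

# Small phenotype table with a configurable family structure.
familyPheno <- function(sizes, seed = 1, values = NULL) {
  set.seed(seed)
  fam <- rep(sprintf("f%03d", seq_along(sizes)), sizes)
  n <- length(fam)
  phenotypeTable(data.frame(
    animal = sprintf("an%04d", seq_len(n)),
    value = if (is.null(values)) rnorm(n) else values,
    family = fam,
    cage = paste0(fam, "_c", 1L + (sequence(sizes) %% 2L)),
    sex = sample(c("F", "M"), n, replace = TRUE),
    x = rnorm(n),
    stringsAsFactors = FALSE))
}

# Desk-scale simulated population (marker panel restricted to the phenotyped
# animals so dosage columns are exactly centred over the analysis set).
quickPopulation <- function(seed, nFamilies = 20, offspringPerFamily = 11,
                            nMarkers = 100, nChromosomes = 2,
                            nBurnGenerations = 25, nQTL = 10, h2QTL = 0.3,
                            h2Polygenic = 0.2, cageFraction = 0.15, ...) {
  cfg <- simConfig(nFamilies = nFamilies,
                   offspringPerFamily = offspringPerFamily,
                   nMarkers = nMarkers, nChromosomes = nChromosomes,
                   nBurnGenerations = nBurnGenerations, nQTL = nQTL,
                   h2QTL = h2QTL, h2Polygenic = h2Polygenic,
                   cageFraction = cageFraction, ...)
  simulatePopulation(cfg, seed)
}

# Panel restricted to the phenotyped animals of a population, frequencies
# recomputed over that analysis set.
analysisPanel <- function(pop) {
  off <- phenoData(pop@phenotypes)$animal
  genotypePanel(genotypeCalls(pop@panel)[off, , drop = FALSE],
                map = markerMap(pop@panel))
}
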