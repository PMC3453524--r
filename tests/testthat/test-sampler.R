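# Gibbs sampler: oracle equivalences, prior reproduction, reproducibility,
# parameterisation invariance.

# Dense mixed-model-equations solve used as the oracle for the polygenic
# model with known variances.
mmeSolve <- function(d, rel, varU, varC, varE) {
  y <- d$value
  Xf <- cbind(mu = 1, sexM = as.numeric(d$sex == "M"), x = d$x - mean(d$x))
  Zc <- outer(d$cage, sort(unique(d$cage)), "==") + 0
  Zu <- matrix(0, length(y), length(rel@animals))
  Zu[cbind(seq_along(y), match(d$animal, rel@animals))] <- 1
  lamU <- varE / varU
  lamC <- varE / varC
  C <- rbind(
    cbind(crossprod(Xf), crossprod(Xf, Zc), crossprod(Xf, Zu)),
    cbind(crossprod(Zc, Xf), crossprod(Zc) + lamC * diag(ncol(Zc)),
          crossprod(Zc, Zu)),
    cbind(crossprod(Zu, Xf), crossprod(Zu, Zc),
          crossprod(Zu) + lamU * as.matrix(rel@Ainv)))
  rhs <- c(crossprod(Xf, y), crossprod(Zc, y), crossprod(Zu, y))
  sol <- solve(C, rhs)
  list(b = sol[2:3],
       u = sol[(ncol(Xf) + ncol(Zc)) + seq_len(length(rel@animals))])
}

test_that("polygenic posterior means match the MME solve at fixed variances", {
  cfg <- simConfig(nFamilies = 16, offspringPerFamily = 10, nMarkers = 10,
                   nChromosomes = 1, nBurnGenerations = 5, nQTL = 0,
                   h2QTL = 0, h2Polygenic = 0.5, cageFraction = 0.2)
  spec <- modelSpec("polygenic", fixedEffects = "sex", covariates = "x")
  varU <- 50; varC <- 20; varE <- 30
  for (seed in 1:5) {
    pop <- simulatePopulation(cfg, seed = 600 + seed)
    rel <- additiveRelationship(pop@pedigree)
    fit <- fitBayes(spec, pop@phenotypes, relationship = rel,
                    chain = chainControl(20000, 4000, 4, seed = seed,
                                         fixVariances = list(varU = varU,
                                                             varC = varC,
                                                             varE = varE)))
    d <- phenoData(pop@phenotypes)
    mme <- mmeSolve(d, rel, varU, varC, varE)
    uG <- geneticValues(fit, "polygenic")
    genSD <- sqrt(varU)
    expect_lt(sqrt(mean((uG - mme$u)^2)) / genSD, 0.02)
    expect_lt(max(abs(colMeans(fit@b) - mme$b)) / genSD, 0.02)
  }
})

test_that("frozen-scale genomic posterior means match closed-form ridge", {
  s0 <- 1.2
  varE <- 9
  spec <- modelSpec("genomic", pi1 = 1, includeCage = FALSE)
  for (seed in 1:5) {
    set.seed(900 + seed)
    n <- 250; m <- 40
    calls <- matrix(rbinom(n * m, 2, 0.5), n, m,
                    dimnames = list(sprintf("a%03d", 1:n),
                                    sprintf("m%03d", 1:m)))
    panel <- genotypePanel(calls)
    enc <- encodeDesign(panel, "dosage")
    beta_t <- rnorm(m, 0, 0.4)
    y <- 5 + drop(enc@X %*% beta_t) + rnorm(n, 0, 3)
    pheno <- data.frame(animal = rownames(calls), value = y,
                        family = "f", cage = "c")
    fit <- fitBayes(spec, pheno, encoding = enc,
                    chain = chainControl(10000, 2000, 4, seed = seed,
                                         sFixed = s0, deltaFixed = TRUE,
                                         fixVariances = list(varE = varE)))
    ridge <- solve(crossprod(enc@X) + (varE / s0^2) * diag(m),
                   crossprod(enc@X, y))
    expect_lt(sqrt(mean((colMeans(fit@beta) - ridge)^2)) / sd(y), 0.02)
  }
})

test_that("a likelihood-disabled chain reproduces its prior", {
  set.seed(11)
  calls <- matrix(rbinom(100 * 80, 2, 0.5), 100, 80,
                  dimnames = list(sprintf("a%03d", 1:100),
                                  sprintf("m%03d", 1:80)))
  enc <- encodeDesign(genotypePanel(calls), "dosage")
  pheno <- data.frame(animal = rownames(calls), value = rnorm(100),
                      family = "f", cage = "c")
  pi1 <- 0.3
  sg1 <- 1.5
  fit <- fitBayes(modelSpec("genomic", pi1 = pi1, includeCage = FALSE),
                  pheno, encoding = enc,
                  chain = chainControl(3000, 500, 1, seed = 4,
                                       priorOnly = TRUE,
                                       startVariances = list(varG1 = sg1^2)))
  nd <- length(fit@delta)
  zDelta <- (mean(fit@delta) - pi1) / sqrt(pi1 * (1 - pi1) / nd)
  expect_lt(abs(zDelta), 3)
  s1 <- fit@s[fit@delta == 1]
  target <- sg1 * sqrt(2 / pi)                   # half-normal mean
  se <- sg1 * sqrt(1 - 2 / pi) / sqrt(length(s1))
  expect_lt(abs(mean(s1) - target) / se, 3)
})

test_that("chains are bit-identical under identical seed and config", {
  pop <- quickPopulation(seed = 41, nFamilies = 8, nMarkers = 40)
  enc <- encodeDesign(analysisPanel(pop), "dosage")
  rel <- additiveRelationship(pop@pedigree)
  spec <- modelSpec("combined", pi1 = 0.1, fixedEffects = "sex",
                    covariates = "x")
  ch <- chainControl(600, 200, 2, seed = 13)
  f1 <- fitBayes(spec, pop@phenotypes, encoding = enc, relationship = rel,
                 chain = ch)
  f2 <- fitBayes(spec, pop@phenotypes, encoding = enc, relationship = rel,
                 chain = ch)
  expect_identical(f1@scalars, f2@scalars)
  expect_identical(f1@beta, f2@beta)
  expect_identical(f1@delta, f2@delta)
  expect_identical(f1@uMean, f2@uMean)
})

test_that("stored sample count follows iterations, burn-in and thinning", {
  pop <- quickPopulation(seed = 42, nFamilies = 6, nMarkers = 20)
  rel <- additiveRelationship(pop@pedigree)
  fit <- fitBayes(modelSpec("polygenic"), pop@phenotypes, relationship = rel,
                  chain = chainControl(1000, 400, 6, seed = 1))
  expect_equal(nrow(fit@scalars), 100L)          # (1000 - 400) / 6
})

test_that("dosage and per-allele encodings give equivalent genomic values", {
  pop <- quickPopulation(seed = 43, nFamilies = 18, nMarkers = 60,
                         h2QTL = 0.4, h2Polygenic = 0)
  panel <- analysisPanel(pop)
  spec <- modelSpec("genomic", pi1 = 1, fixedEffects = "sex",
                    covariates = "x")
  ch <- chainControl(4000, 1000, 3, seed = 5)
  gD <- geneticValues(fitBayes(spec, pop@phenotypes,
                               encoding = encodeDesign(panel, "dosage"),
                               chain = ch), "genomic")
  gA <- geneticValues(fitBayes(spec, pop@phenotypes,
                               encoding = encodeDesign(panel, "allele"),
                               chain = ch), "genomic")
  sdP <- sd(phenoData(pop@phenotypes)$value)
  # equivalent up to the intercept absorbed in mu: compare centred values
  diff <- (gD - mean(gD)) - (gA - mean(gA))
  expect_lt(sqrt(mean(diff^2)) / sdP, 0.05)
})

test_that("inclusion probabilities clamp and genetic values compose", {
  pop <- quickPopulation(seed = 44, nFamilies = 8, nMarkers = 30)
  enc <- encodeDesign(analysisPanel(pop), "dosage")
  rel <- additiveRelationship(pop@pedigree)
  fit <- fitBayes(modelSpec("combined", pi1 = 0.2, fixedEffects = "sex",
                            covariates = "x"),
                  pop@phenotypes, encoding = enc, relationship = rel,
                  chain = chainControl(800, 300, 2, seed = 2))
  S <- nrow(fit@delta)
  p1 <- markerInclusionProb(fit)
  expect_true(all(p1 >= 1 / (2 * S) & p1 <= 1 - 1 / (2 * S)))
  # a marker always in the substantial component clamps to 1 - 1/(2S)
  fitAll <- fit
  fitAll@delta[, 1L] <- 1L
  fitAll@delta[, 2L] <- as.integer(seq_len(S) <= S / 2)
  p1b <- markerInclusionProb(fitAll)
  expect_equal(unname(p1b[1L]), 1 - 1 / (2 * S))
  expect_equal(unname(p1b[2L]), mean(fitAll@delta[, 2L]))
  # total = polygenic + genomic elementwise for the combined model
  tot <- geneticValues(fit, "total")
  expect_equal(tot, geneticValues(fit, "genomic") +
                      geneticValues(fit, "polygenic")[names(tot)])
  # absent components are errors
  fitP <- fitBayes(modelSpec("polygenic"), pop@phenotypes, relationship = rel,
                   chain = chainControl(300, 100, 2, seed = 2))
  expect_error(geneticValues(fitP, "genomic"), "no genomic")
  expect_error(markerInclusionProb(fitP), "mixture")
  fitG <- fitBayes(modelSpec("genomic", pi1 = 1), pop@phenotypes,
                   encoding = enc, chain = chainControl(300, 100, 2, seed = 2))
  expect_error(geneticValues(fitG, "polygenic"), "no polygenic")
  expect_error(markerInclusionProb(fitG), "mixture")
})

test_that("a persistently empty substantial component is flagged", {
  set.seed(3)
  calls <- matrix(rbinom(40 * 50, 2, 0.5), 40, 50,
                  dimnames = list(sprintf("a%02d", 1:40),
                                  sprintf("m%02d", 1:50)))
  enc <- encodeDesign(genotypePanel(calls), "dosage")
  pheno <- data.frame(animal = rownames(calls), value = rnorm(40),
                      family = "f", cage = "c")
  # prior-only chain at a tiny pi1: the component is empty most iterations
  fit <- fitBayes(modelSpec("genomic", pi1 = 0.001, includeCage = FALSE),
                  pheno, encoding = enc,
                  chain = chainControl(400, 100, 1, seed = 1,
                                       priorOnly = TRUE))
  expect_match(fit@chain$warnings, "substantial component empty")
  # draws with no stored samples cannot yield inclusion probabilities
  empty <- fit
  empty@delta <- fit@delta[0, , drop = FALSE]
  expect_error(markerInclusionProb(empty), "no stored samples")
})

test_that("model preconditions are enforced", {
  pop <- quickPopulation(seed = 45, nFamilies = 6, nMarkers = 20)
  enc <- encodeDesign(analysisPanel(pop), "dosage")
  rel <- additiveRelationship(pop@pedigree)
  expect_error(fitBayes(modelSpec("genomic"), pop@phenotypes,
                        relationship = rel, chain = chainControl(100, 10, 1)),
               "DesignEncoding")
  expect_error(fitBayes(modelSpec("polygenic"), pop@phenotypes,
                        encoding = enc, chain = chainControl(100, 10, 1)),
               "RelationshipMatrix")
  expect_error(fitBayes(modelSpec("combined"), pop@phenotypes,
                        encoding = enc, chain = chainControl(100, 10, 1)),
               "RelationshipMatrix")
})
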