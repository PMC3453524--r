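# Split designs, phenotype correction and predictive ability.

# Hand-built draws exposing chosen fixed-effect solutions.
fixedDraws <- function(mu, b, levels, centers = numeric(0)) {
  S <- 10
  bm <- matrix(rep(b, each = S), S, length(b),
               dimnames = list(NULL, names(b)))
  new("PosteriorDraws", modelClass = "polygenic", pi1 = 1, varG0 = NA_real_,
      scalars = cbind(mu = rep(mu, S), varE = 1, varU = 1, varC = 0,
                      varG1 = 0),
      b = bm, beta = matrix(0, S, 0), s = matrix(0, S, 0),
      delta = matrix(0L, S, 0), markers = character(0),
      colMarker = integer(0), uMean = numeric(0), gMean = numeric(0),
      design = list(fixedEffects = names(levels), covariates = names(centers),
                    levels = levels, centers = centers,
                    colnames = colnames(bm)),
      chain = list(iterations = S, burnin = 0, thin = 1, seed = 1,
                   stored = S, warnings = character(0)))
}

test_that("split plans implement the 1:5 two-round design", {
  # 20 singleton families plus 20 families of 5: 100 eligible of 120
  pheno <- familyPheno(c(rep(1L, 20), rep(5L, 20)), seed = 1)
  plan <- makeSplits(pheno, "within", seed = 3)
  expect_length(plan@splits, 10L)
  expect_length(plan@eligible, 100L)
  expect_equal(plan@eligibleFraction, 100 / 120)
  sizes <- vapply(plan@splits, function(s) length(s$validation), integer(1))
  expect_true(all(abs(sizes - 20L) <= 5L))
  for (s in plan@splits)
    expect_setequal(c(s$train, s$validation), animals(pheno))
  # each round's five validation sets are disjoint and cover the eligibles
  for (round in 0:1) {
    vals <- unlist(lapply(plan@splits[round * 5 + 1:5],
                          function(s) s$validation))
    expect_equal(sort(vals), sort(plan@eligible))
  }
  # singleton-family animals never appear in any validation set
  singles <- phenoData(pheno)$animal[phenoData(pheno)$family %in%
                                       sprintf("f%03d", 1:20)]
  expect_length(intersect(unlist(lapply(plan@splits, `[[`, "validation")),
                          singles), 0L)
})

test_that("between-family splits keep families whole", {
  pheno <- familyPheno(rep(c(8L, 5L, 3L), 6), seed = 2)
  plan <- makeSplits(pheno, "between", seed = 9)
  d <- phenoData(pheno)
  for (s in plan@splits) {
    for (fam in unique(d$family)) {
      mem <- d$animal[d$family == fam]
      inVal <- length(intersect(mem, s$validation))
      expect_true(inVal == 0L || inVal == length(mem))
    }
  }
  expect_error(makeSplits(familyPheno(rep(3L, 8)), "between", seed = 1),
               "at least 10 multi-member families")
})

test_that("split invariants hold across random family structures", {
  for (seed in 1:50) {
    set.seed(seed)
    sizes <- sample(1:12, sample(12:25, 1), replace = TRUE)
    pheno <- familyPheno(sizes, seed = seed)
    d <- phenoData(pheno)
    mode <- if (sum(sizes >= 2) >= 10 && seed %% 2 == 0) "between" else "within"
    plan <- makeSplits(pheno, mode, seed = seed)
    famOf <- setNames(d$family, d$animal)
    for (round in 0:1) {
      vals <- lapply(plan@splits[round * 5 + 1:5], `[[`, "validation")
      expect_equal(anyDuplicated(unlist(vals)), 0L)
    }
    for (s in plan@splits) {
      # every validation animal comes from a family with >= 2 members and
      # that family keeps at least one training member (within mode)
      vfam <- famOf[s$validation]
      expect_true(all(table(d$family)[vfam] >= 2L))
      if (mode == "within") {
        tfam <- famOf[s$train]
        expect_true(all(vfam %in% tfam))
      }
    }
  }
})

test_that("phenotype correction applies training fixed-effect solutions", {
  pheno <- familyPheno(c(2L, 2L), seed = 4, values = c(10, 12, 14, 16))
  # zero solutions: realized = y - mu
  f0 <- fixedDraws(mu = 3, b = setNames(numeric(0), character(0)),
                   levels = list())
  expect_equal(unname(correctedPhenotype(pheno, f0)), c(7, 9, 11, 13))

  # sex effect applied only to matching animals
  d <- phenoData(pheno)
  fs <- fixedDraws(mu = 0, b = c("sex:M" = 2), levels = list(sex = c("F", "M")))
  got <- correctedPhenotype(pheno, fs)
  expect_equal(unname(got), d$value - 2 * (d$sex == "M"))

  # hand-built 4-animal case with one covariate: y - mu - x * slope
  fc <- fixedDraws(mu = 1, b = c(x = 0.5), levels = list(),
                   centers = c(x = 0))
  expect_equal(unname(correctedPhenotype(pheno, fc)), d$value - 1 - 0.5 * d$x)

  # unseen factor level is an error naming the level
  d2 <- d
  d2$sex[1] <- "U"
  expect_error(correctedPhenotype(phenotypeTable(d2), fs), "'U'")
})

test_that("predictive ability is the Pearson correlation with guards", {
  expect_equal(predictiveAbility(1:5, 1:5), 1)
  expect_equal(predictiveAbility(1:5, -(1:5)), -1)
  expect_equal(round(predictiveAbility(c(1, 2, 3), c(2, 4, 7)), 4), 0.9934)
  expect_error(predictiveAbility(1:2, 1:2), "at least 3")
  expect_error(predictiveAbility(c(1, 1, 1), 1:3), "constant")
})

test_that("masking phenotypes equals excluding the records entirely", {
  pop <- quickPopulation(seed = 81, nFamilies = 10, nMarkers = 30)
  d <- phenoData(pop@phenotypes)
  rel <- additiveRelationship(pop@pedigree)
  drop <- d$animal[d$family == d$family[1L]]
  masked <- d
  masked$value[masked$animal %in% drop] <- NA_real_
  excl <- d[!d$animal %in% drop, ]
  spec <- modelSpec("polygenic", fixedEffects = "sex", covariates = "x")
  ch <- chainControl(500, 200, 2, seed = 6)
  fM <- fitBayes(spec, phenotypeTable(masked), relationship = rel, chain = ch)
  fE <- fitBayes(spec, phenotypeTable(excl), relationship = rel, chain = ch)
  expect_identical(fM@uMean, fE@uMean)
  expect_identical(fM@scalars, fE@scalars)
})

test_that("a pure-noise trait has predictive ability near zero", {
  pop <- quickPopulation(seed = 82, nFamilies = 16, nMarkers = 60,
                         nQTL = 0, h2QTL = 0, h2Polygenic = 0,
                         cageFraction = 0.15)
  enc <- encodeDesign(analysisPanel(pop), "dosage")
  plan <- makeSplits(pop@phenotypes, "within", seed = 7)
  res <- runCV(modelSpec("genomic", pi1 = 1, fixedEffects = "sex",
                         covariates = "x"),
               pop@phenotypes, encoding = enc, plan = plan,
               chain = chainControl(800, 300, 2, seed = 8))
  expect_lt(abs(res@mean), 3 * res@se + 1e-8)
})

test_that("cross-validation results are reproducible from their seeds", {
  pop <- quickPopulation(seed = 83, nFamilies = 8, nMarkers = 30)
  rel <- additiveRelationship(pop@pedigree)
  plan <- makeSplits(pop@phenotypes, "within", seed = 5)
  spec <- modelSpec("polygenic", fixedEffects = "sex", covariates = "x")
  ch <- chainControl(400, 150, 2, seed = 9)
  r1 <- runCV(spec, pop@phenotypes, relationship = rel, plan = plan,
              chain = ch)
  r2 <- runCV(spec, pop@phenotypes, relationship = rel, plan = plan,
              chain = ch)
  expect_identical(r1@table, r2@table)
  p2 <- makeSplits(pop@phenotypes, "within", seed = 5)
  expect_identical(plan@splits, p2@splits)
})
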