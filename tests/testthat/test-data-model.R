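# Domain types, readers/writers, encodings, HWE imputation, transforms.

test_that("pedigree files are read, reordered and validated", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("animal,sire,dam", "s1,0,0", "d1,0,0", "o1,s1,d1"), f)
  ped <- readPedigree(f)
  expect_length(animals(ped), 3L)
  expect_equal(length(unique(stats::na.omit(pedigreeTable(ped)$family))), 1L)

  # offspring listed before its parents: accepted after topological reorder
  writeLines(c("animal,sire,dam", "o1,s1,d1", "s1,0,0", "d1,0,0"), f)
  ped2 <- readPedigree(f)
  tab <- pedigreeTable(ped2)
  pos <- setNames(seq_len(nrow(tab)), tab$animal)
  expect_true(pos["s1"] < pos["o1"] && pos["d1"] < pos["o1"])

  writeLines(c("animal,sire,dam", "a,0,0", "a,0,0"), f)
  expect_error(readPedigree(f), "duplicate.*'a'")

  writeLines(c("animal,sire,dam", "a,b,0", "b,a,0"), f)
  expect_error(readPedigree(f), "cycl")
})

test_that("matrix-csv genotypes round-trip and validate", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("animal,m1,m2", "a1,0,1", "a2,2,NA"), f)
  panel <- readGenotypes(f)
  expect_equal(sum(is.na(genotypeCalls(panel))), 1L)
  expect_equal(unname(alleleFreq(panel)), c(0.5, 0.5))

  # marker with all calls missing: frequency undefined, dropped from the
  # default analysis set
  writeLines(c("animal,m1,m2", "a1,NA,1", "a2,NA,2"), f)
  p2 <- readGenotypes(f)
  expect_true(is.na(alleleFreq(p2)["m1"]))
  expect_equal(markers(dropUninformative(p2)), "m2")

  writeLines(c("animal,m1", "a1,3"), f)
  expect_error(readGenotypes(f), "m1")
})

test_that("genotype round-trips are lossless for both dialects", {
  for (k in 1:50) {
    panel <- randomPanel(n = sample(3:20, 1), m = sample(2:50, 1), seed = k,
                         missing = ifelse(k %% 2L, 0, 0.15))
    f <- tempfile(fileext = ".csv")
    writeGenotypes(panel, f, "matrix-csv")
    back <- readGenotypes(f, "matrix-csv")
    expect_identical(genotypeCalls(back), genotypeCalls(panel))
    unlink(f)

    base <- tempfile()
    writeGenotypes(panel, base, "plink")
    back2 <- readGenotypes(base, "plink")
    expect_identical(back2@alt, panel@alt)
    expect_identical(back2@miss, panel@miss)
    unlink(paste0(base, c(".ped", ".map")))
  }
})

test_that("plink dialect handles half-missing calls and input errors", {
  base <- tempfile()
  writeLines("1\tsnpA\t0\t100", paste0(base, ".map"))
  writeLines(c("f a1 0 0 0 -9 A C", "f a2 0 0 0 -9 C 0"), paste0(base, ".ped"))
  panel <- readGenotypes(base, "plink")
  expect_equal(unname(panel@alt[, 1]), c(1L, 1L))   # C is the alt allele
  expect_equal(unname(panel@miss[, 1]), c(0L, 1L))
  expect_equal(unname(alleleFreq(panel)), 2 / 3)

  writeLines(c("f a1 0 0 0 -9 A C", "f a2 0 0 0 -9 G A"), paste0(base, ".ped"))
  expect_error(readGenotypes(base, "plink"), "snpA.*allele")

  writeLines(c("1\tsnpA\t0\t100", "1\tsnpB\t0\t200"), paste0(base, ".map"))
  writeLines("f a1 0 0 0 -9 A C", paste0(base, ".ped"))
  expect_error(readGenotypes(base, "plink"), "mismatch")
  unlink(paste0(base, c(".ped", ".map")))
})

test_that("HWE imputation fills missing calls from observed frequencies", {
  # degenerate frequencies impute deterministically at both ends
  calls <- matrix(c(0, 0, NA, NA, 2, 2, NA, NA), 4, 2,
                  dimnames = list(paste0("a", 1:4), c("m1", "m2")))
  imp <- imputeHWE(genotypePanel(calls), seed = 1)
  expect_equal(unname(genotypeCalls(imp)[, "m1"]), rep(0L, 4))  # freq 0
  expect_equal(unname(genotypeCalls(imp)[, "m2"]), rep(2L, 4))  # freq 1

  # binomial oracle: p = 0.5, 10000 missing calls; expected het fraction
  # 0.5 within 3 binomial standard errors, 3 * sqrt(0.25 / 10000)
  big <- matrix(NA_real_, 10002, 1, dimnames = list(NULL, "m"))
  big[1:2, 1] <- c(0, 2)     # observed freq exactly 0.5
  imp2 <- imputeHWE(genotypePanel(big), seed = 7)
  het <- mean(genotypeCalls(imp2)[-(1:2), 1] == 1L)
  expect_lt(abs(het - 0.5), 3 * sqrt(0.25 / 10000))

  # complete panel returned unchanged
  full <- randomPanel(6, 8, seed = 3)
  expect_identical(imputeHWE(full, 1), full)

  # undefined frequency is an error
  allNA <- genotypePanel(matrix(NA_real_, 2, 1, dimnames = list(NULL, "m")))
  expect_error(imputeHWE(allNA, 1), "no observed calls")
})

test_that("different imputation seeds differ only at formerly missing calls", {
  panel <- randomPanel(15, 25, seed = 5, missing = 0.2)
  wasMissing <- panel@miss > 0L
  a <- genotypeCalls(imputeHWE(panel, 1))
  b <- genotypeCalls(imputeHWE(panel, 2))
  expect_identical(a[!wasMissing], b[!wasMissing])
  expect_identical(a[!wasMissing],
                   genotypeCalls(panel)[!wasMissing])
})

test_that("design encodings satisfy their defining identities", {
  calls <- matrix(c(1, 0, 2, 1), 2, 2,
                  dimnames = list(c("a1", "a2"), c("m1", "m2")))
  panel <- genotypePanel(calls)
  al <- encodeDesign(panel, "allele")
  expect_equal(unname(al@X["a1", c("m1_ref", "m1_alt")]), c(1, 1))  # het
  # per-allele rows sum to 2 allele copies per marker
  for (j in unique(al@colMarker))
    expect_equal(unname(rowSums(al@X[, al@colMarker == j, drop = FALSE])),
                 rep(2, 2))

  # third-allele coding represents half-missing calls
  p3 <- genotypePanel(matrix(c(0, 0), 1, 2,
                             dimnames = list("a1", c("m1", "m2"))),
                      missingAlleles = matrix(c(0L, 1L), 1, 2))
  a3 <- encodeDesign(p3, "allele3")
  expect_equal(unname(a3@X[1, 1:3]), c(2, 0, 0))   # hom-ref
  expect_equal(unname(a3@X[1, 4:6]), c(1, 0, 1))   # one allele missing
  for (j in unique(a3@colMarker))
    expect_equal(sum(a3@X[, a3@colMarker == j]), 2)

  # dosage-centred columns have zero means on any panel
  big <- randomPanel(30, 40, seed = 9)
  dz <- encodeDesign(big, "dosage")
  expect_lt(max(abs(colMeans(dz@X))), 1e-10)

  # dosage requires a complete panel
  miss <- randomPanel(6, 6, seed = 2, missing = 0.3)
  expect_error(encodeDesign(miss, "dosage"), "impute")
  expect_error(encodeDesign(miss, "allele"), "impute")
})

test_that("phenotype transforms compute and guard their domains", {
  expect_equal(transformPhenotype(27, "cube-root"), 3)
  expect_equal(transformPhenotype(8, "sqrt-plus-one"), 3)
  expect_equal(transformPhenotype(2, "cube"), 8)
  expect_equal(transformPhenotype(c(1, 8), "cube-root", scaleFactor = 10),
               c(10, 20))
  expect_error(transformPhenotype(c(4, -1), "cube-root"), "index 2")
  expect_error(transformPhenotype(c(-3, 0), "sqrt-plus-one"), "index 1")
  expect_error(transformPhenotype(1, "cube", scaleFactor = -1), "positive")
})
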