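## Within- and between-family cross-validation and predictive ability.

#' Build cross-validation splits
#'
#' Two independent rounds of five disjoint validation sets (ten in total)
#' over the eligible animals, a 1:5 validation-to-training design. Only
#' animals from families with at least two phenotyped members are eligible
#' for validation; the training set of each split is every phenotyped animal
#' outside its validation set.
#'
#' Within-family mode deals each multi-member family's shuffled members
#' round-robin over the five groups from a random offset, so every family
#' with a validation animal also keeps at least one animal in training.
#' Between-family mode assigns whole families to groups, largest first onto
#' the currently smallest group (ties broken by the seeded shuffle), so no
#' family ever spans training and validation.
#'
#' @param pheno a \code{PhenotypeTable}.
#' @param mode \code{"within"} or \code{"between"}.
#' @param seed integer seed.
#' @return A \code{\linkS4class{SplitPlan}}. Between-family mode requires at
#'   least 10 multi-member families.
#' @export
makeSplits <- function(pheno, mode = c("within", "between"), seed) {
  mode <- match.arg(mode)
  if (is.data.frame(pheno)) pheno <- phenotypeTable(pheno)
  d <- phenoData(pheno)
  d <- d[!is.na(d$value), , drop = FALSE]
  famSize <- table(d$family)
  multi <- names(famSize)[famSize >= 2L]
  if (length(multi) < 2L)
    stop("need at least 2 families with >= 2 phenotyped members")
  if (mode == "between" && length(multi) < 10L)
    stop(sprintf(paste0("between-family mode needs at least 10 multi-member ",
                        "families to form 5 family-disjoint groups twice ",
                        "(found %d)"), length(multi)))
  eligible <- d$animal[d$family %in% multi]
  set.seed(as.integer(seed))
  splits <- list()
  for (round in 1:2) {
    groups <- vector("list", 5L)
    if (mode == "within") {
      for (fam in multi) {
        mem <- sample(d$animal[d$family == fam])
        start <- sample.int(5L, 1L)
        g <- ((start + seq_along(mem) - 2L) %% 5L) + 1L
        for (k in seq_along(mem))
          groups[[g[k]]] <- c(groups[[g[k]]], mem[k])
      }
    } else {
      ord <- sample(multi)                       # seeded tie-break
      ord <- ord[order(-famSize[ord])]           # largest family first
      count <- integer(5L)
      for (fam in ord) {
        g <- which.min(count)
        groups[[g]] <- c(groups[[g]], d$animal[d$family == fam])
        count[g] <- count[g] + famSize[[fam]]
      }
    }
    for (g in seq_len(5L)) {
      val <- groups[[g]]
      splits[[length(splits) + 1L]] <-
        list(train = setdiff(d$animal, val), validation = val)
    }
  }
  new("SplitPlan", mode = mode, splits = splits, eligible = eligible,
      phenotyped = d$animal, seed = as.integer(seed),
      eligibleFraction = length(eligible) / nrow(d))
}

#' Fixed-effect-corrected (realized) observations
#'
#' The phenotype minus the training fit's estimates of the general mean,
#' fixed effects and covariate terms. Cage and genetic terms are not
#' removed: the corrected value is what a predicted breeding value is
#' compared against.
#'
#' @param pheno a \code{PhenotypeTable} holding the (uncorrected) values.
#' @param fit a \code{PosteriorDraws} from a training fit; its posterior
#'   mean solutions and factor levels are applied.
#' @param animalIds which animals to correct (default: all with a value).
#' @return Named numeric vector of realized observations. A factor level
#'   unseen in the training fit is an error naming the level.
#' @export
correctedPhenotype <- function(pheno, fit, animalIds = NULL) {
  stopifnot(is(fit, "PosteriorDraws"))
  if (is.data.frame(pheno)) pheno <- phenotypeTable(pheno)
  d <- phenoData(pheno)
  if (is.null(animalIds)) animalIds <- d$animal[!is.na(d$value)]
  rows <- match(animalIds, d$animal)
  if (anyNA(rows))
    stop(sprintf("animal '%s' not in the phenotype table",
                 animalIds[is.na(rows)][1L]))
  meta <- fit@design
  bhat <- colMeans(fit@b)
  muHat <- mean(fit@scalars[, "mu"])
  out <- d$value[rows] - muHat
  for (f in meta$fixedEffects) {
    lv <- meta$levels[[f]]
    vals <- as.character(d[[f]][rows])
    unseen <- setdiff(unique(vals), lv)
    if (length(unseen))
      stop(sprintf("level '%s' of fixed effect '%s' was not in the training fit",
                   unseen[1L], f))
    for (l in lv[-1L])
      out <- out - bhat[[paste0(f, ":", l)]] * (vals == l)
  }
  for (cv in meta$covariates)
    out <- out - bhat[[cv]] * (d[[cv]][rows] - meta$centers[[cv]])
  setNames(out, animalIds)
}

#' Predictive ability
#'
#' Pearson correlation between predicted and realized observations.
#'
#' @param predicted,realized numeric vectors of equal length (>= 3); both
#'   must be non-constant.
#' @return The correlation.
#' @examples
#' predictiveAbility(c(1, 2, 3), c(2, 4, 7))
#' @export
predictiveAbility <- function(predicted, realized) {
  if (length(predicted) != length(realized))
    stop("predicted and realized must have equal length")
  if (length(predicted) < 3L)
    stop("need at least 3 paired values")
  if (sd(predicted) == 0 || sd(realized) == 0)
    stop("correlation undefined for a constant vector")
  cor(predicted, realized)
}

#' Run a cross-validation experiment
#'
#' For each split the model is refitted on the training animals (validation
#' phenotypes masked as missing, so validation animals keep their pedigree
#' links and genotypes but contribute no records), validation animals are
#' predicted by their posterior-mean breeding values (\code{u} for the
#' polygenic model, \code{g} for the genomic model, \code{u + g} for the
#' combined model), observed validation phenotypes are corrected with the
#' training fit's fixed-effect solutions, and the predictive ability is
#' their Pearson correlation. Split \code{i} uses seed \code{seed + i}.
#'
#' @param spec a \code{\link{modelSpec}}.
#' @param pheno a \code{PhenotypeTable} with the full records.
#' @param encoding,relationship model inputs as in \code{\link{fitBayes}}.
#' @param plan a \code{\link{makeSplits}} plan.
#' @param chain a \code{\link{chainControl}}; its seed anchors the per-split
#'   seeds.
#' @return A \code{\linkS4class{PAResult}}.
#' @export
runCV <- function(spec, pheno, encoding = NULL, relationship = NULL, plan,
                  chain = chainControl()) {
  stopifnot(is(plan, "SplitPlan"))
  if (is.data.frame(pheno)) pheno <- phenotypeTable(pheno)
  d <- phenoData(pheno)
  whichVal <- switch(spec@modelClass, polygenic = "polygenic",
                     genomic = "genomic", combined = "total")
  pa <- numeric(length(plan@splits))
  nval <- integer(length(plan@splits))
  for (i in seq_along(plan@splits)) {
    sp <- plan@splits[[i]]
    masked <- d
    masked$value[masked$animal %in% sp$validation] <- NA_real_
    ch <- chain
    ch$seed <- chain$seed + i
    fit <- fitBayes(spec, phenotypeTable(masked), encoding = encoding,
                    relationship = relationship, chain = ch)
    pred <- geneticValues(fit, whichVal)[sp$validation]
    realized <- correctedPhenotype(pheno, fit, sp$validation)
    pa[i] <- predictiveAbility(unname(pred), unname(realized))
    nval[i] <- length(sp$validation)
  }
  tab <- data.frame(split = seq_along(pa), n = nval, pa = pa)
  new("PAResult", table = tab, mean = mean(pa),
      se = sd(pa) / sqrt(length(pa)), mode = plan@mode)
}
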