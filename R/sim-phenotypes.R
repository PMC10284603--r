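# Trait models: additive/dominance QTL effects, covariates, Gaussian
# residual; binary traits through a liability threshold.

#' Trait model for phenotype simulation
#'
#' A quantitative trait is generated as grand mean + sum of QTL
#' additive/dominance contributions + covariate effects + Gaussian residual.
#' A QTL with additive effect \code{a} and dominance \code{d} contributes
#' \code{a * (x - 1) + d * [x == 1]} for genotype x in 0/1/2 copies of the Q
#' allele, so \code{mean(QQ) - mean(qq) = 2a}. If \code{liabilityThreshold}
#' is non-NA the simulated trait is treated as an unobserved liability and a
#' binary trait \code{liability > threshold} is returned alongside it.
#'
#' @slot grandMean trait grand mean (trait units).
#' @slot qtl data.frame with columns \code{chrom}, \code{cm}, \code{a},
#'   \code{d}; each locus must exist on the simulated map.
#' @slot residualSd residual standard deviation (> 0).
#' @slot covariateEffects named numeric vector of linear covariate
#'   coefficients (names must match covariate columns).
#' @slot liabilityThreshold threshold on the liability scale (NA for a
#'   plain quantitative trait; -Inf yields an all-1 binary trait).
#' @export
setClass("TraitModel", representation(
  grandMean = "numeric",
  qtl = "data.frame",
  residualSd = "numeric",
  covariateEffects = "numeric",
  liabilityThreshold = "numeric"
))

setValidity("TraitModel", function(object) {
  msg <- character()
  if (length(object@residualSd) != 1L || !is.finite(object@residualSd) ||
      object@residualSd <= 0)
    msg <- c(msg, "residualSd must be a single positive number")
  q <- object@qtl
  if (nrow(q) && !all(c("chrom", "cm", "a", "d") %in% names(q)))
    msg <- c(msg, "qtl must have columns chrom, cm, a, d")
  if (length(object@covariateEffects) &&
      is.null(names(object@covariateEffects)))
    msg <- c(msg, "covariateEffects must be named")
  if (length(msg)) msg else TRUE
})

#' Construct a trait model
#'
#' @param grandMean trait grand mean.
#' @param qtl data.frame(chrom, cm, a, d); default no QTL.
#' @param residualSd residual SD (> 0).
#' @param covariateEffects named numeric coefficients; default none.
#' @param liabilityThreshold NA (quantitative trait) or a threshold that
#'   dichotomises the trait as a liability.
#' @return A [TraitModel-class].
#' @examples
#' TraitModel(grandMean = 1.0,
#'            qtl = data.frame(chrom = "1", cm = 4, a = 0.265, d = 0),
#'            residualSd = 0.11)
#' @export
TraitModel <- function(grandMean = 0, qtl = data.frame(), residualSd = 1,
                       covariateEffects = numeric(0),
                       liabilityThreshold = NA_real_) {
  if (nrow(qtl)) qtl$chrom <- as.character(qtl$chrom)
  new("TraitModel", grandMean = as.numeric(grandMean), qtl = qtl,
      residualSd = as.numeric(residualSd),
      covariateEffects = covariateEffects,
      liabilityThreshold = as.numeric(liabilityThreshold))
}

setMethod("show", "TraitModel", function(object) {
  cat(sprintf("TraitModel: mean %.3g, %d QTL, residual SD %.3g, %d covariate(s)%s\n",
              object@grandMean, nrow(object@qtl), object@residualSd,
              length(object@covariateEffects),
              if (!is.na(object@liabilityThreshold))
                sprintf(", liability threshold %.3g", object@liabilityThreshold)
              else ""))
})

#' Simulate phenotypes from genotypes under a trait model
#'
#' @param genotypes a [GenotypeMatrix-class] whose map contains every QTL
#'   locus of the model at the exact (chrom, cm) position.
#' @param model a [TraitModel-class].
#' @param covariates optional data.frame of numeric covariates, one row per
#'   individual (column order of the genotype matrix); must contain every
#'   name of \code{covariateEffects}.
#' @param seed integer seed for the Gaussian residuals.
#' @return data.frame with \code{id}, \code{value} (the quantitative trait,
#'   or the liability), and \code{binary} (0/1) when the model carries a
#'   liability threshold.
#' @examples
#' map <- geneticMap("m1", "1", 0)
#' g <- genotypeMatrix(matrix(c(0L, 1L, 2L), 1,
#'                     dimnames = list("m1", c("a", "b", "c"))), map)
#' simulatePhenotypes(g, TraitModel(grandMean = 10, residualSd = 1), seed = 1)
#' @export
simulatePhenotypes <- function(genotypes, model, covariates = NULL, seed = 1L) {
  stopifnot(is(genotypes, "GenotypeMatrix"), is(model, "TraitModel"))
  validObject(model)
  calls <- genotypeCalls(genotypes)
  mk <- mapMarkers(genotypeMap(genotypes))
  n <- ncol(calls)
  set.seed(deriveSeed(seed, "phenotypes"))

  y <- rep(model@grandMean, n)
  q <- model@qtl
  if (nrow(q)) for (k in seq_len(nrow(q))) {
    hit <- which(mk$chrom == q$chrom[k] & mk$cm == q$cm[k])
    if (!length(hit))
      stop(sprintf("QTL locus %s:%g cM is not on the genotype map", q$chrom[k], q$cm[k]))
    x <- calls[mk$marker[hit[1]], ]
    if (anyNA(x)) stop("missing genotype calls at a QTL locus")
    y <- y + q$a[k] * (x - 1) + q$d[k] * (x == 1)
  }
  ce <- model@covariateEffects
  if (length(ce)) {
    if (is.null(covariates) || !all(names(ce) %in% names(covariates)))
      stop("covariates must contain columns: ", paste(names(ce), collapse = ", "))
    y <- y + as.matrix(covariates[, names(ce), drop = FALSE]) %*% ce
  }
  y <- as.numeric(y) + stats::rnorm(n, 0, model@residualSd)
  out <- data.frame(id = colnames(calls), value = y, stringsAsFactors = FALSE)
  if (!is.na(model@liabilityThreshold))
    out$binary <- as.integer(y > model@liabilityThreshold)
  out
}

#' Simulate standard covariates for a pedigree cohort
#'
#' Sex taken from the pedigree (coded 0 = F, 1 = M); age in days and body
#' weight in grams drawn from realistic adult-mouse ranges.
#'
#' @param pedigree data.frame with \code{id} and \code{sex} columns.
#' @param seed integer seed.
#' @return data.frame(id, sex, age, bw).
#' @export
simulateCovariates <- function(pedigree, seed = 1L) {
  set.seed(deriveSeed(seed, "covariates"))
  n <- nrow(pedigree)
  data.frame(id = pedigree$id,
             sex = as.integer(pedigree$sex == "M"),
             age = round(stats::runif(n, 80, 120)),
             bw = round(stats::rnorm(n, 26, 3), 1),
             stringsAsFactors = FALSE)
}

#' Select phenotypic extremes plus a random fill
#'
#' Per trait, the most extreme individuals (split between the two tails) are
#' selected; the per-trait selections are pooled and deduplicated; then
#' \code{nRandom} further individuals are added at random from the rest,
#' balancing sexes and cages as far as integer constraints allow. Ties among
#' equally extreme phenotypes are broken by table order (stable).
#'
#' @param phenotypes data.frame with \code{id} and one numeric column per
#'   trait; optionally \code{sex} and \code{cage} used for balancing.
#' @param traits character vector of trait column names.
#' @param nExtremePerTrait extremes requested per trait (both tails).
#' @param nRandom random additions after deduplication.
#' @param seed integer seed for the random fill.
#' @return Character vector of selected ids (extremes first).
#' @export
selectExtremes <- function(phenotypes, traits, nExtremePerTrait, nRandom = 0L,
                           seed = 1L) {
  stopifnot(all(traits %in% names(phenotypes)), "id" %in% names(phenotypes))
  n <- nrow(phenotypes)
  sel <- character(0)
  for (tr in traits) {
    v <- phenotypes[[tr]]
    o <- order(v)  # stable: ties by row order
    nLo <- nExtremePerTrait %/% 2L
    nHi <- nExtremePerTrait - nLo
    take <- c(utils::head(o, nLo), utils::tail(o, nHi))
    sel <- union(sel, phenotypes$id[take])
  }
  if (length(sel) + nRandom > n)
    stop("requested selection exceeds cohort size")
  if (nRandom > 0) {
    set.seed(deriveSeed(seed, "selection"))
    rest <- phenotypes[!(phenotypes$id %in% sel), , drop = FALSE]
    sex <- if ("sex" %in% names(rest)) rest$sex else rep(0L, nrow(rest))
    cage <- if ("cage" %in% names(rest)) rest$cage else rep(1L, nrow(rest))
    selSex <- if ("sex" %in% names(phenotypes))
      phenotypes$sex[phenotypes$id %in% sel] else integer(0)
    cageCount <- table(factor(
      if ("cage" %in% names(phenotypes))
        phenotypes$cage[phenotypes$id %in% sel] else integer(0),
      levels = sort(unique(cage))))
    nSex <- c(sum(selSex == 0), sum(selSex == 1))
    avail <- rep(TRUE, nrow(rest))
    for (k in seq_len(nRandom)) {
      wantSex <- which.min(nSex) - 1L
      cand <- which(avail & sex == wantSex)
      if (!length(cand)) cand <- which(avail)
      # prefer the least-represented cage, random within it
      cc <- cageCount[as.character(cage[cand])]
      cand <- cand[cc == min(cc)]
      pick <- cand[sample.int(length(cand), 1L)]
      avail[pick] <- FALSE
      nSex[sex[pick] + 1L] <- nSex[sex[pick] + 1L] + 1L
      cageCount[as.character(cage[pick])] <- cageCount[as.character(cage[pick])] + 1L
      sel <- c(sel, rest$id[pick])
    }
  }
  sel
}

#' Simulate a complete AIL cohort
#'
#' Convenience wrapper chaining [simulatePedigree()], [simulateGenotypes()]
#' (with hidden pseudomarkers at off-marker QTL positions so trait models
#' may plant QTL anywhere), [simulateCovariates()] and
#' [simulatePhenotypes()] for one or more trait models. All randomness
#' derives from \code{design@seed}.
#'
#' @param design an [AILDesign-class].
#' @param map the observed marker panel as a [GeneticMap-class].
#' @param models named list of [TraitModel-class] objects.
#' @return list with \code{pedigree}, \code{genotypes} (observed markers,
#'   terminal cohort only), \code{phenotypes} (data.frame id, sex, cage,
#'   covariates, one column per trait, binary traits suffixed
#'   \code{"_bin"}), and \code{truth} (the trait models).
#' @export
simulateAILCohort <- function(design, map, models = list()) {
  ped <- simulatePedigree(design)
  mk <- mapMarkers(map)
  # hidden pseudomarkers for off-panel QTL
  extra <- do.call(rbind, lapply(models, function(m) m@qtl[, c("chrom", "cm")]))
  full <- mk
  if (!is.null(extra) && nrow(extra)) {
    extra <- unique(extra)
    have <- paste(mk$chrom, mk$cm)
    extra <- extra[!(paste(extra$chrom, extra$cm) %in% have), , drop = FALSE]
    if (nrow(extra)) {
      if (!all(extra$chrom %in% mk$chrom))
        stop("QTL chromosome absent from the map")
      full <- rbind(mk, data.frame(marker = sprintf("qtl_%d", seq_len(nrow(extra))),
                                   chrom = extra$chrom, cm = extra$cm))
    }
  }
  fullMap <- geneticMap(full$marker, full$chrom, full$cm)
  g <- simulateGenotypes(ped, fullMap, seed = design@seed)
  cohort <- ped$id[ped$generation == design@tFinal]
  gAll <- genotypeCalls(g)[, cohort, drop = FALSE]
  cov <- simulateCovariates(ped[match(cohort, ped$id), ], seed = design@seed)
  phen <- data.frame(id = cohort, sex = cov$sex,
                     cage = ped$cage[match(cohort, ped$id)],
                     age = cov$age, bw = cov$bw, stringsAsFactors = FALSE)
  gFull <- genotypeMatrix(gAll, fullMap)
  for (nm in names(models)) {
    sim <- simulatePhenotypes(gFull, models[[nm]], covariates = cov,
                              seed = deriveSeed(design@seed, nm))
    phen[[nm]] <- sim$value
    if ("binary" %in% names(sim)) phen[[paste0(nm, "_bin")]] <- sim$binary
  }
  obs <- genotypeMatrix(gAll[mk$marker, , drop = FALSE], map)
  list(pedigree = ped, genotypes = obs, phenotypes = phen, truth = models)
}
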