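# Interval mapping: normalization, map conversion, conditional genotype
# probabilities, EM and logistic scans, peak calling, linked-peak
# resolution and effect estimation.

test_that("covariate normalization returns residuals re-centred at the mean", {
  set.seed(1)
  n <- 200
  ph <- data.frame(id = sprintf("i%d", 1:n), sex = rep(0:1, n / 2),
                   age = runif(n, 80, 120))
  ph$y <- 10 + 2 * ph$sex + rnorm(n)

  adj <- normalizePhenotype(ph, "y", c("sex", "age"))
  # planted sex effect removed
  g0 <- adj$value[ph$sex == 0]; g1 <- adj$value[ph$sex == 1]
  seDiff <- sqrt(var(g0) / length(g0) + var(g1) / length(g1))
  expect_lt(abs(mean(g1) - mean(g0)), 3 * seDiff)
  expect_equal(mean(adj$value), mean(ph$y))

  # covariates orthogonal to the trait leave values unchanged
  ph2 <- ph
  ph2$noise <- rep(c(-1, 1), n / 2)
  ph2$y <- rnorm(n)
  ph2$y <- ph2$y - mean(ph2$y) + 5
  ph2$y[ph2$noise == 1] <- ph2$y[ph2$noise == 1] -
    mean(ph2$y[ph2$noise == 1]) + 5     # exactly zero group difference
  ph2$y[ph2$noise == -1] <- ph2$y[ph2$noise == -1] -
    mean(ph2$y[ph2$noise == -1]) + 5
  adj2 <- normalizePhenotype(ph2, "y", "noise")
  expect_equal(adj2$value, ph2$y)

  expect_error(normalizePhenotype(ph, "y", character(0)), "covariates")
  # missing covariates drop individuals with a logged count
  ph$age[1:3] <- NA
  expect_message(res <- normalizePhenotype(ph, "y", c("sex", "age")),
                 "dropped 3")
  expect_equal(nrow(res), n - 3)
})

test_that("map conversion interpolates linearly and refuses extrapolation", {
  expect_equal(convertMap(c(10, 20, 30), c(10, 30), c(10, 30)), c(10, 20, 30))
  expect_equal(convertMap(20, c(10, 30), c(20, 40)), 30)
  # three anchors, unequal slopes: hand-computed piecewise values
  ao <- c(0, 10, 40); an <- c(0, 30, 45)
  expect_equal(convertMap(c(5, 10, 25, 40), ao, an), c(15, 30, 37.5, 45))
  expect_error(convertMap(50, ao, an), "outside")
  expect_error(convertMap(5, c(10, 5), c(0, 1)), "strictly increasing")
})

test_that("conditional genotype probabilities match exhaustive enumeration", {
  map <- geneticMap(c("m1", "m2"), "1", c(0, 2))
  mkGm <- function(gL, gR) genotypeMatrix(
    matrix(c(gL, gR), 2, 1, dimnames = list(c("m1", "m2"), "i1")), map)

  for (t in c(2L, 14L)) {
    R1 <- expectedRecombinantFraction(haldaneR(1), t)
    R2 <- R1
    for (gL in 0:2) for (gR in 0:2) {
      got <- qtlGenotypeProbs(mkGm(gL, gR), "1", 1, t)[1, ]
      expect_equal(unname(got), oracleGenoProbs(gL, gR, R1, R2),
                   tolerance = 1e-12,
                   info = sprintf("t=%d gL=%d gR=%d", t, gL, gR))
      expect_equal(sum(got), 1)
    }
  }
  # at a typed marker the probabilities collapse to the call
  gm <- mkGm(2L, 1L)
  expect_equal(unname(qtlGenotypeProbs(gm, "1", 0, 14)[1, ]), c(0, 0, 1))
  expect_equal(unname(qtlGenotypeProbs(gm, "1", 2, 14)[1, ]), c(0, 1, 0))
  # no informative flank: population prior
  gmNA <- genotypeMatrix(matrix(NA_integer_, 2, 1,
                                dimnames = list(c("m1", "m2"), "i1")), map)
  expect_equal(unname(qtlGenotypeProbs(gmNA, "1", 1, 14)[1, ]),
               c(0.25, 0.5, 0.25))
  expect_error(qtlGenotypeProbs(gm, "1", 5, 14), "outside")
})

test_that("EM LOD equals direct grid maximization on small instances", {
  map <- geneticMap(c("m1", "m2"), "1", c(0, 4))
  for (s in 1:3) {
    set.seed(s)
    n <- 20
    calls <- matrix(sample(0:2, 2 * n, TRUE, c(.25, .5, .25)), 2, n,
                    dimnames = list(c("m1", "m2"), sprintf("i%d", 1:n)))
    gm <- genotypeMatrix(calls, map)
    P <- qtlGenotypeProbs(gm, "1", 2, t = 14)
    y <- (calls[1, ] - 1) * 0.8 + rnorm(n)
    sc <- scanQuantitative(gm, y, t = 14, step = 2, chrom = "1")[["1"]]
    emLod <- lodValues(sc)[lodPositions(sc) == 2]
    expect_equal(emLod, oracleGridLod(y, P), tolerance = 1e-4)
  }
})

test_that("null and planted-QTL scans behave as the likelihood theory predicts", {
  coh <- plantedCohort(a = 0.4, qtlCm = 20, n = 400, seed = 21)
  y <- coh$phenotypes$q

  # planted QTL: peak near the truth
  sc <- scanQuantitative(coh$genotypes, y, t = 14, step = 0.25)[["1"]]
  expect_lt(abs(lodPositions(sc)[which.max(lodValues(sc))] - 20), 4)

  # LOD is invariant to affine transformation of the trait
  sc2 <- scanQuantitative(coh$genotypes, 3.7 * y - 11, t = 14, step = 0.25)[["1"]]
  expect_equal(lodValues(sc), lodValues(sc2), tolerance = 1e-6)

  # null trait: position-wise LOD is small (chi-square_2 scale: median
  # LR = 1.39 => median LOD = 0.30 < 0.5)
  set.seed(22)
  sc0 <- scanQuantitative(coh$genotypes, rnorm(400), t = 14, step = 1)[["1"]]
  expect_lt(median(lodValues(sc0)), 0.5)

  expect_error(scanQuantitative(coh$genotypes, rep(1, 400)), "monomorphic")
})

test_that("binary scan is chi-square calibrated under the null and flags separation", {
  map <- geneticMap(c("m1", "m2"), "1", c(0, 4))
  set.seed(3)
  n <- 300
  calls <- matrix(sample(0:2, 2 * n, TRUE, c(.25, .5, .25)), 2, n,
                  dimnames = list(c("m1", "m2"), sprintf("i%d", 1:n)))
  gm <- genotypeMatrix(calls, map)

  # null: 2*ln(10)*LOD at one position across replicate traits ~ chi^2_2;
  # its mean 2 corresponds to LOD 2/(2 ln 10) = 0.434
  lods <- vapply(1:300, function(i) {
    yb <- rbinom(n, 1, 0.4)
    max(lodValues(scanBinary(gm, yb, t = 14, step = 4, chrom = "1")[["1"]])[2])
  }, numeric(1))
  lr <- 2 * log(10) * lods
  expect_lt(abs(mean(lr) - 2), 3 * sd(lr) / sqrt(length(lr)) + 0.1)

  # perfectly genotype-determined trait: separation cap + flag
  yb <- as.integer(calls[1, ] == 0)
  scSep <- scanBinary(gm, yb, t = 14, step = 4, chrom = "1")[["1"]]
  expect_true("separation" %in% scSep@flags)
  capLod <- scSep@lod[scSep@flags == "separation"][1]
  dev0 <- suppressWarnings(glm(yb ~ 1, family = binomial()))$deviance
  expect_equal(capLod, dev0 / (2 * log(10)))

  expect_error(scanBinary(gm, rep(1L, n)), "single class")

  # planted liability QTL at 34% prevalence: peak lands on the QTL marker
  mapL <- testMap(40)
  mod <- list(li = TraitModel(grandMean = 0,
                              qtl = data.frame(chrom = "1", cm = 20, a = -0.6, d = 0),
                              residualSd = 1,
                              liabilityThreshold = qnorm(1 - 0.34)))
  coh <- simulateAILCohort(AILDesign(48, 14, finalCohortSize = 400, seed = 5),
                           mapL, mod)
  sb <- scanBinary(coh$genotypes, coh$phenotypes$li_bin, t = 14, step = 0.5)[["1"]]
  expect_lt(abs(lodPositions(sb)[which.max(lodValues(sb))] - 20), 5)
})

test_that("peak calling applies the 1-LOD drop-off and flags overlaps", {
  mkCurve <- function(pos, lod) new("LodCurve", chrom = "1", pos = pos,
                                    lod = lod, model = "quantitative",
                                    fixedMarker = NA_character_, t = 14L,
                                    flags = rep("", length(pos)))
  pos <- seq(0, 30, by = 0.25)

  # flat curve: no peaks
  expect_equal(nrow(findPeaks(mkCurve(pos, rep(0, length(pos))))), 0)

  # single peak of 4.4: support interval is the contiguous lod >= 3.4 region
  lod <- 4.4 * exp(-((pos - 15)^2) / 18)
  pk <- findPeaks(mkCurve(pos, lod))
  expect_equal(nrow(pk), 1)
  expect_equal(pk$peakCm, 15)
  inside <- pos >= pk$ciLo & pos <= pk$ciHi
  expect_true(all(lod[inside] >= 4.4 - 1))
  expect_true(lod[max(which(pos < pk$ciLo), 1)] < 3.4)

  # two adjacent peaks (3.1 and 4.4) with overlapping 1-LOD intervals:
  # both returned and flagged as a pair to resolve
  lod2 <- pmax(3.1 * exp(-((pos - 12)^2) / 30), 4.4 * exp(-((pos - 19)^2) / 30))
  pk2 <- findPeaks(mkCurve(pos, lod2))
  expect_equal(nrow(pk2), 2)
  expect_equal(sort(round(pk2$lod, 1)), c(3.1, 4.4))
  expect_true(all(pk2$overlaps != ""))

  # sub-threshold maxima are not reported
  expect_equal(nrow(findPeaks(mkCurve(pos, lod2), threshold = 5)), 0)
})

test_that("fixed-term re-scan distinguishes linked QTL from ghost peaks", {
  map <- testMap(40)
  # two planted QTL 8 cM apart with large effects
  mod2 <- list(q = TraitModel(grandMean = 0,
                              qtl = data.frame(chrom = "1", cm = c(16, 24),
                                               a = c(0.7, 0.7), d = c(0, 0)),
                              residualSd = 1))
  verdicts <- vapply(1:12, function(s) {
    coh <- simulateAILCohort(AILDesign(48, 14, finalCohortSize = 400, seed = 400 + s),
                             map, mod2)
    sc <- scanQuantitative(coh$genotypes, coh$phenotypes$q, t = 14, step = 0.5)[["1"]]
    pk <- findPeaks(sc, 2)
    pk <- pk[order(-pk$lod), , drop = FALSE]
    if (nrow(pk) < 2) return(NA_character_)
    pair <- pk[1:2, ]
    if (pair$overlaps[1] == "")      # support intervals already separate
      return("distinct")
    tryCatch(resolveLinkedPeaks(coh$genotypes, coh$phenotypes$q, pair, t = 14,
                                step = 0.5)$verdict,
             error = function(e) NA_character_)  # CI too narrow to hold a marker
  }, character(1))
  expect_gte(mean(verdicts == "distinct", na.rm = TRUE), 0.8)

  # one planted QTL: any secondary overlapping peak is a ghost and the
  # conditional scan should absorb it
  mod1 <- list(q = TraitModel(grandMean = 0,
                              qtl = data.frame(chrom = "1", cm = 20, a = 0.5, d = 0),
                              residualSd = 1))
  single <- vapply(1:12, function(s) {
    coh <- simulateAILCohort(AILDesign(48, 14, finalCohortSize = 300, seed = 600 + s),
                             map, mod1)
    sc <- scanQuantitative(coh$genotypes, coh$phenotypes$q, t = 14, step = 0.5)[["1"]]
    pk <- findPeaks(sc, 2)
    pk <- pk[order(-pk$lod), , drop = FALSE]
    if (nrow(pk) < 2 || pk$overlaps[1] == "") return("single")
    resolveLinkedPeaks(coh$genotypes, coh$phenotypes$q, pk[1:2, ], t = 14,
                       step = 0.5)$verdict
  }, character(1))
  expect_gte(mean(single == "single"), 0.8)

  # fixing a marker unlinked to the peak barely changes the curve
  coh <- plantedCohort(a = 0.5, qtlCm = 30, n = 400, seed = 77)
  plain <- scanQuantitative(coh$genotypes, coh$phenotypes$q, t = 14, step = 1)[["1"]]
  fixed <- scanQuantitative(coh$genotypes, coh$phenotypes$q, t = 14, step = 1,
                            fixedMarker = "m01")[["1"]]
  sel <- lodPositions(plain) >= 20
  expect_lt(max(abs(lodValues(plain)[sel] - lodValues(fixed)[sel])), 0.75)
})

test_that("effect estimation reproduces the defining arithmetic", {
  # fully informative classes with parental-scale means
  P <- diag(3)[rep(1:3, each = 2), ]
  y <- rep(c(0.60, 0.865, 1.13), each = 2)
  est <- estimateEffects(P, y, parentalMeans = c(Q = 1.13, q = 0.60))
  expect_equal(est$aQtl, 0.265)
  expect_equal(est$dQtl, 0)            # heterozygote at the midpoint
  expect_equal(est$attributablePct, 50)
  expect_equal(est$direction, "normal")

  # equal homozygote means: no additive effect
  est0 <- estimateEffects(P, rep(c(1, 2, 1), each = 2))
  expect_equal(est0$aQtl, 0)
  expect_equal(est0$dQtl, 1)

  # cryptic direction: the allele from the low-trait strain increases it
  estC <- estimateEffects(P, rep(c(1.13, 0.865, 0.60), each = 2),
                          parentalMeans = c(Q = 1.13, q = 0.60))
  expect_equal(estC$direction, "cryptic")

  expect_error(estimateEffects(diag(3)[c(1, 1, 2, 2), ], rep(1, 4)),
               "zero expected count")
})

test_that("standardized parental difference follows Table-1-style inputs", {
  expect_equal(round(standardizedDifference(1.13, 0.60, 0.11), 1), 4.8)
  expect_error(standardizedDifference(1, 0, 0), "positive")
})
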