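# End-to-end pipeline over a simulated cohort: breeding simulation, trait
# normalization, LOD scans, peak calling and resolution, variant density
# segmentation, candidate filtering, network permutation and feature
# enrichment, with deterministic sub-seeding and stamped artifacts.

pipelineDefaults <- function() list(
  seed = 1L,
  t = 14L,                 # terminal AIL generation
  nPairs = 48L,            # breeding pairs per generation
  finalCohortSize = 400L,  # phenotyped terminal cohort
  step = 0.25,             # scan step, cM
  lodThreshold = 2.0,      # AIL significance threshold
  f2Significant = 4.3,     # classical F2 thresholds (reported alongside)
  f2Suggestive = 2.8,
  binSize = 6e5,           # density bin, bp
  densityCutoff = 1000,    # variants per bin
  networkPermutations = 1000L,   # scaled-down default; study-scale is 1e5
  enrichmentShuffles = 200L,     # scaled-down default; study-scale is 1000
  minScore = 700,          # network combined-score threshold (strict >)
  cpmThreshold = 1,        # expressed-gene rule: CPM > 1 in >= minSamples
  minSamples = 2L,
  bpPerCm = 2e6,           # linear cM -> bp conversion for simulated QTL
  outDir = NULL            # if set, artifacts are written there
)

#' Build and validate a pipeline configuration
#'
#' Returns the default configuration (every default anchored to the study's
#' printed analysis values: 0.25 cM step, LOD 2 threshold, F2 4.3/2.8,
#' 600 kb bins, cutoff 1000, score 700, CPM > 1 in >= 2 samples; the two
#' permutation counts default to scaled-down values suitable for desk runs
#' and can be raised to the study-scale 100,000 / 1000) with the supplied
#' overrides applied. Unknown keys are an error before any computation.
#'
#' @param ... named overrides of the defaults.
#' @return Named list configuration.
#' @export
pipelineConfig <- function(...) {
  cfg <- pipelineDefaults()
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' Simulates an AIL cohort with three planted quantitative QTL and a
#' liability-threshold binary trait, runs the quantitative and binary
#' scans, calls peaks with 1-LOD support intervals, resolves overlapping
#' peak pairs with fixed-term re-scans, estimates effects, and carries the
#' QTL intervals through the downstream stages (variant density
#' segmentation, candidate filtering, network permutation, feature
#' enrichment) on synthetic fixtures generated from the same seed. Re-run
#' with an identical configuration, every artifact is byte-identical.
#'
#' @param config a [pipelineConfig()] list.
#' @return list of stage results (see names); artifacts are additionally
#'   written to \code{config$outDir} when set.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  stopifnot(identical(sort(names(config)), sort(names(pipelineDefaults()))))
  seed <- config$seed

  # --- stage: simulate -----------------------------------------------------
  map <- geneticMap(sprintf("m%02d", 1:26), "1", seq(0, 50, by = 2))
  models <- list(
    fvl = TraitModel(grandMean = 1.0,
                     qtl = data.frame(chrom = "1", cm = c(10, 34), a = c(0.08, 0.06),
                                      d = c(0, 0.02)),
                     residualSd = 0.16,
                     covariateEffects = c(bw = 0.002)),
    fow = TraitModel(grandMean = 0.24,
                     qtl = data.frame(chrom = "1", cm = 24, a = -0.03, d = 0),
                     residualSd = 0.07),
    pfoLiab = TraitModel(grandMean = 0,
                         qtl = data.frame(chrom = "1", cm = 10, a = -0.5, d = 0),
                         residualSd = 1,
                         liabilityThreshold = stats::qnorm(1 - 0.34))
  )
  design <- AILDesign(nPairs = config$nPairs, tFinal = config$t,
                      finalCohortSize = config$finalCohortSize,
                      seed = deriveSeed(seed, "cohort"))
  cohort <- simulateAILCohort(design, map, models)
  phen <- cohort$phenotypes

  # --- stage: normalize + scans -------------------------------------------
  adj <- normalizePhenotype(phen, "fvl", c("sex", "age", "bw"))
  traitVals <- adj$value[match(phen$id, adj$id)]
  scans <- list(
    fvl = scanQuantitative(cohort$genotypes, traitVals, t = config$t,
                           step = config$step)[["1"]],
    fow = scanQuantitative(cohort$genotypes, phen$fow, t = config$t,
                           step = config$step)[["1"]],
    pfo = scanBinary(cohort$genotypes, phen$pfoLiab_bin, t = config$t,
                     step = config$step)[["1"]]
  )

  # --- stage: peaks + resolution + effects ---------------------------------
  peaks <- list()
  for (tr in names(scans)) {
    pk <- findPeaks(scans[[tr]], threshold = config$lodThreshold)
    if (nrow(pk)) {
      pk$trait <- tr
      pk$verdict <- ""
      flagged <- which(pk$overlaps != "")
      if (length(flagged) >= 2) {
        pair <- pk[flagged[1:2], ]
        y <- if (tr == "pfo") phen$pfoLiab_bin else
          if (tr == "fvl") traitVals else phen[[tr]]
        res <- resolveLinkedPeaks(cohort$genotypes, y, pair, t = config$t,
                                  step = config$step,
                                  threshold = config$lodThreshold,
                                  binary = tr == "pfo")
        pk$verdict[flagged[1:2]] <- res$verdict
      }
      eff <- lapply(seq_len(nrow(pk)), function(i) {
        P <- qtlGenotypeProbs(cohort$genotypes, pk$chrom[i], pk$peakCm[i], config$t)
        y <- if (tr == "pfo") phen$pfoLiab_bin else
          if (tr == "fvl") traitVals else phen[[tr]]
        estimateEffects(P, y)
      })
      pk$aQtl <- vapply(eff, `[[`, 0, "aQtl")
      pk$dQtl <- vapply(eff, `[[`, 0, "dQtl")
      peaks[[tr]] <- pk
    }
  }
  peaks <- if (length(peaks)) do.call(rbind, peaks) else emptyPeaks()

  # --- stage: QTL intervals in bp (linear cM -> bp conversion) -------------
  qtlGr <- if (nrow(peaks))
    reduce(GRanges("chr1", IRanges(pmax(1, peaks$ciLo * config$bpPerCm),
                                   pmax(1, peaks$ciHi * config$bpPerCm))))
  else GRanges()

  # --- stage: variants, density, candidates --------------------------------
  fx <- synthFixtures(seed = deriveSeed(seed, "fixtures"))
  hq <- filterHighQuality(fx$variants)
  profile <- binDensity(hq, fx$meta$genome, config$binSize)
  segments <- classifyDensity(profile, config$densityCutoff)
  nQ <- max(1, length(qtlGr))
  qtlVar <- GRanges(rep(names(fx$meta$genome), length.out = nQ),
                    IRanges(start = round(seq(1e6, 2e7, length.out = nQ)),
                            width = 8e6))
  narrowed <- intersectQtl(qtlVar, segments)
  expr <- expressedGenes(fx$counts, config$cpmThreshold, config$minSamples)
  cand <- filterCandidates(hq, qtlVar, expr, segments)

  # --- stage: network permutation ------------------------------------------
  net <- geneNetwork(fx$edges, config$minScore)
  perm <- permutationTest(net, fx$meta$community, expr,
                          n = config$networkPermutations,
                          seed = deriveSeed(seed, "netperm"))
  cent <- centralityRanking(buildSubnetwork(net, fx$meta$community))

  # --- stage: feature enrichment -------------------------------------------
  prom <- definePromoters(data.frame(gene = fx$genes$gene, chrom = fx$genes$chrom,
                                     tss = fx$genes$tss, strand = fx$genes$strand),
                          genome = fx$meta$genome)
  enr <- shuffleNull(hq, prom, qtlVar, n = config$enrichmentShuffles,
                     seed = deriveSeed(seed, "enrich"))

  out <- list(config = config, cohort = cohort, scans = scans, peaks = peaks,
              qtlGr = qtlGr, segments = segments, narrowed = narrowed,
              candidates = cand, permutation = perm, centrality = cent,
              enrichment = enr)

  if (!is.null(config$outDir)) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    o <- function(f) file.path(config$outDir, f)
    for (tr in names(scans)) writeLodCurve(scans[[tr]], o(sprintf("lod_%s.tsv", tr)))
    writeTsv(peaks, o("peaks.tsv"))
    writeBed(segments, o("segments.bed"))
    writeTsv(cand$candidates, o("candidates.tsv"))
    writeTsv(cent, o("centrality.tsv"))
    jsonlite::write_json(list(
      seed = seed,
      parameters = config[setdiff(names(config), "outDir")],
      narrowed = narrowed[c("mbBefore", "mbAfter", "pctRetained")],
      candidates = cand[c("pctInHighDensity", "perQtlAverage", "nQtl")],
      network = list(observedEdges = perm$observed$nEdges,
                     nullMeanEdges = perm$edges$nullMean,
                     nullSdEdges = perm$edges$nullSd,
                     pEdges = perm$edges$pLabel,
                     observedClustering = perm$observed$avgClustering,
                     pClustering = perm$clustering$pLabel),
      enrichment = enr[c("observed", "normalizedEnrichment", "nullMean", "p")]
    ), o("summary.json"), auto_unbox = TRUE, digits = 8, pretty = TRUE)
  }
  out
}
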