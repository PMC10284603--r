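# Variant quality filtering, density binning/segmentation, QTL narrowing,
# expressed-gene rule and candidate filtering.

library(GenomicRanges)

mkVar <- function(chrom, pos, depth = 30, fdr = 0.01, gtA = "hom_alt",
                  gtB = "hom_ref", effectClass = "other", gene = "gX") {
  data.frame(chrom = chrom, pos = pos, depth = depth, fdr = fdr,
             gtA = gtA, gtB = gtB, effectClass = effectClass, gene = gene,
             stringsAsFactors = FALSE)
}

test_that("quality filter applies depth, FDR and zygosity rules", {
  v <- rbind(
    mkVar("c1", 100, depth = 7),                        # depth below 8
    mkVar("c1", 200, depth = 8),                        # inclusive depth kept
    mkVar("c1", 300, fdr = 0.11),                       # FDR above 10%
    mkVar("c1", 400, fdr = 0.10),                       # inclusive FDR kept
    mkVar("c1", 500, gtA = "het", gtB = "het"),         # no homozygous line
    mkVar("c1", 600, gtA = "hom_alt", gtB = "hom_alt"), # both lines alt
    mkVar("c1", 700, gtA = "hom_ref", gtB = "hom_alt"), # kept, strain B
    mkVar("c1", 800, gtA = "hom_alt", gtB = "het"),     # kept, strain A
    mkVar("c1", 900, gtA = "oops", gtB = "hom_ref")     # malformed
  )
  f <- filterHighQuality(v)
  expect_setequal(f$pos, c(200, 400, 700, 800))
  expect_equal(f$strain[f$pos == 700], "B")
  expect_equal(f$strain[f$pos == 800], "A")
  rej <- attr(f, "rejections")
  expect_equal(unname(rej["malformed"]), 1)
  expect_equal(unname(rej["depth"]), 1)
  expect_equal(unname(rej["fdr"]), 1)
  expect_equal(unname(rej["zygosity"]), 2)
})

test_that("binning tiles the genome and counts every variant exactly once", {
  genome <- c(c1 = 1500, c2 = 1000)
  # no variants: all-zero bins
  p0 <- binDensity(data.frame(chrom = character(0), pos = numeric(0)),
                   genome, 600)
  expect_true(all(p0$count == 0))
  expect_equal(nrow(p0), 3 + 2)
  expect_equal(p0$end[3], 1500)          # terminal partial bin keeps width

  # single variant lands in exactly one bin
  p1 <- binDensity(mkVar("c1", 601), genome, 600)
  expect_equal(sum(p1$count), 1)
  expect_equal(p1$count[p1$chrom == "c1" & p1$start == 600], 1)

  # total bin counts equal the variant count
  set.seed(1)
  v <- mkVar("c1", sample(1500, 200, TRUE))
  expect_equal(sum(binDensity(v, genome, 600)$count), 200)
  expect_error(binDensity(v, genome, 0), "positive")
})

test_that("planted low/high blocks give a bimodal profile and are recovered", {
  fx <- synthFixtures(seed = 5)
  prof <- binDensity(fx$variants, fx$meta$genome, 6e5)
  diag <- bimodalityDiagnostic(prof)
  expect_gt(diag$depth, 0)
  expect_true(diag$antimodeCount > 5 && diag$antimodeCount < 2000)

  segs <- classifyDensity(prof, cutoff = 1000)
  truth <- GRanges(fx$meta$blocks$chrom,
                   IRanges(fx$meta$blocks$start + 1, fx$meta$blocks$end))
  # every planted block recovered within one bin width on each side
  hits <- findOverlaps(truth, segs)
  expect_equal(length(unique(queryHits(hits))), length(truth))
  for (i in seq_along(truth)) {
    s <- segs[subjectHits(hits)[queryHits(hits) == i]]
    expect_lte(abs(min(start(s)) - start(truth[i])), 6e5)
    expect_lte(abs(max(end(s)) - end(truth[i])), 6e5)
  }
  # segment length accounting: high bins x bin size minus terminal truncation
  nHigh <- sum(prof$count >= 1000)
  truncation <- sum((prof$end - prof$start)[prof$count >= 1000] - 6e5)
  expect_equal(sum(width(segs)), nHigh * 6e5 + truncation)

  # the bin-size sweep scores 600 kb as clearly bimodal
  sw <- densitySweep(fx$variants, fx$meta$genome, c(1e5, 6e5))
  expect_true(all(sw$depth > 0))
})

test_that("density cutoff is inclusive and empty classifications are empty", {
  prof <- data.frame(chrom = "c1", start = c(0, 600, 1200),
                     end = c(600, 1200, 1800), count = c(999, 1000, 10))
  segs <- classifyDensity(prof, cutoff = 1000)
  expect_equal(length(segs), 1)
  expect_equal(start(segs), 601)        # the count-1000 bin is high density
  expect_equal(length(classifyDensity(prof, cutoff = 2000)), 0)
})

test_that("QTL narrowing reports interval intersection percentages", {
  # printed-aggregate scale: 264.1 Mb of QTL, 109.5 Mb retained -> 41.5%
  qtl <- GRanges("c1", IRanges(1, width = 264.1e6))
  segs <- GRanges("c1", IRanges(1, width = 109.5e6))
  res <- intersectQtl(qtl, segs)
  expect_equal(res$mbBefore, 264.1)
  expect_equal(res$mbAfter, 109.5)
  expect_equal(round(res$pctRetained, 1), 41.5)

  # disjoint and covering cases
  expect_equal(intersectQtl(GRanges("c1", IRanges(1, 10)),
                            GRanges("c1", IRanges(100, 200)))$pctRetained, 0)
  expect_equal(intersectQtl(GRanges("c1", IRanges(50, 99)),
                            GRanges("c1", IRanges(1, 1000)))$pctRetained, 100)
  expect_error(intersectQtl(GRanges(), segs), "empty")
  # intersection length bounded by both sets
  expect_lte(res$mbAfter, min(res$mbBefore, sum(width(segs)) / 1e6))
})

test_that("expressed-gene rule is CPM > 1 in at least two samples", {
  # library size fixed at 1e6 per sample so CPM equals the raw count
  counts <- rbind(
    onTwo = c(2, 2, 0, 0),    # CPM 2 in exactly two samples -> expressed
    onOne = c(5, 0, 0, 0),    # CPM 5 in one sample only -> not expressed
    atOne = c(1, 1, 1, 1),    # CPM exactly 1: the rule is strict -> not
    zero = c(0, 0, 0, 0)
  )
  colnames(counts) <- paste0("s", 1:4)
  counts <- rbind(counts, filler = 1e6 - colSums(counts))

  expr <- expressedGenes(counts)
  expect_true("onTwo" %in% expr)
  expect_false("onOne" %in% expr)
  expect_false("atOne" %in% expr)
  expect_false("zero" %in% expr)
  # an all-zero count matrix has zero library sizes, which is an error
  z <- matrix(0L, 2, 3, dimnames = list(c("a", "b"), NULL))
  expect_error(expressedGenes(z), "library size")
  # genes all zero against a non-zero library: none expressed
  z2 <- rbind(a = c(0L, 0L, 0L), b = c(0L, 0L, 0L), filler = c(10L, 10L, 10L))
  expect_equal(setdiff(expressedGenes(z2), "filler"), character(0))
})

test_that("candidate filtering is order-independent and sums the study arithmetic", {
  set.seed(8)
  qtl <- GRanges("c1", IRanges(c(1, 5e6), width = 2e6))
  segs <- GRanges("c1", IRanges(1, width = 1.5e6))
  v <- rbind(
    mkVar("c1", round(runif(30, 1, 2e6)), effectClass = "high_impact", gene = "gIn"),
    mkVar("c1", round(runif(10, 5e6, 6e6)), effectClass = "deleterious_missense",
          gene = "gIn2"),
    mkVar("c1", round(runif(10, 1, 2e6)), effectClass = "other", gene = "gIn"),
    mkVar("c1", round(runif(10, 3e6, 4e6)), effectClass = "high_impact",
          gene = "gOut"),           # outside QTL
    mkVar("c1", round(runif(10, 1, 2e6)), effectClass = "high_impact",
          gene = "gSilent")         # not expressed
  )
  v <- filterHighQuality(v)
  expressed <- c("gIn", "gIn2")
  res <- filterCandidates(v, qtl, expressed, segs)
  expect_equal(nrow(res$candidates), 40)
  expect_equal(res$nQtl, 2)
  expect_equal(res$perQtlAverage, 20)
  expect_true(all(res$candidates$gene %in% expressed))

  # order independence: QTL restriction before vs after class filtering
  inQtl <- v[countOverlaps(GRanges(v$chrom, IRanges(v$pos, width = 1)), qtl) > 0, ]
  res2 <- filterCandidates(inQtl, qtl, expressed, segs)
  o1 <- res$candidates[order(res$candidates$pos), c("chrom", "pos", "gene")]
  o2 <- res2$candidates[order(res2$candidates$pos), c("chrom", "pos", "gene")]
  rownames(o1) <- rownames(o2) <- NULL
  expect_identical(o1, o2)

  # printed-count arithmetic: 84 of 92 in high-density -> 91.3%
  expect_equal(round(100 * 84 / 92, 1), 91.3)
  expect_equal(round(92 / 37, 1), 2.5)
  # and the package computes the same fractions from tables
  frac <- res$pctInHighDensity
  inSeg <- sum(countOverlaps(GRanges(res$candidates$chrom,
                                     IRanges(res$candidates$pos, width = 1)),
                             segs) > 0)
  expect_equal(frac, 100 * inSeg / nrow(res$candidates))

  # no variants inside QTL: empty table, zero summaries
  none <- filterCandidates(v[v$pos > 3e6 & v$pos < 4e6, ], qtl, expressed, segs)
  expect_equal(nrow(none$candidates), 0)
  expect_equal(none$pctInHighDensity, 0)
})
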