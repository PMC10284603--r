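# Strain-difference variant filtering, genome binning, low/high density
# segmentation and candidate-variant prioritisation.

#' @importFrom GenomicRanges GRanges reduce intersect width seqnames start end findOverlaps countOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
NULL

#' Filter variants to the high-quality strain-difference set
#'
#' Keeps variants with sequencing depth >= 8, estimated FDR <= 10%, and the
#' informative zygosity pattern: homozygous-alternate in exactly one strain
#' with a reference or heterozygous call in the other. Counts of each
#' rejection reason are attached as attribute \code{"rejections"}.
#'
#' @param variants data.frame with columns \code{depth}, \code{fdr},
#'   \code{gtA}, \code{gtB} (zygosity in \{hom_ref, het, hom_alt,
#'   missing\}); other columns pass through.
#' @param minDepth,maxFdr filter thresholds (defaults 8 and 0.10).
#' @return The retained rows, with a rejection-reason tally attached.
#' @export
filterHighQuality <- function(variants, minDepth = 8, maxFdr = 0.10) {
  need <- c("depth", "fdr", "gtA", "gtB")
  stopifnot(all(need %in% names(variants)))
  zyg <- c("hom_ref", "het", "hom_alt", "missing")
  malformed <- !(variants$gtA %in% zyg) | !(variants$gtB %in% zyg)
  lowDepth <- !malformed & variants$depth < minDepth
  highFdr <- !malformed & !lowDepth & variants$fdr > maxFdr
  homA <- variants$gtA == "hom_alt"
  homB <- variants$gtB == "hom_alt"
  other <- ifelse(homA, variants$gtB, variants$gtA)
  goodZyg <- xor(homA, homB) & other %in% c("hom_ref", "het")
  badZyg <- !malformed & !lowDepth & !highFdr & !goodZyg
  keep <- !malformed & !lowDepth & !highFdr & goodZyg
  out <- variants[keep, , drop = FALSE]
  out$strain <- ifelse(homA[keep], "A", "B")   # which line carries the alt allele
  attr(out, "rejections") <- c(malformed = sum(malformed),
                               depth = sum(lowDepth),
                               fdr = sum(highFdr),
                               zygosity = sum(badZyg))
  out
}

#' Bin variant counts across a genome
#'
#' Tiles each chromosome with non-overlapping bins from position 0 and
#' counts variants per bin; the terminal partial bin keeps its true width.
#'
#' @param variants data.frame with \code{chrom} and \code{pos} (1-based).
#' @param genome named numeric vector of chromosome lengths (bp).
#' @param binSize bin width in bp (> 0).
#' @return data.frame(chrom, start, end, count) covering the genome
#'   (0-based half-open bins), with \code{binSize} attached as an
#'   attribute.
#' @export
binDensity <- function(variants, genome, binSize) {
  if (binSize <= 0) stop("binSize must be positive")
  rows <- lapply(names(genome), function(chr) {
    len <- genome[[chr]]
    starts <- seq(0, max(0, len - 1), by = binSize)
    ends <- pmin(starts + binSize, len)
    pos <- variants$pos[variants$chrom == chr]
    cnt <- if (length(pos))
      tabulate(pmin(length(starts), (pos - 1) %/% binSize + 1L), length(starts))
    else integer(length(starts))
    data.frame(chrom = chr, start = starts, end = ends, count = cnt,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "binSize") <- binSize
  out
}

#' Bimodality diagnostic of a density profile
#'
#' Smooths the per-bin count histogram (on log10(count + 1)) and measures
#' the depth of the antimode between the two largest modes: the height
#' of the smaller mode minus the density at the valley, both on the density
#' scale (0 when the distribution is unimodal). The bin size whose profile
#' maximises this depth separates low- from high-density genome segments
#' most clearly.
#'
#' @param profile output of [binDensity()].
#' @return list(depth, antimodeCount = the count value at the valley, or NA
#'   when unimodal).
#' @export
bimodalityDiagnostic <- function(profile) {
  x <- log10(profile$count + 1)
  d <- stats::density(x, n = 512)
  y <- d$y
  pk <- which(diff(sign(diff(y))) == -2) + 1L
  if (length(pk) < 2) return(list(depth = 0, antimodeCount = NA_real_))
  top2 <- pk[order(y[pk], decreasing = TRUE)][1:2]
  top2 <- sort(top2)
  valley <- which.min(y[top2[1]:top2[2]]) + top2[1] - 1L
  list(depth = min(y[top2]) - y[valley],
       antimodeCount = 10^d$x[valley] - 1)
}

#' Sweep bin sizes and score bimodality
#'
#' @param variants,genome as in [binDensity()].
#' @param binSizes bin widths to try (default 50 kb to 1.1 Mb in 50 kb
#'   steps, the conventional sweep).
#' @return data.frame(binSize, depth, antimodeCount).
#' @export
densitySweep <- function(variants, genome,
                         binSizes = seq(50e3, 1.1e6, by = 50e3)) {
  rows <- lapply(binSizes, function(b) {
    diag <- bimodalityDiagnostic(binDensity(variants, genome, b))
    data.frame(binSize = b, depth = diag$depth,
               antimodeCount = diag$antimodeCount)
  })
  do.call(rbind, rows)
}

#' Classify high-variant-density genome segments
#'
#' Bins with count >= cutoff (inclusive) are high density; maximal runs of
#' adjacent high bins are merged into segments.
#'
#' @param profile output of [binDensity()].
#' @param cutoff variants per bin (default 1000, the conventional cutoff at
#'   600 kb bins).
#' @return [GenomicRanges::GRanges] of high-density segments (0-based
#'   half-open coordinates kept in \code{start0}/\code{end0} notation via
#'   \code{start = start0 + 1}).
#' @export
classifyDensity <- function(profile, cutoff = 1000) {
  hi <- profile[profile$count >= cutoff, , drop = FALSE]
  if (!nrow(hi))
    return(GRanges())
  gr <- GRanges(hi$chrom, IRanges(hi$start + 1, hi$end))
  reduce(gr)
}

#' Intersect QTL intervals with density segments
#'
#' Standard interval intersection plus the headline summary: total length
#' before, after, and the percentage retained.
#'
#' @param qtl [GenomicRanges::GRanges] of QTL support intervals (must be
#'   non-empty).
#' @param segments [GenomicRanges::GRanges] of (high-density) segments.
#' @return list(retained = GRanges, mbBefore, mbAfter, pctRetained).
#' @export
intersectQtl <- function(qtl, segments) {
  if (length(qtl) == 0) stop("empty QTL interval set")
  ret <- suppressWarnings(GenomicRanges::intersect(reduce(qtl), reduce(segments),
                                  ignore.strand = TRUE))
  before <- sum(width(reduce(qtl)))
  after <- sum(width(ret))
  list(retained = ret,
       mbBefore = before / 1e6, mbAfter = after / 1e6,
       pctRetained = if (before > 0) 100 * after / before else NA_real_)
}

#' Expressed-gene set from a count matrix
#'
#' A gene is expressed if its counts-per-million exceeds 1 (strictly) in at
#' least two samples; CPM = 1e6 * count / library size.
#'
#' @param counts non-negative count matrix, genes x samples (>= 2 samples).
#' @param cpmThreshold,minSamples rule parameters (defaults 1 and 2).
#' @return Character vector of expressed gene names.
#' @export
expressedGenes <- function(counts, cpmThreshold = 1, minSamples = 2L) {
  stopifnot(ncol(counts) >= 2L, all(counts >= 0))
  lib <- colSums(counts)
  if (any(lib == 0)) stop("zero library size in sample(s): ",
                          paste(colnames(counts)[lib == 0], collapse = ", "))
  cpm <- sweep(counts, 2, lib, "/") * 1e6
  rownames(counts)[rowSums(cpm > cpmThreshold) >= minSamples]
}

#' Candidate-variant filtering under QTL
#'
#' From a high-quality variant table, keeps variants that (i) fall inside a
#' QTL support interval, (ii) lie in an expressed gene, and (iii) carry a
#' damaging effect class (high impact, SIFT-deleterious missense, or
#' non-frameshift deletion). Returns the candidate table with the summary
#' arithmetic of the study: per-gene and per-strain tallies, the fraction
#' of candidates inside high-density segments, and the average number of
#' candidates per QTL.
#'
#' @param variants filtered variant data.frame with \code{chrom},
#'   \code{pos}, \code{gene}, \code{effectClass} and (from
#'   [filterHighQuality()]) \code{strain}.
#' @param qtl [GenomicRanges::GRanges] of QTL intervals.
#' @param expressed character vector of expressed genes.
#' @param segments optional high-density segment GRanges for the
#'   in-segment fraction.
#' @param damagingClasses effect classes considered damaging.
#' @return list(candidates, perGene, perStrain, pctInHighDensity,
#'   perQtlAverage, nQtl).
#' @export
filterCandidates <- function(variants, qtl, expressed, segments = NULL,
                             damagingClasses = c("high_impact",
                                                 "deleterious_missense",
                                                 "nonframeshift_deletion")) {
  keep <- variants$effectClass %in% damagingClasses &
    variants$gene %in% expressed
  v <- variants[keep, , drop = FALSE]
  if (nrow(v)) {
    gr <- GRanges(v$chrom, IRanges(v$pos, width = 1))
    v <- v[countOverlaps(gr, qtl) > 0, , drop = FALSE]
  }
  nQtl <- length(reduce(qtl))
  pctHD <- NA_real_
  if (!is.null(segments) && nrow(v)) {
    gr <- GRanges(v$chrom, IRanges(v$pos, width = 1))
    pctHD <- 100 * mean(countOverlaps(gr, segments) > 0)
  } else if (!is.null(segments)) pctHD <- 0
  perStrain <- if (nrow(v) && "strain" %in% names(v)) {
    do.call(rbind, lapply(split(v, v$strain), function(d)
      data.frame(strain = d$strain[1], nVariants = nrow(d),
                 nGenes = length(unique(d$gene)))))
  } else NULL
  list(candidates = v,
       perGene = if (nrow(v)) sort(table(v$gene), decreasing = TRUE) else table(character(0)),
       perStrain = perStrain,
       pctInHighDensity = pctHD,
       perQtlAverage = if (nQtl > 0) nrow(v) / nQtl else NA_real_,
       nQtl = nQtl)
}
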