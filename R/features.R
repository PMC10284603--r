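# Variant enrichment in genomic features under QTL, with length-matched
# interval-shuffle permutation nulls.

#' @importFrom GenomicRanges GRanges setdiff strand resize shift
NULL

#' Promoter intervals from a TSS table
#'
#' A promoter is the window from 1000 bp upstream to 100 bp downstream of
#' the transcription start site, on the gene's strand: a plus-strand TSS at
#' p gives the 0-based half-open interval [p - 1000, p + 100); minus-strand
#' promoters are mirrored; intervals are clipped at chromosome bounds.
#'
#' @param tss data.frame(gene, chrom, tss, strand) with strand "+" or "-";
#'   \code{tss} is a 0-based coordinate.
#' @param genome named lengths for clipping (optional).
#' @param upstream,downstream window sizes in bp (defaults 1000 and 100).
#' @return [GenomicRanges::GRanges] of promoters (1-based internally),
#'   with 0-based starts recoverable as \code{start - 1}.
#' @export
definePromoters <- function(tss, genome = NULL, upstream = 1000, downstream = 100) {
  stopifnot(all(c("chrom", "tss", "strand") %in% names(tss)))
  if (anyNA(tss$strand) || !all(tss$strand %in% c("+", "-")))
    stop("every TSS needs a '+' or '-' strand")
  plus <- tss$strand == "+"
  start0 <- ifelse(plus, tss$tss - upstream, tss$tss - downstream)
  end0 <- ifelse(plus, tss$tss + downstream, tss$tss + upstream)
  start0 <- pmax(start0, 0)
  if (!is.null(genome)) end0 <- pmin(end0, genome[tss$chrom])
  gr <- GRanges(tss$chrom, IRanges(start0 + 1, end0))
  if ("gene" %in% names(tss)) names(gr) <- tss$gene
  gr
}

#' Candidate enhancer intervals from histone-mark regions
#'
#' Enhancers are regions positive for H3K4me1 and/or H3K27ac, negative for
#' H3K4me3 (any overlap with an H3K4me3 region excludes the interval), and
#' lying within a window of \code{windowKb} kilobases on either side of a
#' gene-set TSS.
#'
#' @param h3k4me1,h3k27ac,h3k4me3 [GenomicRanges::GRanges] of mark regions.
#' @param tss data.frame(chrom, tss) of the gene set's TSS (0-based).
#' @param windowKb window half-size in kb (the conventional sweep is
#'   50-250 kb).
#' @return [GenomicRanges::GRanges] of enhancer candidates.
#' @export
defineEnhancers <- function(h3k4me1, h3k27ac, h3k4me3, tss, windowKb = 50) {
  marks <- Filter(length, list(h3k4me1, h3k27ac))
  if (!length(marks)) return(GRanges())
  cand <- reduce(suppressWarnings(do.call(c, marks)))
  if (length(h3k4me3))
    cand <- cand[countOverlaps(cand, h3k4me3) == 0]
  if (!length(cand)) return(cand)
  w <- windowKb * 1000
  win <- GRanges(tss$chrom, IRanges(pmax(tss$tss - w, 0) + 1, tss$tss + w))
  cand[countOverlaps(cand, win) > 0]
}

#' Observed variant enrichment in a feature within QTL regions
#'
#' Restricts variants to the QTL regions, counts those falling in the
#' feature, and normalizes the variant proportion by the proportion of QTL
#' length the feature covers:
#' \deqn{E = \frac{\mathrm{obs} / n_{QTL}}{|F \cap QTL| / |QTL|}}
#' so a feature covering all of the QTL has enrichment exactly 1, as does
#' (in expectation) a uniformly scattered variant set.
#'
#' @param variants GRanges of variant positions (width-1), or a data.frame
#'   with \code{chrom}, \code{pos}.
#' @param feature feature [GenomicRanges::GRanges].
#' @param qtl QTL region [GenomicRanges::GRanges].
#' @return list(observed, nVariantsInQtl, normalizedEnrichment,
#'   featureCoverage, flag) - \code{flag} marks undefined enrichment
#'   (feature does not intersect the QTL).
#' @export
featureEnrichment <- function(variants, feature, qtl) {
  v <- asPositions(variants)
  qtl <- reduce(qtl)
  v <- v[countOverlaps(v, qtl) > 0]
  fin <- suppressWarnings(GenomicRanges::intersect(reduce(feature), qtl, ignore.strand = TRUE))
  obs <- sum(countOverlaps(v, fin) > 0)
  cov <- sum(width(fin)) / sum(width(qtl))
  if (cov == 0)
    return(list(observed = obs, nVariantsInQtl = length(v),
                normalizedEnrichment = NA_real_, featureCoverage = 0,
                flag = "feature does not intersect QTL"))
  enr <- if (length(v)) (obs / length(v)) / cov else 0
  list(observed = obs, nVariantsInQtl = length(v),
       normalizedEnrichment = enr, featureCoverage = cov, flag = "")
}

asPositions <- function(variants) {
  if (is(variants, "GRanges")) return(variants)
  GRanges(variants$chrom, IRanges(variants$pos, width = 1))
}

# place length-matched intervals uniformly at random inside `space`
# (a GRanges of allowed gaps), without overlap among placed intervals.
# Widths placed longest-first. Gap bookkeeping is done on plain numeric
# vectors (a placement splits one gap into at most two), which keeps the
# shuffle fast enough for permutation use.
placeIntervals <- function(widths, space) {
  p <- placeIntervalsNum(widths, as.character(seqnames(reduce(space))),
                         start(reduce(space)), end(reduce(space)))
  GRanges(p$chr, IRanges(p$start, width = p$width))
}

placeIntervalsNum <- function(widths, gChr, gS, gE) {
  pChr <- character(length(widths))
  pS <- integer(length(widths))
  k <- 0L
  for (w in sort(as.integer(widths), decreasing = TRUE)) {
    slots <- gE - gS + 2L - w        # start positions available per gap
    ok <- which(slots >= 1L)
    if (!length(ok))
      stop(sprintf("cannot place a %d bp interval in the remaining shuffle space", w))
    pick <- if (length(ok) == 1L) ok else
      ok[sample.int(length(ok), 1L, prob = slots[ok])]
    off <- sample.int(slots[pick], 1L) - 1L
    s <- gS[pick] + off
    k <- k + 1L
    pChr[k] <- gChr[pick]; pS[k] <- s
    # split the host gap around the placement
    lftS <- gS[pick]; lftE <- s - 1L
    rgtS <- s + w; rgtE <- gE[pick]
    gS[pick] <- lftS; gE[pick] <- lftE      # may become empty (lftE < lftS)
    if (rgtE >= rgtS) {
      gChr <- c(gChr, gChr[pick]); gS <- c(gS, rgtS); gE <- c(gE, rgtE)
    }
  }
  list(chr = pChr, start = pS, width = sort(as.integer(widths), decreasing = TRUE))
}

#' Interval-shuffle null for feature enrichment
#'
#' Repeats \code{n} times: place intervals length-matched to the observed
#' feature-within-QTL intervals uniformly at random inside the QTL regions
#' (minus any exclusions), without overlap among the placed intervals, and
#' count variant overlap. The empirical p-value is the number of replicates
#' with overlap greater than or equal to the observed count, divided by
#' \code{n}; the null mean is reported with a normal-approximation 95% CI.
#'
#' @inheritParams featureEnrichment
#' @param exclusions GRanges removed from the placement pool (e.g. the
#'   complementary gene set's features); may be empty.
#' @param n number of shuffles (the study convention is 1000).
#' @param seed integer seed.
#' @return list(observed, normalizedEnrichment, nullMean, nullSd, ci95,
#'   p, k, n, nullOverlaps).
#' @export
shuffleNull <- function(variants, feature, qtl, exclusions = GRanges(),
                        n = 1000L, seed = 1L) {
  if (n <= 0) stop("n must be positive")
  set.seed(deriveSeed(seed, "shuffle"))
  v <- asPositions(variants)
  qtl <- reduce(qtl)
  v <- v[countOverlaps(v, qtl) > 0]
  fin <- suppressWarnings(GenomicRanges::intersect(reduce(feature), qtl, ignore.strand = TRUE))
  obs <- sum(countOverlaps(v, fin) > 0)
  space <- GenomicRanges::setdiff(qtl, reduce(exclusions), ignore.strand = TRUE)
  if (sum(width(space)) < sum(width(fin)))
    stop("shuffle space cannot host the feature intervals")
  widths <- width(fin)
  gChr <- as.character(seqnames(space)); gS <- start(space); gE <- end(space)
  # sorted variant positions per chromosome for fast interval counting
  vByChr <- split(start(v), as.character(seqnames(v)))
  vByChr <- lapply(vByChr, sort)
  nullOv <- integer(n)
  for (i in seq_len(n)) {
    p <- placeIntervalsNum(widths, gChr, gS, gE)
    cnt <- 0L
    for (ch in unique(p$chr)) {
      pos <- vByChr[[ch]]
      if (is.null(pos)) next
      sel <- p$chr == ch
      cnt <- cnt + sum(findInterval(p$start[sel] + p$width[sel] - 1L, pos) -
                         findInterval(p$start[sel] - 1L, pos))
    }
    nullOv[i] <- cnt
  }
  k <- sum(nullOv >= obs)
  mu <- mean(nullOv); sdv <- stats::sd(nullOv)
  enr <- featureEnrichment(v, feature, qtl)
  list(observed = obs, normalizedEnrichment = enr$normalizedEnrichment,
       nullMean = mu, nullSd = sdv,
       ci95 = mu + c(-1.96, 1.96) * sdv / sqrt(n),
       p = k / n, k = k, n = n, nullOverlaps = nullOv)
}
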