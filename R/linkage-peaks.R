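# Peak calling with 1-LOD support intervals, fixed-term resolution of
# linked peaks, and additive/dominance effect estimation.

#' Call QTL peaks with 1-LOD support intervals
#'
#' Local maxima of the LOD curve at or above the significance threshold
#' (default 2, the AIL convention; 4.3/2.8 are the classical F2
#' significant/suggestive levels). Each peak receives the maximal
#' contiguous interval around it where LOD >= peak - 1 (the 1-LOD drop-off
#' confidence region). Peaks whose support intervals overlap are flagged
#' for fixed-term resolution.
#'
#' @param curve a [LodCurve-class].
#' @param threshold LOD significance threshold (default 2).
#' @return data.frame with one row per peak: \code{chrom}, \code{peakCm},
#'   \code{lod}, \code{ciLo}, \code{ciHi}, \code{overlaps} (comma-separated
#'   indices of peaks with overlapping support intervals, "" if none).
#'   Zero rows when nothing clears the threshold.
#' @export
findPeaks <- function(curve, threshold = 2.0) {
  stopifnot(is(curve, "LodCurve"))
  lod <- curve@lod
  pos <- curve@pos
  n <- length(lod)
  if (n == 0) return(emptyPeaks())

  isMax <- vapply(seq_len(n), function(i) {
    l <- if (i > 1) lod[i - 1] else -Inf
    r <- if (i < n) lod[i + 1] else -Inf
    lod[i] >= threshold && lod[i] > l && lod[i] >= r
  }, logical(1))
  idx <- which(isMax)
  if (!length(idx)) return(emptyPeaks())

  rows <- lapply(idx, function(i) {
    drop <- lod[i] - 1
    lo <- i; while (lo > 1 && lod[lo - 1] >= drop) lo <- lo - 1
    hi <- i; while (hi < n && lod[hi + 1] >= drop) hi <- hi + 1
    data.frame(chrom = curve@chrom, peakCm = pos[i], lod = lod[i],
               ciLo = pos[lo], ciHi = pos[hi], stringsAsFactors = FALSE)
  })
  peaks <- do.call(rbind, rows)
  peaks$overlaps <- vapply(seq_len(nrow(peaks)), function(i) {
    o <- which(peaks$ciLo <= peaks$ciHi[i] & peaks$ciHi >= peaks$ciLo[i])
    o <- setdiff(o, i)
    paste(o, collapse = ",")
  }, character(1))
  rownames(peaks) <- NULL
  peaks
}

emptyPeaks <- function() {
  data.frame(chrom = character(0), peakCm = numeric(0), lod = numeric(0),
             ciLo = numeric(0), ciHi = numeric(0), overlaps = character(0),
             stringsAsFactors = FALSE)
}

#' Resolve two linked peaks with a fixed-term re-scan
#'
#' For two peaks with overlapping 1-LOD support intervals, re-runs the scan
#' with the typed marker nearest the higher peak included as a fixed term
#' in both null and alternative fits. If the lower peak's conditional LOD
#' (its maximum within the lower peak's original support interval) stays at
#' or above the threshold, the peaks are two distinct QTL; if it collapses,
#' they reflect a single QTL. Tie-break for "nearest marker": smaller cM
#' distance, then lower coordinate.
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @param trait trait values (numeric, or 0/1 when \code{binary = TRUE}).
#' @param peakPair two rows of a [findPeaks()] table on one chromosome,
#'   ordered or not.
#' @param t AIL generation.
#' @param step scan step (cM).
#' @param threshold significance threshold for the verdict.
#' @param binary use the logistic scan instead of the EM scan.
#' @return list(verdict = "single"|"distinct", conditionalLod,
#'   fixedMarker, curve = the conditional [LodCurve-class]).
#' @export
resolveLinkedPeaks <- function(genotypes, trait, peakPair, t = 2L,
                               step = 0.25, threshold = 2.0, binary = FALSE) {
  stopifnot(nrow(peakPair) == 2L, length(unique(peakPair$chrom)) == 1L)
  hi <- which.max(peakPair$lod)
  lo <- 3L - hi
  ch <- peakPair$chrom[1]
  mk <- mapMarkers(genotypeMap(genotypes))
  onChr <- mk[mk$chrom == ch, , drop = FALSE]
  inCi <- onChr[onChr$cm >= peakPair$ciLo[hi] & onChr$cm <= peakPair$ciHi[hi], ,
                drop = FALSE]
  if (!nrow(inCi))
    stop("no typed marker within the higher peak's support interval")
  d <- abs(inCi$cm - peakPair$peakCm[hi])
  inCi <- inCi[order(d, inCi$cm), , drop = FALSE]
  fm <- inCi$marker[1]

  scan <- if (binary)
    scanBinary(genotypes, trait, t = t, step = step, fixedMarker = fm, chrom = ch)
  else
    scanQuantitative(genotypes, trait, t = t, step = step, fixedMarker = fm, chrom = ch)
  curve <- scan[[ch]]
  sel <- curve@pos >= peakPair$ciLo[lo] & curve@pos <= peakPair$ciHi[lo]
  condLod <- if (any(sel)) max(curve@lod[sel]) else 0
  list(verdict = if (condLod >= threshold) "distinct" else "single",
       conditionalLod = condLod, fixedMarker = fm, curve = curve)
}

#' Additive and dominance effects at a QTL
#'
#' Probability-weighted genotype means give the additive effect
#' \code{a = (mean_QQ - mean_qq) / 2} (the effect of one Q-allele copy,
#' positive when Q increases the trait) and the dominance deviation
#' \code{d = mean_Qq - (mean_QQ + mean_qq) / 2}. When the parental strain
#' means are supplied, the additive effect is also expressed as a
#' percentage of the parental mean difference (the trait variance
#' attributable to the QTL on the between-strain scale), and the direction
#' is classified: \code{"normal"} when the strain with the larger parental
#' mean carries the increasing allele, \code{"cryptic"} otherwise.
#'
#' @param probs n x 3 genotype probability matrix (columns qq, Qq, QQ) at
#'   the peak, e.g. from [qtlGenotypeProbs()].
#' @param trait numeric trait values.
#' @param parentalMeans optional c(Q = meanQ strain, q = meanq strain).
#' @return list(aQtl, dQtl, means, attributablePct, direction).
#' @examples
#' # a fully informative locus: parental-like means 1.13 vs 0.60
#' P <- diag(3)[c(1, 2, 3), ]
#' estimateEffects(P, c(0.60, 0.865, 1.13), parentalMeans = c(Q = 1.13, q = 0.60))
#' @export
estimateEffects <- function(probs, trait, parentalMeans = NULL) {
  stopifnot(ncol(probs) == 3L, nrow(probs) == length(trait))
  cs <- colSums(probs)
  if (any(cs <= 1e-9)) stop("a genotype class has zero expected count")
  means <- colSums(probs * trait) / cs
  names(means) <- c("qq", "Qq", "QQ")
  a <- (means["QQ"] - means["qq"]) / 2
  d <- means["Qq"] - (means["QQ"] + means["qq"]) / 2
  res <- list(aQtl = unname(a), dQtl = unname(d), means = means,
              attributablePct = NA_real_, direction = NA_character_)
  if (!is.null(parentalMeans)) {
    diffP <- parentalMeans[["Q"]] - parentalMeans[["q"]]
    if (diffP == 0) stop("parental means are equal; attributable percent undefined")
    res$attributablePct <- unname(100 * a / abs(diffP))
    res$direction <- if (sign(a) == sign(diffP)) "normal" else "cryptic"
  }
  res
}
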