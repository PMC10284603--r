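# Conditional QTL genotype probabilities at scan positions, under the
# AIL-expanded two-gamete Markov model (Haldane, no interference).

# P(gamete allele switches) across an interval of rCm centimorgan after t
# generations: the per-meiosis Haldane fraction expanded by map expansion.
ailR <- function(cmDist, t) expectedRecombinantFraction(haldaneR(cmDist), t)

# two-point transition of a single composite gamete: P(y | x) with switch
# probability R
stepProb <- function(same, R) ifelse(same, 1 - R, R)

# Conditional genotype probabilities at a position between two flanking
# loci for ONE individual, given flanking genotypes gL, gR (0/1/2 copies of
# Q, NA = missing) and the AIL-scale switch probabilities R1 (left->pos)
# and R2 (pos->right). Each composite gamete is a two-state Markov chain
# along the chromosome; a genotype is the unordered pair of its two
# independent gametes, so heterozygous flanks are summed over phase.
conditionalGenoProbs <- function(gL, gR, R1, R2) {
  if (is.na(gL) && is.na(gR)) return(c(0.25, 0.5, 0.25))

  gameteQ <- function(xL, xR) {
    # P(allele at pos = Q | flank alleles), NA flank = unconditioned
    if (is.na(xL) && is.na(xR)) return(0.5)
    if (is.na(xR)) return(stepProb(xL == 1L, R1))
    if (is.na(xL)) return(stepProb(xR == 1L, R2))
    num <- stepProb(xL == 1L, R1) * stepProb(xR == 1L, R2)
    den <- num + stepProb(xL == 0L, R1) * stepProb(xR == 0L, R2)
    num / den
  }
  hapW <- function(xL, xR) {
    # marginal weight of a gamete haplotype across the whole interval
    if (is.na(xL) || is.na(xR)) return(1)
    (1 - R1) * (1 - R2) * (xL == xR) + R1 * R2 * (xL == xR) +
      (R1 * (1 - R2) + (1 - R1) * R2) * (xL != xR)
  }
  phases <- function(g) {
    if (is.na(g)) list(c(NA_integer_, NA_integer_))
    else if (g == 2L) list(c(1L, 1L))
    else if (g == 0L) list(c(0L, 0L))
    else list(c(1L, 0L), c(0L, 1L))
  }

  out <- c(0, 0, 0)
  tot <- 0
  for (phL in phases(gL)) for (phR in phases(gR)) {
    w <- hapW(phL[1], phR[1]) * hapW(phL[2], phR[2])
    if (w <= 0) next
    p1 <- gameteQ(phL[1], phR[1])
    p2 <- gameteQ(phL[2], phR[2])
    out <- out + w * c((1 - p1) * (1 - p2),
                       p1 * (1 - p2) + (1 - p1) * p2,
                       p1 * p2)
    tot <- tot + w
  }
  out / tot
}

#' Conditional QTL genotype probabilities at a scan position
#'
#' For each individual, computes P(qq), P(Qq), P(QQ) at a test position from
#' the genotypes at the nearest informative flanking markers, under a
#' no-interference model in which each composite gamete follows a two-state
#' Markov chain whose switch probability over an interval of d cM is the
#' AIL-expanded fraction \code{expectedRecombinantFraction(haldaneR(d), t)}.
#' At \code{t = 2} this is exactly the standard F2 interval-mapping
#' conditional probability; at a typed marker the probabilities collapse to
#' the observed call; individuals with no informative marker on the
#' chromosome receive the population prior (0.25, 0.5, 0.25).
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @param chrom chromosome of the test position.
#' @param posCm test position (cM); must lie within the chromosome's marker
#'   span.
#' @param t AIL generation (>= 2; 2 = F2).
#' @return numeric matrix n x 3 with columns \code{qq}, \code{Qq},
#'   \code{QQ}, rows in genotype-matrix column order.
#' @export
qtlGenotypeProbs <- function(genotypes, chrom, posCm, t = 2L) {
  stopifnot(is(genotypes, "GenotypeMatrix"), t >= 2)
  mk <- mapMarkers(genotypeMap(genotypes))
  onChr <- mk[mk$chrom == chrom, , drop = FALSE]
  onChr <- onChr[onChr$marker %in% rownames(genotypeCalls(genotypes)), , drop = FALSE]
  if (!nrow(onChr)) stop("no markers on chromosome ", chrom)
  if (posCm < min(onChr$cm) - 1e-9 || posCm > max(onChr$cm) + 1e-9)
    stop("scan position outside the marker span of chromosome ", chrom)

  calls <- genotypeCalls(genotypes)[onChr$marker, , drop = FALSE]
  n <- ncol(calls)
  pos <- onChr$cm
  leftIdx <- findInterval(posCm + 1e-9, pos)       # last marker at/left of pos
  rightIdx <- leftIdx + 1L
  if (leftIdx >= 1L && abs(pos[leftIdx] - posCm) < 1e-9) rightIdx <- leftIdx

  P <- matrix(NA_real_, n, 3, dimnames = list(colnames(calls), c("qq", "Qq", "QQ")))

  # fast path: individuals fully typed at the default flanking markers get
  # their probabilities from a 3 x 3 lookup computed once per position
  gLd <- calls[leftIdx, ]
  gRd <- calls[rightIdx, ]
  fast <- !is.na(gLd) & !is.na(gRd)
  if (any(fast)) {
    R1d <- ailR(posCm - pos[leftIdx], t)
    R2d <- ailR(pos[rightIdx] - posCm, t)
    lut <- matrix(NA_real_, 9, 3)
    for (a in 0:2) for (b in 0:2)
      lut[a * 3 + b + 1, ] <- conditionalGenoProbs(a, b, R1d, R2d)
    P[fast, ] <- lut[gLd[fast] * 3L + gRd[fast] + 1L, , drop = FALSE]
  }
  if (all(fast)) return(P)

  # slow path: search outward for the nearest informative flanks
  memo <- new.env(parent = emptyenv())
  for (i in which(!fast)) {
    gi <- calls[, i]
    li <- leftIdx
    while (li >= 1L && is.na(gi[li])) li <- li - 1L
    ri <- if (rightIdx == leftIdx && !is.na(gi[leftIdx])) li else rightIdx
    if (rightIdx == leftIdx && is.na(gi[leftIdx])) ri <- rightIdx + 1L
    while (ri <= length(pos) && is.na(gi[ri])) ri <- ri + 1L
    gL <- if (li >= 1L) gi[li] else NA_integer_
    gR <- if (ri <= length(pos)) gi[ri] else NA_integer_
    dL <- if (li >= 1L) posCm - pos[li] else NA_real_
    dR <- if (ri <= length(pos)) pos[ri] - posCm else NA_real_
    key <- paste(li, ri, gL, gR)
    hit <- memo[[key]]
    if (is.null(hit)) {
      R1 <- if (is.na(dL)) 0.5 else ailR(dL, t)
      R2 <- if (is.na(dR)) 0.5 else ailR(dR, t)
      hit <- conditionalGenoProbs(gL, gR, R1, R2)
      memo[[key]] <- hit
    }
    P[i, ] <- hit
  }
  P
}
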