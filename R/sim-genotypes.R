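# Gamete-level meiosis under the Haldane model (Poisson crossovers, no
# interference) propagated through a pedigree.

# One meiosis: recombine a parent's two haplotypes (0/1 allele vectors at
# positions posCm on one chromosome) into a transmitted gamete.
meiosisGamete <- function(hap1, hap2, posCm) {
  L <- (max(posCm) - min(posCm)) / 100  # Morgans
  nx <- stats::rpois(1L, L)
  phase <- stats::runif(1) < 0.5        # which haplotype at the chromosome start
  if (nx == 0L) return(if (phase) hap1 else hap2)
  xo <- stats::runif(nx, min(posCm), max(posCm))
  nswitch <- vapply(posCm, function(p) sum(xo <= p), integer(1))
  odd <- nswitch %% 2L == 1L
  out <- if (phase) hap1 else hap2
  other <- if (phase) hap2 else hap1
  out[odd] <- other[odd]
  out
}

#' Simulate marker genotypes through an AIL pedigree
#'
#' Drops two fully inbred, fully informative founder genomes through a
#' pedigree by simulated meiosis: per parent and chromosome, the transmitted
#' gamete carries a Poisson(\code{length in Morgans}) number of crossovers
#' placed uniformly (Haldane model, no interference). Founders are coded Q/Q
#' (sire strain) and q/q (dam strain), so F1s are Q/q everywhere and F2
#' genotype frequencies approach 1:2:1 at any single marker.
#'
#' @param pedigree data.frame from [simulatePedigree()].
#' @param map a [GeneticMap-class]; all simulated loci must lie on it.
#' @param seed integer seed; the same seed reproduces the cohort exactly.
#' @param keepHaplotypes if TRUE, phased haplotypes are attached as
#'   attribute \code{"haplotypes"} (list of two 0/1 matrices).
#' @return A [GenotypeMatrix-class] for the individuals of the pedigree
#'   (founders included), calls coded 0/1/2 copies of the Q allele.
#' @examples
#' map <- geneticMap(paste0("m", 1:6), "1", seq(0, 10, by = 2))
#' ped <- simulatePedigree(AILDesign(nPairs = 4, tFinal = 3, seed = 7))
#' g <- simulateGenotypes(ped, map, seed = 7)
#' @export
simulateGenotypes <- function(pedigree, map, seed = 1L, keepHaplotypes = FALSE) {
  stopifnot(is(map, "GeneticMap"))
  validObject(map)
  mk <- map@markers
  set.seed(deriveSeed(seed, "genotypes"))

  ids <- pedigree$id
  nInd <- length(ids)
  nMrk <- nrow(mk)
  H1 <- matrix(NA_integer_, nMrk, nInd, dimnames = list(mk$marker, ids))
  H2 <- H1

  # founders: rows 1 (Q strain, allele 1) and 2 (q strain, allele 0)
  fQ <- which(is.na(pedigree$sire))
  for (i in fQ) {
    a <- if (pedigree$id[i] == "Q_founder") 1L else 0L
    H1[, i] <- a; H2[, i] <- a
  }

  byChr <- split(seq_len(nMrk), mk$chrom)
  ord <- order(pedigree$generation)  # parents precede offspring
  idx <- stats::setNames(seq_len(nInd), ids)
  for (i in ord) {
    if (is.na(pedigree$sire[i])) next
    si <- idx[[pedigree$sire[i]]]
    di <- idx[[pedigree$dam[i]]]
    for (ch in byChr) {
      pos <- mk$cm[ch]
      H1[ch, i] <- meiosisGamete(H1[ch, si], H2[ch, si], pos)
      H2[ch, i] <- meiosisGamete(H1[ch, di], H2[ch, di], pos)
    }
  }
  g <- H1 + H2
  out <- genotypeMatrix(g, map)
  if (keepHaplotypes) attr(out, "haplotypes") <- list(H1 = H1, H2 = H2)
  out
}

#' Monte-Carlo oracle for AIL two-locus recombinant fractions
#'
#' Forward-simulates a random-mating gamete pool at two loci with
#' per-meiosis recombination fraction \code{r} from F1 gametes (all
#' parental) to generation \code{t}, and returns the recombinant haplotype
#' fraction. This is the independent check of the closed form
#' [expectedRecombinantFraction()].
#'
#' @param r per-meiosis recombination fraction.
#' @param t generation (F2 = 2).
#' @param nLineages gamete pool size (number of simulated lineages).
#' @param seed integer seed.
#' @return Observed recombinant fraction among \code{nLineages} gametes.
#' @export
simulateRecombinantFraction <- function(r, t, nLineages = 1e5, seed = 1L) {
  if (r < 0 || r > 0.5) stop("r must lie in [0, 0.5]")
  if (t < 2) stop("t must be >= 2")
  set.seed(deriveSeed(seed, "twolocus"))
  n <- as.integer(nLineages)
  # pool_g = gametes forming the F_g individuals, coded (a, b) in {0,1} at
  # the two loci. F1 individuals are (11)/(00) heterozygotes exactly, so
  # pool_2 gametes are recombinant with probability r:
  rec <- stats::runif(n) < r
  par <- stats::runif(n) < 0.5
  a <- ifelse(rec, ifelse(par, 1L, 0L), ifelse(par, 1L, 0L))
  b <- ifelse(rec, 1L - a, a)
  if (t > 2) for (g in 3:t) {
    # an F_{g-1} individual = two random gametes of the current pool; its
    # gamete takes locus 1 from one of them and locus 2 from the same
    # gamete unless a crossover (probability r) switches to the other
    i <- sample.int(n, n, replace = TRUE)
    j <- sample.int(n, n, replace = TRUE)
    pick1 <- stats::runif(n) < 0.5
    xo <- stats::runif(n) < r
    na <- ifelse(pick1, a[i], a[j])
    nb <- ifelse(pick1 != xo, b[i], b[j])
    a <- na; b <- nb
  }
  mean(a != b)
}
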