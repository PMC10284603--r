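# Synthetic downstream fixtures: variant catalogs with planted density
# blocks, feature intervals, stochastic-block-model networks and expression
# counts, all with recorded ground truth.

#' Generate synthetic downstream fixtures
#'
#' Produces the inputs the post-linkage stages consume, with known ground
#' truth recorded in \code{$meta}:
#' \itemize{
#'   \item a variant table whose positions follow a two-component density -
#'     background rate \code{lowRate} with planted high-density blocks at
#'     rate \code{highRate} (variants per bp), mimicking the blocky
#'     low/high-polymorphism mosaic of inbred-strain genome pairs;
#'   \item a gene/feature table (TSS, strand) on the same genome;
#'   \item a scored undirected edge list from a two-block stochastic block
#'     model with one dense planted community;
#'   \item an expression count matrix with a known expressed-gene subset.
#' }
#'
#' @param seed integer seed; identical seeds give identical fixtures.
#' @param genome named numeric vector of chromosome lengths (bp).
#' @param nHighBlocks planted high-density blocks per chromosome.
#' @param blockSize width of each planted block (bp).
#' @param lowRate,highRate variant densities (per bp) outside/inside blocks;
#'   defaults correspond to ~5 and ~2000 variants per 600 kb.
#' @param nGenes genes in the network/expression fixtures.
#' @param communitySize size of the planted dense community.
#' @param pIn,pOut edge probabilities inside/outside the community.
#' @param nSamples expression samples.
#' @return list(variants, genes, edges, counts, meta).
#' @export
synthFixtures <- function(seed = 1L,
                          genome = c(chr1 = 60e6, chr2 = 40e6),
                          nHighBlocks = 3L, blockSize = 3e6,
                          lowRate = 5 / 6e5, highRate = 2000 / 6e5,
                          nGenes = 400L, communitySize = 40L,
                          pIn = 0.25, pOut = 0.01, nSamples = 6L) {
  set.seed(deriveSeed(seed, "fixtures"))
  genome <- genome[genome > 0]
  if (!length(genome))
    return(list(variants = data.frame(chrom = character(0), pos = numeric(0)),
                genes = data.frame(), edges = data.frame(),
                counts = matrix(0L, 0, nSamples),
                meta = list(genome = genome, blocks = NULL,
                            community = character(0),
                            expressed = character(0), seed = seed)))

  blocks <- NULL
  vlist <- list()
  for (chr in names(genome)) {
    len <- genome[[chr]]
    # non-overlapping planted blocks on a coarse lattice
    nb <- min(nHighBlocks, floor(len / (2 * blockSize)))
    starts <- sort(sample.int(floor(len / blockSize) - 1L, nb)) * blockSize
    starts <- starts[c(TRUE, diff(starts) >= blockSize)]
    bl <- data.frame(chrom = chr, start = starts, end = starts + blockSize)
    blocks <- rbind(blocks, bl)
    nLow <- stats::rpois(1, lowRate * len)
    pos <- if (nLow) round(stats::runif(nLow, 1, len)) else numeric(0)
    for (i in seq_len(nrow(bl))) {
      nHi <- stats::rpois(1, (highRate - lowRate) * blockSize)
      pos <- c(pos, round(stats::runif(nHi, bl$start[i] + 1, bl$end[i])))
    }
    if (length(pos))
      vlist[[chr]] <- data.frame(chrom = chr, pos = sort(pos))
  }
  variants <- if (length(vlist)) do.call(rbind, vlist) else
    data.frame(chrom = character(0), pos = numeric(0))
  n <- nrow(variants)
  if (n) {
    variants$depth <- stats::rpois(n, 30)
    variants$fdr <- stats::runif(n, 0, 0.05)
    variants$gtA <- sample(c("hom_alt", "hom_ref"), n, TRUE, c(0.5, 0.5))
    variants$gtB <- ifelse(variants$gtA == "hom_alt",
                           sample(c("hom_ref", "het"), n, TRUE, c(0.8, 0.2)),
                           "hom_alt")
    variants$annotation <- sample(c("exonic", "intronic", "intergenic"),
                                  n, TRUE, c(0.05, 0.35, 0.60))
    variants$effectClass <- sample(
      c("high_impact", "deleterious_missense", "nonframeshift_deletion", "other"),
      n, TRUE, c(0.01, 0.03, 0.01, 0.95))
    rownames(variants) <- NULL
  }

  genes <- data.frame(
    gene = sprintf("g%03d", seq_len(nGenes)),
    chrom = sample(names(genome), nGenes, TRUE),
    stringsAsFactors = FALSE)
  genes$tss <- round(stats::runif(nGenes, 1e4, genome[genes$chrom] - 1e4))
  genes$strand <- sample(c("+", "-"), nGenes, TRUE)
  if (n) variants$gene <- genes$gene[
    pmin(nGenes, pmax(1, findInterval(variants$pos, sort(genes$tss)) + 1L))]

  # stochastic block model: dense planted community among the first genes
  comm <- genes$gene[seq_len(communitySize)]
  pairs <- utils::combn(genes$gene, 2)
  inComm <- pairs[1, ] %in% comm & pairs[2, ] %in% comm
  keep <- stats::runif(ncol(pairs)) < ifelse(inComm, pIn, pOut)
  edges <- data.frame(geneA = pairs[1, keep], geneB = pairs[2, keep],
                      score = round(stats::runif(sum(keep), 701, 999)),
                      stringsAsFactors = FALSE)

  expressed <- sort(sample(genes$gene, round(0.7 * nGenes)))
  counts <- matrix(0L, nGenes, nSamples,
                   dimnames = list(genes$gene, sprintf("s%d", seq_len(nSamples))))
  hot <- rownames(counts) %in% expressed
  counts[hot, ] <- stats::rpois(sum(hot) * nSamples, 50)
  counts[!hot, ] <- stats::rpois(sum(!hot) * nSamples, 0.05)

  list(variants = variants, genes = genes, edges = edges, counts = counts,
       meta = list(genome = genome, blocks = blocks, community = comm,
                   expressed = expressed, seed = seed))
}
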