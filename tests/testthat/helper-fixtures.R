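# Shared fixtures and independent oracles used across the test files.
# All fixtures are built in code; nothing is read from disk.

# small single-chromosome map, markers every 2 cM
testMap <- function(lenCm = 40, spacing = 2) {
  pos <- seq(0, lenCm, by = spacing)
  geneticMap(sprintf("m%02d", seq_along(pos)), "1", pos)
}

# breed an AIL cohort with one planted additive QTL and return everything
plantedCohort <- function(a = 0.25, d = 0, qtlCm = 20, t = 14, n = 400,
                          seed = 1, lenCm = 40, sd = 1) {
  map <- testMap(lenCm)
  mod <- list(q = TraitModel(grandMean = 0,
                             qtl = data.frame(chrom = "1", cm = qtlCm, a = a, d = d),
                             residualSd = sd))
  design <- AILDesign(nPairs = 48, tFinal = t, finalCohortSize = n, seed = seed)
  simulateAILCohort(design, map, mod)
}

# ---- independent oracles -------------------------------------------------

# Exhaustive-enumeration oracle for conditional genotype probabilities:
# each composite gamete's haplotype over (left, pos, right) is enumerated
# explicitly with switch probabilities R1, R2 per interval; two gametes are
# independent; conditioning on unordered flank genotypes sums the joint
# table. Independent of the package's closed-form path.
oracleGenoProbs <- function(gL, gR, R1, R2) {
  haps <- expand.grid(aL = 0:1, aP = 0:1, aR = 0:1)
  hapP <- function(h) {
    0.5 * (if (h[1] == h[2]) 1 - R1 else R1) * (if (h[2] == h[3]) 1 - R2 else R2)
  }
  joint <- array(0, c(3, 3, 3))  # gL+1, gPos+1, gR+1
  for (i in seq_len(nrow(haps))) for (j in seq_len(nrow(haps))) {
    h1 <- as.numeric(haps[i, ]); h2 <- as.numeric(haps[j, ])
    p <- hapP(h1) * hapP(h2)
    joint[h1[1] + h2[1] + 1, h1[2] + h2[2] + 1, h1[3] + h2[3] + 1] <-
      joint[h1[1] + h2[1] + 1, h1[2] + h2[2] + 1, h1[3] + h2[3] + 1] + p
  }
  slice <- joint[gL + 1, , gR + 1]
  slice / sum(slice)
}

# Iterated-grid maximizer of the 3-component mixture likelihood (common
# sigma, no covariates): direct maximization oracle for the EM LOD.
oracleGridLod <- function(y, P, iters = 6, pts = 9) {
  n <- length(y)
  loglik <- function(mu1, mu2, mu3, s) {
    sum(log(P[, 1] * dnorm(y, mu1, s) + P[, 2] * dnorm(y, mu2, s) +
              P[, 3] * dnorm(y, mu3, s)))
  }
  ctr <- rep(mean(y), 3)
  sp <- c(diff(range(y)), diff(range(y)), diff(range(y)), sd(y)) # half-spans
  sctr <- sd(y)
  best <- -Inf
  for (it in seq_len(iters)) {
    g1 <- seq(ctr[1] - sp[1], ctr[1] + sp[1], length.out = pts)
    g2 <- seq(ctr[2] - sp[2], ctr[2] + sp[2], length.out = pts)
    g3 <- seq(ctr[3] - sp[3], ctr[3] + sp[3], length.out = pts)
    gs <- seq(max(sctr - sp[4], 1e-3), sctr + sp[4], length.out = pts)
    for (m1 in g1) for (m2 in g2) for (m3 in g3) for (s in gs) {
      ll <- loglik(m1, m2, m3, s)
      if (ll > best) { best <- ll; ctr <- c(m1, m2, m3); sctr <- s }
    }
    sp <- sp * 2.2 / (pts - 1)   # shrink around the incumbent
  }
  s2 <- sum((y - mean(y))^2) / n
  ll0 <- -n / 2 * (log(2 * pi * s2) + 1)
  (best - ll0) / log(10)
}

# Brute-force stress centrality by explicit shortest-path enumeration
oracleStress <- function(g) {
  nm <- igraph::V(g)$name
  out <- stats::setNames(numeric(length(nm)), nm)
  n <- length(nm)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    sp <- suppressWarnings(
      igraph::all_shortest_paths(g, from = nm[s], to = nm[t])$vpaths)
    for (p in sp) {
      inner <- setdiff(igraph::V(g)$name[as.integer(p)], c(nm[s], nm[t]))
      out[inner] <- out[inner] + 1
    }
  }
  out
}

# One-sided Fisher p by explicit hypergeometric tail summation over the
# 2x2 table (a = overlap, set size K, draw size k, universe N)
oracleHyperTail <- function(a, K, k, N) {
  xs <- a:min(K, k)
  sum(choose(K, xs) * choose(N - K, k - xs)) / choose(N, k)
}
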