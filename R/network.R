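# Gene-network subnetwork statistics, permutation nulls, centrality-based
# hub ranking and Fisher over-representation tests.

#' @importFrom igraph graph_from_data_frame induced_subgraph gsize transitivity V betweenness degree simplify vcount as_adj_list
NULL

#' Load a scored gene network
#'
#' Builds an undirected graph from a combined-score edge list, keeping
#' edges with score strictly greater than \code{minScore} (the
#' high-confidence convention on the 0-1000 scale), dropping self-loops and
#' duplicate symmetric edges.
#'
#' @param edges data.frame(geneA, geneB, score).
#' @param minScore strict score threshold (default 700).
#' @return An [igraph::igraph] object.
#' @export
geneNetwork <- function(edges, minScore = 700) {
  stopifnot(all(c("geneA", "geneB", "score") %in% names(edges)))
  if (any(edges$score < 0 | edges$score > 1000))
    stop("scores must be on the 0-1000 scale")
  e <- edges[edges$score > minScore & edges$geneA != edges$geneB, , drop = FALSE]
  g <- graph_from_data_frame(e[, c("geneA", "geneB")], directed = FALSE)
  simplify(g)
}

#' Induced subnetwork on a gene set
#'
#' @param network an [igraph::igraph] from [geneNetwork()].
#' @param geneSet character vector of genes; the subgraph is induced on
#'   \code{geneSet} intersected with the node universe (empty intersection
#'   gives an empty graph, not an error).
#' @return The induced [igraph::igraph].
#' @export
buildSubnetwork <- function(network, geneSet) {
  induced_subgraph(network, intersect(geneSet, igraph::V(network)$name))
}

#' Subnetwork statistics: edge count and average clustering coefficient
#'
#' The average clustering coefficient is the mean of local clustering
#' coefficients over the nodes of the set, with nodes of degree < 2
#' contributing 0 (the common graph-library convention). Genes of the set
#' absent from the network contribute 0 to the average.
#'
#' @param network an [igraph::igraph].
#' @param geneSet character vector of genes.
#' @return list(nEdges, avgClustering, nNodes = genes of the set present).
#' @export
networkStats <- function(network, geneSet) {
  sub <- buildSubnetwork(network, geneSet)
  nIn <- igraph::vcount(sub)
  cc <- if (nIn) transitivity(sub, type = "localundirected", isolates = "zero") else numeric(0)
  avg <- if (length(geneSet)) sum(cc) / length(unique(geneSet)) else NA_real_
  list(nEdges = gsize(sub), avgClustering = avg, nNodes = nIn)
}

#' Permutation null for subnetwork statistics
#'
#' Draws \code{n} random gene sets of the same size uniformly without
#' replacement from the background (e.g. the expressed genes of the
#' relevant condition), recomputes the subnetwork statistics for each, and
#' reports empirical p-values as the proportion of permutations with a
#' statistic greater than or equal to the observed one (k / n; reported as
#' "< 1/n" when k = 0, with the conservative (k+1)/(n+1) available).
#'
#' @param network an [igraph::igraph] from [geneNetwork()].
#' @param geneSet the gene set of interest.
#' @param background background gene pool (must be larger than the set).
#' @param n number of permutations (the study convention is 100,000).
#' @param seed integer seed; the same seed reproduces the p-values exactly.
#' @param conservative use (k+1)/(n+1) instead of k/n.
#' @return list(observed, nullMean, nullSd, p, pLabel, k, n, nullStats).
#' @export
permutationTest <- function(network, geneSet, background, n = 100000L,
                            seed = 1L, conservative = FALSE) {
  if (n <= 0) stop("n must be positive")
  if (length(background) <= length(unique(geneSet)))
    stop("background must be larger than the gene set")
  set.seed(deriveSeed(seed, "netperm"))
  m <- length(unique(geneSet))
  obs <- networkStats(network, geneSet)

  # dense adjacency over the background pool: per permutation the m x m
  # submatrix gives both statistics in O(m^2) time
  bg <- unique(background)
  inNet <- intersect(bg, igraph::V(network)$name)
  A <- matrix(FALSE, length(bg), length(bg))
  if (length(inNet) > 1) {
    eMat <- igraph::as_edgelist(induced_subgraph(network, inNet), names = TRUE)
    ia <- match(eMat[, 1], bg); ib <- match(eMat[, 2], bg)
    A[cbind(ia, ib)] <- TRUE
    A[cbind(ib, ia)] <- TRUE
  }

  nEdges <- integer(n)
  avgCc <- numeric(n)
  for (i in seq_len(n)) {
    pick <- sample.int(length(bg), m)
    S <- A[pick, pick]
    nEdges[i] <- sum(S) / 2L
    dg <- rowSums(S)
    tri <- rowSums((S %*% S) * S) / 2        # closed neighbour pairs per node
    cc <- ifelse(dg >= 2, 2 * tri / (dg * (dg - 1)), 0)
    avgCc[i] <- sum(cc) / m
  }
  pOf <- function(stat, nullv) {
    k <- sum(nullv >= stat)
    p <- if (conservative) (k + 1) / (n + 1) else k / n
    list(k = k, p = p,
         label = if (k == 0 && !conservative) sprintf("< %g", 1 / n)
                 else format(p, digits = 3))
  }
  pe <- pOf(obs$nEdges, nEdges)
  pc <- pOf(obs$avgClustering, avgCc)
  list(observed = obs,
       edges = list(nullMean = mean(nEdges), nullSd = stats::sd(nEdges),
                    k = pe$k, p = pe$p, pLabel = pe$label),
       clustering = list(nullMean = mean(avgCc), nullSd = stats::sd(avgCc),
                         k = pc$k, p = pc$p, pLabel = pc$label),
       n = n, nullEdges = nEdges, nullClustering = avgCc)
}

#' Betweenness and stress centrality ranking
#'
#' Betweenness is the fraction-weighted shortest-path count
#' (sum over pairs of sigma_st(v)/sigma_st); stress is the raw count of
#' shortest paths passing through the node. Components are handled
#' independently; ties are broken by node label.
#'
#' @param graph an [igraph::igraph].
#' @return data.frame(gene, betweenness, stress) sorted by decreasing
#'   stress then betweenness then label.
#' @export
centralityRanking <- function(graph) {
  nm <- igraph::V(graph)$name
  btw <- betweenness(graph, directed = FALSE)
  str <- stressCentrality(graph)
  out <- data.frame(gene = nm, betweenness = unname(btw),
                    stress = unname(str[nm]), stringsAsFactors = FALSE)
  out[order(-out$stress, -out$betweenness, out$gene), , drop = FALSE]
}

#' Stress centrality (raw shortest-path counts)
#'
#' For every node v, the number of shortest paths between unordered node
#' pairs (s, t), s != v != t, that pass through v. Computed by a
#' Brandes-style accumulation: a BFS from each source s yields the number
#' of shortest s-v paths sigma_sv and, walking the BFS DAG backwards, the
#' count psi_s(v) of shortest-path continuations from v; then
#' stress(v) = 1/2 * sum_s sigma_sv * psi_s(v).
#'
#' @param graph an undirected [igraph::igraph].
#' @return Named numeric vector of stress values.
#' @export
stressCentrality <- function(graph) {
  n <- igraph::vcount(graph)
  nm <- igraph::V(graph)$name
  adj <- lapply(as_adj_list(graph), as.integer)
  stress <- numeric(n)
  for (s in seq_len(n)) {
    dist <- rep.int(-1L, n)
    sigma <- numeric(n)
    dist[s] <- 0L
    sigma[s] <- 1
    order <- integer(0)
    frontier <- s
    while (length(frontier)) {
      order <- c(order, frontier)
      nxt <- integer(0)
      for (v in frontier) for (w in adj[[v]]) {
        if (dist[w] < 0L) { dist[w] <- dist[v] + 1L; nxt <- c(nxt, w) }
        if (dist[w] == dist[v] + 1L) sigma[w] <- sigma[w] + sigma[v]
      }
      frontier <- unique(nxt)
    }
    psi <- numeric(n)
    for (w in rev(order)) {
      if (w == s) next
      for (v in adj[[w]]) if (dist[v] == dist[w] - 1L)
        psi[v] <- psi[v] + 1 + psi[w]   # shortest-path continuations via w
    }
    contrib <- sigma * psi
    contrib[s] <- 0
    stress <- stress + contrib
  }
  stats::setNames(stress / 2, nm)
}

#' Hub connection over-representation (Fisher exact)
#'
#' Tests whether the genes of a set are connected to a hub gene (in the
#' full network) more often than the remaining universe genes, with a
#' one-sided Fisher exact test on the 2x2 table set-membership x
#' hub-connection. Degenerate tables (a zero margin) give p = 1 with a
#' flag.
#'
#' @param network the full [igraph::igraph].
#' @param hub hub gene name (must be in the universe).
#' @param geneSet the gene set (hub excluded automatically).
#' @param universe background universe of genes.
#' @return list(p, table, flag).
#' @export
hubConnectionTest <- function(network, hub, geneSet, universe) {
  if (!(hub %in% universe)) stop("hub must be in the universe")
  uni <- setdiff(unique(universe), hub)
  inSet <- uni %in% setdiff(geneSet, hub)
  conn <- rep(FALSE, length(uni))
  if (hub %in% igraph::V(network)$name) {
    nb <- igraph::V(network)$name[as.integer(igraph::neighbors(network, hub))]
    conn <- uni %in% nb
  }
  tab <- matrix(c(sum(inSet & conn), sum(inSet & !conn),
                  sum(!inSet & conn), sum(!inSet & !conn)), 2,
                dimnames = list(c("connected", "not"), c("inSet", "background")))
  flag <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  p <- if (flag) 1 else
    stats::fisher.test(tab, alternative = "greater")$p.value
  list(p = p, table = tab, flag = flag)
}

#' Hub tests across several hubs with BH adjustment
#'
#' @inheritParams hubConnectionTest
#' @param hubs character vector of hub genes.
#' @return data.frame(hub, p, pAdj) (Benjamini-Hochberg across the hubs).
#' @export
hubConnectionTests <- function(network, hubs, geneSet, universe) {
  p <- vapply(hubs, function(h)
    hubConnectionTest(network, h, geneSet, universe)$p, numeric(1))
  data.frame(hub = hubs, p = unname(p),
             pAdj = stats::p.adjust(unname(p), method = "BH"),
             stringsAsFactors = FALSE)
}

#' Kinase substrate over-representation among hub connections
#'
#' One-sided Fisher exact test of whether a hub's network connections are
#' enriched for a substrate set (e.g. known and predicted phosphorylation
#' targets of the kinase) relative to the universe.
#'
#' @param connections genes connected to the hub.
#' @param substrates the substrate set (within the universe).
#' @param universe background universe.
#' @return list(p, table, flag) (flag and p = 1 for degenerate tables,
#'   including empty connection sets).
#' @export
substrateEnrichment <- function(connections, substrates, universe) {
  uni <- unique(universe)
  if (!all(substrates %in% uni)) stop("substrates must lie within the universe")
  isConn <- uni %in% connections
  isSub <- uni %in% substrates
  tab <- matrix(c(sum(isConn & isSub), sum(isConn & !isSub),
                  sum(!isConn & isSub), sum(!isConn & !isSub)), 2,
                dimnames = list(c("substrate", "not"), c("connected", "rest")))
  flag <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  p <- if (flag) 1 else stats::fisher.test(tab, alternative = "greater")$p.value
  list(p = p, table = tab, flag = flag)
}
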