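# Minimum spanning tree (maximum-PLI backbone) and global tree metrics.

#' Build the spanning tree of a PLI matrix
#'
#' Kruskal's algorithm on edges sorted by \emph{descending} PLI, i.e. the
#' maximum-total-PLI spanning tree (equivalently the minimum spanning tree
#' of any strictly decreasing transform such as 1 - PLI: the tree depends
#' only on the weight ranking).  The strongest connections form the
#' backbone.  Ties are broken deterministically by lexicographic (i, j)
#' pair order, a contract this implementation guarantees because
#' finite-sample PLI values need not be unique.  Stored edge weights are
#' the original PLI values.
#'
#' @param adj an \linkS4class{AdjacencyMatrix} (N >= 2)
#' @return a \linkS4class{SpanningTree}
#' @export
buildMst <- function(adj) {
  stopifnot(is(adj, "AdjacencyMatrix"))
  v <- as.matrix(adj)
  n <- nrow(v)
  if (n < 2L) stop("need at least 2 nodes")
  ut <- which(upper.tri(v), arr.ind = TRUE)
  ii <- ut[, 1L]; jj <- ut[, 2L]
  w <- v[ut]
  ord <- order(-w, ii, jj)               # descending weight, then (i, j)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  edges <- matrix(0, n - 1L, 3L, dimnames = list(NULL, c("i", "j", "weight")))
  k <- 0L
  for (e in ord) {
    a <- find(ii[e]); b <- find(jj[e])
    if (a != b) {
      parent[a] <- b
      k <- k + 1L
      edges[k, ] <- c(ii[e], jj[e], w[e])
      if (k == n - 1L) break
    }
  }
  new("SpanningTree", nNodes = n, edges = edges,
      nodeLabels = roiLabels(adj))
}

# adjacency list of a tree: list of integer neighbour vectors
.treeAdjList <- function(n, edges) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1L]; j <- edges[k, 2L]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

# hop distances from source to all nodes by BFS
.bfsDepths <- function(adj, n, src) {
  depth <- rep.int(-1L, n)
  depth[src] <- 0L
  queue <- src
  while (length(queue)) {
    nxt <- integer(0)
    for (u in queue) for (v in adj[[u]]) if (depth[v] < 0L) {
      depth[v] <- depth[u] + 1L
      nxt <- c(nxt, v)
    }
    queue <- nxt
  }
  depth
}

#' Global tree metrics
#'
#' Computes the five global topology metrics of a spanning tree with fixed
#' normalizations (raw values are kept alongside in the \code{raw} slot):
#' maximum degree and leaf count divided by the edge count m = N-1, mean
#' hop eccentricity divided by N-1, maximum betweenness centrality as a
#' fraction of the (N-1)(N-2)/2 node pairs, and tree hierarchy
#' \eqn{T_H = L / (2 m BC_{max})} using the normalized \eqn{BC_{max}}.
#' Betweenness on a tree counts, for each node, the pairs of other nodes
#' whose unique connecting path passes through it.
#'
#' @param tree a \linkS4class{SpanningTree} with at least 3 nodes (with 2
#'   nodes the betweenness normalization degenerates)
#' @return an \linkS4class{MstMetrics}
#' @examples
#' star <- adjacencyMatrix(rbind(c(0, .9, .9), c(.9, 0, .1), c(.9, .1, 0)),
#'                         bandDefinition("theta", 4, 8),
#'                         roiLabels = c("hub", "a", "b"))
#' mstMetrics(buildMst(star))
#' @export
mstMetrics <- function(tree) {
  stopifnot(is(tree, "SpanningTree"))
  n <- tree@nNodes
  if (n < 3L)
    stop("degenerate tree: betweenness normalization requires >= 3 nodes")
  e <- tree@edges
  m <- n - 1L
  deg <- tabulate(c(e[, 1L], e[, 2L]), nbins = n)
  leaves <- sum(deg == 1L)
  adj <- .treeAdjList(n, e)
  ecc <- vapply(seq_len(n), function(s) max(.bfsDepths(adj, n, s)), numeric(1))
  # betweenness on a tree: remove v, component sizes s_k sum to n-1;
  # pairs routed through v = ((n-1)^2 - sum s_k^2) / 2
  bcPairs <- vapply(seq_len(n), function(v) {
    if (deg[v] == 1L) return(0)
    sizes <- vapply(adj[[v]], function(s) {
      depth <- rep.int(-1L, n)
      depth[v] <- 0L; depth[s] <- 1L
      queue <- s
      cnt <- 1L
      while (length(queue)) {
        nxt <- integer(0)
        for (u in queue) for (w in adj[[u]]) if (depth[w] < 0L) {
          depth[w] <- 1L
          nxt <- c(nxt, w)
          cnt <- cnt + 1L
        }
        queue <- nxt
      }
      cnt
    }, integer(1))
    ((n - 1)^2 - sum(as.numeric(sizes)^2)) / 2
  }, numeric(1))
  bcMaxRaw <- max(bcPairs)
  bcMax <- bcMaxRaw / ((n - 1) * (n - 2) / 2)
  metrics <- new("MstMetrics",
                 degreeMax = max(deg) / m,
                 leafFraction = leaves / m,
                 eccentricityMean = mean(ecc) / m,
                 bcMax = bcMax,
                 treeHierarchy = leaves / (2 * m * bcMax),
                 raw = c(degree_max = max(deg), leaf_count = leaves,
                         eccentricity_mean_hops = mean(ecc),
                         bc_max_pairs = bcMaxRaw),
                 nNodes = n)
  metrics
}

#' Per-subject MST profile averaged over epochs
#'
#' Builds the spanning tree and its metrics for every per-epoch PLI matrix
#' and then averages each metric arithmetically across epochs.  Note the
#' order: metrics of per-epoch trees are averaged, never metrics of an
#' averaged matrix (tree construction does not commute with averaging).
#'
#' @param perEpoch non-empty list of per-epoch \linkS4class{AdjacencyMatrix}
#' @return an \linkS4class{MstMetrics} holding epoch-averaged values
#' @export
subjectMstProfile <- function(perEpoch) {
  if (!length(perEpoch)) stop("need at least one epoch matrix")
  ms <- lapply(perEpoch, function(a) mstMetrics(buildMst(a)))
  avg <- function(f) mean(vapply(ms, f, numeric(1)))
  rawAvg <- Reduce(`+`, lapply(ms, function(x) x@raw)) / length(ms)
  new("MstMetrics",
      degreeMax = avg(function(x) x@degreeMax),
      leafFraction = avg(function(x) x@leafFraction),
      eccentricityMean = avg(function(x) x@eccentricityMean),
      bcMax = avg(function(x) x@bcMax),
      treeHierarchy = avg(function(x) x@treeHierarchy),
      raw = rawAvg, nNodes = ms[[1L]]@nNodes)
}
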