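# Shared fixtures and independent oracles used across the suite.

thetaBand <- function() bandDefinition("theta", 4, 8)

# small toy atlas for pipeline-scale tests
tinyAtlas <- function() {
  atlasDefinition(LETTERS[1:6],
                  list(DMN = c("A", "B", "C"),
                       FPN_left = c("D", "E"),
                       FPN_right = c("E", "F")))
}

# random symmetric adjacency in [0, 1] with zero diagonal
randSymAdj <- function(n, band = thetaBand(), labels = sprintf("R%02d", 1:n)) {
  v <- matrix(0, n, n)
  v[upper.tri(v)] <- runif(n * (n - 1) / 2)
  v <- v + t(v)
  adjacencyMatrix(v, band, roiLabels = labels)
}

mkPhaseEpoch <- function(phases, band = thetaBand(), idx = 1L) {
  new("PhaseEpoch", phases = phases, band = band, epochIndex = as.integer(idx))
}

# --- spanning-tree enumeration oracle (Prufer sequences) ------------------

# decode one Prufer sequence into an (n-1) x 2 edge matrix
pruferDecode <- function(pr, n) {
  deg <- tabulate(pr, n) + 1L
  edges <- matrix(0L, n - 1L, 2L)
  for (k in seq_along(pr)) {
    leaf <- which.max(deg == 1L)          # smallest leaf
    edges[k, ] <- c(leaf, pr[k])
    deg[leaf] <- 0L
    deg[pr[k]] <- deg[pr[k]] - 1L
  }
  edges[n - 1L, ] <- which(deg == 1L)
  edges
}

# all labeled spanning trees on n nodes, as a list of edge-index vectors
# into the upper-triangle pair ordering; memoized per n
.treeCatalog <- new.env()
pairIndex <- function(i, j, n) {
  # index of pair (i<j) in column-major upper.tri ordering
  (j - 1L) * (j - 2L) / 2L + i
}
allTreesEdgeIdx <- function(n) {
  key <- as.character(n)
  if (!is.null(.treeCatalog[[key]])) return(.treeCatalog[[key]])
  trees <- if (n == 2L) {
    matrix(pairIndex(1L, 2L, 2L), 1L, 1L)
  } else {
    seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2L)))
    t(apply(seqs, 1L, function(pr) {
      e <- pruferDecode(as.integer(pr), n)
      ij <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
      sort(pairIndex(ij[, 1L], ij[, 2L], n))
    }))
  }
  .treeCatalog[[key]] <- trees
  trees
}

# maximum spanning-tree total weight by exhaustive enumeration
bruteMaxTreeWeight <- function(vals) {
  n <- nrow(vals)
  w <- vals[upper.tri(vals)]
  trees <- allTreesEdgeIdx(n)
  max(rowSums(matrix(w[trees], nrow(trees))))
}

# --- independent tree-metric oracle (all-pairs path walking) --------------

bruteTreeMetrics <- function(edges, n) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1L]; j <- edges[k, 2L]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  # BFS parents from each source, then walk every pair's unique path
  dist <- matrix(0L, n, n)
  through <- numeric(n)
  for (s in seq_len(n)) {
    parent <- rep.int(0L, n); parent[s] <- s
    queue <- s
    order <- s
    while (length(queue)) {
      u <- queue[1L]; queue <- queue[-1L]
      for (v in adj[[u]]) if (parent[v] == 0L) {
        parent[v] <- u
        dist[s, v] <- dist[s, u] + 1L
        queue <- c(queue, v)
      }
    }
    for (t in seq_len(n)) {
      if (t <= s) next
      v <- parent[t]                      # interior nodes of path s..t
      while (v != s) {
        through[v] <- through[v] + 1
        v <- parent[v]
      }
    }
  }
  deg <- lengths(adj)
  m <- n - 1
  list(degreeMax = max(deg) / m,
       leafFraction = sum(deg == 1L) / m,
       eccentricityMean = mean(apply(dist, 1L, max)) / m,
       bcMax = max(through) / (n - 1) / (n - 2) * 2,
       treeHierarchy = sum(deg == 1L) /
         (2 * m * (max(through) / ((n - 1) * (n - 2) / 2))))
}

# cognition fixture: one test per domain, higher-better, population 50/10
flatBattery <- function() {
  data.frame(test = paste0("t_", cognitiveDomains()),
             domain = cognitiveDomains(),
             orientation = "higher_better",
             stringsAsFactors = FALSE)
}
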