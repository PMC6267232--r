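adjFrom <- function(v, labels = sprintf("n%d", seq_len(nrow(v)))) {
  adjacencyMatrix(v, thetaBand(), roiLabels = labels)
}

test_that("the strongest connections form the tree backbone", {
  v <- matrix(0, 3, 3)
  v[1, 2] <- 0.9; v[2, 3] <- 0.8; v[1, 3] <- 0.1
  v <- v + t(v)
  tree <- buildMst(adjFrom(v, c("A", "B", "C")))
  e <- treeEdges(tree)
  expect_identical(nrow(e), 2L)
  expect_setequal(paste(e[, 1], e[, 2]), c("1 2", "2 3"))
  expect_equal(sum(e[, 3]), 1.7, tolerance = 1e-15)
})

test_that("a hub with uniformly strong links yields a star tree", {
  n <- 8
  v <- matrix(0.1, n, n); v[1, ] <- 0.9; v[, 1] <- 0.9; diag(v) <- 0
  tree <- buildMst(adjFrom(v))
  e <- treeEdges(tree)
  expect_true(all(e[, 1] == 1))
  m <- mstMetrics(tree)
  expect_identical(m@leafFraction, 1)
  expect_identical(m@degreeMax, 1)
})

test_that("Kruskal total weight equals exhaustive spanning-tree enumeration", {
  set.seed(13)
  for (rep in 1:40) {
    n <- sample(4:7, 1)
    adj <- randSymAdj(n)
    tree <- buildMst(adj)
    expect_equal(sum(treeEdges(tree)[, 3]),
                 bruteMaxTreeWeight(as.matrix(adj)), tolerance = 1e-12)
  }
})

test_that("tree agrees with igraph's MST on the 1 - PLI distance", {
  skip_if_not_installed("igraph")
  set.seed(14)
  for (rep in 1:10) {
    adj <- randSymAdj(6)
    g <- igraph::graph_from_adjacency_matrix(1 - as.matrix(adj),
                                             mode = "undirected",
                                             weighted = TRUE)
    ig <- igraph::mst(g, algorithm = "prim")
    wIg <- sum(1 - igraph::E(ig)$weight)
    expect_equal(sum(treeEdges(buildMst(adj))[, 3]), wIg,
                 tolerance = 1e-12)
  }
})

test_that("closed-form metrics for star and path are reproduced exactly", {
  n <- 10
  star <- matrix(0.1, n, n); star[1, ] <- 0.9; star[, 1] <- 0.9
  diag(star) <- 0
  m <- mstMetrics(buildMst(adjFrom(star)))
  expect_identical(m@leafFraction, 1)
  expect_identical(m@degreeMax, 1)
  expect_identical(m@bcMax, 1)
  expect_identical(m@treeHierarchy, 0.5)
  expect_equal(m@eccentricityMean, (1 + 9 * 2) / 10 / 9, tolerance = 1e-15)

  path <- matrix(0.1, n, n)
  for (i in 1:(n - 1)) path[i, i + 1] <- path[i + 1, i] <- 0.9
  diag(path) <- 0
  m <- mstMetrics(buildMst(adjFrom(path)))
  expect_equal(m@leafFraction, 2 / 9, tolerance = 1e-15)
  expect_equal(m@degreeMax, 2 / 9, tolerance = 1e-15)
  # central nodes split the path into 4 + 5 -> 20 routed pairs of 36
  expect_equal(m@bcMax, 20 / 36, tolerance = 1e-15)
  expect_equal(m@treeHierarchy, 2 / (2 * 9 * 20 / 36), tolerance = 1e-15)
  expect_equal(m@eccentricityMean, mean(pmax(0:9, 9:0)) / 9,
               tolerance = 1e-15)
})

test_that("tree hierarchy of growing paths decreases toward zero", {
  th <- vapply(c(4, 6, 10, 16, 24), function(n) {
    path <- matrix(0.1, n, n)
    for (i in 1:(n - 1)) path[i, i + 1] <- path[i + 1, i] <- 0.9
    diag(path) <- 0
    mstMetrics(buildMst(adjFrom(path)))@treeHierarchy
  }, numeric(1))
  expect_true(all(diff(th) < 0))
  expect_lt(th[length(th)], 0.2)
})

test_that("metrics agree with the brute-force path-walking oracle", {
  set.seed(15)
  for (rep in 1:15) {
    n <- sample(4:12, 1)
    tree <- buildMst(randSymAdj(n))
    m <- mstMetrics(tree)
    o <- bruteTreeMetrics(treeEdges(tree)[, 1:2, drop = FALSE], n)
    expect_equal(m@degreeMax, o$degreeMax, tolerance = 1e-12)
    expect_equal(m@leafFraction, o$leafFraction, tolerance = 1e-12)
    expect_equal(m@eccentricityMean, o$eccentricityMean, tolerance = 1e-12)
    expect_equal(m@bcMax, o$bcMax, tolerance = 1e-12)
    expect_equal(m@treeHierarchy, o$treeHierarchy, tolerance = 1e-12)
  }
})

test_that("tree betweenness matches igraph on random trees", {
  skip_if_not_installed("igraph")
  set.seed(16)
  for (rep in 1:5) {
    n <- 9
    tree <- buildMst(randSymAdj(n))
    e <- treeEdges(tree)
    g <- igraph::graph_from_edgelist(cbind(e[, 1], e[, 2]), directed = FALSE)
    bcIg <- max(igraph::betweenness(g))
    expect_equal(mstMetrics(tree)@bcMax, bcIg / ((n - 1) * (n - 2) / 2),
                 tolerance = 1e-12)
  }
})

test_that("the tree is invariant under strictly monotone weight transforms", {
  set.seed(17)
  adj <- randSymAdj(7)
  e1 <- treeEdges(buildMst(adj))[, 1:2]
  sq <- as.matrix(adj)^2                  # increasing transform
  e2 <- treeEdges(buildMst(adjFrom(sq, roiLabels(adj))))[, 1:2]
  expect_identical(e1, e2)
  skip_if_not_installed("igraph")
  # the 1/(w + eps) decreasing transform via a minimum spanning tree
  g <- igraph::graph_from_adjacency_matrix(1 / (as.matrix(adj) + 0.01),
                                           mode = "undirected",
                                           weighted = TRUE)
  ig <- igraph::mst(g)
  el <- igraph::as_edgelist(ig, names = FALSE)
  key <- function(m) sort(paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2])))
  expect_identical(key(e1), key(el))
})

test_that("equal weights resolve deterministically by pair order", {
  v <- matrix(0.5, 6, 6); diag(v) <- 0
  e <- treeEdges(buildMst(adjFrom(v)))
  expect_true(all(e[, 1] == 1))           # lexicographic ties -> star at node 1
  expect_identical(e[, 2], as.numeric(2:6))
})

test_that("two-node trees are rejected by the metric normalizations", {
  v <- matrix(c(0, .5, .5, 0), 2)
  tree <- buildMst(adjFrom(v))
  expect_identical(nNodes(tree), 2L)
  expect_error(mstMetrics(tree), "degenerate")
})

test_that("subject profiles average metrics across epochs, not matrices", {
  n <- 10
  star <- matrix(0.1, n, n); star[1, ] <- 0.9; star[, 1] <- 0.9
  diag(star) <- 0
  path <- matrix(0.1, n, n)
  for (i in 1:(n - 1)) path[i, i + 1] <- path[i + 1, i] <- 0.9
  diag(path) <- 0
  aStar <- adjFrom(star); aPath <- adjFrom(path)

  same <- subjectMstProfile(list(aStar, aStar))
  expect_identical(as.data.frame(same), as.data.frame(mstMetrics(buildMst(aStar))))

  mix <- subjectMstProfile(list(aStar, aPath))
  ms <- as.data.frame(mstMetrics(buildMst(aStar)))
  mp <- as.data.frame(mstMetrics(buildMst(aPath)))
  expect_equal(as.numeric(as.data.frame(mix)),
               as.numeric((ms + mp) / 2), tolerance = 1e-15)

  swapped <- subjectMstProfile(list(aPath, aStar))
  expect_identical(as.data.frame(mix), as.data.frame(swapped))
})
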