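# Phase lag index connectivity and its summaries.

#' Phase lag index of a single ROI pair
#'
#' \deqn{PLI = | \langle sign(\Delta\phi(t)) \rangle_t |}
#' where the phase difference is wrapped to (-pi, pi] and samples whose
#' wrapped difference is exactly 0 or pi contribute sign 0 (realized as
#' \code{sign(sin(phi_i - phi_j))}).  PLI is 0 for no consistent lag or a
#' purely zero-lag relation (which volume conduction produces) and 1 for a
#' perfectly consistent nonzero lag.
#'
#' @param phaseI,phaseJ equal-length phase vectors in radians (length >= 2)
#' @return PLI value in [0, 1]
#' @examples
#' t <- seq_len(1000)
#' pliPair(0.02 * t, 0.02 * t - pi / 4)  # constant lag -> 1
#' @export
pliPair <- function(phaseI, phaseJ) {
  if (length(phaseI) != length(phaseJ))
    stop("phase vectors differ in length (", length(phaseI), " vs ",
         length(phaseJ), ")")
  if (length(phaseI) < 2L) stop("need at least 2 samples")
  abs(mean(sign(sin(phaseI - phaseJ))))
}

#' PLI adjacency matrix of one phase epoch
#'
#' Fills all N(N-1)/2 unordered ROI pairs symmetrically; the diagonal is 0.
#' With \code{edgeTrim = TRUE} (default) the first and last 1/16 of the
#' epoch are excluded from the average, suppressing analytic-signal edge
#' artefacts at the epoch boundaries.
#'
#' @param epoch a \linkS4class{PhaseEpoch}
#' @param edgeTrim drop floor(S/16) samples at each end before averaging
#' @return an \linkS4class{AdjacencyMatrix} at level \code{"epoch"}
#' @export
pliMatrix <- function(epoch, edgeTrim = TRUE) {
  stopifnot(is(epoch, "PhaseEpoch"))
  ph <- epoch@phases
  if (nrow(ph) < 2L) stop("need at least 2 ROIs")
  if (isTRUE(edgeTrim)) {
    drop <- ncol(ph) %/% 16L
    if (ncol(ph) - 2L * drop < 2L)
      stop("epoch too short after edge trimming")
    if (drop > 0L) ph <- ph[, (drop + 1L):(ncol(ph) - drop), drop = FALSE]
  }
  vals <- pliMatrixCpp(ph)
  adjacencyMatrix(vals, band = epoch@band, level = "epoch",
                  roiLabels = rownames(epoch@phases))
}

#' Average adjacency matrices over epochs
#'
#' Entrywise arithmetic mean of per-epoch PLI matrices from the same
#' subject, band and ROI set.
#'
#' @param mats non-empty list of \linkS4class{AdjacencyMatrix} with
#'   identical ROI labels and band
#' @return an \linkS4class{AdjacencyMatrix} at level \code{"epoch-averaged"}
#' @export
averageEpochs <- function(mats) {
  if (!length(mats)) stop("need at least one matrix")
  stopifnot(all(vapply(mats, is, logical(1), "AdjacencyMatrix")))
  lab <- roiLabels(mats[[1L]])
  bnd <- bandOf(mats[[1L]])
  for (m in mats) {
    if (!identical(roiLabels(m), lab))
      stop("ROI labels differ between epoch matrices")
    if (!identical(bandOf(m)@name, bnd@name))
      stop("bands differ between epoch matrices")
  }
  avg <- Reduce(`+`, lapply(mats, as.matrix)) / length(mats)
  adjacencyMatrix(avg, band = bnd, level = "epoch-averaged", roiLabels = lab)
}

#' Mean PLI within a resting-state network
#'
#' Mean of the PLI values over all unordered pairs of ROIs inside one RSN
#' (between-RSN pairs are excluded).
#'
#' @param adj an \linkS4class{AdjacencyMatrix}
#' @param atlas an \linkS4class{AtlasDefinition} defining the RSN
#' @param rsn RSN name (must have >= 2 members present in \code{adj})
#' @return mean within-RSN PLI
#' @export
rsnMean <- function(adj, atlas, rsn) {
  stopifnot(is(adj, "AdjacencyMatrix"), is(atlas, "AtlasDefinition"))
  members <- rsnMembers(atlas, rsn)
  if (length(members) < 2L)
    stop("RSN '", rsn, "' has fewer than 2 members")
  missing <- setdiff(members, roiLabels(adj))
  if (length(missing))
    stop("RSN '", rsn, "' member(s) absent from the matrix: ",
         paste(missing, collapse = ", "))
  sub <- as.matrix(adj)[members, members, drop = FALSE]
  mean(sub[upper.tri(sub)])
}

#' Mean PLI over the global network
#'
#' Mean over all N(N-1)/2 unordered ROI pairs.
#'
#' @param adj an \linkS4class{AdjacencyMatrix}
#' @return global mean PLI
#' @export
globalMean <- function(adj) {
  stopifnot(is(adj, "AdjacencyMatrix"))
  v <- as.matrix(adj)
  mean(v[upper.tri(v)])
}
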