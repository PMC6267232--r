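# Central S4 classes.  All matrices are base matrices with ROI labels kept in
# dimnames; accessors (AllGenerics.R) are the supported interface.

#' Frequency band definition
#'
#' A named frequency band \code{[loHz, hiHz]} used for band-limiting and for
#' labelling connectivity matrices.  The packaged defaults
#' (\code{\link{defaultBands}}) are theta 4-8 Hz, lower alpha 8-10 Hz and
#' upper alpha 10-13 Hz.
#'
#' @slot name single character band name
#' @slot loHz,hiHz band edges in Hz, \code{0 < loHz < hiHz}
#' @export
setClass("BandDefinition",
  representation(name = "character", loHz = "numeric", hiHz = "numeric"),
  validity = function(object) {
    if (length(object@name) != 1L || !nzchar(object@name))
      return("band name must be a single non-empty string")
    if (length(object@loHz) != 1L || length(object@hiHz) != 1L)
      return("band edges must be single numbers")
    if (!is.finite(object@loHz) || !is.finite(object@hiHz))
      return("band edges must be finite")
    if (object@loHz <= 0) return("loHz must be > 0")
    if (object@hiHz <= object@loHz) return("hiHz must exceed loHz")
    TRUE
  })

#' @param name single character band name
#' @param loHz,hiHz band edges in Hz
#' @rdname BandDefinition-class
#' @export
bandDefinition <- function(name, loHz, hiHz) {
  new("BandDefinition", name = as.character(name),
      loHz = as.numeric(loHz), hiHz = as.numeric(hiHz))
}

#' Default analysis bands
#'
#' Theta (4-8 Hz), lower alpha (8-10 Hz) and upper alpha (10-13 Hz), the
#' bands in which brain-behaviour associations are typically sought in
#' resting-state MEG work on brain-tumour cohorts.
#'
#' @return named list of \linkS4class{BandDefinition}
#' @export
defaultBands <- function() {
  list(theta  = bandDefinition("theta", 4, 8),
       alpha1 = bandDefinition("alpha1", 8, 10),
       alpha2 = bandDefinition("alpha2", 10, 13))
}

#' ROI time-series container
#'
#' One multichannel recording: an N x T real matrix with one row per atlas
#' region of interest (ROI), plus the sample rate.  ROI labels live in the
#' rownames and are unique; values must be finite.
#'
#' @slot subjectId single character subject identifier
#' @slot data N x T numeric matrix, rownames = ROI labels
#' @slot sampleRateHz positive sampling rate in Hz
#' @export
setClass("RoiTimeSeries",
  representation(subjectId = "character", data = "matrix",
                 sampleRateHz = "numeric"),
  validity = function(object) {
    d <- object@data
    if (!is.numeric(d)) return("data must be numeric")
    if (nrow(d) < 2L) return("need at least 2 ROIs")
    if (ncol(d) < 1L) return("need at least 1 sample")
    if (is.null(rownames(d))) return("data must carry ROI labels as rownames")
    if (anyDuplicated(rownames(d))) return("ROI labels must be unique")
    if (!all(is.finite(d))) return("non-finite values in time series")
    if (length(object@sampleRateHz) != 1L || !is.finite(object@sampleRateHz) ||
        object@sampleRateHz <= 0)
      return("sampleRateHz must be a single positive number")
    if (length(object@subjectId) != 1L)
      return("subjectId must be a single string")
    TRUE
  })

#' @param data N x T numeric matrix (rows = ROIs)
#' @param sampleRateHz sampling rate in Hz
#' @param roiLabels character vector of ROI labels (defaults to rownames)
#' @param subjectId subject identifier
#' @rdname RoiTimeSeries-class
#' @export
roiTimeSeries <- function(data, sampleRateHz, roiLabels = rownames(data),
                          subjectId = "subject") {
  data <- as.matrix(data)
  if (is.null(roiLabels))
    roiLabels <- sprintf("ROI%03d", seq_len(nrow(data)))
  if (length(roiLabels) != nrow(data))
    stop("roiLabels length (", length(roiLabels),
         ") does not match number of rows (", nrow(data), ")")
  rownames(data) <- roiLabels
  colnames(data) <- NULL
  new("RoiTimeSeries", subjectId = as.character(subjectId), data = data,
      sampleRateHz = as.numeric(sampleRateHz))
}

#' Instantaneous-phase epoch
#'
#' Phases (radians, wrapped to (-pi, pi]) of one band-limited epoch, N ROIs
#' by epoch length, as consumed by the phase lag index.
#'
#' @slot phases N x S numeric matrix of phases, rownames = ROI labels
#' @slot band the \linkS4class{BandDefinition} the signal was limited to
#' @slot epochIndex 1-based epoch position within the recording
#' @export
setClass("PhaseEpoch",
  representation(phases = "matrix", band = "BandDefinition",
                 epochIndex = "integer"),
  validity = function(object) {
    p <- object@phases
    if (!is.numeric(p) || !all(is.finite(p))) return("phases must be finite")
    if (is.null(rownames(p))) return("phases must carry ROI labels")
    tol <- 1e-9
    if (any(p > pi + tol) || any(p <= -pi - tol))
      return("phases must be wrapped to (-pi, pi]")
    TRUE
  })

#' Atlas and resting-state-network definition
#'
#' Ordered ROI labels plus named resting-state networks (RSNs), each a
#' subset of the labels.  The packaged default (\code{\link{defaultAtlas}})
#' is the 78-region cortical subset of the AAL atlas with literature-based
#' DMN / left and right frontoparietal assignments.
#'
#' @slot roiLabels ordered character vector of ROI labels
#' @slot rsnMemberships named list; each element a character subset of
#'   \code{roiLabels}
#' @export
setClass("AtlasDefinition",
  representation(roiLabels = "character", rsnMemberships = "list"),
  validity = function(object) {
    if (length(object@roiLabels) < 2L) return("need at least 2 ROI labels")
    if (anyDuplicated(object@roiLabels)) return("ROI labels must be unique")
    m <- object@rsnMemberships
    if (length(m)) {
      if (is.null(names(m)) || any(!nzchar(names(m))))
        return("RSNs must be named")
      if (anyDuplicated(names(m))) return("duplicate RSN names")
      for (nm in names(m)) {
        mem <- m[[nm]]
        if (!is.character(mem))
          return(sprintf("RSN '%s' members must be character", nm))
        bad <- setdiff(mem, object@roiLabels)
        if (length(bad))
          return(sprintf("RSN '%s' member(s) not in roiLabels: %s",
                         nm, paste(bad, collapse = ", ")))
        if (anyDuplicated(mem))
          return(sprintf("RSN '%s' has duplicate members", nm))
      }
    }
    TRUE
  })

#' @param roiLabels ordered character vector of ROI labels
#' @param rsnMemberships named list of character vectors
#' @rdname AtlasDefinition-class
#' @export
atlasDefinition <- function(roiLabels, rsnMemberships = list()) {
  new("AtlasDefinition", roiLabels = as.character(roiLabels),
      rsnMemberships = lapply(rsnMemberships, as.character))
}

#' Symmetric PLI adjacency matrix
#'
#' Phase-lag-index values for all unordered ROI pairs: symmetric, zero
#' diagonal, entries in [0, 1].  \code{level} records whether the matrix is
#' a single epoch's estimate or an epoch average.
#'
#' @slot values symmetric N x N numeric matrix, dimnames = ROI labels
#' @slot band the \linkS4class{BandDefinition} it was computed in
#' @slot level \code{"epoch"} or \code{"epoch-averaged"}
#' @export
setClass("AdjacencyMatrix",
  representation(values = "matrix", band = "BandDefinition",
                 level = "character"),
  validity = function(object) {
    v <- object@values
    if (!is.numeric(v) || nrow(v) != ncol(v)) return("values must be square")
    if (nrow(v) < 2L) return("need at least 2 ROIs")
    if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
      return("values must carry identical row/col ROI labels")
    if (!all(is.finite(v))) return("non-finite connectivity values")
    if (max(abs(v - t(v))) > 1e-12) return("matrix not symmetric (tol 1e-12)")
    if (any(diag(v) != 0)) return("diagonal must be exactly 0")
    if (min(v) < 0 || max(v) > 1) return("entries must lie in [0, 1]")
    if (!object@level %in% c("epoch", "epoch-averaged"))
      return("level must be 'epoch' or 'epoch-averaged'")
    TRUE
  })

#' @param values symmetric numeric matrix
#' @param band a \linkS4class{BandDefinition}
#' @param level \code{"epoch"} or \code{"epoch-averaged"}
#' @param roiLabels optional labels if \code{values} lacks dimnames
#' @rdname AdjacencyMatrix-class
#' @export
adjacencyMatrix <- function(values, band, level = "epoch",
                            roiLabels = rownames(values)) {
  values <- as.matrix(values)
  if (!is.null(roiLabels)) dimnames(values) <- list(roiLabels, roiLabels)
  new("AdjacencyMatrix", values = values, band = band, level = level)
}

#' Spanning tree of a connectivity matrix
#'
#' An acyclic connected subgraph on \code{nNodes} nodes with exactly
#' \code{nNodes - 1} edges; edge weights keep the original PLI values.
#'
#' @slot nNodes number of nodes
#' @slot edges (nNodes-1) x 3 matrix, columns \code{i}, \code{j},
#'   \code{weight}, with \code{i < j} (1-based node indices)
#' @slot nodeLabels character vector of node labels
#' @export
setClass("SpanningTree",
  representation(nNodes = "integer", edges = "matrix",
                 nodeLabels = "character"),
  validity = function(object) {
    n <- object@nNodes
    e <- object@edges
    if (n < 2L) return("need at least 2 nodes")
    if (nrow(e) != n - 1L || ncol(e) != 3L)
      return("edges must be an (nNodes-1) x 3 matrix")
    ii <- e[, 1L]; jj <- e[, 2L]
    if (any(ii < 1 | ii > n | jj < 1 | jj > n | ii != floor(ii) |
            jj != floor(jj)))
      return("invalid node indices")
    if (any(ii >= jj)) return("edges must satisfy i < j")
    # connectivity (and hence acyclicity, given n-1 edges) via union-find
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
    for (k in seq_len(nrow(e))) {
      a <- find(ii[k]); b <- find(jj[k])
      if (a == b) return("edges contain a cycle")
      parent[a] <- b
    }
    if (length(object@nodeLabels) != n)
      return("nodeLabels length must equal nNodes")
    TRUE
  })

#' Global minimum-spanning-tree metrics
#'
#' The five global tree metrics, each normalized to (0, 1]:
#' \describe{
#'   \item{degreeMax}{maximum node degree / (N-1)}
#'   \item{leafFraction}{number of leaves L / (N-1)}
#'   \item{eccentricityMean}{mean hop eccentricity / (N-1)}
#'   \item{bcMax}{maximum betweenness centrality, as a fraction of the
#'     (N-1)(N-2)/2 node pairs not involving the central node}
#'   \item{treeHierarchy}{L / (2 m bcMax) with m = N-1 edges; 0.5 for a
#'     star, tending to 0 for long paths}
#' }
#' Raw (unnormalized) values are kept alongside in \code{raw}.
#'
#' @slot degreeMax,leafFraction,eccentricityMean,bcMax,treeHierarchy
#'   normalized metrics
#' @slot raw named numeric vector of unnormalized values (max degree, leaf
#'   count, mean eccentricity in hops, max betweenness in pair counts)
#' @slot nNodes number of tree nodes the metrics refer to
#' @export
setClass("MstMetrics",
  representation(degreeMax = "numeric", leafFraction = "numeric",
                 eccentricityMean = "numeric", bcMax = "numeric",
                 treeHierarchy = "numeric", raw = "numeric",
                 nNodes = "integer"),
  validity = function(object) {
    v <- c(object@degreeMax, object@leafFraction, object@eccentricityMean,
           object@bcMax, object@treeHierarchy)
    if (length(v) != 5L || !all(is.finite(v))) return("metrics must be finite")
    if (any(v <= 0) || any(v > 1)) return("normalized metrics must lie in (0, 1]")
    TRUE
  })

#' Nonparametric test result
#'
#' Container for a Mann-Whitney U or Kendall tau-b result.
#'
#' @slot statistic the U statistic or tau-b coefficient
#' @slot pValue p-value in [0, 1]
#' @slot n1,n2 sample sizes (\code{n2 = 0} for correlations)
#' @slot sided \code{"one"} or \code{"two"}
#' @slot method \code{"exact"} or \code{"normal-approx"}
#' @export
setClass("StatResult",
  representation(statistic = "numeric", pValue = "numeric",
                 n1 = "integer", n2 = "integer", sided = "character",
                 method = "character"),
  validity = function(object) {
    if (!is.finite(object@pValue) || object@pValue < 0 || object@pValue > 1)
      return("pValue must lie in [0, 1]")
    if (!object@sided %in% c("one", "two")) return("sided must be one|two")
    if (!object@method %in% c("exact", "normal-approx"))
      return("method must be exact|normal-approx")
    TRUE
  })

#' Synthetic-cohort generation parameters
#'
#' All knobs of the coupled-oscillator cohort generator.  The defaults are
#' the emulated study conditions: 20 patients and 20 controls, 78 cortical
#' ROIs, 5 epochs of 4096 samples at 625 Hz, theta-band oscillators, and a
#' working-memory deficit of -0.55 SD in patients whose working-memory
#' score is rank-linked to each subject's within-DMN coupling strength.
#'
#' @slot nPatients,nControls cohort sizes
#' @slot nRois number of regions (default 78)
#' @slot sampleRateHz sampling rate (default 625)
#' @slot epochSamples samples per epoch (default 4096)
#' @slot nEpochs epochs per subject (default 5)
#' @slot band \linkS4class{BandDefinition} the oscillators live in
#' @slot kappaLo,kappaHi range of the uniform per-subject within-RSN
#'   coupling strength kappa_s (per neighbour, radians/step)
#' @slot backgroundCoupling coupling between all other pairs
#' @slot couplingLagRad phase lag delta of the coupling, in (0, pi); a
#'   nonzero lag makes the interaction visible to the PLI
#' @slot couplingCognitionEffect target Kendall tau between the measured
#'   within-RSN PLI and the working-memory z-score (|effect| < 1)
#' @slot pliRankFidelity calibration constant of the generator: the
#'   Kendall tau between the measured within-RSN theta PLI and the true
#'   kappa_s under the default conditions; used to de-attenuate the
#'   kappa-cognition link so the PLI-cognition tau lands on the target
#' @slot wmShiftSd mean shift (in control-SD units) added to patients'
#'   working-memory scores (default -0.55)
#' @slot phaseNoiseSd SD of the per-step phase noise (radians)
#' @slot obsNoiseSd SD of the additive white measurement noise on the
#'   unit-amplitude signal
#' @slot burnIn transient samples discarded before recording
#' @slot seed RNG seed for the whole cohort
#' @export
setClass("CohortConfig",
  representation(nPatients = "integer", nControls = "integer",
                 nRois = "integer", sampleRateHz = "numeric",
                 epochSamples = "integer", nEpochs = "integer",
                 band = "BandDefinition",
                 kappaLo = "numeric", kappaHi = "numeric",
                 backgroundCoupling = "numeric", couplingLagRad = "numeric",
                 couplingCognitionEffect = "numeric",
                 pliRankFidelity = "numeric", wmShiftSd = "numeric",
                 phaseNoiseSd = "numeric", obsNoiseSd = "numeric",
                 burnIn = "integer", seed = "integer"),
  validity = function(object) {
    if (object@nPatients < 1L || object@nControls < 0L)
      return("need at least 1 patient")
    if (object@nRois < 2L) return("need at least 2 ROIs")
    if (object@nEpochs < 1L) return("nEpochs must be >= 1")
    if (object@epochSamples < 64L) return("epochSamples must be >= 64")
    if (object@sampleRateHz <= 0) return("sampleRateHz must be positive")
    if (object@band@hiHz >= object@sampleRateHz / 2)
      return("band must lie below the Nyquist frequency")
    if (object@backgroundCoupling < 0 ||
        object@backgroundCoupling > object@kappaLo ||
        object@kappaLo > object@kappaHi)
      return("need 0 <= backgroundCoupling <= kappaLo <= kappaHi")
    if (object@couplingLagRad <= 0 || object@couplingLagRad >= pi)
      return("couplingLagRad must lie in (0, pi)")
    if (abs(object@couplingCognitionEffect) >= 1)
      return("infeasible coupling-cognition effect: |effect| must be < 1")
    if (object@pliRankFidelity <= 0 || object@pliRankFidelity > 1)
      return("pliRankFidelity must lie in (0, 1]")
    if (object@phaseNoiseSd <= 0 || object@obsNoiseSd < 0)
      return("phaseNoiseSd must be > 0 and obsNoiseSd >= 0")
    if (object@burnIn < 0L) return("burnIn must be >= 0")
    TRUE
  })

#' Synthetic cohort with ground truth
#'
#' Output of \code{\link{generateCohort}}: per-subject ROI time series (for
#' subjects with simulated MEG), group tags, the true per-subject DMN
#' coupling strengths kappa_s, long-format cognitive raw scores, the
#' control norms, and the battery metadata.
#'
#' @slot config the \linkS4class{CohortConfig} used
#' @slot atlas the \linkS4class{AtlasDefinition} used
#' @slot rsn name of the coupling-bearing RSN (default \code{"DMN"})
#' @slot subjects named list of \linkS4class{RoiTimeSeries}
#' @slot groups named character vector, \code{"patient"} or \code{"control"}
#' @slot kappa named numeric vector of true coupling strengths
#' @slot cognition data.frame: subject_id, group, test, raw_score
#' @slot norms data.frame: test, mean, sd (matched-control reference)
#' @slot battery data.frame: test, domain, orientation
#' @export
setClass("SyntheticCohort",
  representation(config = "CohortConfig", atlas = "AtlasDefinition",
                 rsn = "character", subjects = "list", groups = "character",
                 kappa = "numeric", cognition = "data.frame",
                 norms = "data.frame", battery = "data.frame"))
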