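# Generics, accessors and show methods.

#' @rdname RoiTimeSeries-class
#' @param object,x a megnet S4 object
#' @export
setGeneric("roiLabels", function(object) standardGeneric("roiLabels"))
#' @rdname RoiTimeSeries-class
#' @export
setGeneric("sampleRate", function(object) standardGeneric("sampleRate"))
#' @rdname RoiTimeSeries-class
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))
#' @rdname RoiTimeSeries-class
#' @export
setGeneric("nRois", function(object) standardGeneric("nRois"))
#' @rdname RoiTimeSeries-class
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))

#' @rdname RoiTimeSeries-class
#' @export
setMethod("roiLabels", "RoiTimeSeries", function(object) rownames(object@data))
#' @rdname RoiTimeSeries-class
#' @export
setMethod("sampleRate", "RoiTimeSeries", function(object) object@sampleRateHz)
#' @rdname RoiTimeSeries-class
#' @export
setMethod("subjectId", "RoiTimeSeries", function(object) object@subjectId)
#' @rdname RoiTimeSeries-class
#' @export
setMethod("nRois", "RoiTimeSeries", function(object) nrow(object@data))
#' @rdname RoiTimeSeries-class
#' @export
setMethod("nSamples", "RoiTimeSeries", function(object) ncol(object@data))

#' @rdname RoiTimeSeries-class
#' @param ... unused
#' @export
setMethod("as.matrix", "RoiTimeSeries", function(x, ...) x@data)

setMethod("show", "RoiTimeSeries", function(object) {
  cat(sprintf("RoiTimeSeries '%s': %d ROIs x %d samples @ %g Hz (%.3f s)\n",
              object@subjectId, nrow(object@data), ncol(object@data),
              object@sampleRateHz, ncol(object@data) / object@sampleRateHz))
})

#' @rdname AtlasDefinition-class
#' @export
setMethod("roiLabels", "AtlasDefinition", function(object) object@roiLabels)
#' @rdname AtlasDefinition-class
#' @export
setMethod("nRois", "AtlasDefinition", function(object) length(object@roiLabels))

#' @rdname AtlasDefinition-class
#' @export
setGeneric("rsnNames", function(object) standardGeneric("rsnNames"))
#' @rdname AtlasDefinition-class
#' @export
setMethod("rsnNames", "AtlasDefinition",
          function(object) names(object@rsnMemberships))

#' @rdname AtlasDefinition-class
#' @param rsn RSN name
#' @export
setGeneric("rsnMembers", function(object, rsn) standardGeneric("rsnMembers"))
#' @rdname AtlasDefinition-class
#' @export
setMethod("rsnMembers", "AtlasDefinition", function(object, rsn) {
  if (!rsn %in% names(object@rsnMemberships))
    stop("unknown RSN '", rsn, "'; available: ",
         paste(names(object@rsnMemberships), collapse = ", "))
  object@rsnMemberships[[rsn]]
})

setMethod("show", "AtlasDefinition", function(object) {
  cat(sprintf("AtlasDefinition: %d ROIs, %d RSN(s)\n",
              length(object@roiLabels), length(object@rsnMemberships)))
  for (nm in names(object@rsnMemberships))
    cat(sprintf("  %s: %d ROIs\n", nm, length(object@rsnMemberships[[nm]])))
})

#' @rdname AdjacencyMatrix-class
#' @export
setMethod("roiLabels", "AdjacencyMatrix", function(object) rownames(object@values))
#' @rdname AdjacencyMatrix-class
#' @export
setMethod("nRois", "AdjacencyMatrix", function(object) nrow(object@values))
#' @rdname AdjacencyMatrix-class
#' @param x,... see \code{as.matrix}
#' @export
setMethod("as.matrix", "AdjacencyMatrix", function(x, ...) x@values)

#' @rdname AdjacencyMatrix-class
#' @export
setGeneric("bandOf", function(object) standardGeneric("bandOf"))
#' @rdname AdjacencyMatrix-class
#' @export
setMethod("bandOf", "AdjacencyMatrix", function(object) object@band)
#' @rdname PhaseEpoch-class
#' @export
setMethod("bandOf", "PhaseEpoch", function(object) object@band)
#' @rdname PhaseEpoch-class
#' @param object a \linkS4class{PhaseEpoch}
#' @export
setMethod("roiLabels", "PhaseEpoch", function(object) rownames(object@phases))

setMethod("show", "AdjacencyMatrix", function(object) {
  v <- object@values[upper.tri(object@values)]
  cat(sprintf("AdjacencyMatrix (%s, %s): %d ROIs, PLI mean %.4f [%.4f, %.4f]\n",
              object@band@name, object@level, nrow(object@values),
              mean(v), min(v), max(v)))
})

#' @rdname SpanningTree-class
#' @export
setGeneric("nNodes", function(object) standardGeneric("nNodes"))
#' @rdname SpanningTree-class
#' @export
setMethod("nNodes", "SpanningTree", function(object) object@nNodes)

#' @rdname SpanningTree-class
#' @export
setGeneric("treeEdges", function(object) standardGeneric("treeEdges"))
#' @rdname SpanningTree-class
#' @export
setMethod("treeEdges", "SpanningTree", function(object) object@edges)

setMethod("show", "SpanningTree", function(object) {
  cat(sprintf("SpanningTree: %d nodes, %d edges, total weight %.4f\n",
              object@nNodes, nrow(object@edges), sum(object@edges[, 3L])))
})

#' @rdname MstMetrics-class
#' @param x an \linkS4class{MstMetrics}
#' @param row.names,optional,... see \code{as.data.frame}
#' @export
setMethod("as.data.frame", "MstMetrics",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(degree_max = x@degreeMax, leaf_fraction = x@leafFraction,
               eccentricity_mean = x@eccentricityMean, bc_max = x@bcMax,
               tree_hierarchy = x@treeHierarchy)
  })

setMethod("show", "MstMetrics", function(object) {
  cat(sprintf(paste0("MstMetrics (N = %d): degree_max %.3f, leaf_fraction ",
                     "%.3f, eccentricity_mean %.3f, bc_max %.3f, ",
                     "tree_hierarchy %.3f\n"),
              object@nNodes, object@degreeMax, object@leafFraction,
              object@eccentricityMean, object@bcMax, object@treeHierarchy))
})

#' @rdname StatResult-class
#' @param x a \linkS4class{StatResult}
#' @param row.names,optional,... see \code{as.data.frame}
#' @export
setMethod("as.data.frame", "StatResult",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(statistic = x@statistic, p = x@pValue, n1 = x@n1, n2 = x@n2,
               sided = x@sided, method = x@method)
  })

setMethod("show", "StatResult", function(object) {
  cat(sprintf("StatResult: statistic = %g, p = %.4g (%s-sided, %s; n1 = %d%s)\n",
              object@statistic, object@pValue, object@sided, object@method,
              object@n1,
              if (object@n2 > 0) sprintf(", n2 = %d", object@n2) else ""))
})

#' @rdname StatResult-class
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))
#' @rdname StatResult-class
#' @export
setMethod("pValue", "StatResult", function(object) object@pValue)
#' @rdname StatResult-class
#' @export
setGeneric("statistic", function(object) standardGeneric("statistic"))
#' @rdname StatResult-class
#' @export
setMethod("statistic", "StatResult", function(object) object@statistic)

#' @rdname CohortConfig-class
#' @export
setGeneric("epochDuration", function(object) standardGeneric("epochDuration"))
#' Epoch duration in seconds (epochSamples / sampleRateHz)
#' @rdname CohortConfig-class
#' @param object a \linkS4class{CohortConfig}
#' @export
setMethod("epochDuration", "CohortConfig",
          function(object) object@epochSamples / object@sampleRateHz)

setMethod("show", "CohortConfig", function(object) {
  cat(sprintf(paste0("CohortConfig: %d patients / %d controls, %d ROIs, ",
                     "%d x %d samples @ %g Hz (%.4f s epochs)\n"),
              object@nPatients, object@nControls, object@nRois,
              object@nEpochs, object@epochSamples, object@sampleRateHz,
              epochDuration(object)))
  cat(sprintf("  band %s [%g, %g] Hz; kappa U[%g, %g]; background %g; lag %.3f rad\n",
              object@band@name, object@band@loHz, object@band@hiHz,
              object@kappaLo, object@kappaHi, object@backgroundCoupling,
              object@couplingLagRad))
  cat(sprintf("  coupling-cognition effect %.2f; WM shift %.2f SD; seed %d\n",
              object@couplingCognitionEffect, object@wmShiftSd, object@seed))
})

setMethod("show", "SyntheticCohort", function(object) {
  cat(sprintf("SyntheticCohort: %d patients, %d controls, %d with MEG (RSN %s)\n",
              sum(object@groups == "patient"),
              sum(object@groups == "control"),
              length(object@subjects), object@rsn))
})

#' @rdname SyntheticCohort-class
#' @export
setGeneric("cohortGroups", function(object) standardGeneric("cohortGroups"))
#' @rdname SyntheticCohort-class
#' @param object a \linkS4class{SyntheticCohort}
#' @export
setMethod("cohortGroups", "SyntheticCohort", function(object) object@groups)
#' @rdname SyntheticCohort-class
#' @export
setGeneric("cohortSubjects", function(object) standardGeneric("cohortSubjects"))
#' @rdname SyntheticCohort-class
#' @export
setMethod("cohortSubjects", "SyntheticCohort", function(object) object@subjects)
#' @rdname SyntheticCohort-class
#' @export
setGeneric("trueKappa", function(object) standardGeneric("trueKappa"))
#' @rdname SyntheticCohort-class
#' @export
setMethod("trueKappa", "SyntheticCohort", function(object) object@kappa)
#' @rdname SyntheticCohort-class
#' @export
setGeneric("cohortCognition", function(object) standardGeneric("cohortCognition"))
#' @rdname SyntheticCohort-class
#' @export
setMethod("cohortCognition", "SyntheticCohort", function(object) object@cognition)
#' @rdname SyntheticCohort-class
#' @export
setGeneric("cohortConfigOf", function(object) standardGeneric("cohortConfigOf"))
#' @rdname SyntheticCohort-class
#' @export
setMethod("cohortConfigOf", "SyntheticCohort", function(object) object@config)
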