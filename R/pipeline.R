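# End-to-end orchestration: connectivity/MST profiles per subject and band,
# the three result tables, and reproducible report output.

.mstMeasureNames <- c(mst_degree = "degreeMax", mst_leaf = "leafFraction",
                      mst_eccentricity = "eccentricityMean",
                      mst_bc = "bcMax", mst_th = "treeHierarchy")

#' Per-subject network profiles for each band
#'
#' For every subject with MEG data: band-pass, segment into epochs,
#' extract instantaneous phase, compute per-epoch PLI matrices, then (a)
#' average the matrices over epochs and summarize mean PLI within each
#' atlas RSN and globally, and (b) build per-epoch spanning trees and
#' average their metrics over epochs.
#'
#' @param cohort a \linkS4class{SyntheticCohort} (or any object whose
#'   \code{cohortSubjects()} returns \linkS4class{RoiTimeSeries})
#' @param bands named list of \linkS4class{BandDefinition} (default: the
#'   band the cohort was generated in)
#' @param epochSamples epoch length (default from the cohort config)
#' @param edgeTrim drop 1/16 of each epoch end before the PLI average
#' @param verbose log per-subject progress
#' @return data.frame, one row per subject x band, with columns
#'   \code{pli_<RSN>} for each RSN, \code{pli_global}, and the five
#'   \code{mst_*} metrics
#' @export
cohortConnectivity <- function(cohort, bands = NULL, epochSamples = NULL,
                               edgeTrim = TRUE, verbose = FALSE) {
  config <- cohortConfigOf(cohort)
  if (is.null(bands)) bands <- stats::setNames(list(config@band),
                                               config@band@name)
  if (is.null(epochSamples)) epochSamples <- config@epochSamples
  atlas <- cohort@atlas
  subjects <- cohortSubjects(cohort)
  if (!length(subjects)) stop("cohort contains no MEG time series")
  rsns <- rsnNames(atlas)
  rows <- list()
  for (id in names(subjects)) {
    ts <- subjects[[id]]
    for (bn in names(bands)) {
      if (verbose)
        message("connectivity: subject ", id, ", band ", bn)
      epochs <- phaseEpochs(ts, bands[[bn]], epochSamples)
      mats <- lapply(epochs, pliMatrix, edgeTrim = edgeTrim)
      avg <- averageEpochs(mats)
      prof <- subjectMstProfile(mats)
      row <- data.frame(subject_id = id, band = bn,
                        stringsAsFactors = FALSE)
      for (r in rsns) row[[paste0("pli_", r)]] <- rsnMean(avg, atlas, r)
      row$pli_global <- globalMean(avg)
      for (m in names(.mstMeasureNames))
        row[[m]] <- slot(prof, .mstMeasureNames[[m]])
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# domain z-scores for one domain, named by subject
.domainZ <- function(profiles, domain, group = NULL) {
  sel <- profiles$domain == domain
  if (!any(sel)) stop("unknown cognitive domain: ", domain)
  if (!is.null(group)) sel <- sel & profiles$group == group
  stats::setNames(profiles$z[sel], profiles$subject_id[sel])
}

#' Group comparison of cognitive functioning
#'
#' Per cognitive domain: group means and SDs of the domain z-scores and a
#' Mann-Whitney U test of patients against controls (one-tailed by
#' default, alternative patients < controls, matching the direction of
#' the expected deficit).  The reported U is the larger of the two U
#' conventions, \code{max(U, n1 n2 - U)}, the layout most software prints
#' for a patient-vs-control table.
#'
#' @param cohort a \linkS4class{SyntheticCohort}
#' @param profiles optional precomputed \code{\link{cognitiveProfiles}}
#' @param sided \code{"one"} (default) or \code{"two"}
#' @return data.frame, one row per domain
#' @export
runGroupComparison <- function(cohort, profiles = NULL,
                               sided = c("one", "two")) {
  sided <- match.arg(sided)
  if (is.null(profiles))
    profiles <- cognitiveProfiles(cohort@cognition, cohort@norms,
                                  cohort@battery)
  domains <- unique(profiles$domain)
  if (!all(cognitiveDomains() %in% domains))
    stop("missing cognitive domain(s): ",
         paste(setdiff(cognitiveDomains(), domains), collapse = ", "))
  out <- do.call(rbind, lapply(cognitiveDomains(), function(d) {
    zp <- .domainZ(profiles, d, "patient")
    zc <- .domainZ(profiles, d, "control")
    if (!length(zp) || !length(zc)) stop("both groups must be non-empty")
    res <- mannWhitneyU(zp, zc, sided = sided, direction = "less")
    u <- statistic(res)
    data.frame(domain = d,
               patient_mean = mean(zp), patient_sd = sd(zp),
               control_mean = mean(zc), control_sd = sd(zc),
               U = max(u, length(zp) * length(zc) - u),
               p = pValue(res),
               n_patients = length(zp), n_controls = length(zc),
               method = res@method, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Brain-behaviour associations for one cognitive domain
#'
#' Kendall tau-b (two-tailed) between the chosen domain's z-score and,
#' per band, the mean PLI within each RSN plus the five MST metrics
#' (8 measures per band for the packaged three-RSN atlas), computed over
#' the patients with MEG data.
#'
#' @inheritParams cohortConnectivity
#' @param domain cognitive domain name
#' @param conn optional precomputed \code{\link{cohortConnectivity}} table
#' @param profiles optional precomputed \code{\link{cognitiveProfiles}}
#' @return data.frame: domain, band, measure, tau, p, n
#' @export
runBrainBehaviour <- function(cohort, domain = "working_memory",
                              bands = NULL, conn = NULL, profiles = NULL,
                              edgeTrim = TRUE) {
  if (is.null(conn))
    conn <- cohortConnectivity(cohort, bands = bands, edgeTrim = edgeTrim)
  if (is.null(profiles))
    profiles <- cognitiveProfiles(cohort@cognition, cohort@norms,
                                  cohort@battery)
  z <- .domainZ(profiles, domain, "patient")
  measures <- setdiff(names(conn), c("subject_id", "band", "pli_global"))
  out <- list()
  for (bn in unique(conn$band)) {
    sub <- conn[conn$band == bn, ]
    ids <- intersect(sub$subject_id, names(z))
    if (length(ids) < 3L)
      stop("fewer than 3 patients with both MEG and cognition")
    zi <- z[ids]
    sub <- sub[match(ids, sub$subject_id), ]
    for (m in measures) {
      res <- kendallTauB(zi, sub[[m]], sided = "two")
      out[[length(out) + 1L]] <-
        data.frame(domain = domain, band = bn, measure = m,
                   tau = statistic(res), p = pValue(res),
                   n = length(ids), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Global-network correlations for all domains
#'
#' Kendall tau-b (two-tailed) of each of the six cognitive domains
#' against the global mean PLI, per band (a 6 x bands grid), over
#' patients.
#'
#' @inheritParams runBrainBehaviour
#' @return data.frame: domain, band, tau, p, n
#' @export
runGlobalCorrelations <- function(cohort, bands = NULL, conn = NULL,
                                  profiles = NULL, edgeTrim = TRUE) {
  if (is.null(conn))
    conn <- cohortConnectivity(cohort, bands = bands, edgeTrim = edgeTrim)
  if (is.null(profiles))
    profiles <- cognitiveProfiles(cohort@cognition, cohort@norms,
                                  cohort@battery)
  out <- list()
  for (d in cognitiveDomains()) {
    z <- .domainZ(profiles, d, "patient")
    for (bn in unique(conn$band)) {
      sub <- conn[conn$band == bn, ]
      ids <- intersect(sub$subject_id, names(z))
      if (length(ids) < 3L)
        stop("fewer than 3 patients with both MEG and cognition")
      res <- kendallTauB(z[ids],
                         sub$pli_global[match(ids, sub$subject_id)],
                         sided = "two")
      out[[length(out) + 1L]] <-
        data.frame(domain = d, band = bn, tau = statistic(res),
                   p = pValue(res), n = length(ids),
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Run the full analysis and emit the three result tables
#'
#' Orchestrates cognitive profiling, the group comparison, and the
#' connectivity/MST computations, and returns (optionally writes) the
#' three tables: \code{cognition_group}, \code{rsn_mst_correlations} and
#' \code{global_correlations}.  By default, brain-behaviour correlations
#' are computed only for domains whose group difference reaches
#' \code{p < gateAlpha} (the conditional-analysis rule of the replicated
#' design); set \code{allDomains = TRUE} to analyse every domain.
#'
#' @inheritParams cohortConnectivity
#' @param allDomains analyse all domains instead of gating on the group
#'   comparison
#' @param gateAlpha significance gate for domain selection (default 0.05)
#' @param groupSided sidedness of the group Mann-Whitney tests
#' @param outDir if non-NULL, write TSV tables + JSON manifest here
#' @return invisibly, a list with \code{tables} (the three data.frames),
#'   \code{connectivity} and \code{profiles}
#' @export
runPipeline <- function(cohort, bands = NULL, allDomains = FALSE,
                        gateAlpha = 0.05, groupSided = "one",
                        edgeTrim = TRUE, outDir = NULL, verbose = FALSE) {
  profiles <- cognitiveProfiles(cohort@cognition, cohort@norms,
                                cohort@battery)
  groupTab <- runGroupComparison(cohort, profiles = profiles,
                                 sided = groupSided)
  conn <- cohortConnectivity(cohort, bands = bands, edgeTrim = edgeTrim,
                             verbose = verbose)
  domains <- if (allDomains) {
    cognitiveDomains()
  } else groupTab$domain[groupTab$p < gateAlpha]
  bbTab <- if (length(domains)) {
    do.call(rbind, lapply(domains, function(d) {
      runBrainBehaviour(cohort, domain = d, conn = conn,
                        profiles = profiles)
    }))
  } else {
    data.frame(domain = character(0), band = character(0),
               measure = character(0), tau = numeric(0), p = numeric(0),
               n = integer(0), stringsAsFactors = FALSE)
  }
  globalTab <- runGlobalCorrelations(cohort, conn = conn,
                                     profiles = profiles)
  tables <- list(cognition_group = groupTab,
                 rsn_mst_correlations = bbTab,
                 global_correlations = globalTab)
  if (!is.null(outDir))
    writeReport(tables, outDir, config = cohortConfigOf(cohort),
                seed = cohortConfigOf(cohort)@seed)
  invisible(list(tables = tables, connectivity = conn,
                 profiles = profiles))
}
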