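# Reading/writing of external artifacts: time-series matrices (TSV + JSON
# sidecar, or Arrow Feather for large runs), atlas/RSN JSON, cognition and
# battery CSVs, result tables with a JSON run manifest.

.isFeather <- function(path) grepl("\\.feather$", path, ignore.case = TRUE)

.defaultHeaderPath <- function(path) {
  paste0(sub("\\.(tsv|txt|feather)$", "", path, ignore.case = TRUE), ".json")
}

#' Read an ROI time-series matrix
#'
#' The matrix file is either tab-separated text (rows = ROIs, no header
#' row) or an Arrow Feather file (columns = ROIs, needs the \pkg{arrow}
#' package); a JSON sidecar supplies \code{subject_id}, \code{roi_labels}
#' and \code{sample_rate_hz}.  Row order follows the header label order.
#'
#' @param path matrix file (\code{.tsv} or \code{.feather})
#' @param headerPath JSON sidecar; defaults to \code{path} with its
#'   extension replaced by \code{.json}
#' @return a validated \linkS4class{RoiTimeSeries}
#' @export
readTimeSeries <- function(path, headerPath = .defaultHeaderPath(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (!file.exists(headerPath)) stop("missing header file: ", headerPath)
  hdr <- jsonlite::fromJSON(headerPath)
  need <- c("subject_id", "roi_labels", "sample_rate_hz")
  if (!all(need %in% names(hdr)))
    stop("header must contain: ", paste(need, collapse = ", "))
  labels <- as.character(hdr$roi_labels)
  if (.isFeather(path)) {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop("reading .feather requires the 'arrow' package")
    df <- arrow::read_feather(path)
    if (!identical(colnames(df), labels))
      stop("feather columns do not match header roi_labels")
    mat <- t(as.matrix(df))
  } else {
    mat <- as.matrix(read.delim(path, header = FALSE, sep = "\t",
                                colClasses = "numeric"))
    dimnames(mat) <- NULL
    if (nrow(mat) != length(labels))
      stop("matrix has ", nrow(mat), " rows but header lists ",
           length(labels), " ROI labels")
  }
  if (!all(is.finite(mat))) stop("non-finite values in time-series matrix")
  roiTimeSeries(mat, sampleRateHz = as.numeric(hdr$sample_rate_hz),
                roiLabels = labels, subjectId = as.character(hdr$subject_id))
}

#' Write an ROI time-series matrix
#'
#' Text output uses \code{\%.17g} formatting so that read-back is
#' bit-exact for IEEE doubles; Feather output is lossless by construction.
#'
#' @param ts a \linkS4class{RoiTimeSeries}
#' @inheritParams readTimeSeries
#' @return invisibly, \code{path}
#' @export
writeTimeSeries <- function(ts, path, headerPath = .defaultHeaderPath(path)) {
  stopifnot(is(ts, "RoiTimeSeries"))
  if (.isFeather(path)) {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop("writing .feather requires the 'arrow' package")
    df <- as.data.frame(t(ts@data))
    colnames(df) <- roiLabels(ts)
    arrow::write_feather(df, path)
  } else {
    lines <- apply(ts@data, 1L,
                   function(r) paste(sprintf("%.17g", r), collapse = "\t"))
    writeLines(lines, path)
  }
  jsonlite::write_json(
    list(subject_id = subjectId(ts), roi_labels = roiLabels(ts),
         sample_rate_hz = sampleRate(ts)),
    headerPath, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an atlas/RSN definition from JSON
#'
#' Expects keys \code{roi_labels} (ordered array) and
#' \code{rsn_memberships} (object mapping RSN name to a subset of the
#' labels).  Membership errors are caught by class validation.
#'
#' @param path JSON file
#' @return a validated \linkS4class{AtlasDefinition}
#' @export
readAtlas <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  j <- jsonlite::fromJSON(path)
  if (!all(c("roi_labels", "rsn_memberships") %in% names(j)))
    stop("atlas JSON must contain roi_labels and rsn_memberships")
  atlasDefinition(as.character(j$roi_labels),
                  lapply(j$rsn_memberships, as.character))
}

#' @param atlas an \linkS4class{AtlasDefinition}
#' @rdname readAtlas
#' @export
writeAtlas <- function(atlas, path) {
  stopifnot(is(atlas, "AtlasDefinition"))
  jsonlite::write_json(
    list(roi_labels = atlas@roiLabels,
         rsn_memberships = atlas@rsnMemberships),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' Packaged 78-ROI cortical atlas with RSN assignments
#'
#' The cortical subset of the Automated Anatomical Labeling (AAL) atlas
#' (90 cerebral regions minus the 12 subcortical ones: bilateral
#' hippocampus, amygdala, caudate, putamen, pallidum, thalamus), with
#' literature-based assignments for the default mode network (14 ROIs) and
#' the left and right frontoparietal networks (8 ROIs each).  The RSN
#' memberships are a configurable default, not a canonical fact: replace
#' the JSON to use your own assignments.
#'
#' @return an \linkS4class{AtlasDefinition} with 78 ROI labels
#' @export
defaultAtlas <- function() {
  readAtlas(system.file("extdata", "atlas_aal78_rsn.json",
                        package = "megnet", mustWork = TRUE))
}

#' Read a cognitive raw-score table
#'
#' CSV with columns \code{subject_id}, \code{group} (patient|control),
#' \code{test}, \code{raw_score}.
#'
#' @param path CSV file
#' @return data.frame
#' @export
readCognition <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "test", "raw_score")
  if (!all(need %in% names(d)))
    stop("cognition CSV must have columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(d$group), c("patient", "control"))
  if (length(bad)) stop("unknown group tag(s): ", paste(bad, collapse = ", "))
  d
}

#' Read battery metadata (test, domain, orientation)
#'
#' @param path CSV file with columns \code{test}, \code{domain},
#'   \code{orientation} (\code{higher_better} | \code{lower_better})
#' @return data.frame
#' @export
readBattery <- function(path) {
  .checkBattery(read.csv(path, stringsAsFactors = FALSE))
}

#' Packaged default battery: one synthetic test per domain
#'
#' @return data.frame with one test per cognitive domain, including the
#'   population mean/SD used by the synthetic generator
#' @export
defaultBattery <- function() {
  readBattery(system.file("extdata", "battery_default.csv",
                          package = "megnet", mustWork = TRUE))
}

#' Write result tables and a JSON run manifest
#'
#' One TSV per table plus \code{manifest.json} recording the
#' configuration, seed, package and R versions, and an MD5 checksum per
#' table.  The manifest contains no timestamp, so identical runs produce
#' byte-identical output directories.
#'
#' @param tables named list of data.frames
#' @param dir output directory (created if absent)
#' @param config list (or \linkS4class{CohortConfig}) echoed into the
#'   manifest
#' @param seed integer seed echoed into the manifest
#' @return invisibly, the manifest path
#' @export
writeReport <- function(tables, dir, config = NULL, seed = NULL) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  if (!dir.exists(dir))
    if (!dir.create(dir, recursive = TRUE, showWarnings = FALSE))
      stop("cannot create output directory: ", dir)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    utils::write.table(tables[[nm]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths[nm] <- p
  }
  if (is(config, "CohortConfig")) config <- .configToList(config)
  manifest <- list(
    package = "megnet",
    package_version = as.character(utils::packageVersion("megnet")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    config = config,
    tables = as.list(vapply(paths, function(p) unname(tools::md5sum(p)),
                            character(1))))
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(mp)
}

#' Write a whole cohort as portable artifacts
#'
#' Emits, under \code{dir}: \code{atlas.json}, \code{battery.csv},
#' \code{norms.csv}, \code{cognition.csv}, one time-series TSV + JSON
#' sidecar per subject with MEG data (under \code{timeseries/}), and
#' \code{cohort.json} (config, group tags, RSN name and -- for synthetic
#' cohorts -- the true kappa values).
#'
#' @param cohort a \linkS4class{SyntheticCohort}
#' @param dir output directory
#' @param format \code{"tsv"} (default) or \code{"feather"} for the
#'   time-series matrices
#' @return invisibly, \code{dir}
#' @export
writeCohort <- function(cohort, dir, format = c("tsv", "feather")) {
  format <- match.arg(format)
  stopifnot(is(cohort, "SyntheticCohort"))
  tsDir <- file.path(dir, "timeseries")
  dir.create(tsDir, recursive = TRUE, showWarnings = FALSE)
  writeAtlas(cohort@atlas, file.path(dir, "atlas.json"))
  write.csv(cohort@battery, file.path(dir, "battery.csv"), row.names = FALSE)
  write.csv(cohort@norms, file.path(dir, "norms.csv"), row.names = FALSE)
  write.csv(cohort@cognition, file.path(dir, "cognition.csv"),
            row.names = FALSE)
  for (id in names(cohort@subjects))
    writeTimeSeries(cohort@subjects[[id]],
                    file.path(tsDir, paste0(id, ".", format)))
  jsonlite::write_json(
    list(config = .configToList(cohortConfigOf(cohort)), rsn = cohort@rsn,
         groups = as.list(cohort@groups), kappa = as.list(cohort@kappa),
         format = format),
    file.path(dir, "cohort.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort written by \code{\link{writeCohort}}
#'
#' @param dir directory produced by \code{\link{writeCohort}}
#' @return a \linkS4class{SyntheticCohort}
#' @export
readCohort <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "cohort.json"))
  cf <- meta$config
  config <- cohortConfig(
    nPatients = cf$nPatients, nControls = cf$nControls, nRois = cf$nRois,
    sampleRateHz = cf$sampleRateHz, epochSamples = cf$epochSamples,
    nEpochs = cf$nEpochs,
    band = bandDefinition(cf$band$name, cf$band$loHz, cf$band$hiHz),
    kappaLo = cf$kappaLo, kappaHi = cf$kappaHi,
    backgroundCoupling = cf$backgroundCoupling,
    couplingLagRad = cf$couplingLagRad,
    couplingCognitionEffect = cf$couplingCognitionEffect,
    pliRankFidelity = cf$pliRankFidelity, wmShiftSd = cf$wmShiftSd,
    phaseNoiseSd = cf$phaseNoiseSd, obsNoiseSd = cf$obsNoiseSd,
    burnIn = cf$burnIn, seed = cf$seed)
  atlas <- readAtlas(file.path(dir, "atlas.json"))
  tsDir <- file.path(dir, "timeseries")
  ext <- if (identical(meta$format, "feather")) "\\.feather$" else "\\.tsv$"
  files <- list.files(tsDir, pattern = ext, full.names = TRUE)
  subjects <- stats::setNames(
    lapply(files, readTimeSeries),
    sub("\\.(tsv|feather)$", "", basename(files)))
  groups <- unlist(meta$groups)
  subjects <- subjects[intersect(names(groups), names(subjects))]
  new("SyntheticCohort", config = config, atlas = atlas, rsn = meta$rsn,
      subjects = subjects, groups = groups,
      kappa = unlist(meta$kappa),
      cognition = readCognition(file.path(dir, "cognition.csv")),
      norms = read.csv(file.path(dir, "norms.csv"),
                       stringsAsFactors = FALSE),
      battery = readBattery(file.path(dir, "battery.csv")))
}
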