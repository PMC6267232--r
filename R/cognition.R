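# Cognitive z-scores against matched-control norms, domain composites,
# impairment flagging.

#' The six cognitive domains
#'
#' @return character vector of the six domain names
#' @export
cognitiveDomains <- function() {
  c("executive", "psychomotor_speed", "working_memory",
    "information_processing", "attention", "verbal_memory")
}

#' Impairment threshold (z-score units)
#'
#' A domain is flagged impaired when its z-score is 1.5 SD or more below
#' the matched-control mean, i.e. z <= -1.5 (the boundary value counts as
#' impaired).
#' @export
impairmentThreshold <- -1.5

#' Cognitive z-score against matched-control norms
#'
#' \code{(raw - controlMean) / controlSd}, sign-oriented so that higher
#' always means better: for tests where a higher raw score is worse (e.g.
#' completion times), the z-score is negated.
#'
#' @param raw raw test score(s)
#' @param controlMean,controlSd matched-control reference mean and SD
#'   (SD must be positive)
#' @param orientation \code{"higher_better"} (default) or
#'   \code{"lower_better"}
#' @return z-score(s), higher = better
#' @export
zScore <- function(raw, controlMean, controlSd,
                   orientation = c("higher_better", "lower_better")) {
  orientation <- match.arg(orientation)
  if (!is.finite(controlSd) || controlSd <= 0)
    stop("controlSd must be positive (got ", controlSd, ")")
  z <- (raw - controlMean) / controlSd
  if (orientation == "lower_better") z <- -z
  z
}

#' Domain composites from per-test z-scores
#'
#' Unweighted arithmetic mean of the member tests' z-scores for each
#' domain.
#'
#' @param testZ named numeric vector of per-test z-scores
#' @param mapping named list: domain -> character vector of member tests
#' @return named numeric vector of domain z-scores
#' @export
domainComposite <- function(testZ, mapping) {
  stopifnot(is.numeric(testZ), !is.null(names(testZ)), is.list(mapping))
  missing <- setdiff(unlist(mapping), names(testZ))
  if (length(missing))
    stop("missing test z-score(s) for: ", paste(missing, collapse = ", "))
  vapply(mapping, function(tests) mean(testZ[tests]), numeric(1))
}

# battery data.frame -> domain -> tests mapping
.batteryMapping <- function(battery) {
  split(battery$test, battery$domain)
}

.checkBattery <- function(battery) {
  need <- c("test", "domain", "orientation")
  if (!all(need %in% names(battery)))
    stop("battery must have columns: ", paste(need, collapse = ", "))
  bad <- setdiff(battery$orientation, c("higher_better", "lower_better"))
  if (length(bad))
    stop("unknown orientation value(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(battery$test)) stop("duplicate tests in battery")
  invisible(battery)
}

#' Per-subject cognitive profiles
#'
#' Converts long-format raw scores to per-test z-scores against the
#' matched-control norms (orientation-corrected so higher = better),
#' aggregates them into domain composites, and flags impairment at
#' z <= -1.5.
#'
#' @param cognition data.frame with columns \code{subject_id},
#'   \code{group}, \code{test}, \code{raw_score}
#' @param norms data.frame with columns \code{test}, \code{mean},
#'   \code{sd}: the matched-control reference per test (every test
#'   appearing in \code{cognition} needs a norm with sd > 0)
#' @param battery data.frame with columns \code{test}, \code{domain},
#'   \code{orientation} (defaults to the packaged battery)
#' @return data.frame: subject_id, group, domain, z, impaired
#' @export
cognitiveProfiles <- function(cognition, norms, battery = defaultBattery()) {
  need <- c("subject_id", "group", "test", "raw_score")
  if (!all(need %in% names(cognition)))
    stop("cognition must have columns: ", paste(need, collapse = ", "))
  .checkBattery(battery)
  if (!all(c("test", "mean", "sd") %in% names(norms)))
    stop("norms must have columns: test, mean, sd")
  missingNorm <- setdiff(unique(cognition$test), norms$test)
  if (length(missingNorm))
    stop("no matched-control norm for test(s): ",
         paste(missingNorm, collapse = ", "))
  missingBatt <- setdiff(unique(cognition$test), battery$test)
  if (length(missingBatt))
    stop("test(s) absent from battery: ", paste(missingBatt, collapse = ", "))
  if (any(norms$sd <= 0)) stop("control norm SDs must all be positive")

  normMean <- stats::setNames(norms$mean, norms$test)
  normSd <- stats::setNames(norms$sd, norms$test)
  orient <- stats::setNames(battery$orientation, battery$test)
  mapping <- .batteryMapping(battery)

  out <- do.call(rbind, lapply(split(cognition, cognition$subject_id),
    function(sc) {
      z <- vapply(seq_len(nrow(sc)), function(i) {
        zScore(sc$raw_score[i], normMean[[sc$test[i]]],
               normSd[[sc$test[i]]], orient[[sc$test[i]]])
      }, numeric(1))
      names(z) <- sc$test
      dz <- domainComposite(z, mapping)
      data.frame(subject_id = sc$subject_id[1L], group = sc$group[1L],
                 domain = names(dz), z = unname(dz),
                 impaired = unname(dz) <= impairmentThreshold,
                 stringsAsFactors = FALSE)
    }))
  rownames(out) <- NULL
  out
}
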