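# Synthetic cohort generation: coupled phase oscillators with controllable
# within-RSN coupling and a rank-linked coupling-cognition effect.

#' Construct a cohort configuration
#'
#' Defaults are the emulated study conditions: 20 patients / 20 controls,
#' 78 ROIs, 5 epochs x 4096 samples at 625 Hz, theta-band oscillators, a
#' coupling-cognition Kendall tau of 0.5 and a -0.55 SD working-memory
#' shift in patients.  See \linkS4class{CohortConfig} for slot meanings.
#'
#' @param nPatients,nControls cohort sizes
#' @param nRois number of regions
#' @param sampleRateHz sampling rate in Hz
#' @param epochSamples,nEpochs epoch structure
#' @param band a \linkS4class{BandDefinition}
#' @param kappaLo,kappaHi uniform range of per-subject within-RSN coupling
#' @param backgroundCoupling coupling between all remaining pairs
#' @param couplingLagRad coupling phase lag in (0, pi)
#' @param couplingCognitionEffect target Kendall tau between measured
#'   within-RSN PLI and working-memory z (|effect| < 1)
#' @param pliRankFidelity generator calibration constant: Kendall tau
#'   between the measured within-RSN theta PLI and the true kappa_s under
#'   the default conditions (measured once at large n); the kappa-cognition
#'   link is strengthened to compensate for this attenuation
#' @param wmShiftSd patient working-memory mean shift in control-SD units
#' @param phaseNoiseSd per-step phase noise SD (radians)
#' @param obsNoiseSd additive measurement noise SD
#' @param burnIn discarded transient samples
#' @param seed RNG seed
#' @return a validated \linkS4class{CohortConfig}
#' @export
cohortConfig <- function(nPatients = 20, nControls = 20, nRois = 78,
                         sampleRateHz = 625, epochSamples = 4096,
                         nEpochs = 5, band = defaultBands()$theta,
                         kappaLo = 5e-4, kappaHi = 2.5e-3,
                         backgroundCoupling = 1e-4,
                         couplingLagRad = pi / 4,
                         couplingCognitionEffect = 0.5,
                         pliRankFidelity = 0.63,
                         wmShiftSd = -0.55, phaseNoiseSd = 0.02,
                         obsNoiseSd = 0.2, burnIn = 512, seed = 1) {
  new("CohortConfig", nPatients = as.integer(nPatients),
      nControls = as.integer(nControls), nRois = as.integer(nRois),
      sampleRateHz = as.numeric(sampleRateHz),
      epochSamples = as.integer(epochSamples), nEpochs = as.integer(nEpochs),
      band = band, kappaLo = as.numeric(kappaLo),
      kappaHi = as.numeric(kappaHi),
      backgroundCoupling = as.numeric(backgroundCoupling),
      couplingLagRad = as.numeric(couplingLagRad),
      couplingCognitionEffect = as.numeric(couplingCognitionEffect),
      pliRankFidelity = as.numeric(pliRankFidelity),
      wmShiftSd = as.numeric(wmShiftSd),
      phaseNoiseSd = as.numeric(phaseNoiseSd),
      obsNoiseSd = as.numeric(obsNoiseSd), burnIn = as.integer(burnIn),
      seed = as.integer(seed))
}

.configToList <- function(config) {
  list(nPatients = config@nPatients, nControls = config@nControls,
       nRois = config@nRois, sampleRateHz = config@sampleRateHz,
       epochSamples = config@epochSamples, nEpochs = config@nEpochs,
       band = list(name = config@band@name, loHz = config@band@loHz,
                   hiHz = config@band@hiHz),
       kappaLo = config@kappaLo, kappaHi = config@kappaHi,
       backgroundCoupling = config@backgroundCoupling,
       couplingLagRad = config@couplingLagRad,
       couplingCognitionEffect = config@couplingCognitionEffect,
       pliRankFidelity = config@pliRankFidelity,
       wmShiftSd = config@wmShiftSd, phaseNoiseSd = config@phaseNoiseSd,
       obsNoiseSd = config@obsNoiseSd, burnIn = config@burnIn,
       seed = config@seed)
}

#' Simulate one subject's ROI time series
#'
#' Kuramoto-style phase oscillators with an explicit coupling lag:
#' \deqn{\theta_i(t+1) = \theta_i(t) + 2\pi f_i / f_s +
#'   \sum_j K_{ij} \sin(\theta_j - \theta_i - \delta) + \eta_i(t)}
#' with \eqn{K_{ij} = \kappa} inside the designated RSN and
#' \code{backgroundCoupling} elsewhere; the recorded signal is
#' \eqn{\sin\theta_i} plus white measurement noise.  Oscillator
#' frequencies \eqn{f_i} are drawn uniformly inside the configured band.
#' The nonzero lag \eqn{\delta} makes the interaction detectable by the
#' phase lag index (zero-lag coupling would be invisible by design).
#'
#' Uses the current R RNG state; wrap in \code{set.seed()} for
#' reproducibility (as \code{\link{generateCohort}} does).
#'
#' @param config a \linkS4class{CohortConfig}
#' @param kappa within-RSN coupling for this subject (>= 0)
#' @param rsnIndices integer indices (into 1..nRois) of the
#'   coupling-bearing RSN
#' @param roiLabels optional ROI labels (default \code{ROI001}, ...)
#' @param subjectId subject identifier
#' @return a \linkS4class{RoiTimeSeries} with
#'   \code{nEpochs * epochSamples} samples (concatenated epochs)
#' @export
generateSubject <- function(config, kappa, rsnIndices = integer(0),
                            roiLabels = NULL, subjectId = "S01") {
  stopifnot(is(config, "CohortConfig"))
  validObject(config)
  if (!is.finite(kappa) || kappa < 0) stop("kappa must be >= 0")
  n <- config@nRois
  rsnIndices <- as.integer(rsnIndices)
  if (length(rsnIndices) &&
      (min(rsnIndices) < 1L || max(rsnIndices) > n))
    stop("rsnIndices out of range")
  nR <- length(rsnIndices)
  bg <- config@backgroundCoupling
  # per-step phase increment from coupling must stay below 1 radian for
  # every node, or the Euler update becomes unstable
  maxStep <- max(kappa * max(0L, nR - 1L) + bg * (n - nR),
                 bg * (n - 1L))
  if (maxStep >= 1)
    stop("unstable configuration: total per-step coupling ", round(maxStep, 3),
         " >= 1; reduce kappa or backgroundCoupling")
  fs <- config@sampleRateHz
  nT <- config@nEpochs * config@epochSamples
  freqs <- runif(n, config@band@loHz, config@band@hiHz)
  theta0 <- runif(n, -pi, pi)
  noise <- config@phaseNoiseSd *
    matrix(rnorm(n * (config@burnIn + nT)), n, config@burnIn + nT)
  theta <- simOscillatorPhasesCpp(n, nT, config@burnIn,
                                  2 * pi * freqs / fs, rsnIndices,
                                  kappa, bg, config@couplingLagRad,
                                  noise, theta0)
  signal <- sin(theta)
  if (config@obsNoiseSd > 0)
    signal <- signal + config@obsNoiseSd * matrix(rnorm(n * nT), n, nT)
  if (is.null(roiLabels)) roiLabels <- sprintf("ROI%03d", seq_len(n))
  roiTimeSeries(signal, fs, roiLabels = roiLabels, subjectId = subjectId)
}

# rank-based normal scores
.normalScores <- function(v) qnorm((rank(v) - 0.5) / length(v))

#' Generate a synthetic patient/control cohort
#'
#' Draws a per-subject within-RSN coupling strength
#' \eqn{\kappa_s \sim U[\kappa_{lo}, \kappa_{hi}]}, links the
#' working-memory score to \eqn{\kappa_s} through ranks (the latent
#' working-memory z is \eqn{\rho\, u_s + \sqrt{1-\rho^2}\,\epsilon} with
#' \eqn{u_s} the normal score of the rank of \eqn{\kappa_s}; under the
#' Gaussian copula \eqn{\rho = \sin(\pi\tau/2)} maps correlations to
#' Kendall taus, and \eqn{\rho} is chosen as
#' \eqn{\sin(\pi\,\mathrm{effect}/2)/\sin(\pi\,\mathrm{fidelity}/2)} so
#' that after the attenuation of the PLI readout (quantified by the
#' \code{pliRankFidelity} calibration constant) the population tau
#' between measured within-RSN PLI and working memory lands on the
#' configured effect), adds the
#' configured mean shift to patients' working memory, generates the five
#' remaining domains with zero linkage, converts latent z-scores to raw
#' test scores via the battery's population means/SDs (orientation
#' respected), and simulates MEG time series.  Control norms are the
#' empirical mean/SD of the control group's raw scores.
#'
#' All cognitive quantities are drawn before any time series, so cohorts
#' generated with \code{meg = "none"} share their cognition and
#' \eqn{\kappa_s} exactly with \code{meg = "patients"} runs at the same
#' seed.
#'
#' @param config a \linkS4class{CohortConfig}
#' @param atlas an \linkS4class{AtlasDefinition} with
#'   \code{nRois(atlas) == config@nRois}
#' @param rsn name of the coupling-bearing RSN (default \code{"DMN"})
#' @param battery battery metadata (default packaged); optional columns
#'   \code{pop_mean}, \code{pop_sd} set the raw-score scale
#' @param meg which subjects get simulated time series:
#'   \code{"patients"} (default; the emulated study has no control MEG),
#'   \code{"all"}, or \code{"none"} (cognition-only, for fast statistical
#'   experiments)
#' @return a \linkS4class{SyntheticCohort}
#' @export
generateCohort <- function(config, atlas = defaultAtlas(), rsn = "DMN",
                           battery = defaultBattery(),
                           meg = c("patients", "all", "none")) {
  stopifnot(is(config, "CohortConfig"))
  validObject(config)
  meg <- match.arg(meg)
  .checkBattery(battery)
  if (abs(config@couplingCognitionEffect) >= 1)
    stop("infeasible coupling-cognition effect")
  if (nRois(atlas) != config@nRois)
    stop("atlas has ", nRois(atlas), " ROIs but config expects ",
         config@nRois)
  members <- rsnMembers(atlas, rsn)
  rsnIdx <- match(members, roiLabels(atlas))

  oldSeed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv()))
  set.seed(config@seed)

  nP <- config@nPatients; nC <- config@nControls
  ids <- c(sprintf("P%02d", seq_len(nP)), sprintf("C%02d", seq_len(nC)))
  groups <- stats::setNames(rep(c("patient", "control"), c(nP, nC)), ids)
  kappa <- stats::setNames(runif(nP + nC, config@kappaLo, config@kappaHi),
                           ids)

  # latent domain z-scores; working memory carries the effect.  The
  # target tau is between *measured* PLI and working memory; the link to
  # kappa_s is strengthened (Gaussian-copula chain) to undo the
  # PLI-measurement attenuation quantified by pliRankFidelity.
  domains <- cognitiveDomains()
  rhoTarget <- sin(pi * config@couplingCognitionEffect / 2)
  rhoPli <- sin(pi * config@pliRankFidelity / 2)
  rho <- rhoTarget / rhoPli
  if (abs(rho) > 1) {
    warning("target effect ", config@couplingCognitionEffect,
            " exceeds the PLI rank fidelity ", config@pliRankFidelity,
            "; using the strongest attainable link")
    rho <- sign(rho)
  }
  zlat <- matrix(rnorm((nP + nC) * length(domains)), nP + nC,
                 dimnames = list(ids, domains))
  u <- .normalScores(kappa[seq_len(nP)])
  zlat[seq_len(nP), "working_memory"] <-
    rho * u + sqrt(1 - rho^2) * rnorm(nP) + config@wmShiftSd

  popMean <- if ("pop_mean" %in% names(battery)) {
    stats::setNames(battery$pop_mean, battery$test)
  } else stats::setNames(rep(50, nrow(battery)), battery$test)
  popSd <- if ("pop_sd" %in% names(battery)) {
    stats::setNames(battery$pop_sd, battery$test)
  } else stats::setNames(rep(10, nrow(battery)), battery$test)

  cognition <- do.call(rbind, lapply(seq_len(nrow(battery)), function(b) {
    test <- battery$test[b]
    z <- zlat[, battery$domain[b]]
    raw <- if (battery$orientation[b] == "lower_better") {
      popMean[[test]] - popSd[[test]] * z
    } else popMean[[test]] + popSd[[test]] * z
    data.frame(subject_id = ids, group = unname(groups), test = test,
               raw_score = unname(raw), stringsAsFactors = FALSE)
  }))
  rownames(cognition) <- NULL

  ctrl <- cognition[cognition$group == "control", ]
  norms <- if (nC >= 2) {
    do.call(rbind, lapply(split(ctrl, ctrl$test), function(d) {
      data.frame(test = d$test[1L], mean = mean(d$raw_score),
                 sd = sd(d$raw_score), stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(test = battery$test, mean = unname(popMean[battery$test]),
               sd = unname(popSd[battery$test]), stringsAsFactors = FALSE)
  }
  rownames(norms) <- NULL

  simIds <- switch(meg,
                   patients = ids[groups == "patient"],
                   all = ids,
                   none = character(0))
  subjects <- stats::setNames(lapply(simIds, function(id) {
    generateSubject(config, kappa[[id]], rsnIndices = rsnIdx,
                    roiLabels = roiLabels(atlas), subjectId = id)
  }), simIds)

  new("SyntheticCohort", config = config, atlas = atlas, rsn = rsn,
      subjects = subjects, groups = groups, kappa = kappa,
      cognition = cognition, norms = norms, battery = battery)
}
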