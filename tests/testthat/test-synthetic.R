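# Small configurations used throughout: the study-scale defaults are
# exercised in the acceptance suite; here sizes are kept desk-scale.

smallConfig <- function(...) {
  cohortConfig(nPatients = 3, nControls = 3, nRois = 6,
               epochSamples = 512, nEpochs = 2, burnIn = 128, ...)
}

test_that("identical seed and config give byte-identical cohorts", {
  cfg <- smallConfig(seed = 5)
  c1 <- generateCohort(cfg, atlas = tinyAtlas())
  c2 <- generateCohort(cfg, atlas = tinyAtlas())
  expect_identical(lapply(cohortSubjects(c1), as.matrix),
                   lapply(cohortSubjects(c2), as.matrix))
  expect_identical(cohortCognition(c1), cohortCognition(c2))
  expect_identical(trueKappa(c1), trueKappa(c2))
  c3 <- generateCohort(smallConfig(seed = 6), atlas = tinyAtlas())
  expect_false(identical(as.matrix(cohortSubjects(c1)[[1]]),
                         as.matrix(cohortSubjects(c3)[[1]])))
})

test_that("cohort generation does not disturb the caller's RNG stream", {
  set.seed(77)
  a <- rnorm(2)
  set.seed(77)
  invisible(generateCohort(smallConfig(), atlas = tinyAtlas(),
                           meg = "none"))
  b <- rnorm(2)
  expect_identical(a, b)
})

test_that("cognition is identical whether or not MEG is simulated", {
  cfg <- smallConfig(seed = 9)
  cNone <- generateCohort(cfg, atlas = tinyAtlas(), meg = "none")
  cMeg <- generateCohort(cfg, atlas = tinyAtlas(), meg = "patients")
  expect_identical(cohortCognition(cNone), cohortCognition(cMeg))
  expect_identical(trueKappa(cNone), trueKappa(cMeg))
  expect_length(cohortSubjects(cNone), 0L)
  expect_length(cohortSubjects(cMeg), 3L)
  cAll <- generateCohort(cfg, atlas = tinyAtlas(), meg = "all")
  expect_length(cohortSubjects(cAll), 6L)
})

test_that("default-sized cohorts have the study's shape", {
  coh <- generateCohort(cohortConfig(seed = 2), meg = "none")
  groups <- cohortGroups(coh)
  expect_identical(sum(groups == "patient"), 20L)
  expect_identical(sum(groups == "control"), 20L)
  cog <- cohortCognition(coh)
  expect_identical(nrow(cog), 40L * 6L)            # six tests per subject
  expect_setequal(coh@battery$domain, cognitiveDomains())
  expect_true(all(coh@norms$sd > 0))
  expect_true(all(trueKappa(coh) >= coh@config@kappaLo &
                    trueKappa(coh) <= coh@config@kappaHi))
})

test_that("epoch duration of the default configuration is ~6.55 s", {
  expect_equal(epochDuration(cohortConfig()), 4096 / 625, tolerance = 0)
})

test_that("pure-noise oscillators give near-zero PLI over many epochs", {
  # measured on the raw (unfiltered) instantaneous phases: strong phase
  # noise makes successive samples nearly independent, so the PLI floor
  # scales as 1/sqrt(epoch length); band-pass filtering would impose its
  # own ~1/bandwidth correlation time and lift the floor
  cfg <- cohortConfig(nRois = 5, epochSamples = 4096, nEpochs = 6,
                      kappaLo = 0, kappaHi = 0, backgroundCoupling = 0,
                      phaseNoiseSd = 0.6, burnIn = 128)
  set.seed(41)
  ts <- generateSubject(cfg, kappa = 0, rsnIndices = 1:3)
  offdiag <- unlist(lapply(segmentEpochs(ts, cfg@epochSamples), function(e) {
    v <- as.matrix(pliMatrix(mkPhaseEpoch(instantaneousPhase(e))))
    v[upper.tri(v)]
  }))
  expect_lt(mean(offdiag), 3 / sqrt(4096))
})

test_that("a coupled lagged pair locks with a consistent nonzero lag (PLI ~ 1)", {
  # the locked phase offset is asin(delta_omega / (2 kappa cos(lag))): the
  # coupling must dominate the noise but not crush the offset to zero, and
  # the drawn frequency detuning must be nonzero (seed fixes a
  # representative draw)
  cfg <- cohortConfig(nRois = 2, epochSamples = 2048, nEpochs = 3,
                      kappaLo = 0, kappaHi = 0.4, backgroundCoupling = 0,
                      phaseNoiseSd = 0.003, obsNoiseSd = 0.05, burnIn = 256)
  set.seed(2)
  ts <- generateSubject(cfg, kappa = 0.03, rsnIndices = 1:2)
  avg <- averageEpochs(lapply(phaseEpochs(ts, cfg@band, cfg@epochSamples),
                              pliMatrix))
  expect_gt(as.matrix(avg)[1, 2], 0.95)
})

test_that("unstable couplings and infeasible effects are rejected", {
  cfg <- smallConfig()
  expect_error(generateSubject(cfg, kappa = 0.5, rsnIndices = 1:6),
               "unstable")
  expect_error(cohortConfig(couplingCognitionEffect = 1), "infeasible")
  expect_error(cohortConfig(kappaLo = 0.01, backgroundCoupling = 0.02),
               "backgroundCoupling")
  expect_error(generateSubject(cfg, kappa = -1, rsnIndices = 1:2), "kappa")
})

test_that("null effect leaves kappa and working memory unlinked", {
  coh <- generateCohort(cohortConfig(nPatients = 200, nControls = 20,
                                     couplingCognitionEffect = 0,
                                     wmShiftSd = 0, seed = 11),
                        meg = "none")
  prof <- cognitiveProfiles(cohortCognition(coh), coh@norms, coh@battery)
  wm <- prof$z[prof$domain == "working_memory" & prof$group == "patient"]
  names(wm) <- prof$subject_id[prof$domain == "working_memory" &
                                 prof$group == "patient"]
  kap <- trueKappa(coh)[names(wm)]
  expect_lt(abs(statistic(kendallTauB(kap, wm))), 0.1)
})

test_that("the kappa-cognition link carries the de-attenuated effect", {
  # target tau of 0.5 on the *measured PLI* needs a stronger latent link:
  # tau(kappa, wm) = (2/pi) asin(sin(pi*0.5/2) / sin(pi*fidelity/2))
  cfg <- cohortConfig(nPatients = 200, nControls = 20, seed = 12)
  coh <- generateCohort(cfg, meg = "none")
  prof <- cognitiveProfiles(cohortCognition(coh), coh@norms, coh@battery)
  wm <- prof$z[prof$domain == "working_memory" & prof$group == "patient"]
  names(wm) <- prof$subject_id[prof$domain == "working_memory" &
                                 prof$group == "patient"]
  kap <- trueKappa(coh)[names(wm)]
  expected <- 2 / pi * asin(sin(pi * 0.5 / 2) /
                              sin(pi * cfg@pliRankFidelity / 2))
  expect_lt(abs(statistic(kendallTauB(kap, wm)) - expected), 0.12)
  # non-effect domains stay unlinked
  att <- prof$z[prof$domain == "attention" & prof$group == "patient"]
  expect_lt(abs(statistic(kendallTauB(kap, att))), 0.15)
})

test_that("patients carry the configured working-memory deficit", {
  coh <- generateCohort(cohortConfig(nPatients = 400, nControls = 400,
                                     wmShiftSd = -0.55, seed = 13),
                        meg = "none")
  prof <- cognitiveProfiles(cohortCognition(coh), coh@norms, coh@battery)
  wmP <- mean(prof$z[prof$domain == "working_memory" &
                       prof$group == "patient"])
  attP <- mean(prof$z[prof$domain == "attention" & prof$group == "patient"])
  expect_lt(abs(wmP - (-0.55)), 0.15)
  expect_lt(abs(attP), 0.15)
})
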