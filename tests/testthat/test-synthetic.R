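test_that("generation is bit-deterministic given (spec, seed)", {
  spec <- cohortSpec(nBD = 2, nHC = 2, duration = 12, seed = 31)
  r1 <- generateSubject(spec, "BD", 99)
  r2 <- generateSubject(spec, "BD", 99)
  expect_identical(signalData(r1), signalData(r2))
  r3 <- generateSubject(spec, "BD", 100)
  expect_false(identical(signalData(r1), signalData(r3)))
  expect_error(generateSubject(spec, "XX", 1), "invalid group")
})

test_that("cohort spec validity rejects out-of-range parameters", {
  expect_error(cohortSpec(nBD = 1), "at least 2")
  expect_error(cohortSpec(pacDepth = c(BD = 1.2, HC = 0)), "pacDepth")
  ce <- data.frame(paradigm = "eyes_closed", group = "BD", chA = "O1",
                   chB = "O2", band = "alpha", lag = 1, strength = 1.5)
  expect_error(cohortSpec(couplingEdges = ce), "strength")
  expect_error(cohortSpec(duration = 3), "6-s epoch")
})

test_that("a full-strength noiseless coupled edge is recovered at PLI ~ 1", {
  amps <- c(delta = 0, theta = 0, alpha = 1, beta = 0, gamma = 0)
  ce <- data.frame(paradigm = "eyes_closed", group = c("BD", "HC"),
                   chA = "O1", chB = "O2", band = "alpha", lag = pi / 4,
                   strength = 1)
  spec <- cohortSpec(nBD = 2, nHC = 2, duration = 30,
                     bandAmplitudes = list(BD = amps, HC = amps),
                     couplingEdges = ce, pacDepth = c(BD = 0, HC = 0),
                     oneOverFScale = 0, seed = 32)
  rec <- generateSubject(spec, "BD", 7)
  ct <- connectivityTensor(segmentEpochs(rec), canonicalBands()["alpha"])
  m <- pliBand(ct, "alpha")
  # the estimator itself gives exactly 1 for constant-lag phases (see the
  # PLI fixed-point test); end to end, the per-epoch Hilbert distorts a few
  # samples at each epoch edge, so ~1% of signs may flip
  expect_gte(m["O1", "O2"], 0.98)
  expect_gt(m["O1", "O2"], max(m[upper.tri(m) & m < max(m)]))
})

test_that("with no coupling the realized PLI stays at sampling-noise level", {
  # a 1-4 Hz process over 180 s has ~ bandwidth x duration = 540 independent
  # phase stretches; 3/sqrt(540) ~ 0.13 bounds the null PLI
  amps <- c(delta = 8, theta = 0, alpha = 0, beta = 0, gamma = 0)
  spec <- cohortSpec(nBD = 2, nHC = 2,
                     bandAmplitudes = list(BD = amps, HC = amps),
                     couplingEdges = eegparadigm:::.default_edges()[0, ],
                     pacDepth = c(BD = 0, HC = 0), seed = 33)
  rec <- generateSubject(spec, "HC", 8)
  ct <- connectivityTensor(segmentEpochs(rec), canonicalBands()["delta"])
  m <- pliBand(ct, "delta")
  off <- m[upper.tri(m)]
  expect_lt(max(off), 0.2)
  expect_lt(median(off), 0.06)
})

test_that("realized dPAC increases monotonically in the modulation depth", {
  amps <- c(delta = 8, theta = 0, alpha = 0, beta = 3, gamma = 0)
  kappas <- c(0, 0.3, 0.6, 0.9)
  bands <- canonicalBands()
  ok <- vapply(1:20, function(s) {
    dp <- vapply(kappas, function(k) {
      spec <- cohortSpec(nBD = 2, nHC = 2, duration = 24,
                         bandAmplitudes = list(BD = amps, HC = amps),
                         couplingEdges = eegparadigm:::.default_edges()[0, ],
                         pacDepth = c(BD = k, HC = k), oneOverFScale = 1,
                         subjectSd = 0, seed = 34)
      rec <- generateSubject(spec, "BD", 1000 + s)
      es <- segmentEpochs(rec)
      dl <- analyticSignal(bandFilter(es, bands$delta))
      bt <- analyticSignal(bandFilter(es, bands$beta))
      mean(dpac(dl, bt))
    }, numeric(1))
    cor(rank(kappas), rank(dp)) == 1
  }, logical(1))
  expect_true(all(ok))
})

test_that("cohort metadata has the study shape and scores track their drivers", {
  amps <- c(delta = 2, theta = 1, alpha = 0, beta = 0, gamma = 0)
  cm <- eegparadigm:::.default_cognition()
  cm[, "sd"] <- 0
  cm["TMT_B", ] <- c(38, 6, 0, 0)  # delta-driven, noiseless
  spec <- cohortSpec(nBD = 28, nHC = 42, duration = 6,
                     bandAmplitudes = list(BD = amps, HC = amps),
                     couplingEdges = eegparadigm:::.default_edges()[0, ],
                     pacDepth = c(BD = 0, HC = 0), oneOverFScale = 0,
                     cognitionModel = cm, paradigms = "eyes_closed",
                     seed = 35)
  co <- generateCohort(spec)
  expect_equal(nrow(co$metadata), 70)
  expect_equal(sum(co$metadata$group == "BD"), 28)
  expect_equal(names(co$recordings), "eyes_closed")
  # noiseless monotone map: rank correlation with the latent driver is 1
  sc <- spearmanCorr(co$groundTruth$drivers$log_delta, co$metadata$TMT_B)
  expect_equal(sc$rho, 1)
})

test_that("writeCohort lays down signals, metadata and ground truth", {
  spec <- cohortSpec(nBD = 2, nHC = 2, duration = 6, oneOverFScale = 1,
                     paradigms = "eyes_closed", seed = 36)
  co <- generateCohort(spec)
  dir <- tempfile()
  writeCohort(co, dir)
  expect_true(file.exists(file.path(dir, "metadata.tsv")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  md <- read.delim(file.path(dir, "metadata.tsv"))
  expect_true(all(file.exists(file.path(dir, md$file_eyes_closed))))
  back <- readRecording(file.path(dir, md$file_eyes_closed[1]), "matrix",
                        fs = 250)
  expect_equal(dim(signalData(back)), c(19, 1500))
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_true(all(c("couplingEdges", "pacDepth", "drivers") %in% names(gt)))
})
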