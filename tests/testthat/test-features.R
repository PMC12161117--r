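fs <- 250
bands <- canonicalBands()

test_that("analytic signal of an in-band tone has unit envelope and linear phase", {
  t <- seq(1 / fs, 36, by = 1 / fs)
  rec <- recording(rbind(cos(2 * pi * 10 * t)), fs, "O1")
  asig <- analyticSignal(bandFilter(segmentEpochs(rec, 6), bands$alpha))
  ind <- seq(150, 1350)
  expect_equal(mean(amplitudeArray(asig)[1, 1, ind]), 1, tolerance = 0.02)
  dphi <- diff(phaseArray(asig)[1, 1, ind])
  dphi <- dphi + 2 * pi * (dphi < -pi)
  expect_equal(mean(dphi) * fs, 2 * pi * 10, tolerance = 0.01)
  # amplitude is linear in scaling; negation shifts phase by pi
  es <- bandFilter(segmentEpochs(rec, 6), bands$alpha)
  es3 <- es; es3@epochs <- 3 * es@epochs
  expect_equal(amplitudeArray(analyticSignal(es3)),
               3 * amplitudeArray(asig), tolerance = 1e-12)
  esn <- es; esn@epochs <- -es@epochs
  dphase <- phaseArray(analyticSignal(esn)) - phaseArray(asig)
  expect_equal(abs(eegparadigm:::wrapPhase(dphase)),
               array(pi, dim(dphase)), tolerance = 1e-8)
  expect_error(analyticSignal(segmentEpochs(rec, 6)), "band")
})

test_that("pliMatrix equals the brute-force evaluation on random small instances", {
  set.seed(11)
  for (i in 1:8) {
    nep <- sample(1:2, 1); nch <- sample(2:3, 1); ns <- sample(10:50, 1)
    ph <- array(runif(nep * nch * ns, -pi, pi), c(nep, nch, ns))
    m <- pliMatrix(mkAnalytic(ph))
    expect_equal(m, bruteForcePli(ph), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("PLI identities: zero for identical channels, one for constant lag", {
  set.seed(12)
  base <- matrix(runif(2 * 300, -pi, pi), 2, 300)
  ph <- array(NA_real_, c(2, 2, 300))
  ph[, 1, ] <- base; ph[, 2, ] <- base
  expect_equal(max(pliMatrix(mkAnalytic(ph))), 0)
  ph[, 2, ] <- eegparadigm:::wrapPhase(base + pi / 4)
  m <- pliMatrix(mkAnalytic(ph))
  expect_equal(m[1, 2], 1)
  expect_equal(diag(m), c(0, 0), ignore_attr = TRUE)
})

test_that("PLI matrices are symmetric, zero-diagonal, in [0,1], permutation-equivariant", {
  set.seed(13)
  for (i in 1:5) {
    ph <- array(runif(2 * 5 * 100, -pi, pi), c(2, 5, 100))
    m <- pliMatrix(mkAnalytic(ph))
    expect_equal(m, t(m))
    expect_equal(diag(m), rep(0, 5), ignore_attr = TRUE)
    expect_true(all(m >= 0 & m <= 1))
    perm <- sample(5)
    mp <- pliMatrix(mkAnalytic(ph[, perm, , drop = FALSE]))
    expect_equal(mp, m[perm, perm], ignore_attr = TRUE)
  }
})

test_that("PLI under uniform-random phase differences stays near zero", {
  # oracle: |mean of +-1 signs| over N=9000 samples has sd 1/sqrt(N);
  # the 95th percentile over seeds must stay under 0.04 (~3.8 sd)
  set.seed(14)
  vals <- replicate(100, {
    ph <- array(runif(2 * 9000, -pi, pi), c(1, 2, 9000))
    pliMatrix(mkAnalytic(ph))[1, 2]
  })
  expect_lt(quantile(vals, 0.95), 0.04)
})

test_that("Welch band power recovers tone power and partitions white noise", {
  t <- seq(1 / fs, 60, by = 1 / fs)
  es <- segmentEpochs(recording(rbind(sin(2 * pi * 10 * t)), fs, "O1"), 6)
  p <- vapply(bands, function(b) unname(psdBandPower(es, b)), numeric(1))
  expect_equal(unname(p["alpha"]), 0.5, tolerance = 0.02)
  expect_true(all(p[setdiff(names(p), "alpha")] < 0.01 * p["alpha"]))
  # white noise: band power ~ sigma^2 * bandwidth / nyquist
  set.seed(15)
  sigma <- 2
  esn <- segmentEpochs(recording(rbind(rnorm(length(t), 0, sigma)), fs, "X"), 6)
  pn <- vapply(bands, function(b) unname(psdBandPower(esn, b)), numeric(1))
  bw <- vapply(bands, function(b) b@high - b@low, numeric(1))
  expect_equal(unname(pn), unname(sigma^2 * bw / (fs / 2)), tolerance = 0.1)
  # zero signal has zero power everywhere
  es0 <- segmentEpochs(recording(matrix(0, 1, 6 * fs), fs, "Z"), 6)
  expect_equal(unname(psdBandPower(es0, bands$delta)), 0)
  expect_error(psdBandPower(es0, bandDefinition("hf", 130, 140)), "spectral")
})

test_that("differential entropy matches the Gaussian closed form and scales by log c", {
  set.seed(16)
  rec <- recording(matrix(rnorm(2 * 60 * fs), 2), fs, c("A", "B"))
  es <- bandFilter(segmentEpochs(rec, 6), bands$alpha)
  es@epochs <- es@epochs / sqrt(mean(es@epochs^2))  # unit variance overall
  de <- differentialEntropy(es)
  expect_equal(unname(de[1]), 0.5 * log(2 * pi * exp(1)), tolerance = 0.05)
  es5 <- es; es5@epochs <- 5 * es@epochs
  expect_equal(differentialEntropy(es5) - de, c(A = log(5), B = log(5)),
               tolerance = 1e-10)
  es0 <- es; es0@epochs[] <- 0
  expect_error(differentialEntropy(es0), "zero-variance")
})

test_that("differential entropy and log band power are monotonically related", {
  set.seed(17)
  sig <- exp(runif(12, -1, 2))
  de <- numeric(12); lp <- numeric(12)
  for (s in seq_len(12)) {
    rec <- recording(matrix(rnorm(12 * fs, 0, sig[s]), 1), fs, "A")
    es <- segmentEpochs(rec, 6)
    de[s] <- differentialEntropy(bandFilter(es, bands$alpha))
    lp[s] <- log(psdBandPower(es, bands$alpha))
  }
  expect_gt(cor(rank(de), rank(lp)), 0.95)
})

test_that("dPAC matches the closed form for sinusoidal modulation and nulls out", {
  set.seed(18)
  n <- 9000
  phi <- runif(n, -pi, pi)
  dl <- mkAnalytic(array(phi, c(1, 1, n)), band = bands$delta)
  # uniform phase, constant envelope: dPAC near zero
  bt0 <- mkAnalytic(array(0, c(1, 1, n)), array(2, c(1, 1, n)), bands$beta)
  expect_lt(unname(dpac(dl, bt0)), 3 * 2 / sqrt(n))
  # envelope 1 + 0.9 cos(phi): dPAC -> kappa / 2 = 0.45
  a <- 1 + 0.9 * cos(phi)
  bt <- mkAnalytic(array(0, c(1, 1, n)), array(a, c(1, 1, n)), bands$beta)
  expect_equal(unname(dpac(dl, bt)), 0.45, tolerance = 0.02)
  # invariant under global phase rotation
  dlr <- mkAnalytic(array(eegparadigm:::wrapPhase(phi + 1.1), c(1, 1, n)),
                    band = bands$delta)
  expect_equal(dpac(dlr, bt), dpac(dl, bt), tolerance = 1e-12)
  # normalized variant divides by the mean envelope
  expect_equal(unname(dpac(dl, bt, normalize = TRUE)),
               unname(dpac(dl, bt)) / mean(a), tolerance = 1e-12)
  short <- mkAnalytic(array(0, c(1, 1, 10)), band = bands$beta)
  expect_error(dpac(dl, short), "aligned")
})

test_that("AAC is the envelope correlation with the expected null spread", {
  set.seed(19)
  n <- 9000
  e1 <- abs(rnorm(n)) + 0.1
  dl <- mkAnalytic(array(0, c(1, 1, n)), array(e1, c(1, 1, n)), bands$delta)
  aff <- mkAnalytic(array(0, c(1, 1, n)), array(2 * e1 + 1, c(1, 1, n)),
                    bands$beta)
  expect_equal(unname(aac(dl, aff)), 1)
  neg <- mkAnalytic(array(0, c(1, 1, n)), array(max(e1) + 1 - e1, c(1, 1, n)),
                    bands$beta)
  expect_equal(unname(aac(dl, neg)), -1)
  vals <- replicate(50, {
    a2 <- abs(rnorm(n)) + 0.1
    ind <- mkAnalytic(array(0, c(1, 1, n)), array(a2, c(1, 1, n)), bands$beta)
    abs(unname(aac(dl, ind)))
  })
  expect_lt(quantile(vals, 0.95), 0.04)
  const <- mkAnalytic(array(0, c(1, 1, n)), array(1, c(1, 1, n)), bands$beta)
  expect_error(aac(dl, const), "constant envelope")
})

test_that("the feature matrix has the 12 x 19 layout, is deterministic, excludes short subjects", {
  spec <- cohortSpec(nBD = 2, nHC = 2, duration = 12, oneOverFScale = 2,
                     paradigms = "eyes_closed", seed = 21)
  co <- generateCohort(spec)
  fm <- buildFeatureMatrix(co$recordings$eyes_closed, co$metadata)
  expect_s4_class(fm, "FeatureMatrix")
  expect_equal(dim(fm), c(12 * 19, 4))
  rd <- SummarizedExperiment::rowData(fm)
  expect_equal(unique(rd$family), eegparadigm:::.FEATURE_FAMILIES)
  fm2 <- buildFeatureMatrix(co$recordings$eyes_closed, co$metadata)
  expect_identical(SummarizedExperiment::assay(fm),
                   SummarizedExperiment::assay(fm2))
  # a subject without one complete epoch is excluded with a warning
  recs <- co$recordings$eyes_closed
  recs[[1]]@data <- recs[[1]]@data[, 1:500]
  expect_warning(fm3 <- buildFeatureMatrix(recs, co$metadata), "excluded")
  expect_equal(ncol(fm3), 3)
})

test_that("a group difference in PAC depth shows up in the dPAC features", {
  amps <- c(delta = 8, theta = 0, alpha = 0, beta = 3, gamma = 0)
  spec <- cohortSpec(nBD = 6, nHC = 6, duration = 24,
                     bandAmplitudes = list(BD = amps, HC = amps),
                     couplingEdges = eegparadigm:::.default_edges()[0, ],
                     pacDepth = c(BD = 0.8, HC = 0.0), oneOverFScale = 1,
                     subjectSd = 0.1, paradigms = "eyes_closed", seed = 22)
  co <- generateCohort(spec)
  fm <- buildFeatureMatrix(co$recordings$eyes_closed, co$metadata)
  X <- SummarizedExperiment::assay(fm)
  dp <- colMeans(X[SummarizedExperiment::rowData(fm)$family == "dpac", ])
  g <- groupLabels(fm)
  tt <- t.test(dp[g == "BD"], dp[g == "HC"], alternative = "greater")
  expect_lt(tt$p.value, 0.05)
})
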