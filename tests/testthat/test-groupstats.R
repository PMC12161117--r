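test_that("rank-sum test: exact tail, tie handling, monotone invariance, power", {
  # fully separated samples: exact two-sided tail 2/C(6,3) = 0.1
  expect_equal(ranksumTest(c(1, 2, 3), c(4, 5, 6))$p, 0.1)
  # identical multisets: no separation, p = 1
  expect_equal(ranksumTest(c(1, 2, 3), c(1, 2, 3))$p, 1)
  # invariance under strictly monotone transforms of the pooled data
  set.seed(41)
  x <- rnorm(15); y <- rnorm(18, 0.5)
  expect_equal(ranksumTest(x, y)$p, ranksumTest(exp(x), exp(y))$p)
  expect_error(ranksumTest(1, c(1, 2)), ">= 2")
  # power at d = 2 sigma with the study group sizes
  hits <- vapply(1:500, function(s) {
    set.seed(s)
    ranksumTest(rnorm(28, 2), rnorm(42))$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("BH adjustment matches the step-up construction and is monotone", {
  r <- bhFdr(c(0.01, 0.02, 0.03, 0.8))
  expect_equal(r$adjusted, c(0.04, 0.04, 0.04, 0.8))
  expect_equal(r$mask, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(bhFdr(rep(1, 6))$adjusted, rep(1, 6))
  expect_equal(bhFdr(0.03)$adjusted, 0.03)
  expect_error(bhFdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(42)
  for (i in 1:20) {
    p <- runif(sample(5:50, 1))^sample(1:3, 1)
    r <- bhFdr(p, 0.05)
    expect_false(is.unsorted(r$adjusted[order(p)]))
    expect_true(all(r$adjusted >= p))
    # mask from adjusted p equals the classic step-up rejection set
    expect_equal(r$mask, stepUpReject(p, 0.05))
  }
})

test_that("summary-data t reproduces the printed demographics and raw-data Welch t", {
  set.seed(43)
  x <- rnorm(28, 1, 2); y <- rnorm(42, 0, 1)
  ours <- ttestFromSummary(mean(x), sd(x), 28, mean(y), sd(y), 42)
  ref <- t.test(x, y)
  expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-10)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  pooled <- ttestFromSummary(mean(x), sd(x), 28, mean(y), sd(y), 42,
                             welch = FALSE)
  refp <- t.test(x, y, var.equal = TRUE)
  expect_equal(pooled$t, unname(refp$statistic), tolerance = 1e-10)
  expect_equal(ttestFromSummary(5, 1, 10, 5, 1, 10)$t, 0)
  expect_error(ttestFromSummary(1, 0, 10, 2, 0, 10), "zero variance")
})

test_that("Pearson chi-square on 2x2 tables matches the direct formula", {
  expect_equal(chiSquare2x2(10, 0, 0, 10)$x2, 20)
  expect_equal(chiSquare2x2(10, 20, 5, 10)$x2, 0)  # proportional rows
  ref <- suppressWarnings(chisq.test(matrix(c(7, 3, 12, 9), 2, byrow = TRUE),
                                     correct = FALSE))
  ours <- chiSquare2x2(7, 3, 12, 9)
  expect_equal(ours$x2, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  expect_error(chiSquare2x2(0, 0, 3, 4), "margin")
})

test_that("Spearman correlation: monotone invariance, frozen small case, ties", {
  x <- c(0.3, 1.1, 2.2, 3.5, 4.1)
  expect_equal(spearmanCorr(x, exp(x))$rho, 1)
  expect_equal(spearmanCorr(x, -x)$rho, -1)
  # d^2 = {4,1,1,1,1}: rho = 1 - 6*8/(5*24) = 0.6
  expect_equal(spearmanCorr(1:5, c(3, 1, 2, 5, 4))$rho, 0.6)
  set.seed(44)
  a <- rnorm(30); b <- rnorm(30)
  ref <- cor.test(a, b, method = "spearman")
  ours <- spearmanCorr(a, b)
  expect_equal(ours$rho, unname(ref$estimate), tolerance = 1e-12)
  expect_error(spearmanCorr(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(spearmanCorr(1:2, 2:3), "at least 3")
})

test_that("edgewise comparison flags injected connectivity differences per band", {
  set.seed(45)
  nch <- 6
  labs <- sprintf("CH%02d", 1:nch)
  mkct <- function(bump) {
    m <- matrix(0, nch, nch)
    v <- runif(nch * (nch - 1) / 2, 0.05, 0.2)
    m[upper.tri(m)] <- v
    m <- m + t(m)
    m[1, 2] <- m[2, 1] <- m[1, 2] + bump
    new("ConnectivityTensor", pli = list(delta = m), nEpochs = 30L,
        channelLabels = labs)
  }
  bd <- lapply(1:12, function(i) mkct(0.5))
  hc <- lapply(1:12, function(i) mkct(0))
  res <- edgewiseComparison(bd, hc)
  hit <- res[res$chA == "CH01" & res$chB == "CH02", ]
  expect_true(hit$significant)
  expect_equal(hit$direction, "BD>HC")
  expect_lt(sum(res$significant), 4)  # essentially only the injected edge
  expect_error(edgewiseComparison(bd[1], hc), "at least 2")
  bad <- hc
  bad[[1]]@channelLabels <- rev(labs)
  expect_error(edgewiseComparison(bd, bad), "mismatch")
})

test_that("feature t-tests detect injected shifts, keep a ~5% false-positive rate", {
  rows <- which(paste(rep(eegparadigm:::.FEATURE_FAMILIES, each = 19),
                      rep(montage19(), 12), sep = "_") %in%
                c("de_delta_O1", "de_delta_O2"))
  fm <- mkFeatureMatrix(nBD = 14, nHC = 21, shift = 2, shiftRows = rows,
                        seed = 46)
  tab <- featureTTests(fm)
  expect_equal(nrow(tab), 228)
  expect_true(all(tab$significant[rows]))
  expect_equal(unname(tab$region[tab$channel == "O1"][1]), "O")
  # false-positive rate under the null across seeds
  rate <- mean(vapply(1:30, function(s)
    mean(featureTTests(mkFeatureMatrix(seed = 100 + s))$significant),
    numeric(1)))
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
  # constant feature in both groups: NA p, not significant, warning
  fmc <- mkFeatureMatrix(seed = 47)
  SummarizedExperiment::assay(fmc)[5, ] <- 1
  expect_warning(tabc <- featureTTests(fmc), "constant")
  expect_false(tabc$significant[5])
  expect_true(is.na(tabc$p[5]))
})

test_that("feature-cognition correlations find planted monotone links", {
  fm <- mkFeatureMatrix(nBD = 14, nHC = 21, seed = 48)
  rd <- SummarizedExperiment::rowData(fm)
  planted <- which(rd$family == "psd_delta")
  set.seed(48)
  drv <- rnorm(ncol(fm))
  # every delta-power cell shares the latent driver that also sets TMT-B
  SummarizedExperiment::assay(fm)[planted, ] <-
    rep(drv, each = length(planted)) +
    0.3 * rnorm(length(planted) * ncol(fm))
  SummarizedExperiment::colData(fm)$TMT_B <- 38 + 6 * drv +
    rnorm(ncol(fm), 0, 0.5)
  res <- featureCognitionCorrelation(fm)
  sub <- res[res$score == "TMT_B" & res$family == "psd_delta", ]
  expect_gt(mean(sub$significant & sub$rho > 0), 0.9)
  # a subject missing one score is dropped with a warning
  SummarizedExperiment::colData(fm)$DST[3] <- NA
  expect_warning(featureCognitionCorrelation(fm), "dropped")
  fm2 <- mkFeatureMatrix(nBD = 2, nHC = 2, seed = 49)
  SummarizedExperiment::colData(fm2)$SDMT[1:2] <- NA
  expect_error(suppressWarnings(featureCognitionCorrelation(fm2)),
               "fewer than 3")
})
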