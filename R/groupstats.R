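#' @include AllClasses.R features.R
NULL

#' Two-sample rank-sum (Mann-Whitney) test
#'
#' Two-sided comparison of two independent samples. Small tie-free samples
#' (both n <= 20) use exact enumeration of the rank-sum distribution; larger
#' or tied samples use the normal approximation with mid-ranks and the tie
#' correction. This is the appropriate nonparametric test for two
#' independent groups of unequal size.
#'
#' @param x,y numeric samples (each at least 2 values)
#' @return list with `statistic` (Mann-Whitney U for `x`) and `p`
#' @export
ranksumTest <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("both samples need >= 2 values")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && length(x) <= 20 && length(y) <= 20
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = FALSE))
  list(statistic = unname(wt$statistic), p = wt$p.value)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values `p * n / rank` with cumulative-minimum
#' monotonicity enforcement, and the rejection mask at level `q`.
#'
#' @param pvals vector of raw p-values in [0, 1]
#' @param q FDR level (default 0.05)
#' @return list with `adjusted` and logical `mask` (`adjusted < q`)
#' @export
bhFdr <- function(pvals, q = 0.05) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(pvals, method = "BH")
  list(adjusted = adj, mask = adj < q)
}

#' Edgewise group comparison of PLI connectivity
#'
#' For every band and every unique electrode pair, compares the PLI values
#' of the two groups with the rank-sum test and applies Benjamini-Hochberg
#' FDR correction within each band across the edges (171 for the
#' 19-electrode montage). Direction is the sign of the median difference.
#'
#' @param bd,hc lists of [ConnectivityTensor-class], one per subject
#' @param q FDR level (default 0.05)
#' @return data.frame with columns band, chA, chB, statistic, p, p_fdr,
#'   direction ("BD>HC"/"BD<HC"), significant (p_fdr < q)
#' @export
edgewiseComparison <- function(bd, hc, q = 0.05) {
  if (length(bd) < 2 || length(hc) < 2)
    stop("each group needs at least 2 subjects")
  labs <- channelLabels(bd[[1]])
  for (ct in c(bd, hc))
    if (!identical(channelLabels(ct), labs))
      stop("mismatched montages across connectivity tensors")
  bands <- names(bd[[1]]@pli)
  nch <- length(labs)
  res <- list()
  for (bn in bands) {
    xs <- vapply(bd, function(ct) ct@pli[[bn]], matrix(0, nch, nch))
    ys <- vapply(hc, function(ct) ct@pli[[bn]], matrix(0, nch, nch))
    rows <- list()
    for (a in seq_len(nch - 1L)) {
      for (b in (a + 1L):nch) {
        x <- xs[a, b, ]
        y <- ys[a, b, ]
        rt <- ranksumTest(x, y)
        rows[[length(rows) + 1L]] <- data.frame(
          band = bn, chA = labs[a], chB = labs[b],
          statistic = rt$statistic, p = rt$p,
          direction = if (stats::median(x) >= stats::median(y))
            "BD>HC" else "BD<HC")
      }
    }
    tab <- do.call(rbind, rows)
    fdr <- bhFdr(tab$p, q)
    tab$p_fdr <- fdr$adjusted
    tab$significant <- fdr$mask
    res[[bn]] <- tab
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "q") <- q
  out
}

#' Welch or pooled t statistic from summary data
#'
#' Computes the two-sample t-test from printed group means, SDs and sizes.
#' The Welch form (default) uses per-group variances with the
#' Welch-Satterthwaite degrees of freedom; the pooled form assumes equal
#' variances.
#'
#' @param m1,sd1,n1 mean, SD and size of group 1
#' @param m2,sd2,n2 mean, SD and size of group 2
#' @param welch use the Welch form (default TRUE)
#' @return list with `t`, `df` and two-sided `p`
#' @export
ttestFromSummary <- function(m1, sd1, n1, m2, sd2, n2, welch = TRUE) {
  if (n1 < 2 || n2 < 2) stop("group sizes must be >= 2")
  if (sd1 < 0 || sd2 < 0) stop("SDs must be non-negative")
  if (sd1 == 0 && sd2 == 0) stop("both groups have zero variance")
  if (welch) {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    tt <- (m1 - m2) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    tt <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  list(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df))
}

#' Pearson chi-square test on a 2x2 table
#'
#' Without continuity correction, df = 1. Cell layout:
#' `a, b` (row 1), `c, d` (row 2).
#'
#' @param a,b,c,d non-negative cell counts
#' @return list with `x2` and `p`
#' @export
chiSquare2x2 <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("counts must be non-negative")
  n <- a + b + c + d
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) stop("zero row or column margin")
  x2 <- n * (a * d - b * c)^2 / prod(margins)
  list(x2 = x2, p = stats::pchisq(x2, df = 1, lower.tail = FALSE))
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of mid-ranks (average ranks for ties), with the
#' two-sided p-value from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`.
#'
#' @param x,y numeric vectors, n >= 3, finite
#' @return list with `rho` and `p`
#' @export
spearmanCorr <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite values in input")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: rank correlation undefined")
  rho <- stats::cor(rank(x), rank(y))
  n <- length(x)
  if (abs(rho) >= 1) return(list(rho = rho, p = 0))
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tt), n - 2))
}

#' Per-electrode feature t-tests between groups
#'
#' Two-sided independent-samples t-test for every (feature family,
#' electrode) cell of the feature matrix, flagged at p < 0.05. Following
#' common reporting practice for such per-electrode tables, the flags are
#' uncorrected by default; `correct = "BH"` applies FDR correction across
#' all cells instead. A cell that is constant in both groups gets `p = NA`
#' and is flagged not-significant with a warning.
#'
#' @param fm a [FeatureMatrix-class] with both groups present
#' @param welch Welch t-test instead of pooled variance (default FALSE)
#' @param correct `"none"` (default) or `"BH"`
#' @param alpha significance level (default 0.05)
#' @return data.frame: family, channel, region, t, p, significant
#' @export
featureTTests <- function(fm, welch = FALSE, correct = c("none", "BH"),
                          alpha = 0.05) {
  correct <- match.arg(correct)
  g <- groupLabels(fm)
  if (nlevels(droplevels(g)) < 2) stop("both groups must be present")
  if (min(table(g)) < 2) stop("each group needs at least 2 subjects")
  X <- SummarizedExperiment::assay(fm, "features")
  rd <- SummarizedExperiment::rowData(fm)
  regions <- electrodeRegions()
  tt <- numeric(nrow(X)); pp <- numeric(nrow(X))
  degenerate <- FALSE
  for (i in seq_len(nrow(X))) {
    x <- X[i, g == "BD"]; y <- X[i, g == "HC"]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      tt[i] <- NA_real_; pp[i] <- NA_real_
      degenerate <- TRUE
      next
    }
    ht <- stats::t.test(x, y, var.equal = !welch)
    tt[i] <- unname(ht$statistic); pp[i] <- ht$p.value
  }
  if (degenerate)
    warning("constant feature in both groups: p undefined, flagged not-significant")
  sig <- if (correct == "BH") bhFdr(ifelse(is.na(pp), 1, pp), alpha)$mask
         else !is.na(pp) & pp < alpha
  sig[is.na(pp)] <- FALSE
  data.frame(family = rd$family, channel = rd$channel,
             region = unname(regions[rd$channel]),
             t = tt, p = pp, significant = sig)
}

#' Spearman correlations between features and cognitive scores
#'
#' Correlates every (feature family, electrode) cell with each cognitive
#' score (TMT-A, TMT-B, DST, SDMT) across all subjects of a paradigm,
#' flagging cells at p < 0.05. Subjects missing a score are dropped for
#' that score with a warning. The per-paradigm count of significant cells
#' supports ranking paradigms by cognitive relevance.
#'
#' @param fm a [FeatureMatrix-class] whose colData carries the scores
#' @param scores score columns to use (default the four standard tests)
#' @param alpha significance level (default 0.05)
#' @return data.frame: score, family, channel, rho, p, significant; the
#'   number of significant cells is attached as attribute `n_significant`
#' @export
featureCognitionCorrelation <- function(fm, scores = .SCORES, alpha = 0.05) {
  cd <- SummarizedExperiment::colData(fm)
  missing_sc <- setdiff(scores, colnames(cd))
  if (length(missing_sc))
    stop(sprintf("cognitive score(s) absent from metadata: %s",
                 paste(missing_sc, collapse = ", ")))
  X <- SummarizedExperiment::assay(fm, "features")
  rd <- SummarizedExperiment::rowData(fm)
  res <- list()
  for (sc in scores) {
    y <- cd[[sc]]
    keep <- is.finite(y)
    if (!all(keep))
      warning(sprintf("%d subject(s) missing %s dropped", sum(!keep), sc))
    if (sum(keep) < 3)
      stop(sprintf("fewer than 3 subjects with %s", sc))
    for (i in seq_len(nrow(X))) {
      ct <- spearmanCorr(X[i, keep], y[keep])
      res[[length(res) + 1L]] <- data.frame(
        score = sc, family = rd$family[i], channel = rd$channel[i],
        rho = ct$rho, p = ct$p, significant = ct$p < alpha)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "n_significant") <- sum(out$significant)
  out
}
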