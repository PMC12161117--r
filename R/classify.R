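#' @include AllClasses.R features.R
NULL

# --- AdaBoost.M1 on decision-tree stumps ------------------------------------
# Weighted rpart stumps reweighted multiplicatively; final label is the sign
# of the alpha-weighted vote. Written here because no installed package
# provides AdaBoost on tree base learners.

.adaboost_fit <- function(X, y, n_learners = 100L) {
  yy <- ifelse(y == "BD", 1, -1)
  n <- nrow(X)
  w <- rep(1 / n, n)
  df <- data.frame(.y = factor(yy), X, check.names = FALSE)
  ctrl <- rpart::rpart.control(maxdepth = 1, minsplit = 2, minbucket = 1,
                               cp = -1, xval = 0)
  learners <- list()
  alphas <- numeric(0)
  for (m in seq_len(n_learners)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w * n, method = "class",
                        control = ctrl)
    pred <- as.numeric(as.character(predict(fit, df, type = "class")))
    err <- sum(w[pred != yy])
    if (err <= 0) {
      learners[[length(learners) + 1L]] <- fit
      alphas <- c(alphas, 10)
      break
    }
    if (err >= 0.5) break
    alpha <- 0.5 * log((1 - err) / err)
    learners[[length(learners) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    w <- w * exp(-alpha * yy * pred)
    w <- w / sum(w)
  }
  if (!length(learners)) {
    # degenerate training set: fall back to the majority class
    maj <- names(which.max(table(y)))
    return(structure(list(majority = maj), class = "adaboost_const"))
  }
  structure(list(learners = learners, alphas = alphas),
            class = "adaboost_m1")
}

.adaboost_predict <- function(model, X) {
  if (inherits(model, "adaboost_const"))
    return(factor(rep(model$majority, nrow(X)), levels = c("HC", "BD")))
  df <- data.frame(X, check.names = FALSE)
  score <- rep(0, nrow(X))
  for (m in seq_along(model$learners)) {
    pred <- as.numeric(as.character(
      predict(model$learners[[m]], df, type = "class")))
    score <- score + model$alphas[m] * pred
  }
  factor(ifelse(score >= 0, "BD", "HC"), levels = c("HC", "BD"))
}

# --- per-classifier fit/predict ---------------------------------------------

.fit_and_predict <- function(spec, Xtr, ytr, Xte) {
  lv <- c("HC", "BD")
  switch(spec@name,
    ensemble_adaboost = {
      model <- .adaboost_fit(Xtr, ytr, spec@params$n_learners)
      .adaboost_predict(model, Xte)
    },
    knn = {
      k <- min(spec@params$k, nrow(Xtr))  # tiny training folds
      factor(as.character(class::knn(Xtr, Xte, ytr, k = k)), levels = lv)
    },
    naive_bayes = {
      model <- e1071::naiveBayes(Xtr, ytr)
      factor(as.character(predict(model, Xte)), levels = lv)
    },
    random_forest = {
      model <- randomForest::randomForest(Xtr, ytr,
                                          ntree = spec@params$n_trees)
      factor(as.character(predict(model, Xte)), levels = lv)
    },
    svm_linear = {
      model <- e1071::svm(Xtr, ytr, kernel = "linear",
                          cost = spec@params$cost, scale = FALSE)
      factor(as.character(predict(model, Xte)), levels = lv)
    },
    decision_tree = {
      df <- data.frame(.y = ytr, Xtr, check.names = FALSE)
      ctrl <- rpart::rpart.control(minsplit = 5, minbucket = 2, cp = 0.01,
                                   xval = 0)
      model <- rpart::rpart(.y ~ ., data = df, method = "class",
                            control = ctrl)
      factor(as.character(
        predict(model, data.frame(Xte, check.names = FALSE),
                type = "class")), levels = lv)
    },
    stop(sprintf("unknown classifier '%s'", spec@name)))
}

# Stratified fold assignment at the SUBJECT level: every row of one subject
# lands in the same fold, folds balanced within each group.
.subject_folds <- function(subjects, groups, k) {
  us <- !duplicated(subjects)
  uid <- subjects[us]
  ug <- groups[us]
  fold_of <- stats::setNames(integer(length(uid)), uid)
  for (g in unique(ug)) {
    ids <- uid[ug == g]
    if (length(ids) < k)
      stop(sprintf("group %s has fewer subjects (%d) than folds (%d)",
                   g, length(ids), k))
    ids <- sample(ids)
    fold_of[ids] <- rep(seq_len(k), length.out = length(ids))
  }
  unname(fold_of[subjects])
}

.binary_f1 <- function(truth, pred, positive = "BD") {
  tp <- sum(truth == positive & pred == positive)
  fp <- sum(truth != positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  if (2 * tp + fp + fn == 0) return(NA_real_)
  2 * tp / (2 * tp + fp + fn)
}

#' Cross-validated evaluation of one classifier
#'
#' Repeated stratified k-fold cross-validation with subject-level splits
#' (all rows of one subject are confined to a single fold, so epoch-level
#' feature matrices cannot leak across folds). Features are z-scored with
#' the training-fold means and SDs only; features constant on the training
#' fold are dropped for that fold. Accuracy and binary F1 (BD the positive
#' class) are averaged over folds and repeats.
#'
#' @param fm a [FeatureMatrix-class]
#' @param spec a [ClassifierSpec-class]
#' @param k folds (default 5)
#' @param repeats repetitions with reshuffled folds (default 10)
#' @param seed RNG seed governing fold assignment and stochastic learners
#' @return one-row data.frame: classifier, acc_mean, acc_sd, f1_mean,
#'   f1_sd, majority_rate, n_subjects, scheme; fold-level accuracies and F1
#'   values are attached as attributes `fold_acc`, `fold_f1`
#' @export
crossValidate <- function(fm, spec, k = 5L, repeats = 10L, seed = 1L) {
  stopifnot(is(fm, "FeatureMatrix"), is(spec, "ClassifierSpec"))
  X <- featureDesign(fm)
  y <- groupLabels(fm)
  if (nlevels(droplevels(y)) < 2) stop("both classes must be present")
  subjects <- SummarizedExperiment::colData(fm)$subject_id
  accs <- c(); f1s <- c()
  for (r in seq_len(repeats)) {
    set.seed(.substream_seed(seed, r))
    folds <- .subject_folds(subjects, as.character(y), k)
    for (fold in seq_len(k)) {
      te <- folds == fold
      mu <- colMeans(X[!te, , drop = FALSE])
      sg <- apply(X[!te, , drop = FALSE], 2, stats::sd)
      keep <- sg > 0
      Xtr <- sweep(sweep(X[!te, keep, drop = FALSE], 2, mu[keep]), 2,
                   sg[keep], "/")
      Xte <- sweep(sweep(X[te, keep, drop = FALSE], 2, mu[keep]), 2,
                   sg[keep], "/")
      set.seed(.substream_seed(seed, r * 1000L + fold))
      pred <- .fit_and_predict(spec, Xtr, y[!te], Xte)
      accs <- c(accs, mean(pred == y[te]))
      f1s <- c(f1s, .binary_f1(y[te], pred))
    }
  }
  maj <- max(table(y)) / length(y)
  out <- data.frame(classifier = spec@name,
                    acc_mean = 100 * mean(accs),
                    acc_sd = 100 * stats::sd(accs),
                    f1_mean = 100 * mean(f1s, na.rm = TRUE),
                    f1_sd = 100 * stats::sd(f1s, na.rm = TRUE),
                    majority_rate = 100 * maj,
                    n_subjects = length(unique(subjects)),
                    scheme = sprintf("stratified %d-fold x %d, subject-level",
                                     k, repeats))
  attr(out, "fold_acc") <- accs
  attr(out, "fold_f1") <- f1s
  out
}

#' Benchmark all classifiers across paradigms
#'
#' Runs [crossValidate()] for every (paradigm, classifier) combination and
#' ranks the paradigms by their best-classifier mean accuracy.
#'
#' @param fms named list (paradigm -> [FeatureMatrix-class]); `NULL`
#'   entries are logged and skipped
#' @param specs list of [ClassifierSpec-class] (default all six)
#' @param k,repeats,seed passed to [crossValidate()]
#' @return data.frame of per-(paradigm, classifier) results with the
#'   paradigm ranking attached as attribute `ranking`
#' @export
runBenchmark <- function(fms, specs = allClassifierSpecs(), k = 5L,
                         repeats = 10L, seed = 1L) {
  avail <- !vapply(fms, is.null, logical(1))
  if (any(!avail))
    warning(sprintf("missing paradigm(s): %s",
                    paste(names(fms)[!avail], collapse = ", ")))
  fms <- fms[avail]
  if (!length(fms)) stop("no feature matrices supplied")
  if (length(fms) == 1)
    warning("single paradigm supplied; ranking is degenerate")
  rows <- list()
  for (p in names(fms)) {
    for (spec in specs) {
      row <- crossValidate(fms[[p]], spec, k = k, repeats = repeats,
                           seed = seed)
      row <- cbind(paradigm = p, row)
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  best <- vapply(split(out$acc_mean, out$paradigm), max, numeric(1))
  attr(out, "ranking") <- names(sort(best, decreasing = TRUE))
  out
}
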