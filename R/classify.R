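#' Extract a feature matrix from mask voxels
#'
#' One column per mask voxel in stable linear-index order. Column j's
#' voxel is recoverable through the recorded feature index
#' ([featureVoxelCoords()]). Constant-zero columns are dropped with a
#' warning.
#'
#' @param stack a [GmvStack-class]
#' @param mask logical 3-D array of selected voxels (e.g. the
#'   `significantMask` of [clusterFwe()])
#' @param subjects subject table supplying the two-level group labels;
#'   the second level (e.g. PTSD) is the positive class
#' @param groupCol name of the group column
#' @return a [FeatureMatrix-class]
#' @export
extractFeatures <- function(stack, mask, subjects, groupCol = "group") {
  stopifnot(is(stack, "GmvStack"))
  d <- gridDim(stack)
  stopifnot(identical(dim(mask), as.integer(d)))
  idx <- which(as.logical(mask))
  if (!length(idx)) stop("feature mask is empty")
  n <- nSubjects(stack)
  X <- matrix(stack@data, n, prod(d))[, idx, drop = FALSE]
  zero <- apply(X, 2L, function(c) all(c == 0))
  if (any(zero)) {
    warning(sum(zero), " constant-zero feature columns dropped")
    X <- X[, !zero, drop = FALSE]
    idx <- idx[!zero]
  }
  y <- droplevels(factor(subjects[[groupCol]]))
  if (nlevels(y) != 2L) stop("'", groupCol, "' must have two levels")
  colnames(X) <- sprintf("vox%06d", idx)
  new("FeatureMatrix", X = X, y = y, featureIndex = as.integer(idx),
      dim = as.integer(d), affine = stack@affine,
      subjectIds = subjectIds(stack))
}

#' Voxel coordinates of feature columns
#' @param fm a [FeatureMatrix-class]
#' @param j column index (default all)
#' @return matrix of 1-based voxel coordinates
#' @export
featureVoxelCoords <- function(fm, j = seq_along(fm@featureIndex)) {
  voxelCoords(fm@featureIndex[j], fm@dim)
}

subsetFeatureMatrix <- function(fm, i) {
  new("FeatureMatrix", X = fm@X[i, , drop = FALSE],
      y = factor(fm@y[i], levels = levels(fm@y)),
      featureIndex = fm@featureIndex, dim = fm@dim, affine = fm@affine,
      subjectIds = fm@subjectIds[i])
}

#' Stratified train/test split
#'
#' Splits subjects into a training and a held-out test set preserving
#' class proportions to within one subject, deterministically for a
#' given seed. The default 0.1 test fraction realizes a 9:1 split.
#'
#' @param fm a [FeatureMatrix-class]
#' @param testFraction fraction of subjects held out (default 0.1)
#' @param seed integer seed
#' @return list with `train` and `test` [FeatureMatrix-class] objects
#'   and the held-out row indices `testIdx`
#' @export
splitTrainTest <- function(fm, testFraction = 0.1, seed = 1L) {
  stopifnot(is(fm, "FeatureMatrix"))
  n <- nrow(fm@X)
  set.seed(seed)
  testIdx <- integer(0)
  for (lv in levels(fm@y)) {
    rows <- which(fm@y == lv)
    k <- round(length(rows) * testFraction)
    if (testFraction > 0) k <- max(1L, k)
    if (k >= length(rows))
      stop("test fraction leaves no training subjects in class '", lv,
           "'; use more subjects or a smaller fraction")
    testIdx <- c(testIdx, sort(sample(rows, k)))
  }
  testIdx <- sort(testIdx)
  if (!length(testIdx))
    stop("empty test set; use a positive test fraction")
  if (nlevels(droplevels(fm@y[testIdx])) < 2L ||
      nlevels(droplevels(fm@y[-testIdx])) < 2L)
    stop("a class is absent from one partition; use more subjects")
  list(train = subsetFeatureMatrix(fm, -testIdx),
       test = subsetFeatureMatrix(fm, testIdx),
       testIdx = testIdx)
}

#' Classifier specification
#'
#' The six supported families mirror common MRI case-control
#' benchmarks: linear- and RBF-kernel support vector machines, random
#' forest, (ridge-regularized) logistic regression, a decision tree and
#' gradient-boosted trees. Each family carries a small fixed default
#' hyperparameter grid searched by cross-validation.
#'
#' @param family one of "svm_linear", "svm_rbf", "random_forest",
#'   "logistic", "decision_tree", "xgboost"
#' @param grid data.frame of hyperparameter configurations (one row per
#'   configuration); NULL selects the family default
#' @param seed integer seed used for model fitting and fold assignment
#' @return a list of class `ClassifierSpec`
#' @export
classifierSpec <- function(family = c("svm_linear", "svm_rbf",
                                      "random_forest", "logistic",
                                      "decision_tree", "xgboost"),
                           grid = NULL, seed = 1L) {
  family <- match.arg(family)
  if (is.null(grid)) grid <- defaultGrid(family)
  if (!nrow(grid)) stop("hyperparameter grid must be nonempty")
  structure(list(family = family, grid = grid, seed = as.integer(seed)),
            class = "ClassifierSpec")
}

defaultGrid <- function(family) {
  switch(family,
    svm_linear = expand.grid(cost = c(0.1, 1, 10)),
    svm_rbf = expand.grid(cost = c(0.1, 1, 10),
                          gamma = c(NA, 0.01)),  # NA = 1/d ("scale")
    random_forest = expand.grid(num.trees = c(200L, 500L),
                                max.depth = c(0L, 8L)),
    logistic = expand.grid(lambda = c(0.01, 0.1, 1)),
    decision_tree = expand.grid(cp = c(0.01, 0.001),
                                maxdepth = c(30L, 8L)),
    xgboost = expand.grid(max_depth = c(2L, 3L), eta = c(0.1, 0.3),
                          nrounds = 100L))
}

# Fit one family at one configuration on (X, y). Features are z-scored
# with training statistics only; the scaler travels with the model.
fitClassifier <- function(family, params, X, y, seed = 1L) {
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  Xs <- scale(X, ctr, scl)
  pos <- levels(y)[2L]
  set.seed(seed)
  model <- switch(family,
    svm_linear = e1071::svm(Xs, y, kernel = "linear", cost = params$cost,
                            probability = TRUE, scale = FALSE),
    svm_rbf = {
      g <- params$gamma
      if (is.na(g)) g <- 1 / ncol(Xs)
      e1071::svm(Xs, y, kernel = "radial", cost = params$cost, gamma = g,
                 probability = TRUE, scale = FALSE)
    },
    random_forest = ranger::ranger(
      x = Xs, y = y, num.trees = params$num.trees,
      max.depth = params$max.depth, probability = TRUE,
      num.threads = 1L, seed = seed),
    logistic = glmnet::glmnet(Xs, y, family = "binomial", alpha = 0,
                              lambda = params$lambda, standardize = FALSE),
    decision_tree = {
      df <- data.frame(y = y, Xs)
      rpart::rpart(y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(
                     cp = params$cp, maxdepth = params$maxdepth,
                     xval = 0L))
    },
    xgboost = {
      dtrain <- xgboost::xgb.DMatrix(Xs, label = as.numeric(y == pos))
      xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = params$max_depth, eta = params$eta,
                      nthread = 1L, seed = seed),
        data = dtrain, nrounds = params$nrounds, verbose = 0L)
    },
    stop("unknown family ", family))
  structure(list(family = family, params = params, model = model,
                 center = ctr, scale = scl, levels = levels(y),
                 positive = pos, featureNames = colnames(X)),
            class = "viciClassifier")
}

#' Positive-class probability of a fitted classifier
#'
#' All families expose the same output: the predicted probability of
#' the positive ("patient") class. This is the model output that
#' Shapley attributions decompose.
#'
#' @param object a fitted model from [tuneFit()] or [fitClassifier]
#' @param X feature matrix on the original (unstandardized) scale
#' @return numeric vector of probabilities
#' @export
predictProb <- function(object, X) {
  stopifnot(inherits(object, "viciClassifier"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  colnames(X) <- object$featureNames
  Xs <- scale(X, object$center, object$scale)
  pos <- object$positive
  p <- switch(object$family,
    svm_linear = , svm_rbf = {
      pr <- stats::predict(object$model, Xs, probability = TRUE)
      pm <- attr(pr, "probabilities")
      if (is.null(pm)) {
        dv <- attr(stats::predict(object$model, Xs,
                                  decision.values = TRUE),
                   "decision.values")
        flip <- !startsWith(colnames(dv)[1L], pos)
        stats::plogis(if (flip) -dv[, 1L] else dv[, 1L])
      } else pm[, pos]
    },
    random_forest = stats::predict(object$model, data = Xs,
                                   num.threads = 1L)$predictions[, pos],
    logistic = as.numeric(stats::predict(object$model, Xs,
                                         type = "response")),
    decision_tree = stats::predict(object$model,
                                   data.frame(Xs, check.names = FALSE),
                                   type = "prob")[, pos],
    xgboost = stats::predict(object$model, xgboost::xgb.DMatrix(Xs)))
  as.numeric(p)
}

stratifiedFolds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (lv in levels(y)) {
    rows <- sample(which(y == lv))
    fold[rows] <- rep_len(seq_len(k), length(rows))
  }
  fold
}

#' Hyperparameter tuning by stratified cross-validation
#'
#' Grid search maximizing mean cross-validated ROC-AUC with stratified
#' folds (10 by default; lowered with a warning when a class has fewer
#' subjects than folds), then a refit of the winning configuration on
#' the full training set. Ties go to the earlier grid row.
#'
#' @param spec a [classifierSpec()]
#' @param train training [FeatureMatrix-class] (from [splitTrainTest()])
#' @param folds number of CV folds (default 10)
#' @param cvSingle if FALSE and the grid has a single row, the CV pass
#'   is skipped (the selected model is identical either way); used to
#'   cheapen permutation loops
#' @return list of class `TunedClassifier`: `model`, `best` (winning
#'   configuration), `cvTable` (per-configuration mean and sd of CV
#'   AUC), `folds`, `foldAssign`
#' @export
tuneFit <- function(spec, train, folds = 10L, cvSingle = TRUE) {
  stopifnot(inherits(spec, "ClassifierSpec"), is(train, "FeatureMatrix"))
  y <- train@y
  X <- train@X
  minClass <- min(table(y))
  k <- folds
  if (minClass < k) {
    k <- max(2L, minClass)
    warning("lowering CV folds from ", folds, " to ", k,
            " (smallest class has ", minClass, " subjects)")
  }
  grid <- spec$grid
  cvTable <- cbind(grid, mean_auc = NA_real_, sd_auc = NA_real_)
  runCv <- nrow(grid) > 1L || cvSingle
  foldAssign <- stratifiedFolds(y, k, deriveSeed(spec$seed, 11L))
  if (runCv) {
    for (gi in seq_len(nrow(grid))) {
      aucs <- rep(NA_real_, k)
      for (f in seq_len(k)) {
        tr <- foldAssign != f
        if (nlevels(droplevels(y[tr])) < 2L) next
        fit <- tryCatch(
          fitClassifier(spec$family, grid[gi, , drop = FALSE],
                        X[tr, , drop = FALSE], y[tr],
                        seed = deriveSeed(spec$seed, 100L + f)),
          error = function(e) NULL)
        if (is.null(fit)) next
        sc <- predictProb(fit, X[!tr, , drop = FALSE])
        aucs[f] <- rocAuc(sc, y[!tr] == levels(y)[2L])
      }
      cvTable$mean_auc[gi] <- mean(aucs, na.rm = TRUE)
      cvTable$sd_auc[gi] <- stats::sd(aucs, na.rm = TRUE)
    }
    if (all(!is.finite(cvTable$mean_auc)))
      stop("all hyperparameter configurations failed in cross-validation")
    bestIdx <- which.max(cvTable$mean_auc)
  } else {
    bestIdx <- 1L
  }
  best <- grid[bestIdx, , drop = FALSE]
  model <- fitClassifier(spec$family, best, X, y,
                         seed = deriveSeed(spec$seed, 7L))
  structure(list(model = model, best = best, cvTable = cvTable,
                 folds = k, foldAssign = foldAssign, spec = spec),
            class = "TunedClassifier")
}

#' Held-out evaluation of a tuned classifier
#'
#' Accuracy, sensitivity (patient class positive), specificity and
#' rank-based ROC-AUC with midrank tie handling, computed on a test
#' set untouched during tuning. Class predictions threshold the
#' positive-class probability at 0.5.
#'
#' @param fit a `TunedClassifier` (or `viciClassifier`)
#' @param test test [FeatureMatrix-class]
#' @return data.frame with accuracy, sensitivity, specificity, roc_auc
#' @export
evaluateModel <- function(fit, test) {
  model <- if (inherits(fit, "TunedClassifier")) fit$model else fit
  y <- test@y
  if (!length(y)) stop("empty test set")
  sc <- predictProb(model, test@X)
  metricsFromScores(sc, y == levels(y)[2L])
}

# metric core shared by evaluateModel and tests: positive-class scores
# against a logical positive indicator
metricsFromScores <- function(scores, isPos, threshold = 0.5) {
  pred <- scores > threshold
  tp <- sum(pred & isPos); tn <- sum(!pred & !isPos)
  fp <- sum(pred & !isPos); fn <- sum(!pred & isPos)
  data.frame(
    accuracy = (tp + tn) / length(isPos),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    roc_auc = rocAuc(scores, isPos))
}

#' Label-permutation significance of held-out performance
#'
#' The test statistic is the held-out ROC-AUC of the full
#' split-tune-evaluate procedure. Group labels are permuted before
#' splitting on every iteration, the identical procedure is rerun, and
#' the add-one p-value `(1 + #\{perm AUC >= observed\}) / (nPerm + 1)`
#' is returned.
#'
#' @param spec a [classifierSpec()]
#' @param fm full [FeatureMatrix-class]
#' @param nPerm number of label permutations (default 1000)
#' @param seed integer seed governing splits and permutations
#' @param testFraction held-out fraction (default 0.1)
#' @param folds CV folds inside tuning (default 10)
#' @param cvSingle see [tuneFit()]
#' @return list: `p`, `observedAuc`, `permAuc` (length nPerm)
#' @export
permutationSignificance <- function(spec, fm, nPerm = 1000L, seed = 1L,
                                    testFraction = 0.1, folds = 10L,
                                    cvSingle = FALSE) {
  if (nPerm < 1L) stop("'nPerm' must be at least 1")
  runOnce <- function(fmx, sd) {
    sp <- splitTrainTest(fmx, testFraction, seed = deriveSeed(sd, 1L))
    fit <- suppressWarnings(tuneFit(spec, sp$train, folds = folds,
                                    cvSingle = cvSingle))
    evaluateModel(fit, sp$test)$roc_auc
  }
  obs <- runOnce(fm, seed)
  permAuc <- numeric(nPerm)
  n <- nrow(fm@X)
  for (b in seq_len(nPerm)) {
    set.seed(deriveSeed(seed, 1000L + b))
    fmP <- fm
    fmP@y <- fm@y[sample.int(n)]
    permAuc[b] <- tryCatch(runOnce(fmP, deriveSeed(seed, 2000L + b)),
                           error = function(e) NA_real_)
  }
  ok <- is.finite(permAuc)
  p <- (1 + sum(permAuc[ok] >= obs)) / (sum(ok) + 1)
  list(p = p, observedAuc = obs, permAuc = permAuc)
}

#' Benchmark several classifier families on one split
#'
#' All families are tuned and evaluated on the same stratified split,
#' yielding one metric row per family sorted by accuracy then AUC.
#' With `nPerm > 0` each family additionally receives a
#' label-permutation p-value for its held-out AUC. A family that errors
#' is reported as an NA row without aborting the others.
#'
#' @param fm a [FeatureMatrix-class]
#' @param specs list of [classifierSpec()]; default all six families
#' @param seed master seed: fixes the shared split and fans out to
#'   per-family fitting seeds
#' @param testFraction held-out fraction (default 0.1)
#' @param folds CV folds (default 10)
#' @param nPerm label permutations per family (default 1000; 0 skips)
#' @return list: `table` (one row per family), `fits` (named list of
#'   `TunedClassifier`), `split`
#' @export
benchmarkClassifiers <- function(fm, specs = NULL, seed = 1L,
                                 testFraction = 0.1, folds = 10L,
                                 nPerm = 1000L) {
  if (is.null(specs))
    specs <- lapply(c("svm_linear", "svm_rbf", "random_forest",
                      "logistic", "decision_tree", "xgboost"),
                    classifierSpec, seed = seed)
  if (!length(specs)) stop("need at least one classifier spec")
  sp <- splitTrainTest(fm, testFraction, seed = deriveSeed(seed, 3L))
  rows <- list()
  fits <- list()
  for (s in specs) {
    res <- tryCatch({
      fit <- suppressWarnings(tuneFit(s, sp$train, folds = folds))
      met <- evaluateModel(fit, sp$test)
      pp <- if (nPerm > 0L)
        permutationSignificance(s, fm, nPerm = nPerm,
                                seed = deriveSeed(seed, 5L),
                                testFraction = testFraction,
                                folds = folds)$p
      else NA_real_
      fits[[s$family]] <- fit
      cbind(data.frame(classifier = s$family), met,
            data.frame(permutation_p = pp))
    }, error = function(e)
      data.frame(classifier = s$family, accuracy = NA_real_,
                 sensitivity = NA_real_, specificity = NA_real_,
                 roc_auc = NA_real_, permutation_p = NA_real_))
    rows[[length(rows) + 1L]] <- res
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$accuracy, -tab$roc_auc, na.last = TRUE), ,
             drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab, fits = fits, split = sp)
}
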