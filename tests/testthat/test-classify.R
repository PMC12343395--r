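test_that("feature extraction keeps shape, ordering and back-projection", {
  co <- smallCohort(nA = 4, nB = 4, shape = c(8, 8, 8), seed = 5)
  mask <- array(FALSE, c(8, 8, 8))
  sel <- sort(sample(512, 10))
  mask[sel] <- TRUE
  fm <- extractFeatures(cohortVolumes(co), mask, cohortSubjects(co))
  expect_equal(dim(fm@X), c(8L, 10L))
  expect_identical(fm@featureIndex, as.integer(sel))
  # back-projection: column j's voxel coordinate recovers its index
  cc <- featureVoxelCoords(fm, 3)
  expect_equal((cc[3] - 1) * 64 + (cc[2] - 1) * 8 + cc[1], sel[3])
  expect_error(extractFeatures(cohortVolumes(co),
                               array(FALSE, c(8, 8, 8)),
                               cohortSubjects(co)), "empty")
})

test_that("features inside the planted cluster separate groups in the planted direction", {
  co <- smallCohort(nA = 12, nB = 12, shape = c(12, 12, 12),
                    magnitude = -0.15, radius = 8, seed = 19)
  fm <- extractFeatures(cohortVolumes(co), truthMask(co),
                        cohortSubjects(co))
  g <- cohortSubjects(co)$group
  # direct per-column oracle on the raw stack
  flat <- matrix(gmvData(cohortVolumes(co)), 24, 12^3)
  for (j in seq_len(ncol(fm@X))) {
    expect_identical(fm@X[, j], flat[, fm@featureIndex[j]])
    expect_lt(mean(fm@X[g == "PTSD", j]), mean(fm@X[g == "HC", j]))
  }
})

test_that("stratified split is 9:1, deterministic, and guards degeneracy", {
  fm <- toyFeatureMatrix(n = 100)
  sp <- splitTrainTest(fm, 0.1, seed = 3)
  expect_equal(nrow(sp$train@X), 90L)
  expect_equal(nrow(sp$test@X), 10L)
  expect_equal(as.vector(table(sp$test@y)), c(5L, 5L))
  sp2 <- splitTrainTest(fm, 0.1, seed = 3)
  expect_identical(sp$testIdx, sp2$testIdx)
  sp3 <- splitTrainTest(fm, 0.1, seed = 4)
  expect_false(identical(sp$testIdx, sp3$testIdx))
  expect_error(splitTrainTest(fm, 0), "test")
  expect_error(splitTrainTest(toyFeatureMatrix(n = 4), 0.9), "subjects")
})

test_that("cross-validated tuning selects on AUC with a clean fold partition", {
  fm <- toyFeatureMatrix(n = 60, sep = 3)
  sp <- splitTrainTest(fm, 0.2, seed = 2)
  # one-row grid: CV table has one row, model equals the direct fit
  spec1 <- classifierSpec("svm_linear",
                          grid = data.frame(cost = 1), seed = 5)
  fit1 <- tuneFit(spec1, sp$train, folds = 5)
  expect_equal(nrow(fit1$cvTable), 1L)
  direct <- vicindex:::fitClassifier("svm_linear", data.frame(cost = 1),
                                     sp$train@X, sp$train@y,
                                     seed = deriveSeed(5L, 7L))
  expect_equal(predictProb(fit1$model, sp$test@X),
               predictProb(direct, sp$test@X), tolerance = 1e-10)
  # separable data: CV AUC 1
  expect_equal(fit1$cvTable$mean_auc, 1)
  # fold partition audit: disjoint folds cover the train set once,
  # stratified, reproducible
  f <- fit1$foldAssign
  expect_equal(length(f), 48L)
  expect_true(all(tabulate(f, 5) >= 8))
  for (lv in levels(sp$train@y)) {
    perFold <- table(f[sp$train@y == lv])
    expect_lte(diff(range(perFold)), 1)
  }
  fit1b <- tuneFit(spec1, sp$train, folds = 5)
  expect_identical(fit1$foldAssign, fit1b$foldAssign)
  # folds are lowered with a warning when a class is tiny
  fmTiny <- toyFeatureMatrix(n = 12)
  spT <- splitTrainTest(fmTiny, 0.2, seed = 1)
  expect_warning(tuneFit(spec1, spT$train, folds = 10), "lowering")
})

test_that("held-out metrics match exhaustive pair counting", {
  # Mann-Whitney oracle: count score pairs won by positives
  scores <- c(0.9, 0.8, 0.2, 0.6)
  isPos <- c(TRUE, FALSE, FALSE, TRUE)
  pairs <- expand.grid(p = which(isPos), n = which(!isPos))
  aucOracle <- mean(ifelse(scores[pairs$p] > scores[pairs$n], 1,
                           ifelse(scores[pairs$p] == scores[pairs$n],
                                  0.5, 0)))
  expect_equal(aucOracle, 0.75)
  met <- vicindex:::metricsFromScores(scores, isPos)
  expect_equal(met$roc_auc, aucOracle)
  # thresholded predictions [1,1,0,1]: TP=2 TN=1 FP=1 FN=0
  expect_equal(met$accuracy, 0.75)
  expect_equal(met$sensitivity, 1)
  expect_equal(met$specificity, 0.5)
  # ties get midrank credit
  expect_equal(rocAuc(c(1, 1, 0), c(TRUE, FALSE, FALSE)), 0.75)
  # perfect scores: everything 1
  perfect <- vicindex:::metricsFromScores(c(.9, .8, .1, .2),
                                          c(TRUE, TRUE, FALSE, FALSE))
  expect_true(all(unlist(perfect) == 1))
  # label inversion swaps sensitivity and specificity
  inv <- vicindex:::metricsFromScores(1 - scores, !isPos)
  expect_equal(inv$sensitivity, met$specificity)
  expect_equal(inv$specificity, met$sensitivity)
  expect_equal(inv$roc_auc, met$roc_auc)
})

test_that("every classifier family fits, predicts probabilities and evaluates", {
  fm <- toyFeatureMatrix(n = 50, sep = 2.5, seed = 7)
  sp <- splitTrainTest(fm, 0.2, seed = 9)
  for (fam in c("svm_linear", "svm_rbf", "random_forest", "logistic",
                "decision_tree", "xgboost")) {
    fit <- suppressWarnings(
      tuneFit(classifierSpec(fam, seed = 2), sp$train, folds = 5))
    p <- predictProb(fit$model, sp$test@X)
    expect_true(all(p >= 0 & p <= 1), info = fam)
    ev <- evaluateModel(fit, sp$test)
    expect_gt(ev$roc_auc, 0.7)
  }
})

test_that("label permutation gives the add-one bound on separable data", {
  fm <- toyFeatureMatrix(n = 60, sep = 4, seed = 3)
  spec <- classifierSpec("svm_linear", grid = data.frame(cost = 1),
                         seed = 5)
  ps <- permutationSignificance(spec, fm, nPerm = 19, seed = 7,
                                testFraction = 0.2, folds = 3)
  expect_equal(ps$observedAuc, 1)
  expect_equal(ps$p, 1 / 20)     # no permutation ties the perfect AUC
  expect_equal(length(ps$permAuc), 19L)
  ps2 <- permutationSignificance(spec, fm, nPerm = 19, seed = 7,
                                 testFraction = 0.2, folds = 3)
  expect_identical(ps$permAuc, ps2$permAuc)
})

test_that("benchmark runs all six families on one split, deterministically", {
  fm <- toyFeatureMatrix(n = 60, sep = 2, seed = 11)
  b <- suppressWarnings(
    benchmarkClassifiers(fm, seed = 2, testFraction = 0.2, folds = 3,
                         nPerm = 0))
  expect_equal(nrow(b$table), 6L)
  expect_setequal(b$table$classifier,
                  c("svm_linear", "svm_rbf", "random_forest", "logistic",
                    "decision_tree", "xgboost"))
  expect_named(b$table, c("classifier", "accuracy", "sensitivity",
                          "specificity", "roc_auc", "permutation_p"))
  # sorted by accuracy then AUC
  expect_true(all(diff(b$table$accuracy) <= 0))
  b2 <- suppressWarnings(
    benchmarkClassifiers(fm, seed = 2, testFraction = 0.2, folds = 3,
                         nPerm = 0))
  expect_identical(b$table, b2$table)
  # single spec reduces to tune + evaluate on the same split
  spec <- classifierSpec("logistic", seed = 2)
  b1 <- suppressWarnings(
    benchmarkClassifiers(fm, list(spec), seed = 2, testFraction = 0.2,
                         folds = 3, nPerm = 0))
  sp <- splitTrainTest(fm, 0.2, seed = deriveSeed(2L, 3L))
  fit <- suppressWarnings(tuneFit(spec, sp$train, folds = 3))
  ev <- evaluateModel(fit, sp$test)
  expect_equal(b1$table$roc_auc, ev$roc_auc)
})

test_that("selecting features on all subjects inflates null accuracy (circularity)", {
  # null cohorts: no effect anywhere; pooled selection takes top-|t|
  # voxels using all subjects before splitting, train-only selection
  # uses the training subjects only
  aucPooled <- aucTrainonly <- numeric(8)
  for (s in seq_len(8)) {
    co <- smallCohort(nA = 15, nB = 15, shape = c(10, 10, 10),
                      magnitude = 0, noiseSd = 0.05, smooth = 0,
                      seed = 100 + s)
    st <- cohortVolumes(co); subj <- cohortSubjects(co)
    topMask <- function(idx) {
      m <- fitGlmTmap(st2 <- gmvStack(gmvData(st)[idx, , , , drop = FALSE],
                                      affine = affineMatrix(st),
                                      subjectIds = subjectIds(st)[idx]),
                      subj[idx, , drop = FALSE],
                      covariates = character(0))
      k <- order(-abs(tMap(m)))[1:20]
      msk <- array(FALSE, c(10, 10, 10)); msk[k] <- TRUE
      msk
    }
    all30 <- seq_len(30)
    spec <- classifierSpec("svm_linear", grid = data.frame(cost = 1),
                           seed = s)
    # pooled selection
    fmP <- extractFeatures(st, topMask(all30), subj)
    spP <- splitTrainTest(fmP, 0.2, seed = s)
    aucPooled[s] <- evaluateModel(
      tuneFit(spec, spP$train, folds = 3, cvSingle = FALSE), spP$test)$roc_auc
    # train-only selection: same split, mask from training subjects only
    trIdx <- setdiff(all30, spP$testIdx)
    fmS <- extractFeatures(st, topMask(trIdx), subj)
    spS <- list(train = vicindex:::subsetFeatureMatrix(fmS, trIdx),
                test = vicindex:::subsetFeatureMatrix(fmS, spP$testIdx))
    aucTrainonly[s] <- evaluateModel(
      tuneFit(spec, spS$train, folds = 3, cvSingle = FALSE), spS$test)$roc_auc
  }
  expect_gt(mean(aucPooled), mean(aucTrainonly) + 0.1)
  expect_gt(mean(aucPooled), 0.6)    # optimistic bias on pure noise
})
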