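test_that("covariate-free GLM equals the pooled two-sample t", {
  vals <- matrix(runif(6 * 8, 4, 6), 6, 8)
  vals[, 1] <- c(2, 3, 4, 6, 7, 8)
  st <- toyStack(vals)
  subj <- toySubjects(6, rep(c("HC", "PTSD"), each = 3))
  m <- fitGlmTmap(st, subj, covariates = character(0))
  # oracle: classical pooled t-test, PTSD minus HC
  or <- t.test(c(6, 7, 8), c(2, 3, 4), var.equal = TRUE)
  expect_equal(tMap(m)[1, 1, 1], unname(or$statistic), tolerance = 1e-10)
  expect_equal(dfResidual(m), 4)
  expect_equal(pUncorrected(m)[1, 1, 1], or$p.value, tolerance = 1e-10)
  # every voxel matches the oracle loop
  for (j in 2:8) {
    co <- arrayInd(j, c(2, 2, 2))
    tj <- t.test(vals[4:6, j], vals[1:3, j], var.equal = TRUE)$statistic
    expect_equal(tMap(m)[co], unname(tj), tolerance = 1e-10)
  }
})

test_that("GLM with covariates matches lm() per voxel", {
  set.seed(21)
  vals <- matrix(rnorm(20 * 8, 5), 20, 8)
  st <- toyStack(vals)
  subj <- toySubjects(20, seed = 4)
  m <- fitGlmTmap(st, subj)
  for (j in c(1, 5, 8)) {
    fit <- lm(vals[, j] ~ subj$group + subj$age + subj$tiv)
    tj <- summary(fit)$coefficients["subj$groupPTSD", "t value"]
    expect_equal(tMap(m)[arrayInd(j, c(2, 2, 2))], tj,
                 tolerance = 1e-10)
  }
  expect_equal(dfResidual(m), 16)
})

test_that("degenerate designs error instead of returning zero maps", {
  vals <- matrix(runif(6 * 8, 4, 6), 6, 8)
  st <- toyStack(vals)
  subj <- toySubjects(6)
  subj$group <- factor(rep("PTSD", 6))
  expect_error(fitGlmTmap(st, subj), "two levels")
  subj2 <- toySubjects(6)
  subj2$tiv <- subj2$age * 2          # collinear covariate
  expect_error(fitGlmTmap(st, subj2), "tiv")
})

test_that("the map pipeline is invariant to subject ordering", {
  co <- smallCohort(nA = 8, nB = 8, shape = c(10, 10, 10), seed = 6)
  st <- cohortVolumes(co)
  subj <- cohortSubjects(co)
  m1 <- fitGlmTmap(st, subj)
  perm <- sample(nSubjects(st))
  st2 <- gmvStack(gmvData(st)[perm, , , , drop = FALSE],
                  affine = affineMatrix(st),
                  subjectIds = subjectIds(st)[perm])
  m2 <- fitGlmTmap(st2, subj[perm, , drop = FALSE])
  expect_equal(tMap(m1), tMap(m2), tolerance = 1e-10)
})

test_that("smoothing preserves the image sum and matches dense convolution", {
  # identity at fwhm 0
  st <- toyStack(matrix(runif(2 * 8), 2, 8))
  expect_identical(gmvData(smoothGaussian(st, 0)), gmvData(st))
  expect_error(smoothGaussian(st, -1), "nonnegative")

  # unit impulse on a 9^3 grid, 8 mm fwhm, 2 mm voxels
  a <- array(0, c(1, 9, 9, 9)); a[1, 5, 5, 5] <- 1
  sm <- smoothGaussian(gmvStack(a, voxelSize = 2), 8)
  sigma <- 8 / (2 * sqrt(2 * log(2))) / 2
  expect_equal(sigma, 1.6986436, tolerance = 1e-6)
  # dense convolution oracle: explicit triple loop with the same
  # truncated-normalized kernel and mirror boundary
  r <- ceiling(4 * sigma)
  k <- exp(-(-r:r)^2 / (2 * sigma^2)); k <- k / sum(k)
  reflect <- function(j, n) {
    while (any(j < 1 | j > n)) {
      j <- ifelse(j < 1, 1 - j, j); j <- ifelse(j > n, 2 * n + 1 - j, j)
    }
    j
  }
  # explicit (non-separable) triple-sum convolution at probe voxels
  vol <- a[1, , , ]
  dense <- function(i, j, l) {
    s <- 0
    for (aa in -r:r) for (bb in -r:r) for (cc in -r:r)
      s <- s + k[aa + r + 1] * k[bb + r + 1] * k[cc + r + 1] *
        vol[reflect(i + aa, 9), reflect(j + bb, 9), reflect(l + cc, 9)]
    s
  }
  probes <- rbind(c(5, 5, 5), c(1, 1, 1), c(5, 3, 7), c(9, 5, 2))
  for (q in seq_len(nrow(probes))) {
    pv <- probes[q, ]
    expect_equal(gmvData(sm)[1, pv[1], pv[2], pv[3]],
                 dense(pv[1], pv[2], pv[3]), tolerance = 1e-12)
  }
  expect_equal(gmvData(sm)[1, 5, 5, 5], k[r + 1]^3, tolerance = 1e-12)
  expect_equal(sum(gmvData(sm)), 1, tolerance = 1e-6)

  # sum preservation on arbitrary data
  set.seed(2)
  b <- array(runif(2 * 11^3), c(2, 11, 11, 11))
  smb <- smoothGaussian(gmvStack(b, voxelSize = 2), 8)
  expect_equal(sum(gmvData(smb)[1, , , ]), sum(b[1, , , ]),
               tolerance = 1e-6 * sum(b[1, , , ]))
})

test_that("cluster labeling follows the chosen neighborhood and ordering", {
  tArr <- array(0, c(6, 6, 6))
  m <- toyStatMap(tArr)
  empty <- thresholdClusters(m, 0.001)
  expect_identical(nrow(empty$clusters), 0L)

  # two voxels touching at a corner: one cluster under 26-connectivity,
  # two under 6-connectivity
  tArr[2, 2, 2] <- 8; tArr[3, 3, 3] <- 9
  # a separate face-touching pair
  tArr[5, 5, 5] <- 7; tArr[6, 5, 5] <- 7.5
  m <- toyStatMap(tArr)
  cl26 <- thresholdClusters(m, 0.001, connectivity = 26)
  expect_equal(sort(cl26$clusters$extent), c(2, 2))
  cl6 <- thresholdClusters(m, 0.001, connectivity = 6)
  expect_equal(sort(cl6$clusters$extent), c(1, 1, 2))
  # labels ordered by extent then smallest linear index
  expect_equal(cl26$clusters$label, 1:2)
  expect_true(min(which(cl26$labels == 1)) < min(which(cl26$labels == 2)))
  # signs cluster separately even when adjacent
  tArr2 <- array(0, c(6, 6, 6))
  tArr2[2, 2, 2] <- 8; tArr2[3, 2, 2] <- -8
  cls <- thresholdClusters(toyStatMap(tArr2), 0.001)
  expect_equal(nrow(cls$clusters), 2L)
  expect_setequal(cls$clusters$sign, c("pos", "neg"))
})

test_that("peak world coordinates follow the affine", {
  tArr <- array(0, c(4, 4, 4)); tArr[3, 2, 4] <- 10
  aff <- diag(c(3, 3, 3, 1)); aff[1:3, 4] <- c(-10, -20, -30)
  m <- new("StatMap", t = tArr, df = 10,
           pUnc = array(ifelse(tArr != 0, 1e-6, 1), dim(tArr)),
           mask = array(TRUE, dim(tArr)), affine = aff)
  cl <- thresholdClusters(m, 0.001)
  # 0-based voxel (2,1,3) through the affine
  expect_equal(unlist(cl$clusters[1, c("x", "y", "z")]),
               c(x = 2 * 3 - 10, y = 1 * 3 - 20, z = 3 * 3 - 30))
})

test_that("permutation FWE p-values behave like the add-one estimator", {
  co <- smallCohort(nA = 10, nB = 10, shape = c(14, 14, 14),
                    magnitude = -0.2, noiseSd = 0.02, radius = 8,
                    seed = 9)
  fw <- clusterFwe(cohortVolumes(co), cohortSubjects(co), nPerm = 99,
                   seed = 17)
  cl <- fw$clusters
  expect_true(nrow(cl) >= 1)
  # the planted cluster dwarfs every permutation maximum
  expect_equal(cl$fwe_p[1], 1 / 100)
  expect_true(all(cl$fwe_p >= 1 / 100 & cl$fwe_p <= 1))
  # monotone: larger extent never has larger FWE p
  ord <- order(-cl$extent)
  expect_true(all(diff(cl$fwe_p[ord]) >= 0))
  expect_error(clusterFwe(cohortVolumes(co), cohortSubjects(co),
                          nPerm = 0), "at least 1")
})

test_that("an uncorrelated covariate barely moves the t statistic", {
  set.seed(31)
  n <- 200
  vals <- matrix(rnorm(n * 8, 5), n, 8)
  grp <- rep(c("HC", "PTSD"), each = n / 2)
  vals[grp == "PTSD", ] <- vals[grp == "PTSD", ] + 0.3
  subj <- toySubjects(n, groups = grp, seed = 8)
  subj$junk <- rnorm(n)
  st <- toyStack(vals)
  t0 <- tMap(fitGlmTmap(st, subj, covariates = character(0)))
  t1 <- tMap(fitGlmTmap(st, subj, covariates = "junk"))
  expect_lt(max(abs(t1 - t0)), 0.25)
})

test_that("clinical correlation handles identity, hand oracle and degeneracy", {
  subj <- toySubjects(5)
  subj$caps <- c(10, 20, 30, 40, 50)
  r1 <- clinicalCorrelation(subj$caps, subj, "caps")
  expect_equal(r1$r, 1)
  expect_lt(r1$p, 1e-10)

  # hand-computed Pearson oracle on printed vectors
  v <- c(1, 2, 3, 4, 5); w <- c(2, 1, 4, 3, 6)
  subj$mmse <- w
  rHand <- sum((v - 3) * (w - mean(w))) /
    sqrt(sum((v - 3)^2) * sum((w - mean(w))^2))
  r2 <- clinicalCorrelation(v, subj, "mmse")
  expect_equal(r2$r, rHand, tolerance = 1e-12)

  # pairwise deletion of missing scores
  subj$moca <- c(20, NA, 24, 26, 28)
  r3 <- clinicalCorrelation(v, subj, "moca")
  expect_equal(r3$n, 4L)

  # zero variance flags instead of NaN
  subj$gds <- rep(3, 5)
  r4 <- clinicalCorrelation(v, subj, "gds")
  expect_true(r4$degenerate)
  expect_true(is.na(r4$r))
  expect_error(clinicalCorrelation(v[1:2], subj[1:2, ], "caps"),
               "at least 3")
})
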