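# Shared in-code fixtures; everything is generated, nothing is stored.

# tiny stack with known voxel values: subjects x 2 x 2 x 2
toyStack <- function(values, voxelSize = 2) {
  n <- nrow(values)
  stopifnot(ncol(values) == 8L)
  gmvStack(array(values, c(n, 2, 2, 2)), voxelSize = voxelSize)
}

toySubjects <- function(n, groups = rep(c("HC", "PTSD"), length.out = n),
                        seed = 1) {
  set.seed(seed)
  data.frame(id = sprintf("s%03d", seq_len(n)),
             group = factor(groups, levels = c("HC", "PTSD")),
             age = runif(n, 60, 80), tiv = rnorm(n, 1450, 120),
             caps = runif(n, 0, 100), mmse = round(runif(n, 24, 30)),
             moca = round(runif(n, 22, 30)), gds = round(runif(n, 0, 8)))
}

# separable two-class feature matrix for classifier tests
toyFeatureMatrix <- function(n = 60, d = 8, sep = 1.5, seed = 42) {
  set.seed(seed)
  X <- matrix(rnorm(n * d), n, d)
  y <- factor(rep(c("HC", "PTSD"), length.out = n),
              levels = c("HC", "PTSD"))
  X[y == "PTSD", 1:2] <- X[y == "PTSD", 1:2] + sep
  colnames(X) <- paste0("f", seq_len(d))
  new("FeatureMatrix", X = X, y = y, featureIndex = seq_len(d),
      dim = c(2L, 2L, 2L), affine = diag(4),
      subjectIds = sprintf("s%03d", seq_len(n)))
}

# hand-made StatMap on a small grid
toyStatMap <- function(tArr, df = 10, voxelSize = 2,
                       mask = array(TRUE, dim(tArr))) {
  p <- array(1, dim(tArr))
  p[mask] <- pmax(2 * pt(-abs(tArr[mask]), df), .Machine$double.xmin)
  new("StatMap", t = tArr, df = df, pUnc = p, mask = mask,
      affine = diag(c(rep(voxelSize, 3), 1)))
}

# small planted-effect cohort on a reduced grid (clusters scaled in)
smallCohort <- function(nA = 12, nB = 12, shape = c(16, 16, 16),
                        magnitude = -0.15, noiseSd = 0.02,
                        radius = 10, smooth = 8, seed = 1) {
  simulateCohort(cohortConfig(
    nGroupA = nA, nGroupB = nB, shape = shape,
    effectClusters = if (magnitude == 0) list() else
      list(list(center = round(shape / 2), radiusMm = radius,
                magnitude = magnitude)),
    noiseSd = noiseSd, smoothFwhmMm = smooth, seed = seed))
}
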