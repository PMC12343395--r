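#' Gaussian smoothing of a volume stack
#'
#' Separable Gaussian convolution of every subject volume with
#' `sigma_vox = fwhm / (2 sqrt(2 ln 2)) / voxelSize`. Boundaries use
#' half-sample mirror reflection, under which the total image sum is
#' preserved exactly.
#'
#' @param stack a [GmvStack-class]
#' @param fwhmMm full width at half maximum in mm (default 8); 0 returns
#'   the stack unchanged
#' @return a smoothed [GmvStack-class]
#' @export
smoothGaussian <- function(stack, fwhmMm = 8) {
  stopifnot(is(stack, "GmvStack"))
  if (fwhmMm < 0) stop("'fwhmMm' must be nonnegative")
  if (fwhmMm == 0) return(stack)
  vox <- voxelSize(stack)
  sigma <- fwhmMm / (2 * sqrt(2 * log(2))) / vox
  d <- gridDim(stack)
  Ms <- lapply(1:3, function(k) gaussianSmoothMatrix(d[k], sigma))
  out <- stack@data
  for (i in seq_len(nSubjects(stack))) {
    v <- subjectVolume(stack, i)
    for (k in 1:3) v <- applyAlong(v, Ms[[k]], k)
    out[i, , , ] <- v
  }
  new("GmvStack", data = out, affine = stack@affine,
      subjectIds = stack@subjectIds)
}

# Shared voxelwise OLS core. X: n x k design, Y: n x V response matrix,
# contrast: length-k vector. Returns the contrast t statistic per voxel
# and the residual df. Voxels with (near) zero residual variance get
# t = NA.
glmContrastT <- function(X, Y, contrast) {
  n <- nrow(X)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  XtXinv <- chol2inv(qr.R(qrx))
  beta <- XtXinv %*% crossprod(X, Y)            # k x V
  res <- Y - X %*% beta
  df <- n - ncol(X)
  sigma2 <- colSums(res^2) / df
  cb <- as.vector(crossprod(contrast, beta))
  cvc <- as.numeric(t(contrast) %*% XtXinv %*% contrast)
  se <- sqrt(sigma2 * cvc)
  t <- ifelse(se > sqrt(.Machine$double.eps) * max(1, mean(abs(Y))),
              cb / se, NA_real_)
  list(t = t, df = df, sigma2 = sigma2)
}

buildDesign <- function(subjects, covariates, groupCol = "group") {
  g <- subjects[[groupCol]]
  if (is.null(g)) stop("subject table lacks a '", groupCol, "' column")
  g <- droplevels(factor(g))
  if (nlevels(g) != 2L)
    stop("'", groupCol, "' must have exactly two levels, got ",
         nlevels(g))
  if (any(table(g) < 2L)) stop("each group needs at least 2 subjects")
  X <- cbind(intercept = 1, group = as.numeric(g == levels(g)[2L]))
  for (cv in covariates) {
    if (is.null(subjects[[cv]]))
      stop("subject table lacks covariate '", cv, "'")
    X <- cbind(X, as.numeric(subjects[[cv]]))
    colnames(X)[ncol(X)] <- cv
  }
  list(X = X, groupLevels = levels(g))
}

#' Voxelwise GLM group-contrast t-map
#'
#' Fits, at each voxel inside the analysis mask, an ordinary least
#' squares model of GMV on intercept, group indicator and the named
#' nuisance covariates, and returns the group-contrast t statistic
#' (second group level minus first; with levels HC, PTSD a negative t
#' means lower GMV in patients), residual degrees of freedom
#' `n - rank(X)` and two-sided Student-t p-values. With no covariates
#' this reduces exactly to the pooled-variance two-sample t-test.
#'
#' The analysis mask keeps voxels whose across-subject mean GMV exceeds
#' `maskProportion` times the global mean; voxels with degenerate
#' residual variance are excluded as well.
#'
#' @param stack a [GmvStack-class]
#' @param subjects data.frame aligned to the stack rows, with a
#'   two-level `group` column and the covariate columns
#' @param covariates names of nuisance covariate columns
#'   (default `c("age", "tiv")`)
#' @param maskProportion analysis-mask threshold as a fraction of the
#'   global mean GMV (default 0.1)
#' @param mask optional logical 3-D array overriding the automatic mask
#' @return a [StatMap-class]
#' @export
fitGlmTmap <- function(stack, subjects, covariates = c("age", "tiv"),
                       maskProportion = 0.1, mask = NULL) {
  stopifnot(is(stack, "GmvStack"))
  if (nrow(subjects) != nSubjects(stack))
    stop("subject table rows must match the number of volumes")
  d <- gridDim(stack)
  n <- nSubjects(stack)
  Y <- matrix(stack@data, n, prod(d))
  if (is.null(mask)) {
    mvox <- colMeans(Y)
    mask <- array(mvox > maskProportion * mean(mvox), d)
  } else {
    stopifnot(identical(dim(mask), as.integer(d)))
    mask <- array(as.logical(mask), d)
  }
  des <- buildDesign(subjects, covariates)
  contrast <- c(0, 1, rep(0, length(covariates)))
  idx <- which(mask)
  fit <- glmContrastT(des$X, Y[, idx, drop = FALSE], contrast)
  tArr <- array(0, d)
  pArr <- array(1, d)
  ok <- !is.na(fit$t)
  mask[idx[!ok]] <- FALSE          # degenerate-variance voxels
  tArr[idx[ok]] <- fit$t[ok]
  pArr[idx[ok]] <- 2 * stats::pt(-abs(fit$t[ok]), fit$df)
  pArr[idx[ok]] <- pmax(pArr[idx[ok]], .Machine$double.xmin)
  new("StatMap", t = tArr, df = as.numeric(fit$df), pUnc = pArr,
      mask = mask, affine = stack@affine)
}

#' Suprathreshold clusters of a statistical map
#'
#' Labels connected components (26-neighborhood by default: faces,
#' edges and corners) of voxels with uncorrected p below `voxelP`,
#' clustering negative-t and positive-t voxels separately. Labels are
#' assigned in order of decreasing extent, ties broken by the smallest
#' linear voxel index; an empty result is allowed.
#'
#' @param map a [StatMap-class]
#' @param voxelP uncorrected voxelwise threshold (default 0.001)
#' @param connectivity 6, 18 or 26 (default 26)
#' @return list with `clusters` (data.frame: label, sign, extent,
#'   peak_t, peak voxel and world coordinates) and `labels` (integer
#'   3-D array, 0 outside clusters)
#' @export
thresholdClusters <- function(map, voxelP = 0.001, connectivity = 26L) {
  stopifnot(is(map, "StatMap"))
  if (voxelP <= 0 || voxelP >= 1) stop("'voxelP' must be in (0,1)")
  d <- dim(map@t)
  labels <- array(0L, d)
  rows <- list()
  nextLabel <- 0L
  pieces <- list()
  for (sgn in c(-1, 1)) {
    idx <- which(map@mask & map@pUnc < voxelP & sign(map@t) == sgn)
    if (!length(idx)) next
    comp <- connectedComponents(idx, d, as.integer(connectivity))
    for (l in sort(unique(comp))) {
      vox <- idx[comp == l]
      pk <- vox[which.max(abs(map@t[vox]))]
      pieces[[length(pieces) + 1L]] <-
        list(sign = sgn, vox = vox, extent = length(vox),
             minIdx = min(vox), peak = pk, peakT = map@t[pk])
    }
  }
  if (length(pieces)) {
    ord <- order(-vapply(pieces, `[[`, 0, "extent"),
                 vapply(pieces, `[[`, 0, "minIdx"))
    pieces <- pieces[ord]
    for (k in seq_along(pieces)) {
      p <- pieces[[k]]
      labels[p$vox] <- k
      co <- voxelCoords(p$peak, d)
      wo <- voxelToWorld(co - 1, map@affine)
      rows[[k]] <- data.frame(
        label = k, sign = if (p$sign < 0) "neg" else "pos",
        extent = p$extent, peak_t = p$peakT,
        vx = co[1], vy = co[2], vz = co[3],
        x = wo[1], y = wo[2], z = wo[3])
    }
  }
  clusters <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = integer(0), sign = character(0),
               extent = integer(0), peak_t = numeric(0),
               vx = integer(0), vy = integer(0), vz = integer(0),
               x = numeric(0), y = numeric(0), z = numeric(0))
  list(clusters = clusters, labels = labels)
}

#' Cluster-extent family-wise-error correction by permutation
#'
#' Builds the null distribution of the maximum suprathreshold cluster
#' extent by refitting the voxelwise GLM under random permutations of
#' the group labels (covariates stay attached to their subjects), and
#' assigns each observed cluster the add-one estimate
#' `p_FWE = (1 + #\{perm max extent >= observed extent\}) / (nPerm + 1)`.
#' The returned table is sorted by FWE p, then decreasing extent.
#'
#' @inheritParams fitGlmTmap
#' @inheritParams thresholdClusters
#' @param nPerm number of label permutations (>= 1; default 1000)
#' @param seed integer seed for the permutation stream
#' @param clusterAlpha FWE significance level used for the
#'   `significant` flag column (default 0.05)
#' @return list with `clusters` (data.frame adding `fwe_p` and
#'   `significant`), `labels`, `map` (the observed [StatMap-class]),
#'   `significantMask` (logical array: voxels in FWE-significant
#'   clusters) and `nullMaxExtent` (the permutation distribution)
#' @export
clusterFwe <- function(stack, subjects, covariates = c("age", "tiv"),
                       voxelP = 0.001, connectivity = 26L,
                       nPerm = 1000L, seed = 1L, clusterAlpha = 0.05,
                       maskProportion = 0.1, mask = NULL) {
  if (nPerm < 1L) stop("'nPerm' must be at least 1")
  map <- fitGlmTmap(stack, subjects, covariates,
                    maskProportion = maskProportion, mask = mask)
  obs <- thresholdClusters(map, voxelP, connectivity)

  d <- gridDim(stack)
  n <- nSubjects(stack)
  Y <- matrix(stack@data, n, prod(d))[, which(map@mask), drop = FALSE]
  des <- buildDesign(subjects, covariates)
  contrast <- c(0, 1, rep(0, length(covariates)))
  tcrit <- stats::qt(1 - voxelP / 2, map@df)
  idxMask <- which(map@mask)

  set.seed(seed)
  nullMax <- numeric(nPerm)
  X <- des$X
  for (b in seq_len(nPerm)) {
    Xp <- X
    Xp[, "group"] <- X[sample.int(n), "group"]
    tb <- tryCatch(glmContrastT(Xp, Y, contrast)$t,
                   error = function(e) rep(NA_real_, ncol(Y)))
    mx <- 0L
    for (sgn in c(-1, 1)) {
      supra <- idxMask[!is.na(tb) & sgn * tb > tcrit]
      if (length(supra)) {
        comp <- connectedComponents(supra, d, as.integer(connectivity))
        mx <- max(mx, max(tabulate(comp)))
      }
    }
    nullMax[b] <- mx
  }

  cl <- obs$clusters
  if (nrow(cl)) {
    cl$fwe_p <- vapply(cl$extent,
                       function(e) (1 + sum(nullMax >= e)) / (nPerm + 1),
                       numeric(1))
    cl$significant <- cl$fwe_p < clusterAlpha
    cl <- cl[order(cl$fwe_p, -cl$extent), , drop = FALSE]
    rownames(cl) <- NULL
  } else {
    cl$fwe_p <- numeric(0)
    cl$significant <- logical(0)
  }
  sigMask <- array(FALSE, d)
  if (any(cl$significant))
    sigMask[obs$labels %in% cl$label[cl$significant]] <- TRUE
  list(clusters = cl, labels = obs$labels, map = map,
       significantMask = sigMask, nullMaxExtent = nullMax)
}

#' Pearson correlation of a per-subject measure with a clinical score
#'
#' Missing scores are dropped pairwise and the effective n is reported.
#' If either variable has zero variance the correlation is flagged as
#' undefined rather than propagating NaN.
#'
#' @param values per-subject numeric vector (e.g. mean GMV in a cluster,
#'   or the VICI scalar)
#' @param subjects subject table holding the score column
#' @param scoreName column name, e.g. "caps", "mmse", "moca", "gds"
#' @return data.frame with score, r, p, n, degenerate flag
#' @export
clinicalCorrelation <- function(values, subjects, scoreName) {
  sc <- subjects[[scoreName]]
  if (is.null(sc)) stop("no score column '", scoreName, "'")
  ok <- is.finite(values) & is.finite(sc)
  n <- sum(ok)
  if (n < 3L) stop("need at least 3 paired non-missing observations")
  v <- values[ok]; s <- sc[ok]
  if (stats::sd(v) == 0 || stats::sd(s) == 0)
    return(data.frame(score = scoreName, r = NA_real_, p = NA_real_,
                      n = n, degenerate = TRUE))
  ct <- stats::cor.test(v, s, method = "pearson")
  data.frame(score = scoreName, r = unname(ct$estimate),
             p = ct$p.value, n = n, degenerate = FALSE)
}
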