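#' Configuration for a synthetic case-control GMV cohort
#'
#' Bundles and validates every knob of the cohort generator. The
#' defaults emulate a late-life case-control morphometry study: 40
#' controls versus 62 patients aged 60-80, modulated GMV on an isotropic
#' grid, two planted spherical hypo-volume clusters in the patient
#' group, linear age and head-size (TIV) trends at every voxel,
#' additive Gaussian voxel noise and 8 mm FWHM smoothing.
#'
#' @param nGroupA number of control ("HC") subjects
#' @param nGroupB number of patient ("PTSD") subjects
#' @param shape integer(3) voxel grid
#' @param voxelSize isotropic voxel edge, mm
#' @param effectClusters list of planted effects, each
#'   `list(center = voxel coords (1-based), radiusMm = sphere radius,
#'   magnitude = fractional GMV change in group B, e.g. -0.15)`
#' @param ageRange years, subjects drawn uniformly within
#' @param ageSlope GMV units per year added at every voxel
#' @param tivSlope GMV units per mL of TIV added at every voxel
#' @param tivMean,tivSd TIV distribution, mL
#' @param noiseSd additive voxel noise SD, GMV units
#' @param smoothFwhmMm Gaussian smoothing FWHM, mm (0 disables)
#' @param clinicalCoupling strength (SD units) by which the CAPS score
#'   tracks each subject's GMV deficit inside the planted clusters;
#'   0 (default) leaves clinical scores independent of the voxel data
#' @param seed integer seed; the generator is fully deterministic
#' @return a validated list of class `CohortConfig`
#' @export
cohortConfig <- function(nGroupA = 40L, nGroupB = 62L,
                         shape = c(40L, 48L, 40L), voxelSize = 4,
                         effectClusters = list(
                           list(center = c(14, 30, 16), radiusMm = 14,
                                magnitude = -0.15),
                           list(center = c(27, 18, 22), radiusMm = 11,
                                magnitude = -0.15)),
                         ageRange = c(60, 80), ageSlope = -0.002,
                         tivSlope = 5e-5, tivMean = 1450, tivSd = 120,
                         noiseSd = 0.02, smoothFwhmMm = 8,
                         clinicalCoupling = 0, seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop("'shape' must be three positive integers")
  if (nGroupA < 2L || nGroupB < 2L)
    stop("each group needs at least 2 subjects")
  if (noiseSd < 0) stop("'noiseSd' must be nonnegative")
  if (smoothFwhmMm < 0) stop("'smoothFwhmMm' must be nonnegative")
  for (cl in effectClusters) {
    if (!all(c("center", "radiusMm", "magnitude") %in% names(cl)))
      stop("each effect cluster needs center, radiusMm, magnitude")
    if (cl$radiusMm <= 0) stop("cluster radius must be positive")
  }
  structure(list(nGroupA = as.integer(nGroupA),
                 nGroupB = as.integer(nGroupB),
                 shape = shape, voxelSize = voxelSize,
                 effectClusters = effectClusters,
                 ageRange = ageRange, ageSlope = ageSlope,
                 tivSlope = tivSlope, tivMean = tivMean, tivSd = tivSd,
                 noiseSd = noiseSd, smoothFwhmMm = smoothFwhmMm,
                 clinicalCoupling = clinicalCoupling,
                 seed = as.integer(seed)),
            class = "CohortConfig")
}

# Smooth radial baseline template: bright center, dim periphery, in
# modulated-GMV-like units. Keeps the package free of bundled templates.
baselineTemplate <- function(shape) {
  ctr <- (shape + 1) / 2
  ax <- lapply(1:3, function(k) ((seq_len(shape[k]) - ctr[k]) / (shape[k] / 2))^2)
  r2 <- outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+")
  0.15 + 0.55 * exp(-2 * r2)
}

sphereMask <- function(shape, center, radiusVox) {
  ax <- lapply(1:3, function(k) (seq_len(shape[k]) - center[k])^2)
  r2 <- outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+")
  r2 <= radiusVox^2
}

#' Simulate a synthetic case-control GMV cohort
#'
#' Generates per-subject modulated-GMV volumes with group-B effect
#' clusters planted multiplicatively on a radial baseline template
#' (`baseline * (1 + magnitude)` inside each sphere), linear age and TIV
#' trends at every voxel, i.i.d. Gaussian voxel noise, and optional
#' Gaussian smoothing applied after effect and noise — mirroring
#' pipelines that smooth preprocessed images before statistics. The
#' subject table carries group, age, TIV and four clinical scores; the
#' CAPS-like severity score is elevated in the patient group and, by
#' default, statistically independent of the voxel data.
#'
#' @param config a [cohortConfig()]
#' @return a [SyntheticCohort-class]
#' @examples
#' co <- simulateCohort(cohortConfig(nGroupA = 4, nGroupB = 4,
#'                                   shape = c(10, 10, 10), seed = 2))
#' co
#' @export
simulateCohort <- function(config) {
  stopifnot(inherits(config, "CohortConfig"))
  set.seed(config$seed)
  shape <- config$shape
  nA <- config$nGroupA
  nB <- config$nGroupB
  n <- nA + nB
  group <- factor(rep(c("HC", "PTSD"), c(nA, nB)), levels = c("HC", "PTSD"))

  base <- baselineTemplate(shape)
  truth <- array(FALSE, shape)
  effect <- array(0, shape)
  for (cl in config$effectClusters) {
    if (cl$magnitude == 0) next
    m <- sphereMask(shape, cl$center, cl$radiusMm / config$voxelSize)
    truth <- truth | m
    effect[m] <- effect[m] + cl$magnitude
  }

  age <- stats::runif(n, config$ageRange[1], config$ageRange[2])
  tiv <- stats::rnorm(n, config$tivMean, config$tivSd)
  ageC <- age - mean(config$ageRange)
  tivC <- tiv - config$tivMean

  nvox <- prod(shape)
  dat <- array(0, c(n, shape))
  baseVec <- as.vector(base)
  effVec <- as.vector(effect)
  flat <- matrix(0, n, nvox)
  for (i in seq_len(n)) {
    mu <- baseVec * (1 + if (group[i] == "PTSD") effVec else 0) +
      config$ageSlope * ageC[i] + config$tivSlope * tivC[i]
    flat[i, ] <- mu + if (config$noiseSd > 0)
      stats::rnorm(nvox, 0, config$noiseSd) else 0
  }
  dat <- array(flat, c(n, shape))

  ids <- sprintf("sub-%03d", seq_len(n))
  stack <- gmvStack(dat, affine = diag(c(rep(config$voxelSize, 3), 1)),
                    subjectIds = ids)
  if (config$smoothFwhmMm > 0)
    stack <- smoothGaussian(stack, config$smoothFwhmMm)

  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  caps <- ifelse(group == "PTSD",
                 stats::rnorm(n, 70, 15), stats::rnorm(n, 5, 4))
  caps <- clamp(caps, 0, 136)
  if (config$clinicalCoupling != 0 && any(truth)) {
    deficit <- -rowMeans(matrix(gmvData(stack), n, nvox)[, which(truth),
                                                         drop = FALSE])
    caps <- caps + config$clinicalCoupling * as.numeric(scale(deficit)) * 15
    caps <- clamp(caps, 0, 136)
  }
  subjects <- data.frame(
    id = ids, group = group, age = age, tiv = tiv,
    caps = round(caps, 1),
    mmse = round(clamp(stats::rnorm(n, 28, 1.5), 0, 30), 0),
    moca = round(clamp(stats::rnorm(n, 26, 2), 0, 30), 0),
    gds = round(clamp(stats::rnorm(n, ifelse(group == "PTSD", 4, 2), 2),
                      0, 15), 0),
    stringsAsFactors = FALSE)

  new("SyntheticCohort", volumes = stack, subjects = subjects,
      truthMask = truth, config = unclass(config))
}

#' Configuration for a synthetic multi-donor expression array
#'
#' Desk-scale stand-in for post-mortem multi-donor microarray atlases:
#' a handful of donors, a regional parcellation, and a gene pool in
#' which a chosen subset is spatially coupled to a supplied regional
#' signal.
#'
#' @param nDonors number of donors (>= 2)
#' @param nRegions number of parcellation regions
#' @param nGenes size of the gene pool
#' @param nCoupled number of genes spatially coupled to the regional
#'   signal (first `nCoupled` genes)
#' @param couplingStrength target Spearman correlation between each
#'   coupled gene's regional profile and the signal, in [-1, 1]
#' @param noiseSd SD of donor-level measurement noise for coupled genes
#'   (uncoupled genes get a per-gene inflated noise, emulating the broad
#'   reliability spread of microarray probes)
#' @param seed integer seed
#' @return a validated list of class `ExpressionConfig`
#' @export
expressionConfig <- function(nDonors = 6L, nRegions = 118L,
                             nGenes = 200L, nCoupled = 8L,
                             couplingStrength = 0.8, noiseSd = 0.2,
                             seed = 1L) {
  if (nDonors < 2L) stop("'nDonors' must be at least 2")
  if (nCoupled > nGenes) stop("'nCoupled' cannot exceed 'nGenes'")
  if (abs(couplingStrength) > 1) stop("'couplingStrength' must be in [-1,1]")
  if (noiseSd < 0) stop("'noiseSd' must be nonnegative")
  structure(list(nDonors = as.integer(nDonors),
                 nRegions = as.integer(nRegions),
                 nGenes = as.integer(nGenes),
                 nCoupled = as.integer(nCoupled),
                 couplingStrength = couplingStrength,
                 noiseSd = noiseSd, seed = as.integer(seed)),
            class = "ExpressionConfig")
}

#' Simulate a multi-donor region x gene expression array
#'
#' Each gene has a latent regional profile shared by all donors; each
#' donor observes it with additive noise, so donor profiles are
#' correlated and differential stability is informative. Coupled genes
#' mix the (normal-scores transform of the) regional signal into their
#' latent profile with a Gaussian-copula weight chosen so the
#' gene-signal Spearman correlation targets `couplingStrength`
#' (lambda = 2 sin(pi * rho_S / 6)); uncoupled genes are independent of
#' the signal and carry per-gene inflated donor noise. Values are
#' shifted to a positive log-intensity-like scale.
#'
#' @param config an [expressionConfig()]
#' @param regionalSignal numeric vector, one value per region, that
#'   coupled genes track (e.g. regional mean t values)
#' @return an [ExpressionArray-class]
#' @export
simulateExpression <- function(config, regionalSignal) {
  stopifnot(inherits(config, "ExpressionConfig"))
  if (length(regionalSignal) != config$nRegions)
    stop("'regionalSignal' must have one value per region (",
         config$nRegions, ")")
  set.seed(config$seed)
  nR <- config$nRegions; nG <- config$nGenes; nD <- config$nDonors
  # normal-scores transform keeps the copula Gaussian whatever the
  # marginal of the supplied signal
  s <- stats::qnorm((rank(regionalSignal, ties.method = "average") - 0.5) / nR)
  lambda <- 2 * sin(pi * config$couplingStrength / 6)

  genes <- sprintf("gene%04d", seq_len(nG))
  coupled <- seq_len(config$nCoupled)
  latent <- matrix(stats::rnorm(nR * nG), nR, nG)
  if (length(coupled))
    latent[, coupled] <- lambda * s +
      sqrt(max(0, 1 - lambda^2)) * latent[, coupled, drop = FALSE]

  noise <- rep(config$noiseSd, nG)
  if (nG > config$nCoupled)
    noise[-coupled] <- config$noiseSd *
      stats::runif(nG - config$nCoupled, 1, 3)
  vals <- array(0, c(nD, nR, nG))
  for (d in seq_len(nD))
    vals[d, , ] <- latent +
      matrix(stats::rnorm(nR * nG), nR, nG) * rep(noise, each = nR)
  vals <- vals + 8  # arbitrary positive log2-intensity-like offset

  new("ExpressionArray", values = vals, genes = genes,
      regions = sprintf("region%03d", seq_len(nR)),
      donors = sprintf("donor%d", seq_len(nD)),
      normalized = FALSE)
}
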