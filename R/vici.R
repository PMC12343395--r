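#' Volumetric integrated classification index (VICI)
#'
#' Collapses a subject's Shapley attributions over voxel features into
#' a single index by weighted summation, and back-projects the weighted
#' attributions into volume space as a per-subject VICI map. Two
#' weighting schemes are provided:
#' \describe{
#'   \item{unit}{all weights 1. The scalar is then exactly
#'     `model output - base value`, so the index is an affine transform
#'     of the model output and provably ROC-equivalent to the model.}
#'   \item{importance}{weight_j proportional to the across-subject mean
#'     |phi_j|, normalized to sum 1 — the literal "weighted summation"
#'     reading, emphasizing globally important features.}
#' }
#' If all attributions are zero under the importance scheme the unit
#' scheme is used instead, with a warning.
#'
#' @param attr an [AttributionMatrix-class]
#' @param fm the [FeatureMatrix-class] the attributions were computed
#'   on (supplies feature voxel indices, grid and affine)
#' @param scheme "unit" (default) or "importance"
#' @return a [ViciResult-class]
#' @export
computeVici <- function(attr, fm, scheme = c("unit", "importance")) {
  stopifnot(is(attr, "AttributionMatrix"), is(fm, "FeatureMatrix"))
  scheme <- match.arg(scheme)
  phi <- attr@phi
  if (ncol(phi) != length(fm@featureIndex))
    stop("attribution columns must match the feature index")
  if (scheme == "importance") {
    w <- colMeans(abs(phi))
    if (sum(w) == 0) {
      warning("all attributions are zero; falling back to unit weights")
      scheme <- "unit"
      w <- rep(1, ncol(phi))
    } else {
      w <- w / sum(w)
    }
  } else {
    w <- rep(1, ncol(phi))
  }
  weighted <- sweep(phi, 2L, w, "*")
  scalar <- rowSums(weighted)
  names(scalar) <- attr@subjectIds
  d <- fm@dim
  maps <- array(0, c(nrow(phi), d))
  flat <- matrix(maps, nrow(phi), prod(d))
  flat[, fm@featureIndex] <- weighted
  maps <- array(flat, c(nrow(phi), d))
  new("ViciResult", scalar = scalar, weights = w, maps = maps,
      featureIndex = fm@featureIndex, baseValue = attr@baseValue,
      affine = fm@affine, scheme = scheme)
}

#' VICI group-difference map with cluster-extent FWE
#'
#' Treats the per-subject VICI maps as a volume stack and delegates to
#' the voxelwise GLM ([fitGlmTmap()]) and permutation cluster-extent
#' FWE correction ([clusterFwe()]) with the same covariates, thresholds
#' and conventions as the GMV analysis. VICI maps are zero outside the
#' feature voxels, so the analysis is restricted to feature voxels with
#' non-degenerate variance.
#'
#' @param result a [ViciResult-class]
#' @param subjects subject table aligned to the maps
#' @param covariates nuisance covariates (default `c("age", "tiv")`)
#' @param voxelP voxelwise threshold (default 0.001)
#' @param nPerm label permutations (default 1000)
#' @param seed integer seed
#' @param clusterAlpha cluster-level FWE threshold (default 0.05)
#' @return as [clusterFwe()]
#' @export
viciGroupMap <- function(result, subjects, covariates = c("age", "tiv"),
                         voxelP = 0.001, nPerm = 1000L, seed = 1L,
                         clusterAlpha = 0.05) {
  stopifnot(is(result, "ViciResult"))
  d <- dim(result@maps)[-1L]
  featMask <- array(FALSE, d)
  featMask[result@featureIndex] <- TRUE
  stack <- new("GmvStack", data = result@maps, affine = result@affine,
               subjectIds = names(result@scalar) %||%
                 sprintf("s%03d", seq_len(dim(result@maps)[1L])))
  clusterFwe(stack, subjects, covariates = covariates, voxelP = voxelP,
             nPerm = nPerm, seed = seed, clusterAlpha = clusterAlpha,
             mask = featMask)
}

#' Spatial coupling between VICI and volumetric abnormality
#'
#' Spearman rank correlation between the |t| patterns of the VICI
#' group-difference map and the GMV group-difference map, either
#' voxelwise over the shared analysis mask or at region level (mean |t|
#' per atlas label).
#'
#' @param viciT,gmvT [StatMap-class] objects on the same grid
#' @param level "voxel" (default) or "region"
#' @param atlas integer 3-D labeled volume, required at region level
#' @return list: `rho`, `p`, `n` (units correlated)
#' @export
abnormalityCoupling <- function(viciT, gmvT, level = c("voxel", "region"),
                                atlas = NULL) {
  stopifnot(is(viciT, "StatMap"), is(gmvT, "StatMap"))
  level <- match.arg(level)
  if (!identical(dim(viciT@t), dim(gmvT@t)))
    stop("maps must share a voxel grid")
  if (level == "voxel") {
    m <- viciT@mask & gmvT@mask
    a <- abs(viciT@t[m]); b <- abs(gmvT@t[m])
  } else {
    if (is.null(atlas)) stop("region level requires an atlas volume")
    ra <- regionalAggregate(viciT, atlas, absolute = TRUE)
    rb <- regionalAggregate(gmvT, atlas, absolute = TRUE)
    ok <- !is.na(ra$mean_t) & !is.na(rb$mean_t)
    a <- ra$mean_t[ok]; b <- rb$mean_t[ok]
  }
  if (length(a) < 3L) stop("need at least 3 units to correlate")
  ct <- suppressWarnings(stats::cor.test(a, b, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(a))
}

#' Correlations of the VICI scalar with clinical scores
#'
#' Pearson correlation of the per-subject index against each requested
#' clinical scale, with pairwise deletion of missing scores
#' (see [clinicalCorrelation()]). By default the correlation is
#' computed within the patient group (the second group level):
#' pooling both groups would conflate any group separation of the
#' index with severity scaling inside the clinical population.
#'
#' @param result a [ViciResult-class]
#' @param subjects subject table
#' @param scores score columns (default caps, mmse, moca, gds)
#' @param group restrict to this group level; NULL pools all subjects.
#'   Default the second level of `subjects$group` (patients).
#' @return data.frame, one row per score
#' @export
viciClinical <- function(result, subjects,
                         scores = c("caps", "mmse", "moca", "gds"),
                         group = levels(factor(subjects$group))[2L]) {
  stopifnot(is(result, "ViciResult"))
  keep <- if (is.null(group)) rep(TRUE, nrow(subjects))
          else subjects$group == group
  if (sum(keep) < 3L) stop("fewer than 3 subjects in group '", group, "'")
  do.call(rbind, lapply(scores, function(s)
    clinicalCorrelation(result@scalar[keep],
                        subjects[keep, , drop = FALSE], s)))
}
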