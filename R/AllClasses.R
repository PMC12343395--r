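#' @import methods
NULL

#' GmvStack: a stack of per-subject gray-matter-volume images
#'
#' Container for a 4-D array of subject-wise gray-matter-volume (GMV)
#' values sharing a single voxel grid and voxel-to-world affine. It is
#' the raw material of every voxelwise statistic in the package.
#'
#' @slot data numeric 4-D array, subjects x X x Y x Z. Values are
#'   modulated GMV in arbitrary nonnegative units.
#' @slot affine 4x4 voxel-to-world matrix (0-based voxel indices map to
#'   world mm).
#' @slot subjectIds character vector aligned to the first array dimension.
#'
#' @seealso [gmvStack()] for the user-facing constructor,
#'   [smoothGaussian()], [fitGlmTmap()]
#' @export
setClass("GmvStack",
  representation(
    data = "array",
    affine = "matrix",
    subjectIds = "character"
  )
)

setValidity("GmvStack", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 4L)
    msg <- c(msg, "'data' must be a 4-D array (subjects x X x Y x Z)")
  if (!identical(dim(object@affine), c(4L, 4L)))
    msg <- c(msg, "'affine' must be a 4x4 matrix")
  if (length(dim(object@data)) == 4L &&
      length(object@subjectIds) != dim(object@data)[1L])
    msg <- c(msg, "length of 'subjectIds' must equal the number of volumes")
  if (anyDuplicated(object@subjectIds))
    msg <- c(msg, "'subjectIds' must be unique")
  if (anyNA(object@data))
    msg <- c(msg, "'data' must not contain NA")
  if (length(msg)) msg else TRUE
})

#' StatMap: a voxelwise statistical map
#'
#' Voxelwise t statistics with residual degrees of freedom, two-sided
#' uncorrected p-values and the analysis mask, as produced by
#' [fitGlmTmap()] and consumed by [thresholdClusters()] and
#' [clusterFwe()].
#'
#' @slot t numeric 3-D array of t statistics (0 outside the mask).
#' @slot df residual degrees of freedom of the voxelwise model.
#' @slot pUnc numeric 3-D array of two-sided uncorrected p-values
#'   (1 outside the mask).
#' @slot mask logical 3-D array: voxels entering the analysis.
#' @slot affine 4x4 voxel-to-world matrix inherited from the input stack.
#' @export
setClass("StatMap",
  representation(
    t = "array",
    df = "numeric",
    pUnc = "array",
    mask = "array",
    affine = "matrix"
  )
)

setValidity("StatMap", function(object) {
  msg <- character()
  d <- dim(object@t)
  if (length(d) != 3L)
    msg <- c(msg, "'t' must be a 3-D array")
  if (!identical(dim(object@pUnc), d) || !identical(dim(object@mask), d))
    msg <- c(msg, "'t', 'pUnc' and 'mask' must share dimensions")
  inmask <- object@mask
  if (any(inmask) && (any(!is.finite(object@t[inmask])) ||
                      any(object@pUnc[inmask] <= 0 | object@pUnc[inmask] > 1)))
    msg <- c(msg, "inside the mask, t must be finite and pUnc in (0, 1]")
  if (length(object@df) != 1L || object@df <= 0)
    msg <- c(msg, "'df' must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' FeatureMatrix: subjects x voxel-features with labels
#'
#' GMV values extracted at a fixed set of mask voxels, one column per
#' voxel in stable linear-index order, together with the binary group
#' label. The recorded voxel indices allow attributions computed on the
#' columns to be projected back into volume space.
#'
#' @slot X numeric matrix, subjects x features.
#' @slot y factor of length nrow(X) with exactly two levels; the second
#'   level is the positive ("patient") class.
#' @slot featureIndex integer vector of 1-based linear voxel indices,
#'   one per column of X.
#' @slot dim integer(3) voxel grid the indices refer to.
#' @slot affine 4x4 voxel-to-world matrix.
#' @slot subjectIds character, aligned to rows of X.
#' @export
setClass("FeatureMatrix",
  representation(
    X = "matrix",
    y = "factor",
    featureIndex = "integer",
    dim = "integer",
    affine = "matrix",
    subjectIds = "character"
  )
)

setValidity("FeatureMatrix", function(object) {
  msg <- character()
  if (length(object@y) != nrow(object@X))
    msg <- c(msg, "'y' length must equal nrow(X)")
  if (nlevels(object@y) != 2L)
    msg <- c(msg, "'y' must have exactly two levels")
  if (length(object@featureIndex) != ncol(object@X))
    msg <- c(msg, "'featureIndex' length must equal ncol(X)")
  if (length(object@dim) != 3L)
    msg <- c(msg, "'dim' must be integer(3)")
  if (length(msg)) msg else TRUE
})

#' AttributionMatrix: per-subject, per-feature Shapley values
#'
#' Shapley attributions phi (in units of the model output, here the
#' positive-class probability) together with the base value, i.e. the
#' expected model output over the background set. Local accuracy
#' requires baseValue + rowSums(phi) to match the model output at each
#' subject up to estimator tolerance.
#'
#' @slot phi numeric matrix, subjects x features.
#' @slot se Monte-Carlo standard errors of phi (zero matrix for exact
#'   enumeration).
#' @slot baseValue expected model output over the background rows.
#' @slot backgroundIds identifiers of the background rows used.
#' @slot subjectIds character, aligned to rows of phi.
#' @export
setClass("AttributionMatrix",
  representation(
    phi = "matrix",
    se = "matrix",
    baseValue = "numeric",
    backgroundIds = "character",
    subjectIds = "character"
  )
)

setValidity("AttributionMatrix", function(object) {
  msg <- character()
  if (length(object@baseValue) != 1L || !is.finite(object@baseValue))
    msg <- c(msg, "'baseValue' must be a single finite number")
  if (!all(is.finite(object@phi)))
    msg <- c(msg, "'phi' must be finite")
  if (length(object@subjectIds) &&
      length(object@subjectIds) != nrow(object@phi))
    msg <- c(msg, "'subjectIds' must align with rows of phi")
  if (length(msg)) msg else TRUE
})

#' ViciResult: the volumetric integrated classification index
#'
#' The composite index built from Shapley attributions: a per-subject
#' scalar (the weighted sum of attributions), the per-feature weight
#' vector, and per-subject voxel maps of the weighted attributions
#' back-projected through the feature index.
#'
#' @slot scalar named numeric, one value per subject (model-output units).
#' @slot weights per-feature nonnegative weights; unit vector or
#'   normalized to sum 1.
#' @slot maps numeric 4-D array, subjects x X x Y x Z, zero outside the
#'   feature voxels.
#' @slot featureIndex linear voxel indices of the features.
#' @slot baseValue base value inherited from the attribution matrix.
#' @slot affine 4x4 voxel-to-world matrix.
#' @slot scheme weighting scheme used ("unit" or "importance").
#' @export
setClass("ViciResult",
  representation(
    scalar = "numeric",
    weights = "numeric",
    maps = "array",
    featureIndex = "integer",
    baseValue = "numeric",
    affine = "matrix",
    scheme = "character"
  )
)

setValidity("ViciResult", function(object) {
  msg <- character()
  if (length(dim(object@maps)) != 4L)
    msg <- c(msg, "'maps' must be 4-D (subjects x X x Y x Z)")
  if (length(object@scalar) != dim(object@maps)[1L])
    msg <- c(msg, "'scalar' must have one value per subject map")
  if (length(object@weights) != length(object@featureIndex))
    msg <- c(msg, "'weights' must align with 'featureIndex'")
  if (any(object@weights < 0))
    msg <- c(msg, "'weights' must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' ExpressionArray: donor x region x gene expression
#'
#' Microarray-like expression values for a set of brain regions measured
#' in several donors, the substrate of differential-stability filtering
#' and imaging-transcriptomic association.
#'
#' @slot values numeric 3-D array, donors x regions x genes.
#' @slot genes character gene names (third dimension).
#' @slot regions character region identifiers (second dimension),
#'   matching parcellation labels.
#' @slot donors character donor identifiers (first dimension).
#' @slot normalized logical flag set by [normalizeExpression()].
#' @export
setClass("ExpressionArray",
  representation(
    values = "array",
    genes = "character",
    regions = "character",
    donors = "character",
    normalized = "logical"
  )
)

setValidity("ExpressionArray", function(object) {
  msg <- character()
  d <- dim(object@values)
  if (length(d) != 3L)
    msg <- c(msg, "'values' must be donors x regions x genes")
  else {
    if (length(object@donors) != d[1L])
      msg <- c(msg, "'donors' must match dim 1")
    if (length(object@regions) != d[2L])
      msg <- c(msg, "'regions' must match dim 2")
    if (length(object@genes) != d[3L])
      msg <- c(msg, "'genes' must match dim 3")
  }
  if (anyDuplicated(object@genes))
    msg <- c(msg, "gene names must be unique")
  if (!all(is.finite(object@values)))
    msg <- c(msg, "'values' must be finite")
  if (length(msg)) msg else TRUE
})

#' SyntheticCohort: a simulated case-control GMV cohort
#'
#' Output of [simulateCohort()]: the volume stack, the subject table
#' (group, age, TIV and four clinical scores), the binary truth mask of
#' planted-effect voxels, and an echo of the generating configuration.
#'
#' @slot volumes a [GmvStack-class].
#' @slot subjects data.frame with columns id, group, age, tiv, caps,
#'   mmse, moca, gds.
#' @slot truthMask logical 3-D array marking planted-effect voxels.
#' @slot config the [cohortConfig()] list that generated the cohort.
#' @export
setClass("SyntheticCohort",
  representation(
    volumes = "GmvStack",
    subjects = "data.frame",
    truthMask = "array",
    config = "list"
  )
)

setValidity("SyntheticCohort", function(object) {
  msg <- character()
  if (nrow(object@subjects) != dim(object@volumes@data)[1L])
    msg <- c(msg, "subject table rows must equal number of volumes")
  if (!identical(dim(object@truthMask), dim(object@volumes@data)[-1L]))
    msg <- c(msg, "truth mask shape must equal volume shape")
  need <- c("id", "group", "age", "tiv", "caps", "mmse", "moca", "gds")
  if (!all(need %in% names(object@subjects)))
    msg <- c(msg, paste("subject table must contain columns:",
                        paste(need, collapse = ", ")))
  if (length(msg)) msg else TRUE
})
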