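#' Construct a GmvStack
#'
#' @param data 4-D numeric array, subjects x X x Y x Z.
#' @param affine 4x4 voxel-to-world matrix; default an isotropic
#'   `voxelSize` mm grid with the world origin at voxel (0,0,0).
#' @param subjectIds character vector of subject identifiers; default
#'   `s001, s002, ...`.
#' @param voxelSize isotropic voxel edge in mm, used only when `affine`
#'   is not given.
#' @return a [GmvStack-class]
#' @examples
#' stk <- gmvStack(array(runif(2 * 4 * 4 * 4), c(2, 4, 4, 4)))
#' nSubjects(stk)
#' @export
gmvStack <- function(data, affine = NULL, subjectIds = NULL, voxelSize = 2) {
  if (is.null(affine)) {
    affine <- diag(c(rep(voxelSize, 3L), 1))
  }
  if (is.null(subjectIds)) {
    subjectIds <- sprintf("s%03d", seq_len(dim(data)[1L]))
  }
  new("GmvStack", data = data, affine = affine,
      subjectIds = as.character(subjectIds))
}

#' @rdname gmvStack
#' @param x a GmvStack
#' @export
nSubjects <- function(x) dim(x@data)[1L]

#' @rdname gmvStack
#' @export
gridDim <- function(x) {
  if (is(x, "GmvStack")) dim(x@data)[-1L]
  else if (is(x, "StatMap")) dim(x@t)
  else stop("no voxel grid for class ", class(x))
}

#' @rdname gmvStack
#' @export
gmvData <- function(x) x@data

#' @rdname gmvStack
#' @export
subjectIds <- function(x) x@subjectIds

#' Voxel-to-world affine of a volume object
#' @param x a GmvStack, StatMap, FeatureMatrix or ViciResult
#' @export
affineMatrix <- function(x) x@affine

#' Isotropic voxel edge length in mm derived from the affine
#' @param x object carrying an affine
#' @export
voxelSize <- function(x) {
  aff <- affineMatrix(x)
  sizes <- sqrt(colSums(aff[1:3, 1:3]^2))
  if (diff(range(sizes)) > 1e-6 * mean(sizes))
    warning("anisotropic voxels; returning the mean edge length")
  mean(sizes)
}

#' Extract one subject's volume as a 3-D array
#' @param x a GmvStack
#' @param i subject index or id
#' @export
subjectVolume <- function(x, i) {
  if (is.character(i)) i <- match(i, x@subjectIds)
  v <- x@data[i, , , , drop = FALSE]
  array(v, dim(x@data)[-1L])
}

#' @rdname statMapAccessors
#' @name statMapAccessors
#' @title Accessors for StatMap
#' @param x a [StatMap-class]
#' @export
tMap <- function(x) x@t

#' @rdname statMapAccessors
#' @export
pUncorrected <- function(x) x@pUnc

#' @rdname statMapAccessors
#' @export
analysisMask <- function(x) x@mask

#' @rdname statMapAccessors
#' @export
dfResidual <- function(x) x@df

#' Accessors for AttributionMatrix
#' @param x an [AttributionMatrix-class]
#' @name attributionAccessors
#' @rdname attributionAccessors
#' @export
phiMatrix <- function(x) x@phi

#' @rdname attributionAccessors
#' @export
baseValue <- function(x) x@baseValue

#' Accessors for ViciResult
#' @param x a [ViciResult-class]
#' @name viciAccessors
#' @rdname viciAccessors
#' @export
viciScalar <- function(x) x@scalar

#' @rdname viciAccessors
#' @export
viciWeights <- function(x) x@weights

#' @rdname viciAccessors
#' @export
viciMaps <- function(x) x@maps

#' Accessors for ExpressionArray
#' @param x an [ExpressionArray-class]
#' @name expressionAccessors
#' @rdname expressionAccessors
#' @export
expressionValues <- function(x) x@values

#' @rdname expressionAccessors
#' @export
geneNames <- function(x) x@genes

#' @rdname expressionAccessors
#' @export
regionIds <- function(x) x@regions

#' @rdname expressionAccessors
#' @export
donorIds <- function(x) x@donors

#' Accessors for SyntheticCohort
#' @param x a [SyntheticCohort-class]
#' @name cohortAccessors
#' @rdname cohortAccessors
#' @export
cohortVolumes <- function(x) x@volumes

#' @rdname cohortAccessors
#' @export
cohortSubjects <- function(x) x@subjects

#' @rdname cohortAccessors
#' @export
truthMask <- function(x) x@truthMask

#' @rdname cohortAccessors
#' @export
cohortConfigEcho <- function(x) x@config

setMethod("show", "GmvStack", function(object) {
  d <- dim(object@data)
  cat("GmvStack:", d[1L], "subjects on a", paste(d[-1L], collapse = " x "),
      "grid,", format(voxelSize(object), digits = 3), "mm voxels\n")
})

setMethod("show", "StatMap", function(object) {
  cat("StatMap:", paste(dim(object@t), collapse = " x "),
      "grid, df =", object@df, "\n")
  cat("  mask voxels:", sum(object@mask),
      " |t| range in mask:",
      if (any(object@mask))
        paste(format(range(abs(object@t[object@mask])), digits = 3),
              collapse = " - ")
      else "(empty)", "\n")
})

setMethod("show", "FeatureMatrix", function(object) {
  cat("FeatureMatrix:", nrow(object@X), "subjects x", ncol(object@X),
      "voxel features; classes:",
      paste(sprintf("%s (n=%d)", levels(object@y), tabulate(object@y)),
            collapse = ", "), "\n")
})

setMethod("show", "AttributionMatrix", function(object) {
  cat("AttributionMatrix:", nrow(object@phi), "subjects x",
      ncol(object@phi), "features; base value",
      format(object@baseValue, digits = 4), "\n")
})

setMethod("show", "ViciResult", function(object) {
  cat("ViciResult (", object@scheme, " weights): ",
      length(object@scalar), " subjects, ",
      length(object@featureIndex), " feature voxels\n", sep = "")
})

setMethod("show", "ExpressionArray", function(object) {
  d <- dim(object@values)
  cat("ExpressionArray:", d[1L], "donors x", d[2L], "regions x",
      d[3L], "genes", if (object@normalized) "(normalized)" else "", "\n")
})

setMethod("show", "SyntheticCohort", function(object) {
  tab <- table(object@subjects$group)
  cat("SyntheticCohort:", paste(names(tab), tab, sep = "=", collapse = ", "),
      "on a", paste(gridDim(object@volumes), collapse = " x "), "grid;",
      sum(object@truthMask), "truth-mask voxels\n")
})
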