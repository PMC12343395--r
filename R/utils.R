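#' Derive a stage seed from a master seed
#'
#' One master seed fans out to per-stage seeds so that stages are
#' reproducible in isolation yet mutually decorrelated. The rule is
#' `(master * 1009 + 97 * stage) mod (2^31 - 1)`: a fixed affine map per
#' stage index, kept inside the 32-bit integer range R requires.
#'
#' @param master master seed (integer)
#' @param stage stage index (integer >= 0)
#' @return an integer usable with [set.seed()]
#' @export
deriveSeed <- function(master, stage) {
  as.integer((as.numeric(master) * 1009 + 97 * as.numeric(stage)) %%
               2147483647)
}

#' Area under the ROC curve from continuous scores
#'
#' Rank-statistic (Mann-Whitney) AUC with midranks for ties: the
#' probability that a randomly chosen positive scores above a randomly
#' chosen negative, counting ties as one half.
#'
#' @param scores numeric scores, larger meaning more positive
#' @param labels logical or 0/1 vector; TRUE/1 is the positive class
#' @return AUC in [0, 1], or NA if a class is absent
#' @export
rocAuc <- function(scores, labels) {
  labels <- as.logical(as.integer(labels))
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Dice overlap between two binary masks
#' @param a,b logical arrays of equal shape
#' @return 2|A∩B| / (|A|+|B|); 1 when both masks are empty
#' @export
diceOverlap <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  stopifnot(length(a) == length(b))
  denom <- sum(a) + sum(b)
  if (denom == 0L) return(1)
  2 * sum(a & b) / denom
}

# 1-D Gaussian smoothing matrix with reflect (half-sample mirror)
# boundary handling. Columns sum to 1 exactly, so convolution preserves
# the image sum.
gaussianSmoothMatrix <- function(n, sigmaVox) {
  if (sigmaVox <= 0) return(diag(n))
  r <- max(1L, ceiling(4 * sigmaVox))
  offs <- -r:r
  w <- exp(-offs^2 / (2 * sigmaVox^2))
  w <- w / sum(w)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i + offs
    # reflect: ... 2 1 | 1 2 ... n-1 n | n n-1 ...
    j <- ifelse(j < 1L, 1L - j, j)
    j <- ifelse(j > n, 2L * n + 1L - j, j)
    # long kernels may need repeated folding on tiny axes
    while (any(j < 1L | j > n)) {
      j <- ifelse(j < 1L, 1L - j, j)
      j <- ifelse(j > n, 2L * n + 1L - j, j)
    }
    for (k in seq_along(offs)) S[j[k], i] <- S[j[k], i] + w[k]
  }
  t(S)
}

# Apply a matrix along one dimension of a 3-D array: out = A applied on
# axis `along`, i.e. out[i,,] = sum_k M[i,k] x[k,,] for along = 1, etc.
applyAlong <- function(x, M, along) {
  d <- dim(x)
  perm <- c(along, setdiff(1:3, along))
  xp <- aperm(x, perm)
  m <- matrix(xp, nrow = d[along])
  yp <- M %*% m
  y <- array(yp, dim = d[perm])
  aperm(y, order(perm))
}

# Connected components of a voxel index set under 6/18/26-neighborhood.
# Returns an integer label per input voxel; labels are ordered by
# decreasing component size, ties broken by smallest linear voxel index.
connectedComponents <- function(voxelIdx, dim3, connectivity = 26L) {
  stopifnot(connectivity %in% c(6L, 18L, 26L))
  nv <- length(voxelIdx)
  if (nv == 0L) return(integer(0))
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  ord <- rowSums(abs(offs))
  keep <- switch(as.character(connectivity),
                 "6" = ord == 1, "18" = ord >= 1 & ord <= 2, "26" = ord >= 1)
  offs <- offs[keep, , drop = FALSE]
  # half-space offsets suffice for undirected edges
  half <- offs[offs[, 3] > 0 | (offs[, 3] == 0 & offs[, 2] > 0) |
                 (offs[, 3] == 0 & offs[, 2] == 0 & offs[, 1] > 0), ,
               drop = FALSE]
  co <- arrayInd(voxelIdx, dim3)
  edges <- NULL
  for (k in seq_len(nrow(half))) {
    nb <- sweep(co, 2L, half[k, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dim3[1] &
          nb[, 2] >= 1 & nb[, 2] <= dim3[2] &
          nb[, 3] >= 1 & nb[, 3] <= dim3[3]
    if (!any(ok)) next
    nbIdx <- (nb[ok, 3] - 1) * dim3[1] * dim3[2] +
             (nb[ok, 2] - 1) * dim3[1] + nb[ok, 1]
    m <- match(nbIdx, voxelIdx)
    hit <- !is.na(m)
    if (any(hit))
      edges <- rbind(edges, cbind(which(ok)[hit], m[hit]))
  }
  if (is.null(edges)) {
    comp <- seq_len(nv)
  } else {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, nv - igraph::vcount(g)))
    comp <- igraph::components(g)$membership
  }
  # deterministic relabeling: by decreasing size, tie by min voxel index
  sizes <- tabulate(comp)
  minIdx <- vapply(seq_along(sizes),
                   function(l) min(voxelIdx[comp == l]), numeric(1))
  newOrder <- order(-sizes, minIdx)
  relabel <- integer(length(sizes))
  relabel[newOrder] <- seq_along(sizes)
  relabel[comp]
}

# linear index -> 1-based voxel coordinates
voxelCoords <- function(idx, dim3) arrayInd(idx, dim3)

# 0-based voxel coordinates -> world mm through the affine
voxelToWorld <- function(coords0, affine) {
  h <- cbind(coords0, 1)
  t(affine %*% t(h))[, 1:3, drop = FALSE]
}
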