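#' Model function of a fitted classifier
#'
#' Wraps a fitted model as a plain `function(X) -> numeric` returning
#' the positive-class probability, the model output that Shapley
#' attributions decompose.
#'
#' @param fit a `TunedClassifier` or `viciClassifier`
#' @return function taking a feature matrix
#' @export
modelFunction <- function(fit) {
  model <- if (inherits(fit, "TunedClassifier")) fit$model else fit
  force(model)
  function(X) predictProb(model, X)
}

#' Exact Shapley attribution by coalition enumeration
#'
#' Interventional Shapley values: the value of a coalition S is the
#' background-averaged model output with the features in S taken from
#' the explained point and the rest from the background rows,
#' `v(S) = mean_b f(x_S, b_{-S})`. Each feature's value is the
#' Shapley-weighted sum of its marginal contributions over all
#' 2^(d-1) coalitions, and `base = v(empty set)`. Exact enumeration is
#' limited to d <= 12 features; beyond that use
#' [shapleyMonteCarlo()].
#'
#' Satisfies efficiency (`base + sum(phi) = f(x)`), symmetry and the
#' dummy axiom to numerical precision.
#'
#' @param modelFn function mapping a feature matrix to model outputs
#' @param x numeric feature vector of the point to explain
#' @param background matrix of background rows (the reference
#'   distribution the expectation is taken over)
#' @return list: `phi` (length d), `baseValue`
#' @export
shapleyExact <- function(modelFn, x, background) {
  background <- as.matrix(background)
  d <- length(x)
  stopifnot(ncol(background) == d)
  if (d > 12L)
    stop("exact enumeration is limited to 12 features; ",
         "use shapleyMonteCarlo()")
  nB <- nrow(background)
  nS <- 2L^d
  # evaluate all coalitions in one batched model call
  big <- matrix(0, nS * nB, d)
  for (m in seq_len(nS)) {
    inS <- bitwAnd(m - 1L, bitwShiftL(1L, 0:(d - 1L))) != 0L
    blk <- background
    if (any(inS)) blk[, inS] <- rep(x[inS], each = nB)
    big[((m - 1L) * nB + 1L):(m * nB), ] <- blk
  }
  out <- modelFn(big)
  v <- colMeans(matrix(out, nB, nS))
  # Shapley kernel weights by coalition size
  sizes <- vapply(seq_len(nS) - 1L,
                  function(m) sum(bitwAnd(m, bitwShiftL(1L, 0:(d - 1L))) != 0L),
                  integer(1))
  wBySize <- exp(lfactorial(0:(d - 1L)) + lfactorial(d - 1L - (0:(d - 1L))) -
                   lfactorial(d))
  phi <- numeric(d)
  for (j in seq_len(d)) {
    bit <- bitwShiftL(1L, j - 1L)
    without <- which(bitwAnd(seq_len(nS) - 1L, bit) == 0L)
    withJ <- without + bit / 1L
    s <- sizes[without]
    phi[j] <- sum(wBySize[s + 1L] * (v[withJ] - v[without]))
  }
  list(phi = phi, baseValue = v[1L])
}

#' Monte-Carlo Shapley attribution by permutation sampling
#'
#' Seeded permutation-sampling estimator of interventional Shapley
#' values: for each of `nSamples` draws a random feature order and a
#' random background row are taken, features are switched from the
#' background value to the explained point's value in that order, and
#' the output change when a feature switches is its sampled marginal
#' contribution. The estimator is unbiased for the exact enumeration
#' values and its per-feature Monte-Carlo standard error is returned.
#'
#' @param modelFn function mapping a feature matrix to model outputs
#' @param X matrix (or [FeatureMatrix-class]) of points to explain
#' @param background matrix of background rows
#' @param nSamples permutations per explained point (default 200)
#' @param seed integer seed
#' @return an [AttributionMatrix-class] (with the `se` slot filled)
#' @export
shapleyMonteCarlo <- function(modelFn, X, background, nSamples = 200L,
                              seed = 1L) {
  if (is(X, "FeatureMatrix")) {
    ids <- X@subjectIds
    X <- X@X
  } else {
    X <- as.matrix(X)
    ids <- rownames(X)
    if (is.null(ids)) ids <- sprintf("row%03d", seq_len(nrow(X)))
  }
  background <- as.matrix(background)
  if (!nrow(background)) stop("background set is empty")
  if (nSamples < 1L) stop("'nSamples' must be at least 1")
  d <- ncol(X)
  n <- nrow(X)
  base <- mean(modelFn(background))
  phi <- matrix(0, n, d, dimnames = list(ids, colnames(X)))
  se <- matrix(0, n, d, dimnames = list(ids, colnames(X)))
  set.seed(seed)
  for (i in seq_len(n)) {
    perms <- replicate(nSamples, sample.int(d), simplify = FALSE)
    bIdx <- sample.int(nrow(background), nSamples, replace = TRUE)
    # rows: for each sample, the d+1 states from all-background to all-x
    big <- matrix(0, nSamples * (d + 1L), d)
    for (s in seq_len(nSamples)) {
      z <- background[bIdx[s], ]
      o <- (s - 1L) * (d + 1L)
      big[o + 1L, ] <- z
      for (k in seq_len(d)) {
        z[perms[[s]][k]] <- X[i, perms[[s]][k]]
        big[o + 1L + k, ] <- z
      }
    }
    out <- matrix(modelFn(big), d + 1L, nSamples)
    contrib <- matrix(0, nSamples, d)
    for (s in seq_len(nSamples))
      contrib[s, perms[[s]]] <- diff(out[, s])
    phi[i, ] <- colMeans(contrib)
    se[i, ] <- apply(contrib, 2L, stats::sd) / sqrt(nSamples)
  }
  new("AttributionMatrix", phi = phi, se = se, baseValue = base,
      backgroundIds = as.character(rownames(background) %||%
                                     seq_len(nrow(background))),
      subjectIds = ids)
}

#' Exact attributions for a whole matrix of points
#'
#' Convenience wrapper running [shapleyExact()] row by row; subject to
#' the same d <= 12 guard.
#'
#' @inheritParams shapleyMonteCarlo
#' @return an [AttributionMatrix-class] (se all zero)
#' @export
shapleyExactMatrix <- function(modelFn, X, background) {
  if (is(X, "FeatureMatrix")) {
    ids <- X@subjectIds
    X <- X@X
  } else {
    X <- as.matrix(X)
    ids <- rownames(X) %||% sprintf("row%03d", seq_len(nrow(X)))
  }
  res <- lapply(seq_len(nrow(X)),
                function(i) shapleyExact(modelFn, X[i, ], background))
  phi <- do.call(rbind, lapply(res, `[[`, "phi"))
  dimnames(phi) <- list(ids, colnames(X))
  new("AttributionMatrix", phi = phi,
      se = matrix(0, nrow(phi), ncol(phi)),
      baseValue = res[[1L]]$baseValue,
      backgroundIds = as.character(rownames(background) %||%
                                     seq_len(nrow(background))),
      subjectIds = ids)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Draw a seeded background subsample from a training set
#'
#' @param train a [FeatureMatrix-class]
#' @param size background rows to keep (default 50; capped at n)
#' @param seed integer seed
#' @return matrix of background rows
#' @export
backgroundSample <- function(train, size = 50L, seed = 1L) {
  X <- if (is(train, "FeatureMatrix")) train@X else as.matrix(train)
  if (nrow(X) <= size) return(X)
  set.seed(seed)
  X[sort(sample.int(nrow(X), size)), , drop = FALSE]
}
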