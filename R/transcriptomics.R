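#' Regional aggregation of a statistical map
#'
#' Mean t value per atlas label over voxels inside the analysis mask.
#' Regions with no masked voxel are reported with NA and flagged.
#'
#' @param map a [StatMap-class]
#' @param atlas integer 3-D volume of region labels (0 = background),
#'   on the same grid as the map
#' @param absolute if TRUE, aggregate |t| instead of signed t
#' @return data.frame: region (label), mean_t, n_voxels, missing
#' @export
regionalAggregate <- function(map, atlas, absolute = FALSE) {
  stopifnot(is(map, "StatMap"))
  if (!identical(dim(atlas), dim(map@t)))
    stop("atlas grid does not match the map grid")
  labs <- sort(unique(as.integer(atlas[atlas > 0])))
  tvals <- if (absolute) abs(map@t) else map@t
  rows <- lapply(labs, function(l) {
    sel <- atlas == l & map@mask
    n <- sum(sel)
    data.frame(region = l,
               mean_t = if (n) mean(tvals[sel]) else NA_real_,
               n_voxels = n, missing = n == 0L)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# scaled robust sigmoid over a numeric vector: outlier-robust sigmoid
# (median/IQR) rescaled to [0, 1]. Zero IQR falls back to rank scaling.
scaledRobustSigmoid <- function(x) {
  iqr <- stats::IQR(x)
  if (iqr < .Machine$double.eps^0.5) {
    if (length(unique(x)) == 1L)
      return(structure(rep(0.5, length(x)), degenerate = TRUE))
    r <- rank(x, ties.method = "average")
    return(structure((r - min(r)) / (max(r) - min(r)), degenerate = TRUE))
  }
  s <- 1 / (1 + exp(-(x - stats::median(x)) / (iqr / 1.35)))
  structure((s - min(s)) / (max(s) - min(s)), degenerate = FALSE)
}

#' Scaled-robust-sigmoid normalization of an expression array
#'
#' Within each donor, expression is normalized with the outlier-robust
#' sigmoid (median/IQR-standardized logistic, rescaled to the unit
#' interval) first across genes within each region, then across regions
#' within each gene — the two-pass sample/gene normalization used when
#' harmonizing multi-donor microarray atlases. Rank order is preserved
#' along each normalized axis. Axes with zero IQR fall back to rank
#' scaling and raise the `degenerate` flag.
#'
#' @param arr an [ExpressionArray-class]
#' @return a normalized [ExpressionArray-class] (values in [0, 1]);
#'   attribute `degenerate` reports whether any axis needed the
#'   fallback
#' @export
normalizeExpression <- function(arr) {
  stopifnot(is(arr, "ExpressionArray"))
  v <- arr@values
  nD <- dim(v)[1L]; nR <- dim(v)[2L]; nG <- dim(v)[3L]
  if (nR < 2L) stop("need at least 2 regions")
  degen <- FALSE
  for (d in seq_len(nD)) {
    for (r in seq_len(nR)) {           # across genes within region
      s <- scaledRobustSigmoid(v[d, r, ])
      degen <- degen || attr(s, "degenerate")
      v[d, r, ] <- s
    }
    for (g in seq_len(nG)) {           # across regions within gene
      s <- scaledRobustSigmoid(v[d, , g])
      degen <- degen || attr(s, "degenerate")
      v[d, , g] <- s
    }
  }
  out <- new("ExpressionArray", values = v, genes = arr@genes,
             regions = arr@regions, donors = arr@donors,
             normalized = TRUE)
  attr(out, "degenerate") <- degen
  out
}

#' Differential stability of genes across donors
#'
#' DS(gene) = mean over donor pairs of the Spearman correlation between
#' the two donors' regional expression profiles: a reproducibility
#' score for each gene's spatial pattern, invariant to monotone
#' per-donor transforms.
#'
#' @param arr an [ExpressionArray-class] with >= 2 donors
#' @return named numeric vector of DS scores, one per gene
#' @export
differentialStability <- function(arr) {
  stopifnot(is(arr, "ExpressionArray"))
  v <- arr@values
  nD <- dim(v)[1L]
  if (nD < 2L) stop("differential stability needs at least 2 donors")
  pairs <- utils::combn(nD, 2L)
  ds <- vapply(seq_len(dim(v)[3L]), function(g) {
    mean(vapply(seq_len(ncol(pairs)), function(k) {
      a <- v[pairs[1L, k], , g]
      b <- v[pairs[2L, k], , g]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
      if (all(a == b)) return(1)   # exact for identical profiles
      stats::cor(a, b, method = "spearman")
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  names(ds) <- arr@genes
  ds
}

#' Retain the most differentially stable genes
#'
#' Keeps the top `fraction` of genes ranked by differential stability
#' (default the top half). Ties at the cut are broken deterministically
#' by gene name.
#'
#' @param arr an [ExpressionArray-class]
#' @param fraction fraction of genes to retain (default 0.5)
#' @return the filtered [ExpressionArray-class]; retained DS scores in
#'   attribute `ds`
#' @export
filterByStability <- function(arr, fraction = 0.5) {
  stopifnot(fraction > 0, fraction <= 1)
  ds <- differentialStability(arr)
  keepN <- max(1L, floor(length(ds) * fraction))
  ord <- order(-ds, arr@genes)
  keep <- sort(ord[seq_len(keepN)])
  out <- new("ExpressionArray", values = arr@values[, , keep, drop = FALSE],
             genes = arr@genes[keep], regions = arr@regions,
             donors = arr@donors, normalized = arr@normalized)
  attr(out, "ds") <- ds[keep]
  out
}

#' Gene-wise association between regional abnormality and expression
#'
#' Donor-averaged expression of each requested risk gene is correlated
#' (Spearman) across regions with the regional mean t of the VICI
#' group-difference map, with Bonferroni correction over the number of
#' genes actually tested. Risk genes absent from the (stability-
#' filtered) array are reported in the `missing` attribute, never
#' silently dropped.
#'
#' @param regionalT data.frame from [regionalAggregate()] (columns
#'   region, mean_t) or a named numeric vector of per-region t values
#' @param arr a normalized [ExpressionArray-class], regions named as in
#'   `regionalT`
#' @param riskGenes character vector of gene names to test
#' @param alpha significance level after Bonferroni (default 0.05)
#' @param absolute correlate |t| instead of signed t (default FALSE)
#' @return data.frame sorted by corrected p: gene, rho, p, p_bonferroni,
#'   pass; attribute `missing` lists risk genes not in the array
#' @export
geneViciAssociation <- function(regionalT, arr, riskGenes, alpha = 0.05,
                                absolute = FALSE) {
  stopifnot(is(arr, "ExpressionArray"))
  if (is.data.frame(regionalT)) {
    tvec <- regionalT$mean_t
    names(tvec) <- as.character(regionalT$region)
  } else {
    tvec <- regionalT
  }
  if (absolute) tvec <- abs(tvec)
  common <- intersect(names(tvec)[!is.na(tvec)], arr@regions)
  if (length(common) < 4L)
    stop("need at least 4 overlapping regions, got ", length(common))
  missing <- setdiff(riskGenes, arr@genes)
  if (length(missing))
    warning(length(missing), " risk gene(s) not present after filtering: ",
            paste(missing, collapse = ", "))
  tested <- intersect(riskGenes, arr@genes)
  if (!length(tested)) stop("no risk genes available to test")
  ridx <- match(common, arr@regions)
  expr <- apply(arr@values[, ridx, match(tested, arr@genes), drop = FALSE],
                c(2L, 3L), mean)       # regions x genes, donor-averaged
  tv <- tvec[common]
  rows <- lapply(seq_along(tested), function(k) {
    ct <- suppressWarnings(stats::cor.test(tv, expr[, k],
                                           method = "spearman",
                                           exact = FALSE))
    data.frame(gene = tested[k], rho = unname(ct$estimate),
               p = ct$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, stats::p.adjust(out$p, method = "bonferroni"))
  out$pass <- out$p_bonferroni < alpha
  out <- out[order(out$p_bonferroni, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "missing") <- missing
  attr(out, "n_regions") <- length(common)
  out
}
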