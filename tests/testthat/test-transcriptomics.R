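makeExpr <- function(vals, genes = NULL, regions = NULL, donors = NULL,
                     normalized = FALSE) {
  d <- dim(vals)
  new("ExpressionArray", values = vals,
      genes = genes %||% sprintf("gene%03d", seq_len(d[3])),
      regions = regions %||% sprintf("region%03d", seq_len(d[2])),
      donors = donors %||% sprintf("donor%d", seq_len(d[1])),
      normalized = normalized)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("regional aggregation averages t within labels", {
  tArr <- array(0, c(4, 1, 1)); tArr[, 1, 1] <- c(1, 3, 2, -4)
  m <- toyStatMap(tArr)
  atlas <- array(c(1L, 1L, 2L, 3L), c(4, 1, 1))
  agg <- regionalAggregate(m, atlas)
  expect_equal(agg$mean_t, c(2, 2, -4))
  expect_equal(agg$n_voxels, c(2L, 1L, 1L))
  # uniform map: every region mean equals the constant
  u <- toyStatMap(array(2, c(4, 4, 4)))
  atlas2 <- array(rep(1:4, each = 16), c(4, 4, 4))
  expect_true(all(regionalAggregate(u, atlas2)$mean_t == 2))
  # single-region atlas equals the global masked mean
  one <- array(1L, c(4, 4, 4))
  r <- rnorm(64); mm <- toyStatMap(array(r, c(4, 4, 4)))
  expect_equal(regionalAggregate(mm, one)$mean_t, mean(r))
  # masked-out regions are flagged missing
  msk <- array(TRUE, c(4, 1, 1)); msk[3, 1, 1] <- FALSE
  m2 <- toyStatMap(tArr, mask = msk)
  agg2 <- regionalAggregate(m2, atlas)
  expect_true(agg2$missing[agg2$region == 2])
  expect_error(regionalAggregate(m, array(1L, c(2, 2, 2))), "grid")
})

test_that("scaled robust sigmoid normalization matches the direct formula", {
  # independently coded oracle on a printed 3-region, 2-gene matrix
  vals <- array(0, c(1, 3, 2))
  vals[1, , 1] <- c(1, 2, 10)
  vals[1, , 2] <- c(5, 3, 4)
  srs <- function(x) {
    s <- 1 / (1 + exp(-(x - median(x)) / (IQR(x) / 1.35)))
    (s - min(s)) / (max(s) - min(s))
  }
  # pass 1 within each region across genes, pass 2 within each gene
  # across regions
  step1 <- vals
  for (r in 1:3) step1[1, r, ] <- srs(vals[1, r, ])
  expected <- step1
  for (g in 1:2) expected[1, , g] <- srs(step1[1, , g])
  out <- normalizeExpression(makeExpr(vals))
  expect_equal(expressionValues(out), expected, tolerance = 1e-12)
  expect_true(all(expressionValues(out) >= 0 &
                    expressionValues(out) <= 1))
})

test_that("normalization preserves rank order and flags degenerate axes", {
  set.seed(5)
  vals <- array(rnorm(2 * 10 * 6), c(2, 10, 6))
  n1 <- normalizeExpression(makeExpr(vals))
  # each pass is monotone along its own axis: the final (region-axis)
  # ranks equal the ranks of the first-pass intermediate, recomputed
  # here with the direct formula
  srs <- function(x) {
    s <- 1 / (1 + exp(-(x - median(x)) / (IQR(x) / 1.35)))
    (s - min(s)) / (max(s) - min(s))
  }
  step1 <- vals
  for (d in 1:2) for (r in 1:10) step1[d, r, ] <- srs(vals[d, r, ])
  for (d in 1:2) for (g in 1:6)
    expect_equal(rank(expressionValues(n1)[d, , g]),
                 rank(step1[d, , g]))
  # and the first pass preserves within-region gene ranks of the input
  for (d in 1:2) for (r in 1:10)
    expect_equal(rank(step1[d, r, ]), rank(vals[d, r, ]))
  # identical values along an axis: constant output plus flag
  flat <- array(1, c(2, 5, 3))
  nf <- normalizeExpression(makeExpr(flat))
  expect_true(attr(nf, "degenerate"))
  expect_true(all(expressionValues(nf) == 0.5))
})

test_that("differential stability is 1 for identical donors and ~0 for independent ones", {
  set.seed(6)
  prof <- matrix(rnorm(50 * 8), 50, 8)
  vals <- array(0, c(3, 50, 8))
  for (d in 1:3) vals[d, , ] <- prof
  expect_true(all(differentialStability(makeExpr(vals)) == 1))
  # monotone per-donor transforms leave DS unchanged
  vals2 <- vals
  vals2[2, , ] <- exp(vals2[2, , ])
  vals2[3, , ] <- 5 * vals2[3, , ] - 1
  expect_equal(differentialStability(makeExpr(vals2)),
               differentialStability(makeExpr(vals)))
  # independent donors: DS centered near zero
  indep <- array(rnorm(4 * 50 * 200), c(4, 50, 200))
  ds <- differentialStability(makeExpr(indep))
  expect_lt(abs(mean(ds)), 0.05)
  expect_error(differentialStability(
    makeExpr(array(rnorm(50), c(1, 10, 5)))), "2 donors")
})

test_that("stability filtering keeps the top fraction with name tie-breaks", {
  vals <- array(0, c(2, 20, 4))
  set.seed(7)
  base <- matrix(rnorm(20 * 4), 20, 4)
  # genes 1,2 perfectly stable; genes 3,4 pure noise
  vals[1, , ] <- base
  vals[2, , 1:2] <- base[, 1:2]
  vals[2, , 3:4] <- matrix(rnorm(40), 20, 2)
  ex <- makeExpr(vals)
  kept <- filterByStability(ex, 0.5)
  expect_equal(geneNames(kept), c("gene001", "gene002"))
  expect_equal(length(attr(kept, "ds")), 2L)
  # exact ties broken deterministically by gene name
  tied <- array(rep(base, each = 2), c(2, 20, 4))
  keptTied <- filterByStability(makeExpr(tied), 0.5)
  expect_equal(geneNames(keptTied), c("gene001", "gene002"))
})

test_that("gene association recovers an exact expression-t match", {
  set.seed(9)
  nR <- 20
  tvec <- setNames(rnorm(nR), sprintf("region%03d", 1:nR))
  vals <- array(rnorm(2 * nR * 5), c(2, nR, 5))
  vals[1, , 3] <- tvec; vals[2, , 3] <- tvec   # gene003 == t vector
  ex <- makeExpr(vals)
  tab <- geneViciAssociation(tvec, ex, sprintf("gene%03d", 1:5))
  expect_equal(tab$rho[tab$gene == "gene003"], 1)
  expect_equal(tab$p_bonferroni, pmin(1, tab$p * 5), tolerance = 1e-12)
  expect_true(tab$pass[tab$gene == "gene003"])
  # missing risk genes are reported, not silently dropped
  expect_warning(
    tab2 <- geneViciAssociation(tvec, ex, c("gene001", "nope")),
    "nope")
  expect_equal(attr(tab2, "missing"), "nope")
  expect_error(geneViciAssociation(tvec[1:3], ex, "gene001"),
               "4 overlapping")
})

test_that("the association pipeline is invariant to region relabeling", {
  set.seed(10)
  nR <- 30
  sig <- rnorm(nR)
  ex <- simulateExpression(
    expressionConfig(nRegions = nR, nGenes = 20, nCoupled = 4,
                     seed = 3), sig)
  exN <- normalizeExpression(ex)
  tvec <- setNames(sig, regionIds(exN))
  tab1 <- geneViciAssociation(tvec, exN, geneNames(exN)[1:10])
  # permute region order consistently in both inputs
  perm <- sample(nR)
  exP <- makeExpr(expressionValues(exN)[, perm, , drop = FALSE],
                  genes = geneNames(exN),
                  regions = regionIds(exN)[perm], normalized = TRUE)
  tab2 <- geneViciAssociation(tvec[perm], exP, geneNames(exN)[1:10])
  expect_equal(tab1, tab2, tolerance = 1e-12)
})

test_that("null gene associations are uniform and Bonferroni controls the FWE", {
  set.seed(11)
  nR <- 30; nG <- 20; reps <- 200
  anyPass <- logical(reps)
  pAll <- c()
  for (r in seq_len(reps)) {
    tvec <- setNames(rnorm(nR), sprintf("region%03d", 1:nR))
    ex <- makeExpr(array(rnorm(2 * nR * nG), c(2, nR, nG)),
                   normalized = TRUE)
    tab <- geneViciAssociation(tvec, ex, geneNames(ex))
    pAll <- c(pAll, tab$p)
    anyPass[r] <- any(tab$pass)
  }
  # family-wise error within the binomial 95% band around 0.05
  expect_lt(mean(anyPass), 0.05 + 1.96 * sqrt(0.05 * 0.95 / reps) + 0.01)
  # rank-based p-values are discrete, so jitter-free KS is approximate
  expect_gt(suppressWarnings(ks.test(pAll, "punif"))$p.value, 1e-4)
})
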