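pipelineConfigKeys <- c(
  "voxel_p", "cluster_alpha", "test_fraction", "cv_folds", "n_perm",
  "n_perm_classify", "bonferroni_alpha", "ds_fraction", "smooth_fwhm",
  "seed", "n_background", "n_shap_samples", "weight_scheme",
  "classifier_families", "n_regions", "n_genes", "n_coupled",
  "coupling_strength", "n_donors", "selection_mode", "cohort")

#' Pipeline configuration
#'
#' Aggregates every threshold and seed of the end-to-end analysis:
#' voxelwise p 0.001, cluster-level FWE alpha 0.05, 9:1 train/test
#' split, tenfold cross-validation, 1000 permutations, Bonferroni alpha
#' 0.05, top-50% differential-stability filter and 8 mm smoothing. One
#' master seed fans out to per-stage seeds via [deriveSeed()].
#' Serializes to a single JSON document; unknown keys are rejected on
#' read.
#'
#' @param ... overrides of the default fields (see
#'   `vicindex:::pipelineConfigKeys`)
#' @return list of class `PipelineConfig`
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    voxel_p = 0.001, cluster_alpha = 0.05, test_fraction = 0.1,
    cv_folds = 10L, n_perm = 1000L, n_perm_classify = 1000L,
    bonferroni_alpha = 0.05, ds_fraction = 0.5, smooth_fwhm = 8,
    seed = 1L, n_background = 50L, n_shap_samples = 200L,
    weight_scheme = "unit",
    classifier_families = c("svm_linear", "svm_rbf", "random_forest",
                            "logistic", "decision_tree", "xgboost"),
    n_regions = 118L, n_genes = 200L, n_coupled = 8L,
    coupling_strength = 0.8, n_donors = 6L,
    selection_mode = "pooled",
    cohort = list())
  over <- list(...)
  bad <- setdiff(names(over), pipelineConfigKeys)
  if (length(bad))
    stop("unknown pipeline config key(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  if (!cfg$selection_mode %in% c("pooled", "trainonly"))
    stop("'selection_mode' must be \"pooled\" or \"trainonly\"")
  structure(cfg, class = "PipelineConfig")
}

#' @rdname pipelineConfig
#' @param path JSON file
#' @export
writePipelineConfig <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pipelineConfig
#' @param cfg a `PipelineConfig`
#' @export
readPipelineConfig <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipelineConfig, raw)
}

#' Deterministic synthetic parcellation of a grid
#'
#' Voronoi parcellation: `nRegions` seed voxels are drawn uniformly at
#' random (seeded) and every voxel joins its nearest seed, yielding a
#' labeled atlas volume for region-level analyses on synthetic data.
#'
#' @param shape integer(3) grid
#' @param nRegions number of parcels
#' @param seed integer seed
#' @return integer 3-D array of labels 1..nRegions
#' @export
syntheticAtlas <- function(shape, nRegions, seed = 1L) {
  set.seed(seed)
  nvox <- prod(shape)
  stopifnot(nRegions >= 1, nRegions <= nvox)
  seeds <- arrayInd(sample.int(nvox, nRegions), shape)
  co <- arrayInd(seq_len(nvox), shape)
  lab <- integer(nvox)
  # nearest seed by squared Euclidean distance in voxel units
  d2min <- rep(Inf, nvox)
  for (k in seq_len(nRegions)) {
    d2 <- (co[, 1] - seeds[k, 1])^2 + (co[, 2] - seeds[k, 2])^2 +
      (co[, 3] - seeds[k, 3])^2
    upd <- d2 < d2min
    lab[upd] <- k
    d2min[upd] <- d2[upd]
  }
  array(lab, shape)
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Chains every stage on a simulated cohort: cohort generation, the
#' voxelwise GLM with permutation cluster-extent FWE, feature
#' extraction from the FWE-significant clusters, benchmarking of the
#' configured classifier families, Monte-Carlo Shapley attribution of
#' the best model, VICI construction with its group-difference map,
#' abnormality coupling and clinical correlations, and the
#' imaging-transcriptomic gene association on a synthetic multi-donor
#' expression array coupled to the observed regional abnormality. With
#' `selection_mode = "trainonly"` the feature-selecting VBM contrast is
#' computed on the training subjects only (no selection leakage); the
#' default `"pooled"` mode selects on all subjects, replicating the
#' common but leaky protocol.
#'
#' @param cfg a [pipelineConfig()]
#' @param outDir optional directory; when given, volumes and tables are
#'   written as NIfTI/TSV/JSON artifacts with a provenance manifest
#' @param verbose log stage progress to stderr
#' @return list with the per-stage results
#' @export
runPipeline <- function(cfg = pipelineConfig(), outDir = NULL,
                        verbose = TRUE) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  say <- function(...) if (verbose) message("[vicindex] ", ...)
  t0 <- Sys.time()

  say("simulating cohort")
  cohortArgs <- cfg$cohort
  cohortArgs$smoothFwhmMm <- cfg$smooth_fwhm
  cohortArgs$seed <- deriveSeed(cfg$seed, 1L)
  cohort <- simulateCohort(do.call(cohortConfig, cohortArgs))
  stack <- cohortVolumes(cohort)
  subjects <- cohortSubjects(cohort)

  say("voxelwise GLM + permutation cluster FWE (nPerm=", cfg$n_perm, ")")
  selIdx <- seq_len(nrow(subjects))
  if (cfg$selection_mode == "trainonly") {
    # features must be selected without the held-out subjects
    fmAll <- extractFeatures(stack, array(TRUE, gridDim(stack)), subjects)
    spPre <- splitTrainTest(fmAll, cfg$test_fraction,
                            seed = deriveSeed(cfg$seed, 3L))
    selIdx <- setdiff(seq_len(nrow(subjects)), spPre$testIdx)
  }
  selStack <- new("GmvStack",
                  data = stack@data[selIdx, , , , drop = FALSE],
                  affine = stack@affine,
                  subjectIds = stack@subjectIds[selIdx])
  vbm <- clusterFwe(selStack, subjects[selIdx, , drop = FALSE],
                    voxelP = cfg$voxel_p, nPerm = cfg$n_perm,
                    seed = deriveSeed(cfg$seed, 2L),
                    clusterAlpha = cfg$cluster_alpha)
  if (!any(vbm$significantMask))
    stop("no FWE-significant cluster; nothing to classify")
  say(sum(vbm$clusters$significant), " significant cluster(s), ",
      sum(vbm$significantMask), " feature voxels")

  fm <- extractFeatures(stack, vbm$significantMask, subjects)
  say("benchmarking ", length(cfg$classifier_families), " classifiers")
  specs <- lapply(cfg$classifier_families, classifierSpec,
                  seed = deriveSeed(cfg$seed, 4L))
  bench <- benchmarkClassifiers(fm, specs, seed = cfg$seed,
                                testFraction = cfg$test_fraction,
                                folds = cfg$cv_folds,
                                nPerm = cfg$n_perm_classify)
  bestFamily <- bench$table$classifier[1L]
  bestFit <- bench$fits[[bestFamily]]
  say("best family: ", bestFamily)

  say("Shapley attribution (", cfg$n_shap_samples, " samples/subject)")
  bg <- backgroundSample(bench$split$train, cfg$n_background,
                         seed = deriveSeed(cfg$seed, 6L))
  attr <- shapleyMonteCarlo(modelFunction(bestFit), fm, bg,
                            nSamples = cfg$n_shap_samples,
                            seed = deriveSeed(cfg$seed, 8L))

  say("VICI construction and group map")
  vici <- computeVici(attr, fm, scheme = cfg$weight_scheme)
  viciMap <- viciGroupMap(vici, subjects, voxelP = cfg$voxel_p,
                          nPerm = cfg$n_perm,
                          seed = deriveSeed(cfg$seed, 9L),
                          clusterAlpha = cfg$cluster_alpha)
  coupling <- abnormalityCoupling(viciMap$map, vbm$map)
  clinical <- viciClinical(vici, subjects)

  say("imaging-transcriptomic association")
  atlas <- syntheticAtlas(gridDim(stack), cfg$n_regions,
                          seed = deriveSeed(cfg$seed, 10L))
  regT <- regionalAggregate(viciMap$map, atlas)
  regT$regionName <- sprintf("region%03d", regT$region)
  signal <- regT$mean_t
  signal[is.na(signal)] <- 0
  excfg <- expressionConfig(nDonors = cfg$n_donors,
                            nRegions = cfg$n_regions,
                            nGenes = cfg$n_genes,
                            nCoupled = cfg$n_coupled,
                            couplingStrength = cfg$coupling_strength,
                            seed = deriveSeed(cfg$seed, 12L))
  expr <- simulateExpression(excfg, signal)
  exprN <- normalizeExpression(expr)
  exprF <- filterByStability(exprN, cfg$ds_fraction)
  riskGenes <- geneNames(expr)[seq_len(min(34L, length(geneNames(expr))))]
  tvec <- regT$mean_t
  names(tvec) <- regT$regionName
  genes <- suppressWarnings(
    geneViciAssociation(tvec, exprF, riskGenes,
                        alpha = cfg$bonferroni_alpha))

  res <- list(config = cfg, cohort = cohort, vbm = vbm, features = fm,
              benchmark = bench, attributions = attr, vici = vici,
              viciMap = viciMap, coupling = coupling,
              clinical = clinical, atlas = atlas, regionalT = regT,
              expression = exprF, genes = genes,
              elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  if (!is.null(outDir)) {
    say("writing artifacts to ", outDir)
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeCohort(cohort, file.path(outDir, "cohort"))
    writeStatMap(vbm$map, file.path(outDir, "gmv"))
    writeClusterTable(vbm$clusters, file.path(outDir, "gmv_clusters.tsv"))
    utils::write.table(bench$table, file.path(outDir, "classifiers.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeStatMap(viciMap$map, file.path(outDir, "vici"))
    writeClusterTable(viciMap$clusters,
                      file.path(outDir, "vici_clusters.tsv"))
    utils::write.table(clinical, file.path(outDir, "vici_clinical.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(genes, file.path(outDir, "gene_association.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- list(
      config = unclass(cfg),
      seeds = lapply(stats::setNames(c(1:12), paste0("stage", 1:12)),
                     function(s) deriveSeed(cfg$seed, s)),
      r_version = as.character(getRversion()),
      package_version = as.character(utils::packageVersion("vicindex")))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}
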