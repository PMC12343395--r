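writeVolumeNifti <- function(vol, affine, path) {
  img <- RNifti::asNifti(vol)
  vox <- sqrt(colSums(affine[1:3, 1:3]^2))
  RNifti::pixdim(img) <- vox
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

readVolumeNifti <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = dim(aff))
  list(data = array(as.vector(img), dim(img)), affine = aff)
}

#' Read a stack of NIfTI volumes
#'
#' All files must share grid shape and affine; a mismatch errors with
#' the offending file named.
#'
#' @param paths NIfTI-1 file paths, one per subject
#' @param subjectIds subject ids (default file basenames)
#' @return a [GmvStack-class]
#' @export
readVolumes <- function(paths, subjectIds = NULL) {
  if (!length(paths)) stop("no volume files given")
  first <- readVolumeNifti(paths[1L])
  d <- dim(first$data)
  dat <- array(0, c(length(paths), d))
  dat[1L, , , ] <- first$data
  if (length(paths) > 1L) for (i in 2L:length(paths)) {
    v <- readVolumeNifti(paths[i])
    if (!identical(dim(v$data), d))
      stop("volume shape mismatch in file: ", paths[i])
    if (max(abs(v$affine - first$affine)) > 1e-4)
      stop("affine mismatch in file: ", paths[i])
    dat[i, , , ] <- v$data
  }
  if (is.null(subjectIds))
    subjectIds <- sub("\\.nii(\\.gz)?$", "", basename(paths))
  gmvStack(dat, affine = first$affine, subjectIds = subjectIds)
}

#' Write a stack of NIfTI volumes
#' @param stack a [GmvStack-class]
#' @param dir output directory (created if needed)
#' @return invisibly, the written paths
#' @export
writeVolumes <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(subjectIds(stack), ".nii.gz"))
  for (i in seq_len(nSubjects(stack)))
    writeVolumeNifti(subjectVolume(stack, i), stack@affine, paths[i])
  invisible(paths)
}

#' Read a subject table from TSV
#'
#' Expects columns id, group, age, tiv, caps, mmse, moca, gds; empty
#' cells parse as missing (NA), never as 0. Group levels keep their
#' order of first appearance.
#'
#' @param path TSV file
#' @return data.frame
#' @export
readSubjects <- function(path) {
  df <- utils::read.delim(path, sep = "\t", na.strings = c("", "NA"),
                          stringsAsFactors = FALSE)
  need <- c("id", "group", "age", "tiv", "caps", "mmse", "moca", "gds")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("subjects table ", path, " lacks columns: ",
         paste(miss, collapse = ", "))
  df$id <- as.character(df$id)
  df$group <- factor(df$group, levels = unique(df$group))
  for (cl in c("age", "tiv", "caps", "mmse", "moca", "gds"))
    df[[cl]] <- as.numeric(df[[cl]])
  df
}

#' Write a subject table to TSV
#' @param subjects data.frame
#' @param path output TSV
#' @export
writeSubjects <- function(subjects, path) {
  utils::write.table(subjects, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Write a StatMap to disk
#'
#' Emits `<prefix>_t.nii.gz`, `<prefix>_p.nii.gz`,
#' `<prefix>_mask.nii.gz` and `<prefix>_meta.json` (df).
#'
#' @param map a [StatMap-class]
#' @param prefix file path prefix
#' @export
writeStatMap <- function(map, prefix) {
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  writeVolumeNifti(map@t, map@affine, paste0(prefix, "_t.nii.gz"))
  writeVolumeNifti(map@pUnc, map@affine, paste0(prefix, "_p.nii.gz"))
  writeVolumeNifti(array(as.numeric(map@mask), dim(map@mask)),
                   map@affine, paste0(prefix, "_mask.nii.gz"))
  jsonlite::write_json(list(df = map@df), paste0(prefix, "_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Read a StatMap written by [writeStatMap()]
#' @param prefix file path prefix
#' @return a [StatMap-class]
#' @export
readStatMap <- function(prefix) {
  tv <- readVolumeNifti(paste0(prefix, "_t.nii.gz"))
  pv <- readVolumeNifti(paste0(prefix, "_p.nii.gz"))
  mk <- readVolumeNifti(paste0(prefix, "_mask.nii.gz"))
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  new("StatMap", t = tv$data, df = as.numeric(meta$df), pUnc = pv$data,
      mask = array(mk$data > 0.5, dim(mk$data)), affine = tv$affine)
}

#' Write a cluster table to TSV
#'
#' Columns: contrast, region_label, x, y, z, extent, peak_t, fwe_p.
#'
#' @param clusters cluster data.frame from [clusterFwe()]
#' @param path output TSV
#' @export
writeClusterTable <- function(clusters, path) {
  out <- data.frame(
    contrast = clusters$sign,
    region_label = if (is.null(clusters$region_label))
      rep(NA_character_, nrow(clusters)) else clusters$region_label,
    x = clusters$x, y = clusters$y, z = clusters$z,
    extent = clusters$extent, peak_t = clusters$peak_t,
    fwe_p = if (is.null(clusters$fwe_p)) rep(NA_real_, nrow(clusters))
            else clusters$fwe_p)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Write a synthetic cohort to a directory
#'
#' Emits one NIfTI volume per subject (shared affine), `subjects.tsv`,
#' `truth_mask.nii.gz` and `config.json`; the set round-trips through
#' [readCohort()].
#'
#' @param cohort a [SyntheticCohort-class]
#' @param dir output directory
#' @return invisibly, `dir`
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "SyntheticCohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeVolumes(cohort@volumes, file.path(dir, "volumes"))
  writeSubjects(cohort@subjects, file.path(dir, "subjects.tsv"))
  writeVolumeNifti(array(as.numeric(cohort@truthMask),
                         dim(cohort@truthMask)),
                   cohort@volumes@affine,
                   file.path(dir, "truth_mask.nii.gz"))
  jsonlite::write_json(cohort@config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a synthetic cohort written by [writeCohort()]
#' @param dir cohort directory
#' @return a [SyntheticCohort-class]
#' @export
readCohort <- function(dir) {
  subjects <- readSubjects(file.path(dir, "subjects.tsv"))
  paths <- file.path(dir, "volumes", paste0(subjects$id, ".nii.gz"))
  stack <- readVolumes(paths, subjectIds = subjects$id)
  tm <- readVolumeNifti(file.path(dir, "truth_mask.nii.gz"))
  config <- jsonlite::read_json(file.path(dir, "config.json"),
                                simplifyVector = TRUE)
  new("SyntheticCohort", volumes = stack, subjects = subjects,
      truthMask = array(tm$data > 0.5, dim(tm$data)),
      config = as.list(config))
}

#' Read a risk-gene list from a plain-text file
#'
#' One gene symbol per line; blank lines and lines starting with `#`
#' are skipped.
#'
#' @param path text file
#' @return character vector of gene symbols
#' @export
readRiskGenes <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  if (!length(x)) stop("no gene symbols found in ", path)
  if (anyDuplicated(x)) {
    warning("duplicate gene symbols collapsed")
    x <- unique(x)
  }
  x
}
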