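#' @importFrom utils read.delim read.csv write.table head
#' @importFrom Matrix readMM writeMM
NULL

.readTable <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    read.csv(path, header = TRUE, check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    read.delim(path, header = TRUE, check.names = FALSE, stringsAsFactors = FALSE)
  }
}

#' Read sample coordinates
#'
#' TSV or CSV with a header row; first column sample ids, remaining columns
#' numeric dimensions of the input space.
#'
#' @param path path to the coordinate table.
#' @return n x d numeric matrix with sample ids as rownames.
#' @export
readCoordinates <- function(path) {
  df <- .readTable(path)
  if (ncol(df) < 2L) stop("coordinate file needs a sample id column plus >= 1 dimension")
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("non-numeric or missing coordinate values in ", path)
  rownames(m) <- ids
  m
}

#' Read an activity matrix
#'
#' Either a Matrix Market sparse matrix with feature / sample id sidecar
#' files (10x convention; orientation fixed downstream against the
#' coordinate table), or a dense TSV/CSV with feature ids in the first
#' column and samples in the remaining columns.
#'
#' @param path path to a .mtx file or a dense TSV/CSV.
#' @param featuresPath,samplesPath sidecar files (one id per line) required
#'   for MTX input; defaults look for features.tsv / barcodes.tsv next to
#'   the matrix.
#' @return f x n (or transposed; see \code{\link{readInputs}}) matrix,
#'   sparse for MTX input.
#' @export
readActivity <- function(path, featuresPath = NULL, samplesPath = NULL) {
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    m <- methods::as(readMM(path), "CsparseMatrix")
    dir <- dirname(path)
    if (is.null(featuresPath)) featuresPath <- file.path(dir, "features.tsv")
    if (is.null(samplesPath)) samplesPath <- file.path(dir, "barcodes.tsv")
    if (!file.exists(featuresPath) || !file.exists(samplesPath)) {
      stop("MTX input needs feature and sample id sidecar files")
    }
    feat <- readLines(featuresPath)
    samp <- readLines(samplesPath)
    # 10x features.tsv may carry extra columns; ids are the first field
    feat <- vapply(strsplit(feat, "\t", fixed = TRUE), `[[`, character(1), 1L)
    samp <- vapply(strsplit(samp, "\t", fixed = TRUE), `[[`, character(1), 1L)
    if (nrow(m) == length(feat) && ncol(m) == length(samp)) {
      dimnames(m) <- list(feat, samp)
    } else if (nrow(m) == length(samp) && ncol(m) == length(feat)) {
      m <- Matrix::t(m)
      dimnames(m) <- list(feat, samp)
    } else {
      stop("sidecar id counts do not match the MTX dimensions")
    }
    m
  } else {
    df <- .readTable(path)
    ids <- as.character(df[[1L]])
    m <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    m
  }
}

#' Read and align coordinates and activity
#'
#' Aligns the activity matrix to the coordinate table by sample id
#' (intersection, in coordinate-file order), auto-detecting the orientation
#' of the activity matrix by matching the sample dimension. Negative
#' activity values are an error unless \code{rescaleActivity = TRUE}, in
#' which case every feature is min-max rescaled to [0, 1] (the convention
#' used for signed module scores).
#'
#' @param coordsPath coordinate table (see \code{\link{readCoordinates}}).
#' @param activityPath activity matrix (see \code{\link{readActivity}}).
#' @param featuresPath,samplesPath MTX sidecars, if applicable.
#' @param rescaleActivity min-max rescale each feature to [0, 1].
#' @return list with aligned \code{coords} (n x d) and \code{activity}
#'   (f x n).
#' @export
readInputs <- function(coordsPath, activityPath, featuresPath = NULL,
                       samplesPath = NULL, rescaleActivity = FALSE) {
  coords <- readCoordinates(coordsPath)
  act <- readActivity(activityPath, featuresPath, samplesPath)
  if (is.null(colnames(act)) || is.null(rownames(act))) {
    stop("activity matrix must carry feature and sample identifiers")
  }
  # orientation: samples must be columns; flip if ids match rows instead
  overlapCols <- length(intersect(colnames(act), rownames(coords)))
  overlapRows <- length(intersect(rownames(act), rownames(coords)))
  if (overlapRows > overlapCols) act <- Matrix::t(act)
  common <- intersect(rownames(coords), colnames(act))
  if (length(common) == 0L) stop("no sample ids shared between coordinates and activity")
  dropped <- (nrow(coords) - length(common)) + (ncol(act) - length(common))
  if (dropped > 0L) {
    warning(dropped, " sample(s) outside the id intersection dropped")
  }
  coords <- coords[common, , drop = FALSE]
  act <- act[, common, drop = FALSE]
  hasNeg <- if (is(act, "sparseMatrix")) any(act@x < 0) else any(act < 0)
  if (hasNeg) {
    if (!rescaleActivity) {
      stop("negative activity values; pass rescaleActivity = TRUE to min-max ",
           "rescale each feature to [0, 1]")
    }
    act <- rescaleFeatures(act)
  }
  list(coords = coords, activity = act)
}

#' Min-max rescale each feature to [0, 1]
#'
#' @param activity f x n matrix (dense or sparse; output is dense).
#' @return f x n matrix with every non-constant feature spanning [0, 1];
#'   constant features become all-zero.
#' @export
rescaleFeatures <- function(activity) {
  m <- as.matrix(activity)
  lo <- apply(m, 1L, min)
  hi <- apply(m, 1L, max)
  span <- hi - lo
  span[span == 0] <- 1
  out <- (m - lo) / span
  out[hi == lo, ] <- 0
  out
}

#' Write a result table to TSV
#'
#' Columns feature_id, D_KL, log10_pval, log10_pval_adj, rank, flag, sorted
#' by rank (flagged NA-rank features last).
#'
#' @param result a \linkS4class{HaystackResult}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeHaystackResult <- function(result, path) {
  stopifnot(is(result, "HaystackResult"))
  df <- as.data.frame(result@table)
  df <- df[order(df$rank, na.last = TRUE), , drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic dataset to disk
#'
#' Writes coords.tsv, matrix.mtx with features.tsv / barcodes.tsv sidecars,
#' and truth.tsv into a directory, the on-disk layout the readers expect.
#'
#' @param sim a list from \code{\link{simulateHaystack}}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeSyntheticDataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  coordsDf <- data.frame(sample_id = rownames(sim$coords), sim$coords,
                         check.names = FALSE)
  write.table(coordsDf, file.path(dir, "coords.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  act <- sim$activity
  if (!is(act, "sparseMatrix")) act <- methods::as(act, "CsparseMatrix")
  writeMM(act, file.path(dir, "matrix.mtx"))
  writeLines(rownames(act), file.path(dir, "features.tsv"))
  writeLines(colnames(act), file.path(dir, "barcodes.tsv"))
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
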