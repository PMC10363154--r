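#' Differential-activity scan, end to end
#'
#' Runs the full pipeline: coordinate standardization, grid point selection,
#' bandwidth and density estimation, reference distribution Q, per-feature
#' activity distributions P_f and their Kullback-Leibler divergences from Q,
#' a CV-stratified permutation null, cross-validated spline calibration, and
#' log-space p-values.
#'
#' The coordinates can be any input space: 1D pseudotime, 2-3D spatial
#' coordinates, or a latent embedding of any dimension. The activity matrix
#' holds non-negative values (counts, normalized expression, accessibility,
#' module scores) with features in rows and samples in columns; a
#' SummarizedExperiment / SingleCellExperiment can be passed instead, in
#' which case an assay (and, for coordinates, a reducedDim name) is
#' extracted.
#'
#' @param coords n x d numeric matrix of sample coordinates (rownames =
#'   sample ids), or the name of a reducedDim when \code{activity} is a
#'   SingleCellExperiment.
#' @param activity f x n non-negative matrix (dense or sparse), or a
#'   SummarizedExperiment-like object.
#' @param g number of grid points (default 100).
#' @param gridMethod "kmeans" (default), "seeding" or "user".
#' @param gridCoords user grid coordinates for \code{gridMethod = "user"}.
#' @param scaleCoords standardize each coordinate dimension to mean 0, sd 1
#'   (default TRUE).
#' @param splineType "ns" (natural cubic splines, default) or "bs"
#'   (B-splines) for the null-model curves.
#' @param nRef number of CV-spanning reference features (default 100).
#' @param nPerm permutations per reference feature (default 100).
#' @param seed master RNG seed; every stochastic stage (grid k-means,
#'   permutations, CV folds) derives its stream from it, so identical seeds
#'   give byte-identical results.
#' @param assay assay name or index used when \code{activity} is a
#'   SummarizedExperiment (default first assay).
#' @param keepPf keep the f x g matrix of P_f profiles in the result
#'   (needed for \code{\link{clusterTopFeatures}}; default TRUE).
#' @param verbose print stage progress.
#' @return a \linkS4class{HaystackResult}.
#' @examples
#' sim <- simulateHaystack(n = 200, d = 2, nPlanted = 10, nNull = 60, seed = 1)
#' res <- runHaystack(sim$coords, sim$activity, g = 30, nRef = 30,
#'                    nPerm = 50, seed = 1)
#' topFeatures(res, 5)
#' @export
runHaystack <- function(coords, activity, g = 100L,
                        gridMethod = c("kmeans", "seeding", "user"),
                        gridCoords = NULL, scaleCoords = TRUE,
                        splineType = c("ns", "bs"),
                        nRef = 100L, nPerm = 100L, seed = 42L,
                        assay = 1L, keepPf = TRUE, verbose = FALSE) {
  gridMethod <- match.arg(gridMethod)
  splineType <- match.arg(splineType)
  seed <- as.integer(seed)

  if (methods::is(activity, "SummarizedExperiment")) {
    if (!requireNamespace("SummarizedExperiment", quietly = TRUE)) {
      stop("the SummarizedExperiment package is needed for this input type")
    }
    se <- activity
    activity <- SummarizedExperiment::assay(se, assay)
    if (is.character(coords) && length(coords) == 1L &&
        requireNamespace("SingleCellExperiment", quietly = TRUE) &&
        methods::is(se, "SingleCellExperiment")) {
      coords <- SingleCellExperiment::reducedDim(se, coords)
    }
  }
  coords <- .asCoordMatrix(coords)
  activity <- .asActivity(activity)
  if (ncol(activity) != nrow(coords)) {
    stop("grid stage: activity columns (samples) must match coordinate rows; ",
         "use readInputs() for id-based alignment")
  }
  say <- function(...) if (verbose) message(...)

  say("grid: ", g, " points (", gridMethod, "), scale = ", scaleCoords)
  grid <- buildGrid(coords, g = g, method = gridMethod,
                    userCoords = gridCoords, scale = scaleCoords, seed = seed)
  say("bandwidth h = ", format(grid@bandwidth, digits = 4))

  say("divergence: ", nrow(activity), " features")
  kl <- computeAllDKL(grid@density, activity, keepPf = keepPf)

  say("null model: ", nRef, " reference features x ", nPerm, " permutations")
  cv <- computeCV(activity)
  refIdx <- selectReferenceFeatures(cv, m = nRef)
  refReps <- t(vapply(seq_along(refIdx), function(k) {
    y <- as.numeric(activity[refIdx[k], ])
    randomizeDKL(grid@density, y, nPerm = nPerm, seed = seed + k)
  }, numeric(as.integer(nPerm))))
  nullModel <- fitNullModel(log(cv[refIdx]), refReps, splineType = splineType,
                            seed = seed,
                            refFeatures = rownames(activity)[refIdx])
  say("spline df: mean = ", nullModel@dfMean, ", sd = ", nullModel@dfSd)

  tab <- predictPvalues(nullModel, cv, kl$DKL,
                        featureIds = rownames(activity))
  res <- methods::new("HaystackResult",
    table = tab, grid = grid, nullModel = nullModel,
    Pf = if (keepPf) kl$Pf else NULL,
    metadata = list(
      seed = seed, g = nrow(grid@gridCoords), bandwidth = grid@bandwidth,
      gridMethod = gridMethod, splineType = splineType,
      dfMean = nullModel@dfMean, dfSd = nullModel@dfSd,
      nRef = length(refIdx), nPerm = as.integer(nPerm),
      nFlagged = table(tab$flag)
    ))
  say("flags: ", sum(tab$flag == "ok"), " ok / ",
      sum(tab$flag != "ok"), " flagged")
  res
}

#' End-to-end run from files
#'
#' File-based front end: reads and aligns a coordinate table and an activity
#' matrix, runs \code{\link{runHaystack}}, writes the result TSV and a small
#' run log (seed, grid size, bandwidth, selected spline flexibility, flag
#' counts).
#'
#' @inheritParams runHaystack
#' @inheritParams readInputs
#' @param outPath output TSV for the result table.
#' @param logPath optional run-log path (default \code{outPath} with a
#'   ".log" suffix).
#' @param ... further arguments to \code{\link{runHaystack}}.
#' @return the \linkS4class{HaystackResult}, invisibly.
#' @export
runHaystackFiles <- function(coordsPath, activityPath, outPath,
                             featuresPath = NULL, samplesPath = NULL,
                             rescaleActivity = FALSE, logPath = NULL, ...) {
  inp <- readInputs(coordsPath, activityPath, featuresPath, samplesPath,
                    rescaleActivity = rescaleActivity)
  res <- runHaystack(inp$coords, inp$activity, ...)
  writeHaystackResult(res, outPath)
  if (is.null(logPath)) logPath <- paste0(outPath, ".log")
  md <- res@metadata
  writeLines(c(
    paste0("seed\t", md$seed),
    paste0("grid_points\t", md$g),
    paste0("bandwidth\t", format(md$bandwidth, digits = 10)),
    paste0("spline_df_mean\t", md$dfMean),
    paste0("spline_df_sd\t", md$dfSd),
    paste0("n_ok\t", sum(res@table$flag == "ok")),
    paste0("n_all_zero\t", sum(res@table$flag == "all_zero")),
    paste0("n_zero_cv\t", sum(res@table$flag == "zero_cv"))
  ), logPath)
  invisible(res)
}
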