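#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' Grid model: geometry of the input space
#'
#' Holds the scaffolding on which densities are evaluated: the grid point
#' coordinates, the Gaussian kernel bandwidth, the sample-to-grid density
#' contribution matrix and the normalized reference distribution Q.
#'
#' @slot gridCoords g x d matrix of grid point coordinates, in the same
#'   (typically standardized) space as the sample coordinates.
#' @slot bandwidth positive scalar; median Euclidean distance from samples to
#'   their nearest grid point.
#' @slot density n x g matrix of density contributions
#'   \eqn{d_{ij} = \exp(-(\|s_i - g_j\|/h)^2 / 2)}; all entries in (0, 1].
#' @slot Q length-g reference distribution; strictly positive, sums to 1.
#' @slot scaled whether the sample coordinates were standardized before grid
#'   construction.
#'
#' @export
setClass("HaystackGrid",
  representation(
    gridCoords = "matrix",
    bandwidth  = "numeric",
    density    = "matrix",
    Q          = "numeric",
    scaled     = "logical"
  )
)

setValidity("HaystackGrid", function(object) {
  msg <- character()
  g <- nrow(object@gridCoords)
  if (g < 2L) msg <- c(msg, "need at least 2 grid points")
  if (length(object@bandwidth) != 1L || !is.finite(object@bandwidth) ||
      object@bandwidth <= 0) {
    msg <- c(msg, "bandwidth must be a single positive number")
  }
  if (ncol(object@density) != g) {
    msg <- c(msg, "density must have one column per grid point")
  }
  if (any(object@density <= 0) || any(object@density > 1 + 1e-12)) {
    msg <- c(msg, "density contributions must lie in (0, 1]")
  }
  if (length(object@Q) != g) msg <- c(msg, "Q must have one entry per grid point")
  if (abs(sum(object@Q) - 1) > 1e-12) msg <- c(msg, "Q must sum to 1")
  if (any(object@Q <= 0)) msg <- c(msg, "all Q entries must be positive")
  if (length(msg)) msg else TRUE
})

#' Permutation null model for log divergences
#'
#' Summarises, for a CV-spanning panel of reference features, the mean and
#' standard deviation of log D_KL under random permutation of activities, and
#' carries the two cross-validated spline regressions that predict those
#' moments from log CV for any feature.
#'
#' @slot refFeatures identifiers of the reference features used.
#' @slot refLogCV log coefficient of variation of each reference feature.
#' @slot refMeanLogDKL per-reference-feature mean of log D_KL over permutations.
#' @slot refSdLogDKL per-reference-feature sd of log D_KL over permutations.
#' @slot splineType "ns" (natural cubic) or "bs" (B-spline).
#' @slot dfMean,dfSd degrees of freedom selected by tenfold cross-validation
#'   for the mean and sd curves.
#' @slot degreeMean,degreeSd polynomial degree (B-splines only; 3 for ns).
#' @slot fitMean,fitSd fitted \code{lm} objects mapping log CV to the
#'   predicted mean / sd of log D_KL under the null.
#' @slot cvSpan range of reference log CV values; predictions outside this
#'   span are clamped to its boundary.
#' @slot nPermutations permutations drawn per reference feature.
#' @slot seed RNG seed the permutations and fold assignment derive from.
#'
#' @export
setClass("HaystackNull",
  representation(
    refFeatures   = "character",
    refLogCV      = "numeric",
    refMeanLogDKL = "numeric",
    refSdLogDKL   = "numeric",
    splineType    = "character",
    dfMean        = "integer",
    dfSd          = "integer",
    degreeMean    = "integer",
    degreeSd      = "integer",
    fitMean       = "ANY",
    fitSd         = "ANY",
    cvSpan        = "numeric",
    nPermutations = "integer",
    seed          = "integer"
  )
)

setValidity("HaystackNull", function(object) {
  msg <- character()
  m <- length(object@refFeatures)
  if (length(object@refLogCV) != m || length(object@refMeanLogDKL) != m ||
      length(object@refSdLogDKL) != m) {
    msg <- c(msg, "reference statistic vectors must have one entry per reference feature")
  }
  if (any(object@refSdLogDKL <= 0)) {
    msg <- c(msg, "reference sd of log D_KL must be positive (after flooring)")
  }
  if (!object@splineType %in% c("ns", "bs")) {
    msg <- c(msg, "splineType must be 'ns' or 'bs'")
  }
  if (object@dfMean < 1L || object@dfMean > 10L ||
      object@dfSd < 1L || object@dfSd > 10L) {
    msg <- c(msg, "selected degrees of freedom must lie in 1..10")
  }
  if (length(object@cvSpan) != 2L || object@cvSpan[1] > object@cvSpan[2]) {
    msg <- c(msg, "cvSpan must be an increasing length-2 range")
  }
  if (length(msg)) msg else TRUE
})

#' Result of a differential-activity scan
#'
#' Per-feature Kullback-Leibler divergences, log10 p-values (raw and
#' Benjamini-Hochberg adjusted), significance ranks and QC flags, together
#' with the grid and null models that produced them and (optionally) the
#' normalized activity distributions P_f over grid points.
#'
#' @slot table a \link[S4Vectors]{DataFrame} with columns \code{feature_id},
#'   \code{D_KL}, \code{log10_pval}, \code{log10_pval_adj}, \code{rank} and
#'   \code{flag} ("ok", "all_zero" or "zero_cv"), in input feature order.
#' @slot grid the \linkS4class{HaystackGrid} used.
#' @slot nullModel the fitted \linkS4class{HaystackNull}.
#' @slot Pf optional f x g matrix of per-feature activity distributions over
#'   grid points (NULL when not kept).
#' @slot metadata list of run provenance: seed, g, bandwidth, spline degrees
#'   of freedom, flag counts.
#'
#' @export
setClass("HaystackResult",
  representation(
    table     = "DataFrame",
    grid      = "HaystackGrid",
    nullModel = "HaystackNull",
    Pf        = "ANY",
    metadata  = "list"
  )
)

setValidity("HaystackResult", function(object) {
  msg <- character()
  need <- c("feature_id", "D_KL", "log10_pval", "log10_pval_adj", "rank", "flag")
  if (!all(need %in% colnames(object@table))) {
    msg <- c(msg, paste("table must have columns:", paste(need, collapse = ", ")))
  } else {
    ok <- object@table$flag == "ok"
    rk <- object@table$rank[ok]
    if (length(rk) && !identical(sort(rk), seq_along(rk))) {
      msg <- c(msg, "ranks of ok-flagged features must be a permutation of 1..n_ok")
    }
    lp <- object@table$log10_pval
    la <- object@table$log10_pval_adj
    bad <- !is.na(lp) & !is.na(la) & la < lp - 1e-9
    if (any(bad)) msg <- c(msg, "adjusted log10 p-values must not be smaller than raw ones")
  }
  if (length(msg)) msg else TRUE
})

#' Module assignment of top-ranked features
#'
#' Labels from clustering the activity distributions of top-ranked features
#' into expression modules, plus the per-module mean profile over grid points.
#'
#' @slot features identifiers of the clustered (top-ranked) features.
#' @slot labels integer module label per feature.
#' @slot centers k x g matrix of module mean profiles.
#' @slot method "kmeans" or "hclust".
#' @slot order for hclust, the dendrogram leaf order; otherwise seq_along.
#'
#' @export
setClass("HaystackModules",
  representation(
    features = "character",
    labels   = "integer",
    centers  = "matrix",
    method   = "character",
    order    = "integer"
  )
)

setValidity("HaystackModules", function(object) {
  msg <- character()
  if (length(object@labels) != length(object@features)) {
    msg <- c(msg, "one module label per feature required")
  }
  if (length(unique(object@labels)) != nrow(object@centers)) {
    msg <- c(msg, "centers must have one row per module")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "HaystackGrid", function(object) {
  cat("HaystackGrid:", nrow(object@gridCoords), "grid points in",
      ncol(object@gridCoords), "dimension(s)\n")
  cat("  bandwidth h =", format(object@bandwidth, digits = 4),
      "| samples:", nrow(object@density),
      "| coordinates standardized:", object@scaled, "\n")
})

setMethod("show", "HaystackNull", function(object) {
  cat("HaystackNull:", length(object@refFeatures), "reference features,",
      object@nPermutations, "permutations each\n")
  cat("  spline:", object@splineType,
      "| df(mean) =", object@dfMean, "| df(sd) =", object@dfSd)
  if (object@splineType == "bs") {
    cat(" | degree(mean) =", object@degreeMean,
        "| degree(sd) =", object@degreeSd)
  }
  cat("\n  log CV span: [", format(object@cvSpan[1], digits = 3), ",",
      format(object@cvSpan[2], digits = 3), "]\n")
})

setMethod("show", "HaystackResult", function(object) {
  tab <- object@table
  cat("HaystackResult:", nrow(tab), "features (",
      sum(tab$flag == "ok"), "ok,",
      sum(tab$flag == "all_zero"), "all-zero,",
      sum(tab$flag == "zero_cv"), "zero-CV )\n")
  top <- head(tab[order(tab$rank), , drop = FALSE], 5L)
  cat("Top features by significance:\n")
  show(top)
})

setMethod("show", "HaystackModules", function(object) {
  cat("HaystackModules:", length(object@features), "features in",
      nrow(object@centers), "modules (", object@method, ")\n")
  print(table(module = object@labels))
})
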