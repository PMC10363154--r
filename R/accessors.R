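#' Accessors for kldHaystack objects
#'
#' Small generics for extracting the parts of a \linkS4class{HaystackGrid},
#' \linkS4class{HaystackNull}, \linkS4class{HaystackResult} or
#' \linkS4class{HaystackModules} without touching slots directly.
#'
#' @param object a kldHaystack S4 object.
#' @return \code{gridCoords}: the g x d grid coordinate matrix.
#'   \code{bandwidth}: the kernel bandwidth h. \code{densityMatrix}: the
#'   n x g density-contribution matrix. \code{refDistribution}: the length-g
#'   reference distribution Q. \code{resultTable}: the per-feature result
#'   \link[S4Vectors]{DataFrame}. \code{featureDistributions}: the f x g
#'   matrix of P_f profiles (or NULL). \code{moduleLabels}: named integer
#'   module labels. \code{moduleProfiles}: the k x g module mean profiles.
#'
#' @name accessors
#' @aliases gridCoords bandwidth densityMatrix refDistribution resultTable
#'   featureDistributions moduleLabels moduleProfiles
#' @examples
#' sim <- simulateHaystack(n = 120, d = 2, nPlanted = 5, nNull = 20, seed = 1)
#' grid <- buildGrid(sim$coords, g = 20, seed = 1)
#' dim(densityMatrix(grid))
#' sum(refDistribution(grid))
NULL

#' @rdname accessors
#' @export
setGeneric("gridCoords", function(object) standardGeneric("gridCoords"))

#' @rdname accessors
#' @export
setGeneric("bandwidth", function(object) standardGeneric("bandwidth"))

#' @rdname accessors
#' @export
setGeneric("densityMatrix", function(object) standardGeneric("densityMatrix"))

#' @rdname accessors
#' @export
setGeneric("refDistribution", function(object) standardGeneric("refDistribution"))

#' @rdname accessors
#' @export
setGeneric("resultTable", function(object) standardGeneric("resultTable"))

#' @rdname accessors
#' @export
setGeneric("featureDistributions", function(object) standardGeneric("featureDistributions"))

#' @rdname accessors
#' @export
setGeneric("moduleLabels", function(object) standardGeneric("moduleLabels"))

#' @rdname accessors
#' @export
setGeneric("moduleProfiles", function(object) standardGeneric("moduleProfiles"))

#' @rdname accessors
setMethod("gridCoords", "HaystackGrid", function(object) object@gridCoords)

#' @rdname accessors
setMethod("bandwidth", "HaystackGrid", function(object) object@bandwidth)

#' @rdname accessors
setMethod("densityMatrix", "HaystackGrid", function(object) object@density)

#' @rdname accessors
setMethod("refDistribution", "HaystackGrid", function(object) object@Q)

#' @rdname accessors
setMethod("resultTable", "HaystackResult", function(object) object@table)

#' @rdname accessors
setMethod("featureDistributions", "HaystackResult", function(object) object@Pf)

#' @rdname accessors
setMethod("moduleLabels", "HaystackModules", function(object) {
  stats::setNames(object@labels, object@features)
})

#' @rdname accessors
setMethod("moduleProfiles", "HaystackModules", function(object) object@centers)

#' Top-ranked features of a scan
#'
#' @param object a \linkS4class{HaystackResult}.
#' @param n how many features to return.
#' @return a \link[S4Vectors]{DataFrame} with the \code{n} most significant
#'   features, sorted by rank.
#' @examples
#' sim <- simulateHaystack(n = 150, d = 2, nPlanted = 5, nNull = 30, seed = 2)
#' res <- runHaystack(sim$coords, sim$activity, g = 20, nRef = 20,
#'                    nPerm = 50, seed = 2)
#' topFeatures(res, 5)
#' @export
topFeatures <- function(object, n = 10L) {
  stopifnot(is(object, "HaystackResult"))
  tab <- object@table
  tab <- tab[!is.na(tab$rank), , drop = FALSE]
  utils::head(tab[order(tab$rank), , drop = FALSE], n)
}
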