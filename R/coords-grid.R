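#' @importFrom stats kmeans median sd
NULL

# Squared Euclidean cross-distances between the rows of two matrices,
# clamped at zero to absorb catastrophic cancellation.
.crossDist2 <- function(a, b) {
  d2 <- outer(rowSums(a * a), rowSums(b * b), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

.asCoordMatrix <- function(coords) {
  if (is.data.frame(coords)) coords <- as.matrix(coords)
  if (!is.matrix(coords) || !is.numeric(coords)) {
    stop("coordinates must be a numeric matrix (samples x dimensions)")
  }
  if (anyNA(coords) || any(!is.finite(coords))) {
    stop("coordinates contain missing or non-finite values")
  }
  coords
}

#' Standardize sample coordinates
#'
#' Rescales each dimension of the input space to mean 0 and standard
#' deviation 1 (sample sd, n-1 denominator), so that dimensions with large
#' numeric ranges do not dominate Euclidean distances. Zero-variance columns
#' are centered and left at zero, with a warning, so column indices stay
#' stable.
#'
#' @param coords numeric n x d matrix (n >= 2), one row per sample.
#' @return n x d matrix of standardized coordinates, dimnames preserved.
#' @examples
#' scaleCoordinates(matrix(c(1, 3), ncol = 1))  # -> c(-1, 1)/sqrt(2)
#' @export
scaleCoordinates <- function(coords) {
  coords <- .asCoordMatrix(coords)
  if (nrow(coords) < 2L) stop("at least 2 samples are required to scale coordinates")
  ctr <- colMeans(coords)
  out <- sweep(coords, 2L, ctr, "-")
  s <- apply(out, 2L, sd)
  degenerate <- s == 0
  if (any(degenerate)) {
    warning(sum(degenerate), " zero-variance coordinate column(s) left at 0 after centering")
    s[degenerate] <- 1
  }
  sweep(out, 2L, s, "/")
}

# k-means++ seeding: probabilistic spread of g starting points, no Lloyd
# iterations. Squared-distance-proportional sampling after a uniform first
# pick.
.kmeansppSeed <- function(coords, g) {
  n <- nrow(coords)
  idx <- integer(g)
  idx[1L] <- sample.int(n, 1L)
  d2 <- .crossDist2(coords, coords[idx[1L], , drop = FALSE])[, 1L]
  for (k in seq_len(g - 1L)) {
    if (all(d2 == 0)) {
      idx[k + 1L] <- sample.int(n, 1L)
    } else {
      idx[k + 1L] <- sample.int(n, 1L, prob = d2)
    }
    dNew <- .crossDist2(coords, coords[idx[k + 1L], , drop = FALSE])[, 1L]
    d2 <- pmin(d2, dNew)
  }
  coords[idx, , drop = FALSE]
}

#' Choose grid points in the input space
#'
#' Places \code{g} grid points over the subspace occupied by the samples.
#' The default runs k-means on the sample coordinates and uses the centroids,
#' which spreads grid points roughly uniformly over occupied regions (the
#' clusters themselves are irrelevant; only the centroids are kept).
#' \code{method = "seeding"} uses the k-means++ seeding rule alone, and
#' \code{method = "user"} passes through user-supplied coordinates.
#'
#' @param coords numeric n x d matrix of (typically standardized) sample
#'   coordinates.
#' @param g number of grid points (>= 2); clamped to n with a warning when
#'   g > n.
#' @param method one of "kmeans", "seeding", "user".
#' @param userCoords g x d matrix of grid coordinates when
#'   \code{method = "user"}.
#' @param seed RNG seed making grid selection reproducible.
#' @param iterMax iteration cap for k-means.
#' @return g x d matrix of grid point coordinates.
#' @examples
#' xy <- matrix(rnorm(200), ncol = 2)
#' dim(selectGridPoints(xy, g = 10, seed = 1))
#' @export
selectGridPoints <- function(coords, g = 100L,
                             method = c("kmeans", "seeding", "user"),
                             userCoords = NULL, seed = 42L, iterMax = 100L) {
  coords <- .asCoordMatrix(coords)
  method <- match.arg(method)
  if (method == "user") {
    userCoords <- .asCoordMatrix(userCoords)
    if (ncol(userCoords) != ncol(coords)) {
      stop("user grid coordinates must have the same dimensionality as the samples")
    }
    if (nrow(userCoords) < 2L) stop("at least 2 grid points are required")
    return(userCoords)
  }
  g <- as.integer(g)
  if (g < 2L) stop("at least 2 grid points are required")
  n <- nrow(coords)
  if (g > n) {
    warning("requested ", g, " grid points for ", n, " samples; using g = ", n)
    g <- n
  }
  set.seed(as.integer(seed))
  if (method == "seeding") {
    return(.kmeansppSeed(coords, g))
  }
  if (g == n) {
    # k = n limit: every sample is its own centroid (kmeans rejects k = n)
    return(unname(coords))
  }
  km <- kmeans(coords, centers = g, iter.max = iterMax, nstart = 1L)
  unname(km$centers)
}

#' Kernel bandwidth from nearest-grid distances
#'
#' The Gaussian kernel bandwidth h is the median, over samples, of the
#' Euclidean distance to the closest grid point. Distances between samples
#' and grid points are later normalized by h, making the density
#' contributions invariant to joint rescaling of the space.
#'
#' @param coords numeric n x d sample coordinates.
#' @param gridCoords g x d grid coordinates in the same space.
#' @return positive scalar bandwidth.
#' @examples
#' computeBandwidth(matrix(0:3, ncol = 1), matrix(c(0.5, 2.5), ncol = 1))
#' @export
computeBandwidth <- function(coords, gridCoords) {
  coords <- .asCoordMatrix(coords)
  gridCoords <- .asCoordMatrix(gridCoords)
  if (ncol(coords) != ncol(gridCoords)) {
    stop("sample and grid coordinates must have the same dimensionality")
  }
  nearest2 <- apply(.crossDist2(coords, gridCoords), 1L, min)
  h <- median(sqrt(nearest2))
  if (h == 0) {
    stop("degenerate geometry: median nearest-grid distance is 0 ",
         "(too many grid points or coincident samples); ",
         "reduce g or perturb the grid coordinates")
  }
  h
}

#' Sample-to-grid density contributions
#'
#' Evaluates the Gaussian kernel between every sample and every grid point:
#' \eqn{d_{ij} = \exp(-(\|s_i - g_j\| / h)^2 / 2)}. Entries are strictly
#' positive and reach 1 exactly when a sample coincides with a grid point,
#' so the downstream reference distribution never has empty bins.
#'
#' @param coords numeric n x d sample coordinates.
#' @param gridCoords g x d grid coordinates.
#' @param h positive kernel bandwidth (see \code{\link{computeBandwidth}}).
#' @return n x g matrix of density contributions.
#' @examples
#' computeDensity(matrix(0, 1, 1), matrix(c(0.5, 2.5), ncol = 1), h = 0.5)
#' @export
computeDensity <- function(coords, gridCoords, h) {
  coords <- .asCoordMatrix(coords)
  gridCoords <- .asCoordMatrix(gridCoords)
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0) {
    stop("bandwidth h must be a single positive number")
  }
  d2 <- .crossDist2(coords, gridCoords)
  dens <- exp(-d2 / (2 * h * h))
  # the kernel is strictly positive mathematically; restore that where the
  # tail underflows to exactly 0 in double precision
  pmax(dens, .Machine$double.xmin)
}

#' Build the full grid model
#'
#' Convenience constructor running coordinate standardization, grid point
#' selection, bandwidth estimation, density contributions and the reference
#' distribution Q in one call.
#'
#' @inheritParams selectGridPoints
#' @param scale standardize coordinates first (default TRUE).
#' @return a \linkS4class{HaystackGrid}.
#' @examples
#' xy <- matrix(rnorm(400), ncol = 2)
#' buildGrid(xy, g = 25, seed = 7)
#' @export
buildGrid <- function(coords, g = 100L, method = c("kmeans", "seeding", "user"),
                      userCoords = NULL, scale = TRUE, seed = 42L) {
  coords <- .asCoordMatrix(coords)
  if (scale) coords <- scaleCoordinates(coords)
  gp <- selectGridPoints(coords, g = g, method = method,
                         userCoords = userCoords, seed = seed)
  h <- computeBandwidth(coords, gp)
  dens <- computeDensity(coords, gp, h)
  rownames(dens) <- rownames(coords)
  new("HaystackGrid", gridCoords = gp, bandwidth = h, density = dens,
      Q = computeQ(dens), scaled = isTRUE(scale))
}
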