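#' @importFrom stats rnorm runif rpois rlnorm
NULL

#' Generate sample coordinates with known structure
#'
#' Emulates the three kinds of input spaces the method is used on:
#' \describe{
#'   \item{blobs}{a Gaussian mixture in d dimensions (cluster-structured
#'     latent spaces such as principal components); blob centers are drawn
#'     with a minimum separation so clusters are well separated, and the true
#'     blob label of each sample is attached as attribute \code{"labels"}.}
#'   \item{uniform}{a uniform hypercube (homogeneous tissue sections).}
#'   \item{trajectory}{sorted 1D pseudotime values in [0, 1] (d must be 1).}
#' }
#'
#' @param n number of samples (>= 10).
#' @param d dimensionality of the space.
#' @param structure "blobs", "uniform" or "trajectory".
#' @param nBlobs number of mixture components for "blobs".
#' @param blobSd within-blob standard deviation.
#' @param seed RNG seed; identical seeds reproduce coordinates exactly.
#' @return n x d numeric matrix with sample ids as rownames; for "blobs",
#'   integer attribute \code{"labels"} gives the generating component.
#' @examples
#' head(makeCoords(100, 2, "blobs", nBlobs = 4, seed = 1))
#' @export
makeCoords <- function(n, d = 2L, structure = c("blobs", "uniform", "trajectory"),
                       nBlobs = 5L, blobSd = 0.6, seed = 42L) {
  structure <- match.arg(structure)
  n <- as.integer(n)
  d <- as.integer(d)
  if (n < 10L) stop("at least 10 samples are required")
  if (structure == "trajectory" && d != 1L) {
    stop("trajectory coordinates are one-dimensional; set d = 1")
  }
  set.seed(as.integer(seed))
  coords <- switch(structure,
    uniform = matrix(runif(n * d), nrow = n, ncol = d),
    trajectory = matrix(sort(runif(n)), ncol = 1L),
    blobs = {
      centers <- matrix(runif(d, -4, 4), nrow = 1L)
      tries <- 0L
      while (nrow(centers) < nBlobs && tries < 1000L) {
        cand <- runif(d, -4, 4)
        d2 <- .crossDist2(matrix(cand, 1L), centers)
        if (min(d2) > (5 * blobSd)^2) centers <- rbind(centers, cand)
        tries <- tries + 1L
      }
      if (nrow(centers) < nBlobs) {
        stop("could not place ", nBlobs, " separated blob centers; ",
             "reduce nBlobs or blobSd")
      }
      lab <- sort(rep_len(seq_len(nBlobs), n))
      pts <- centers[lab, , drop = FALSE] +
        matrix(rnorm(n * d, sd = blobSd), nrow = n)
      attr(pts, "labels") <- lab
      attr(pts, "centers") <- centers
      pts
    })
  rownames(coords) <- sprintf("sample_%d", seq_len(n))
  colnames(coords) <- sprintf("dim_%d", seq_len(d))
  coords
}

#' Generate an activity matrix with planted differential features
#'
#' Planted features have an intensity surface
#' \eqn{\lambda_i = b + A \exp(-\|s_i - c\|^2 / (2 w^2))} centered on a
#' randomly chosen sample coordinate c (so effects are never in empty
#' space), with Poisson (UMI-like) or log-normal (normalized-expression-like)
#' noise. Null features use the same intensity construction but the surface
#' is permuted across samples before noise is drawn: their marginal level
#' distribution matches the planted features yet activity is exchangeable
#' across samples, i.e. independent of position.
#'
#' @param coords n x d sample coordinate matrix (e.g. from
#'   \code{\link{makeCoords}}).
#' @param nPlanted,nNull numbers of planted / null features.
#' @param amplitude peak intensity A of the planted bump above baseline.
#' @param width bump width w in coordinate units.
#' @param baseline baseline intensity b (> 0).
#' @param noise "poisson" or "lognormal".
#' @param sdlog log-normal noise sd (ignored for Poisson).
#' @param centers optional matrix of bump centers recycled over planted
#'   features (rows; d columns); default draws one center per feature from
#'   the sample coordinates.
#' @param sparse return a \link[Matrix]{dgCMatrix-class} (default) instead
#'   of a dense matrix.
#' @param seed RNG seed; identical seeds reproduce the matrix exactly.
#' @return list with \code{activity} (f x n matrix, planted features first),
#'   \code{truth} (data.frame: feature_id, label "planted"/"null", center
#'   columns, amplitude, width) and \code{seed}.
#' @examples
#' xy <- makeCoords(200, 2, "blobs", nBlobs = 4, seed = 3)
#' sim <- makeActivity(xy, nPlanted = 10, nNull = 50, seed = 3)
#' table(sim$truth$label)
#' @export
makeActivity <- function(coords, nPlanted = 100L, nNull = 1900L,
                         amplitude = 2, width = 1, baseline = 0.5,
                         noise = c("poisson", "lognormal"), sdlog = 0.4,
                         centers = NULL, sparse = TRUE, seed = 42L) {
  noise <- match.arg(noise)
  coords <- .asCoordMatrix(coords)
  if (amplitude < 0) stop("amplitude must be non-negative")
  if (width <= 0) stop("width must be positive")
  if (baseline <= 0) stop("baseline must be positive")
  n <- nrow(coords)
  f <- nPlanted + nNull
  set.seed(as.integer(seed))

  drawNoise <- function(lambda) {
    if (noise == "poisson") rpois(n, lambda) else lambda * rlnorm(n, 0, sdlog)
  }
  bumpLambda <- function(center) {
    d2 <- .crossDist2(coords, matrix(center, nrow = 1L))[, 1L]
    baseline + amplitude * exp(-d2 / (2 * width * width))
  }

  vals <- matrix(0, nrow = f, ncol = n)
  ctrs <- matrix(NA_real_, nrow = f, ncol = ncol(coords))
  for (i in seq_len(f)) {
    center <- if (i <= nPlanted && !is.null(centers)) {
      centers[((i - 1L) %% nrow(centers)) + 1L, ]
    } else {
      coords[sample.int(n, 1L), ]
    }
    lambda <- bumpLambda(center)
    if (i > nPlanted) lambda <- lambda[sample.int(n)]  # break position link
    vals[i, ] <- drawNoise(lambda)
    if (i <= nPlanted) ctrs[i, ] <- center
  }

  ids <- c(sprintf("planted_%d", seq_len(nPlanted)),
           sprintf("null_%d", seq_len(nNull)))
  dimnames(vals) <- list(ids, rownames(coords))
  truth <- data.frame(
    feature_id = ids,
    label = rep(c("planted", "null"), c(nPlanted, nNull)),
    amplitude = rep(c(amplitude, NA_real_), c(nPlanted, nNull)),
    width = rep(c(width, NA_real_), c(nPlanted, nNull)),
    stringsAsFactors = FALSE
  )
  colnames(ctrs) <- paste0("center_", colnames(coords))
  truth <- cbind(truth, as.data.frame(ctrs))
  if (sparse) vals <- methods::as(methods::as(vals, "CsparseMatrix"), "dMatrix")
  list(activity = vals, truth = truth, seed = as.integer(seed))
}

#' One-call synthetic dataset
#'
#' Convenience wrapper around \code{\link{makeCoords}} and
#' \code{\link{makeActivity}} returning coordinates, activity matrix and
#' ground-truth labels together.
#'
#' @inheritParams makeCoords
#' @inheritParams makeActivity
#' @param ... further arguments passed to \code{\link{makeActivity}}.
#' @return list with \code{coords}, \code{activity}, \code{truth},
#'   \code{seed}.
#' @examples
#' sim <- simulateHaystack(n = 100, d = 2, nPlanted = 5, nNull = 20, seed = 1)
#' dim(sim$activity)
#' @export
simulateHaystack <- function(n = 1000L, d = 2L,
                             structure = c("blobs", "uniform", "trajectory"),
                             nBlobs = 5L, nPlanted = 100L, nNull = 1900L,
                             seed = 42L, ...) {
  structure <- match.arg(structure)
  coords <- makeCoords(n, d, structure, nBlobs = nBlobs, seed = seed)
  sim <- makeActivity(coords, nPlanted = nPlanted, nNull = nNull,
                      seed = seed + 1L, ...)
  list(coords = coords, activity = sim$activity, truth = sim$truth,
       seed = as.integer(seed))
}
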