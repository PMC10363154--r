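#' @importFrom Matrix rowSums rowMeans t
NULL

.asActivity <- function(activity) {
  if (is.data.frame(activity)) activity <- as.matrix(activity)
  if (!(is.matrix(activity) || is(activity, "Matrix"))) {
    stop("activity must be a (possibly sparse) features x samples matrix")
  }
  neg <- if (is(activity, "sparseMatrix")) any(activity@x < 0) else any(activity < 0)
  if (isTRUE(neg)) stop("activity values must be non-negative")
  activity
}

#' Reference distribution Q over grid points
#'
#' The local density of samples around each grid point: column sums of the
#' density-contribution matrix, normalized to sum to one. All entries are
#' strictly positive because the Gaussian kernel never vanishes.
#'
#' @param density n x g density-contribution matrix from
#'   \code{\link{computeDensity}}.
#' @return length-g probability vector.
#' @examples
#' dens <- computeDensity(matrix(0:3, ncol = 1),
#'                        matrix(c(0.5, 2.5), ncol = 1), h = 0.5)
#' computeQ(dens)  # symmetric layout -> c(0.5, 0.5)
#' @export
computeQ <- function(density) {
  q <- colSums(density)
  q / sum(q)
}

#' Activity-weighted distribution P_f of one feature
#'
#' Sums density contributions to each grid point weighted by the feature's
#' activity in each sample, then normalizes:
#' \eqn{P_{f,j} \propto \sum_i d_{ij} y_{f,i}}. Constant activity yields
#' exactly the reference distribution Q; positive rescaling of the activity
#' leaves P_f unchanged.
#'
#' @param density n x g density-contribution matrix.
#' @param y length-n non-negative activity vector with a positive sum.
#' @return length-g probability vector.
#' @examples
#' dens <- computeDensity(matrix(0:3, ncol = 1),
#'                        matrix(c(0.5, 2.5), ncol = 1), h = 0.5)
#' computePf(dens, c(1, 0, 0, 0))
#' @export
computePf <- function(density, y) {
  if (length(y) != nrow(density)) {
    stop("activity vector length must equal the number of samples")
  }
  if (any(y < 0)) stop("activity values must be non-negative")
  if (sum(y) <= 0) {
    stop("all-zero activity vector: P_f is undefined; skip the feature and report NA")
  }
  p <- as.numeric(crossprod(density, y))
  p / sum(p)
}

#' Kullback-Leibler divergence of P_f from Q
#'
#' \eqn{D_{KL}(f) = \sum_j P_{f,j} \log(P_{f,j} / Q_j)} with natural
#' logarithm; terms with \eqn{P_{f,j} = 0} contribute 0 by continuity.
#' Non-negative, and 0 exactly when the two distributions coincide.
#'
#' @param Pf length-g probability vector (feature distribution).
#' @param Q length-g strictly positive probability vector (reference).
#' @return non-negative scalar divergence.
#' @examples
#' computeDKL(c(1, 0), c(0.5, 0.5))  # log(2)
#' @export
computeDKL <- function(Pf, Q) {
  if (length(Pf) != length(Q)) stop("P_f and Q must have the same length")
  if (any(Q <= 0)) stop("all Q entries must be strictly positive")
  nz <- Pf > 0
  sum(Pf[nz] * (log(Pf[nz]) - log(Q[nz])))
}

#' Divergences for all features at once
#'
#' Vectorized application over the activity matrix: one sparse-capable
#' matrix product (activity x density) followed by row normalization and a
#' row-wise KL sum, numerically identical to looping
#' \code{\link{computePf}} / \code{\link{computeDKL}} per feature. All-zero
#' features yield NA and are flagged rather than dropped, so output rows
#' stay aligned with input features.
#'
#' @param density n x g density-contribution matrix.
#' @param activity f x n non-negative activity matrix (dense or
#'   \link[Matrix]{dgCMatrix-class}), samples in columns aligned with
#'   \code{density} rows.
#' @param keepPf also return the f x g matrix of P_f profiles.
#' @return list with \code{DKL} (length-f, NA for all-zero features),
#'   \code{allZero} (logical flags) and, if requested, \code{Pf}.
#' @examples
#' dens <- computeDensity(matrix(0:3, ncol = 1),
#'                        matrix(c(0.5, 2.5), ncol = 1), h = 0.5)
#' y <- rbind(constant = rep(1, 4), localized = c(1, 0, 0, 0))
#' computeAllDKL(dens, y)$DKL
#' @export
computeAllDKL <- function(density, activity, keepPf = FALSE) {
  activity <- .asActivity(activity)
  if (ncol(activity) != nrow(density)) {
    stop("activity columns (samples) must align with density rows")
  }
  P <- as.matrix(activity %*% density)
  rs <- rowSums(P)
  allZero <- Matrix::rowSums(activity) == 0
  rs[allZero] <- NA_real_
  P <- P / rs
  Q <- computeQ(density)
  PlogP <- P * log(P)
  PlogP[which(P == 0)] <- 0
  dkl <- rowSums(PlogP) - as.numeric(P %*% log(Q))
  dkl[allZero] <- NA_real_
  names(dkl) <- rownames(activity)
  out <- list(DKL = dkl, allZero = allZero)
  if (keepPf) {
    rownames(P) <- rownames(activity)
    out$Pf <- P
  }
  out
}
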