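#' @importFrom stats lm predict pnorm setNames
#' @importFrom splines ns bs
NULL

#' Coefficient of variation per feature
#'
#' CV = sd / mean of each feature's activity across samples (sample sd,
#' n-1 denominator). The CV is the predictor used by the null model: under
#' permutation, features with similar CV have similar null distributions of
#' log D_KL. All-zero features give NA; constant non-zero features give 0.
#'
#' @param activity f x n non-negative activity matrix (dense or sparse).
#' @return length-f numeric vector of CVs, named by feature.
#' @examples
#' computeCV(rbind(a = c(2, 2, 2, 2), b = c(0, 0, 2, 2)))
#' @export
computeCV <- function(activity) {
  activity <- .asActivity(activity)
  n <- ncol(activity)
  if (n < 2L) stop("at least 2 samples are required to compute a CV")
  m <- as.numeric(Matrix::rowMeans(activity))
  msq <- as.numeric(Matrix::rowMeans(activity * activity))
  v <- (msq - m * m) * n / (n - 1)
  s <- sqrt(pmax(v, 0))
  cv <- ifelse(m > 0, s / m, NA_real_)
  setNames(cv, rownames(activity))
}

#' Select reference features spread over the CV range
#'
#' Picks \code{m} features whose CVs are spread evenly over the observed CV
#' range: \code{m} target values are placed evenly over the span (on the
#' log-CV scale by default, matching the scale the null model is fitted on)
#' and each target greedily claims the nearest not-yet-used feature. The
#' minimum- and maximum-CV features are always included and the selection is
#' deterministic.
#'
#' @param cv length-f vector of CVs (NA and non-positive entries are
#'   ineligible).
#' @param m number of reference features (default 100).
#' @param scale spacing scale, "log" (default) or "linear".
#' @return integer vector of m feature indices (sorted by CV).
#' @examples
#' selectReferenceFeatures(1:100, m = 10, scale = "linear")
#' @export
selectReferenceFeatures <- function(cv, m = 100L, scale = c("log", "linear")) {
  scale <- match.arg(scale)
  eligible <- which(is.finite(cv) & cv > 0)
  if (length(eligible) == 0L) stop("no features with finite positive CV")
  m <- as.integer(m)
  if (length(eligible) <= m) {
    if (length(eligible) < m) {
      warning("only ", length(eligible), " features with finite positive CV; using all of them")
    }
    return(eligible[order(cv[eligible])])
  }
  val <- if (scale == "log") log(cv[eligible]) else cv[eligible]
  targets <- seq(min(val), max(val), length.out = m)
  used <- rep(FALSE, length(eligible))
  picked <- integer(m)
  for (k in seq_len(m)) {
    dist <- abs(val - targets[k])
    dist[used] <- Inf
    j <- which.min(dist)
    used[j] <- TRUE
    picked[k] <- eligible[j]
  }
  picked[order(cv[picked])]
}

#' Null divergences of one feature under permutation
#'
#' Randomly permutes the feature's activity across samples, recomputes P_f
#' against the fixed grid and reference distribution, and returns the
#' resulting D_KL for each replicate. These replicates form the empirical
#' null the spline model is trained on.
#'
#' @param density n x g density-contribution matrix.
#' @param y length-n non-negative activity vector with a positive sum.
#' @param nPerm number of permutations (>= 2; default 100).
#' @param seed optional RNG seed; when NULL the current RNG stream is used.
#' @return length-nPerm vector of D_KL values under the permutation null.
#' @examples
#' dens <- computeDensity(matrix(0:3, ncol = 1),
#'                        matrix(c(0.5, 2.5), ncol = 1), h = 0.5)
#' randomizeDKL(dens, c(3, 1, 0, 0), nPerm = 10, seed = 1)
#' @export
randomizeDKL <- function(density, y, nPerm = 100L, seed = NULL) {
  nPerm <- as.integer(nPerm)
  if (nPerm < 2L) stop("at least 2 permutations are required (sd undefined otherwise)")
  n <- nrow(density)
  if (length(y) != n) stop("activity vector length must equal the number of samples")
  if (sum(y) <= 0) stop("all-zero activity vector cannot be permuted into a distribution")
  if (!is.null(seed)) set.seed(as.integer(seed))
  Ymat <- vapply(seq_len(nPerm), function(k) y[sample.int(n)], numeric(n))
  P <- crossprod(density, Ymat)            # g x nPerm
  P <- sweep(P, 2L, colSums(P), "/")
  Q <- computeQ(density)
  PlogP <- P * log(P)
  PlogP[which(P == 0)] <- 0
  as.numeric(colSums(PlogP) - crossprod(log(Q), P))
}

# Tenfold-CV selection of spline flexibility for one curve y ~ spline(x).
# Searches df 1..10 for natural cubic splines, degree 1..5 x df degree..10
# for B-splines; minimal mean squared prediction error wins (ties -> the
# simplest candidate). Folds come from a seeded shuffle of the points.
.cvSplineFit <- function(x, y, splineType, seed, nFolds = 10L) {
  m <- length(x)
  stopifnot(length(y) == m)
  set.seed(as.integer(seed))
  fold <- sample(rep(seq_len(nFolds), length.out = m))
  candidates <- if (splineType == "ns") {
    data.frame(degree = 3L, df = 1:10)
  } else {
    cand <- expand.grid(degree = 1:5, df = 1:10)
    cand[cand$df >= cand$degree, , drop = FALSE]
  }
  mse <- vapply(seq_len(nrow(candidates)), function(ci) {
    dfi <- candidates$df[ci]
    deg <- candidates$degree[ci]
    errs <- vapply(seq_len(nFolds), function(k) {
      tr <- fold != k
      if (sum(tr) < dfi + 2L || sum(!tr) == 0L) return(NA_real_)
      dat <- data.frame(x = x[tr], y = y[tr])
      fit <- if (splineType == "ns") {
        lm(y ~ splines::ns(x, df = dfi), data = dat)
      } else {
        lm(y ~ splines::bs(x, df = dfi, degree = deg), data = dat)
      }
      pred <- suppressWarnings(predict(fit, newdata = data.frame(x = x[!tr])))
      mean((y[!tr] - pred)^2)
    }, numeric(1))
    mean(errs, na.rm = TRUE)
  }, numeric(1))
  # prefer the simplest candidate among numerically tied minima (candidates
  # are ordered by increasing flexibility)
  best <- which(mse <= min(mse, na.rm = TRUE) * (1 + 1e-6) + 1e-12)[1L]
  dfi <- candidates$df[best]
  deg <- candidates$degree[best]
  dat <- data.frame(x = x, y = y)
  fit <- if (splineType == "ns") {
    lm(y ~ splines::ns(x, df = dfi), data = dat)
  } else {
    lm(y ~ splines::bs(x, df = dfi, degree = deg), data = dat)
  }
  list(fit = fit, df = as.integer(dfi), degree = as.integer(deg), cvMSE = mse)
}

#' Fit the permutation null model
#'
#' For each reference feature the permutation replicates' log D_KL values are
#' summarised by their mean and standard deviation (log D_KL under the null
#' is approximately normal), and two spline regressions are fitted mapping
#' log CV to those moments. Spline flexibility is chosen independently for
#' the mean and sd curves by tenfold cross-validation (natural cubic splines
#' df 1..10 by default; B-splines additionally search degree 1..5).
#'
#' @param refLogCV length-m log CVs of the reference features.
#' @param refReplicates m x nPerm matrix (or list of length-m) of permutation
#'   D_KL replicates, rows aligned with \code{refLogCV}.
#' @param splineType "ns" (default) or "bs".
#' @param seed RNG seed for fold assignment.
#' @param refFeatures optional identifiers for the reference features.
#' @return a \linkS4class{HaystackNull}.
#' @export
fitNullModel <- function(refLogCV, refReplicates, splineType = c("ns", "bs"),
                         seed = 42L, refFeatures = NULL) {
  splineType <- match.arg(splineType)
  if (is.list(refReplicates)) {
    refReplicates <- do.call(rbind, refReplicates)
  }
  m <- length(refLogCV)
  stopifnot(nrow(refReplicates) == m)
  if (m < 12L) stop("at least 12 reference features are required for tenfold cross-validation")
  if (is.null(refFeatures)) refFeatures <- as.character(seq_len(m))
  nPerm <- ncol(refReplicates)

  keep <- rep(TRUE, m)
  mu <- sig <- rep(NA_real_, m)
  for (i in seq_len(m)) {
    reps <- refReplicates[i, ]
    pos <- reps[reps > 0]
    if (length(pos) < 2L) {
      keep[i] <- FALSE
      next
    }
    lg <- log(pos)
    mu[i] <- mean(lg)
    sig[i] <- sd(lg)
  }
  if (!all(keep)) {
    warning(sum(!keep), " reference feature(s) dropped: permutation replicates ",
            "were (almost) entirely zero")
  }
  if (!any(keep)) stop("all reference features had degenerate permutation replicates")
  refLogCV <- refLogCV[keep]
  mu <- mu[keep]
  sig <- pmax(sig[keep], 1e-6)
  refFeatures <- refFeatures[keep]
  if (length(refLogCV) < 12L) {
    stop("fewer than 12 usable reference features remain after dropping degenerate ones")
  }

  fitM <- .cvSplineFit(refLogCV, mu, splineType, seed = seed)
  fitS <- .cvSplineFit(refLogCV, sig, splineType, seed = seed)

  new("HaystackNull",
      refFeatures = as.character(refFeatures),
      refLogCV = as.numeric(refLogCV),
      refMeanLogDKL = mu,
      refSdLogDKL = sig,
      splineType = splineType,
      dfMean = fitM$df, dfSd = fitS$df,
      degreeMean = fitM$degree, degreeSd = fitS$degree,
      fitMean = fitM$fit, fitSd = fitS$fit,
      cvSpan = range(refLogCV),
      nPermutations = as.integer(nPerm),
      seed = as.integer(seed))
}

# Benjamini-Hochberg adjustment carried out on log10 p-values, so that
# adjustment works far below double underflow. NA entries pass through.
.bhAdjustLog10 <- function(lp) {
  ok <- which(!is.na(lp))
  m <- length(ok)
  out <- rep(NA_real_, length(lp))
  if (m == 0L) return(out)
  o <- order(lp[ok])
  adj <- lp[ok][o] + log10(m) - log10(seq_len(m))
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 0)
  tmp <- numeric(m)
  tmp[o] <- adj
  out[ok] <- tmp
  out
}

#' Predict p-values from the null model
#'
#' For every feature, the null model predicts the mean and sd of log D_KL
#' under permutation from the feature's log CV; the observed log D_KL is
#' standardized against those moments and an upper-tail normal p-value is
#' computed entirely in log space (values like 1e-300 and far below stay
#' finite). Log CVs outside the reference span are clamped to the span
#' boundary. Features with all-zero activity are flagged \code{all_zero}
#' (NA p-value); features with zero CV or zero divergence are flagged
#' \code{zero_cv} with p = 1.
#'
#' @param model a fitted \linkS4class{HaystackNull}.
#' @param cv length-f CV vector (see \code{\link{computeCV}}).
#' @param dkl length-f observed D_KL vector.
#' @param featureIds optional feature identifiers.
#' @return a \link[S4Vectors]{DataFrame} with columns \code{feature_id},
#'   \code{D_KL}, \code{log10_pval}, \code{log10_pval_adj}, \code{rank},
#'   \code{flag}, in input order. Ranks order ok-flagged features 1..n_ok by
#'   increasing log10 p (ties broken by input order), then zero-CV features;
#'   all-zero features get NA.
#' @export
predictPvalues <- function(model, cv, dkl, featureIds = NULL) {
  if (!is(model, "HaystackNull")) stop("model must be a fitted HaystackNull")
  f <- length(cv)
  stopifnot(length(dkl) == f)
  if (is.null(featureIds)) {
    featureIds <- if (!is.null(names(dkl))) names(dkl) else as.character(seq_len(f))
  }

  flag <- rep("ok", f)
  flag[is.na(cv) | is.na(dkl)] <- "all_zero"
  flag[flag == "ok" & (cv <= 0 | dkl <= 0)] <- "zero_cv"

  lp <- rep(NA_real_, f)
  idx <- which(flag == "ok")
  if (length(idx)) {
    logCV <- log(cv[idx])
    nClamp <- sum(logCV < model@cvSpan[1] | logCV > model@cvSpan[2])
    if (nClamp > 0) {
      warning(nClamp, " feature(s) with log CV outside the reference span; ",
              "clamped to the span boundary")
      logCV <- pmin(pmax(logCV, model@cvSpan[1]), model@cvSpan[2])
    }
    muHat <- as.numeric(predict(model@fitMean, newdata = data.frame(x = logCV)))
    sdHat <- pmax(as.numeric(predict(model@fitSd, newdata = data.frame(x = logCV))), 1e-6)
    z <- (log(dkl[idx]) - muHat) / sdHat
    lp[idx] <- pnorm(z, lower.tail = FALSE, log.p = TRUE) / log(10)
  }
  lp[flag == "zero_cv"] <- 0  # p = 1: no divergence to test

  lpAdj <- .bhAdjustLog10(lp)

  rank <- rep(NA_integer_, f)
  okIdx <- which(flag == "ok")
  rank[okIdx[order(lp[okIdx])]] <- seq_along(okIdx)
  zcIdx <- which(flag == "zero_cv")
  rank[zcIdx] <- length(okIdx) + seq_along(zcIdx)

  DataFrame(feature_id = as.character(featureIds),
            D_KL = as.numeric(dkl),
            log10_pval = lp,
            log10_pval_adj = lpAdj,
            rank = rank,
            flag = flag)
}
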