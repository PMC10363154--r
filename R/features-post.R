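#' @importFrom stats kmeans hclust cutree cor as.dist
NULL

#' Read gene sets from a GMT file
#'
#' One set per line: set id, description, then member feature ids, all
#' tab-separated.
#'
#' @param path path to a GMT file.
#' @return named list of character vectors of member feature ids.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 3L
  if (any(bad)) stop("malformed GMT: every line needs id, description and >= 1 member")
  setNames(lapply(fields, function(x) unique(x[-(1:2)])),
           vapply(fields, `[[`, character(1), 1L))
}

#' Gene-set ("module") scores per sample
#'
#' A deliberately simple per-sample summary of a gene set's collective
#' activity: each member feature is max-normalized (dividing by its maximum,
#' so highly expressed members do not dominate), member profiles are
#' averaged, and each set's score vector is min-max rescaled to [0, 1].
#' The output is a non-negative sets x samples matrix directly usable as an
#' activity matrix for \code{\link{runHaystack}}. This score is not
#' Seurat's AddModuleScore (no expression-bin-matched control subtraction);
#' it is a documented simplification capturing average member activity.
#'
#' @param activity f x n non-negative activity matrix.
#' @param sets named list of member feature id vectors (see
#'   \code{\link{readGmt}}).
#' @param minSize minimum number of members present in the activity matrix
#'   for a set to be retained (default 10).
#' @param verbose report sets excluded by the size filter.
#' @return sets x samples numeric matrix with values in [0, 1].
#' @export
geneSetScores <- function(activity, sets, minSize = 10L, verbose = TRUE) {
  activity <- .asActivity(activity)
  if (is.null(rownames(activity))) stop("activity matrix must have feature ids as rownames")
  present <- lapply(sets, intersect, rownames(activity))
  keep <- lengths(present) >= minSize
  if (verbose && any(!keep)) {
    message(sum(!keep), " set(s) excluded: fewer than ", minSize,
            " member features present")
  }
  present <- present[keep]
  if (length(present) == 0L) stop("no gene set retains >= minSize member features")
  scores <- t(vapply(present, function(members) {
    sub <- as.matrix(activity[members, , drop = FALSE])
    mx <- apply(sub, 1L, max)
    ok <- mx > 0
    if (!any(ok)) return(rep(0, ncol(sub)))
    s <- colMeans(sub[ok, , drop = FALSE] / mx[ok])
    rng <- range(s)
    if (rng[2] > rng[1]) (s - rng[1]) / (rng[2] - rng[1]) else rep(0, length(s))
  }, numeric(ncol(activity))))
  dimnames(scores) <- list(names(present), colnames(activity))
  scores
}

#' Cluster top-ranked features into expression modules
#'
#' Takes the most significant features of a scan and clusters their
#' normalized activity distributions over grid points (P_f profiles) into
#' modules. k-means (seeded, deterministic) follows the convention for
#' trajectory module detection; hierarchical clustering uses correlation
#' distance (1 - Pearson between profiles) with average linkage and returns
#' the dendrogram leaf order along with a k-cut labelling, the convention
#' for grouping high-scoring gene sets by spatial similarity.
#'
#' @param result a \linkS4class{HaystackResult} with kept P_f profiles, or
#'   NULL when \code{profiles} is given directly.
#' @param profiles optional top-f x g profile matrix overriding the ones in
#'   \code{result}.
#' @param method "kmeans" (default) or "hclust".
#' @param k number of modules (default 6).
#' @param topN number of top-ranked features to cluster (default 1000).
#' @param seed RNG seed for k-means.
#' @return a \linkS4class{HaystackModules}.
#' @export
clusterTopFeatures <- function(result = NULL, profiles = NULL,
                               method = c("kmeans", "hclust"),
                               k = 6L, topN = 1000L, seed = 42L) {
  method <- match.arg(method)
  k <- as.integer(k)
  if (is.null(profiles)) {
    if (is.null(result) || !is(result, "HaystackResult")) {
      stop("either a HaystackResult or a profile matrix is required")
    }
    if (is.null(result@Pf)) {
      stop("result carries no P_f profiles; rerun with keepPf = TRUE ",
           "or supply profiles directly")
    }
    tab <- result@table
    ok <- tab[tab$flag == "ok", , drop = FALSE]
    topN <- min(as.integer(topN), nrow(ok))
    ids <- ok$feature_id[order(ok$rank)][seq_len(topN)]
    profiles <- result@Pf[ids, , drop = FALSE]
  } else {
    profiles <- as.matrix(profiles)
    topN <- nrow(profiles)
    if (is.null(rownames(profiles))) {
      rownames(profiles) <- sprintf("feature_%d", seq_len(topN))
    }
  }
  if (k > nrow(profiles)) stop("k must not exceed the number of clustered features")

  if (method == "kmeans") {
    set.seed(as.integer(seed))
    km <- kmeans(profiles, centers = k, iter.max = 100L, nstart = 10L)
    labels <- km$cluster
    ord <- seq_len(nrow(profiles))
  } else {
    cc <- suppressWarnings(cor(t(profiles)))
    cc[!is.finite(cc)] <- 0
    hc <- hclust(as.dist(1 - cc), method = "average")
    labels <- cutree(hc, k = k)
    ord <- hc$order
  }
  centers <- do.call(rbind, lapply(sort(unique(labels)), function(l) {
    colMeans(profiles[labels == l, , drop = FALSE])
  }))
  rownames(centers) <- paste0("module_", sort(unique(labels)))
  new("HaystackModules",
      features = rownames(profiles),
      labels = as.integer(labels),
      centers = centers,
      method = method,
      order = as.integer(ord))
}
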