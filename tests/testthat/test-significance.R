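# Controlled null model: reference replicates drawn log-normal with a known
# linear mean(logCV) relation and constant sd, so fitted curves are known.
makeToyNull <- function(m = 30, a = -3, b = 1.5, s = 0.3, nPerm = 60,
                        seed = 42, splineType = "ns") {
  set.seed(seed)
  logcv <- seq(log(0.2), log(5), length.out = m)
  reps <- t(vapply(seq_len(m), function(i) {
    exp(rnorm(nPerm, a + b * logcv[i], s))
  }, numeric(nPerm)))
  list(logcv = logcv,
       model = fitNullModel(logcv, reps, splineType = splineType, seed = seed))
}

test_that("coefficient of variation follows sd/mean with n-1 denominator", {
  cv <- computeCV(rbind(a = c(2, 2, 2, 2), b = c(0, 0, 2, 2),
                        c = c(0, 0, 0, 0)))
  expect_equal(cv[["a"]], 0)
  expect_equal(cv[["b"]], 2 * sqrt(1 / 3), tolerance = 1e-12)  # mean 1, sd sqrt(4/3)
  expect_true(is.na(cv[["c"]]))
  # scale invariance
  y <- matrix(c(1, 3, 0, 2), nrow = 1)
  expect_equal(computeCV(y), computeCV(7 * y), tolerance = 1e-12)
  # sparse and dense agree
  m <- matrix(rpois(200, 1), nrow = 10)
  expect_equal(unname(computeCV(m)),
               unname(computeCV(methods::as(m, "CsparseMatrix"))),
               tolerance = 1e-12)
})

test_that("reference features are spread evenly over the CV range", {
  # exhaustive case: as many eligible features as requested
  expect_identical(selectReferenceFeatures(c(0.5, 2, 1), m = 3), c(1L, 3L, 2L))
  # linear-spacing variant on integer CVs 1..100 picks the even-target set
  picked <- selectReferenceFeatures(1:100, m = 10, scale = "linear")
  expect_identical(picked, as.integer(c(1, 12, 23, 34, 45, 56, 67, 78, 89, 100)))
  # determinism, and min/max always included (log scale)
  set.seed(4)
  cv <- exp(runif(500, -2, 2))
  a <- selectReferenceFeatures(cv, m = 50)
  expect_identical(a, selectReferenceFeatures(cv, m = 50))
  expect_true(which.min(cv) %in% a && which.max(cv) %in% a)
  expect_equal(length(unique(a)), 50L)
  # fewer eligible than requested: use all, warn
  expect_warning(few <- selectReferenceFeatures(c(1, 2, NA, 0), m = 10), "using all")
  expect_identical(sort(few), c(1L, 2L))
})

test_that("permutation replicates match exhaustive enumeration on 4 samples", {
  dens <- computeDensity(toyCoords(), toyGrid(), h = 0.5)
  y <- c(0.3, 0, 1, 2)
  q <- computeQ(dens)
  perms <- allPermutations(4L)
  exhaustive <- apply(perms, 1L, function(p) {
    computeDKL(computePf(dens, y[p]), q)
  })
  sampled <- randomizeDKL(dens, y, nPerm = 50, seed = 9)
  expect_true(all(vapply(sampled, function(v) {
    any(abs(exhaustive - v) < 1e-12)
  }, logical(1))))
  expect_true(all(sampled >= -1e-12))
  # constant activity: every permutation reproduces Q exactly
  expect_lt(max(abs(randomizeDKL(dens, rep(2, 4), nPerm = 10, seed = 1))), 1e-12)
  expect_identical(randomizeDKL(dens, y, nPerm = 20, seed = 3),
                   randomizeDKL(dens, y, nPerm = 20, seed = 3))
  expect_error(randomizeDKL(dens, y, nPerm = 1), "at least 2")
  expect_error(randomizeDKL(dens, c(0, 0, 0, 0), nPerm = 10), "all-zero")
})

test_that("null model recovers known linear mean and constant sd curves", {
  a <- -3; b <- 1.5; s <- 0.3
  toy <- makeToyNull(m = 100, a = a, b = b, s = s, nPerm = 100, seed = 42)
  model <- toy$model
  x <- seq(min(toy$logcv), max(toy$logcv), length.out = 41)
  predMean <- as.numeric(predict(model@fitMean, newdata = data.frame(x = x)))
  predSd <- as.numeric(predict(model@fitSd, newdata = data.frame(x = x)))
  expect_lt(max(abs(predMean - (a + b * x)) / abs(a + b * x + 1e-9)), 0.05)
  expect_lt(max(abs(predSd - s) / s), 0.05)
})

test_that("flat reference statistics select the simplest spline", {
  # identical replicate statistics at all CVs: no signal to overfit
  m <- 20
  logcv <- seq(-1, 1, length.out = m)
  reps <- matrix(rep(exp(seq(-3, -2, length.out = 40)), each = m), nrow = m)
  model <- fitNullModel(logcv, reps, seed = 1)
  expect_identical(model@dfMean, 1L)
  x <- seq(-1, 1, length.out = 11)
  pm <- as.numeric(predict(model@fitMean, newdata = data.frame(x = x)))
  expect_lt(diff(range(pm)), 1e-8)
})

test_that("null model refit with the same seed is identical", {
  t1 <- makeToyNull(seed = 7)
  t2 <- makeToyNull(seed = 7)
  expect_identical(t1$model@dfMean, t2$model@dfMean)
  expect_identical(t1$model@dfSd, t2$model@dfSd)
  expect_equal(coef(t1$model@fitMean), coef(t2$model@fitMean), tolerance = 0)
  expect_error(fitNullModel(1:5, matrix(1, 5, 10)), "at least 12")
})

test_that("degenerate reference replicates are dropped with a warning", {
  set.seed(3)
  logcv <- seq(-1, 1, length.out = 15)
  reps <- t(vapply(logcv, function(x) exp(rnorm(30, x, 0.2)), numeric(30)))
  reps[3, ] <- 0
  expect_warning(model <- fitNullModel(logcv, reps, seed = 2), "dropped")
  expect_equal(length(model@refLogCV), 14L)
})

test_that("p-values come from the normal upper tail in log space", {
  toy <- makeToyNull(seed = 11)
  model <- toy$model
  cvs <- exp(c(-1, 0, 1))
  mu <- as.numeric(predict(model@fitMean, newdata = data.frame(x = log(cvs))))
  sd <- pmax(as.numeric(predict(model@fitSd, newdata = data.frame(x = log(cvs)))), 1e-6)

  # observed divergence exactly at the null mean: p = 0.5
  tab <- predictPvalues(model, cvs, exp(mu))
  expect_equal(tab$log10_pval, rep(log10(0.5), 3), tolerance = 1e-9)
  expect_equal(tab$log10_pval, rep(-0.30103, 3), tolerance = 1e-5)

  # z = 40: far below double underflow, checked against the asymptotic
  # normal-tail expansion log10 p ~ (-z^2/2 - log(z sqrt(2 pi)) + log(1 - z^-2 + 3 z^-4)) / log(10)
  z <- 40
  tab40 <- predictPvalues(model, cvs, exp(mu + z * sd))
  oracle <- (-z^2 / 2 - log(z * sqrt(2 * pi)) + log(1 - z^-2 + 3 * z^-4)) / log(10)
  expect_true(all(is.finite(tab40$log10_pval)))
  expect_true(all(tab40$log10_pval < -300))
  expect_equal(tab40$log10_pval, rep(oracle, 3), tolerance = 1e-6)
})

test_that("monotonicity: larger divergence never gives a larger p-value", {
  toy <- makeToyNull(seed = 13)
  model <- toy$model
  dkls <- exp(seq(-6, 1, length.out = 30))
  tab <- predictPvalues(model, rep(1.0, 30), dkls)
  expect_true(all(diff(tab$log10_pval) <= 1e-12))
})

test_that("flags, ranks and BH adjustment behave as contracted", {
  toy <- makeToyNull(seed = 17)
  model <- toy$model
  cv <- c(1.2, 0.8, NA, 0, 2.0)
  dkl <- c(0.5, 0.01, NA, 0, 0.2)
  tab <- predictPvalues(model, cv, dkl)
  expect_identical(tab$flag, c("ok", "ok", "all_zero", "zero_cv", "ok"))
  expect_true(is.na(tab$log10_pval[3]))
  expect_equal(tab$log10_pval[4], 0)  # p = 1
  ok <- tab$flag == "ok"
  expect_identical(sort(tab$rank[ok]), seq_len(sum(ok)))
  expect_true(all(tab$rank[tab$flag == "zero_cv"] > sum(ok)))
  expect_true(all(is.na(tab$rank[tab$flag == "all_zero"])))
  # BH on the log scale never decreases a p-value
  expect_true(all(tab$log10_pval_adj >= tab$log10_pval - 1e-9, na.rm = TRUE))

  # CVs outside the reference span are clamped with a warning
  expect_warning(predictPvalues(model, c(1, 50), c(0.1, 0.1)), "clamped")

  # agreement with stats::p.adjust where doubles do not underflow
  set.seed(5)
  lp <- log10(runif(200))
  expect_equal(10^kldHaystack:::.bhAdjustLog10(lp),
               p.adjust(10^lp, "BH"), tolerance = 1e-12)
})
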