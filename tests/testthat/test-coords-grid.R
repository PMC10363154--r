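test_that("coordinate scaling centers and standardizes each dimension", {
  # two-point column: center to +/-1, divide by sample sd sqrt(2)
  expect_equal(scaleCoordinates(matrix(c(1, 3), ncol = 1)),
               matrix(c(-1, 1) / sqrt(2), ncol = 1),
               tolerance = 1e-12)

  set.seed(1)
  x <- matrix(rnorm(300, mean = 5, sd = 3), ncol = 3)
  sx <- scaleCoordinates(x)
  expect_lt(max(abs(colMeans(sx))), 1e-9)
  expect_lt(max(abs(apply(sx, 2, sd) - 1)), 1e-9)

  # already standardized input comes back unchanged
  expect_equal(scaleCoordinates(sx), sx, tolerance = 1e-12)

  expect_error(scaleCoordinates(matrix(1, 1, 1)), "at least 2 samples")
  expect_error(scaleCoordinates(matrix(c(1, NA), ncol = 1)), "missing")
})

test_that("zero-variance columns are centered, zeroed and warned about", {
  x <- cbind(c(1, 2, 3), c(5, 5, 5))
  expect_warning(sx <- scaleCoordinates(x), "zero-variance")
  expect_identical(sx[, 2], c(0, 0, 0))
  expect_equal(ncol(sx), 2L)  # column kept for index stability
})

test_that("grid point selection is deterministic and respects the space", {
  # two distinct 1D samples, g = 2: each point is its own centroid
  two <- matrix(c(-1, 1), ncol = 1)
  gp <- selectGridPoints(two, g = 2, seed = 1)
  expect_equal(sort(gp[, 1]), c(-1, 1))

  set.seed(99)
  xy <- matrix(rnorm(600), ncol = 2)
  a <- selectGridPoints(xy, g = 25, seed = 5)
  b <- selectGridPoints(xy, g = 25, seed = 5)
  expect_identical(a, b)
  s1 <- selectGridPoints(xy, g = 25, method = "seeding", seed = 5)
  s2 <- selectGridPoints(xy, g = 25, method = "seeding", seed = 5)
  expect_identical(s1, s2)
  # seeding picks actual sample points
  expect_true(all(s1[, 1] %in% xy[, 1]))

  expect_warning(gp <- selectGridPoints(xy[1:10, ], g = 50, seed = 1), "g = 10")
  expect_equal(nrow(gp), 10L)
  expect_error(selectGridPoints(xy, g = 1), "at least 2")
  expect_error(
    selectGridPoints(xy, method = "user", userCoords = matrix(1, 3, 3)),
    "dimensionality")
})

test_that("k-means grid recovers well-separated blob centers", {
  coords <- makeCoords(400, 2, "blobs", nBlobs = 4, seed = 13)
  labels <- attr(coords, "labels")
  gp <- selectGridPoints(coords, g = 4, seed = 13)
  # one centroid inside each blob's bounding box
  hits <- vapply(sort(unique(labels)), function(l) {
    box <- apply(coords[labels == l, , drop = FALSE], 2, range)
    any(gp[, 1] >= box[1, 1] & gp[, 1] <= box[2, 1] &
        gp[, 2] >= box[1, 2] & gp[, 2] <= box[2, 2])
  }, logical(1))
  expect_true(all(hits))
})

test_that("bandwidth is the median nearest-grid distance", {
  expect_equal(computeBandwidth(toyCoords(), toyGrid()), 0.5)
  # homogeneity: doubling all coordinates doubles h
  expect_equal(computeBandwidth(2 * toyCoords(), 2 * toyGrid()), 1.0)
  # grid on top of the samples: degenerate geometry
  expect_error(computeBandwidth(toyCoords(), toyCoords()), "degenerate")
})

test_that("density contributions follow the Gaussian kernel formula", {
  # sample on a grid point
  expect_equal(computeDensity(matrix(0.5), toyGrid(), h = 0.5)[1, 1], 1)
  # distance exactly h
  expect_equal(computeDensity(matrix(0), matrix(0.5), h = 0.5)[1, 1],
               exp(-0.5), tolerance = 1e-12)
  # frozen row for the 1D toy setup: normalized distances 1 and 5
  row <- computeDensity(matrix(0), toyGrid(), h = 0.5)
  expect_equal(as.numeric(row), c(exp(-0.5), exp(-12.5)), tolerance = 1e-12)
  expect_equal(as.numeric(row), c(0.60653066, 3.7266532e-06), tolerance = 1e-7)

  set.seed(7)
  coords <- matrix(rnorm(60), ncol = 3)
  grid <- matrix(rnorm(15), ncol = 3)
  d <- computeDensity(coords, grid, h = 0.8)
  expect_equal(d, densityOracle(coords, grid, 0.8), tolerance = 1e-12)
  expect_true(all(d > 0 & d <= 1))

  expect_error(computeDensity(matrix(Inf), toyGrid(), 0.5), "non-finite")
  expect_error(computeDensity(toyCoords(), toyGrid(), h = 0), "positive")
})

test_that("density is invariant to rigid rotations and joint rescaling", {
  set.seed(11)
  coords <- matrix(rnorm(100), ncol = 2)
  grid <- selectGridPoints(coords, g = 8, seed = 3)
  h <- computeBandwidth(coords, grid)
  base <- computeDensity(coords, grid, h)
  for (theta in runif(3, 0, 2 * pi)) {
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
    rot <- computeDensity(coords %*% R, grid %*% R,
                          computeBandwidth(coords %*% R, grid %*% R))
    expect_equal(rot, base, tolerance = 1e-10)
  }
  # uniform scaling with h recomputed leaves normalized distances unchanged
  scl <- computeDensity(3.7 * coords, 3.7 * grid,
                        computeBandwidth(3.7 * coords, 3.7 * grid))
  expect_equal(scl, base, tolerance = 1e-10)
})

test_that("buildGrid assembles a valid grid model with positive Q", {
  coords <- makeCoords(300, 2, "blobs", nBlobs = 3, seed = 17)
  grid <- buildGrid(coords, g = 20, seed = 17)
  expect_s4_class(grid, "HaystackGrid")
  expect_true(validObject(grid))
  expect_equal(sum(refDistribution(grid)), 1, tolerance = 1e-12)
  expect_true(all(refDistribution(grid) > 0))
  expect_equal(dim(densityMatrix(grid)), c(300L, 20L))
  expect_equal(nrow(gridCoords(grid)), 20L)
})
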