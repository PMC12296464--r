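test_that("3x3 smoothing matches the direct convolution oracle", {
  one <- matrix(1, 8, 8)
  sm <- smoothMask(one)
  expect_equal(sm$values[4, 4], 1)

  iso <- matrix(0, 9, 9); iso[5, 5] <- 1
  expect_equal(smoothMask(iso)$values[5, 5], 1 / 9)

  set.seed(60)
  m <- matrix(rbinom(256, 1, 0.3), 16, 16)
  expect_equal(smoothMask(m)$values, oracleSmooth(m), tolerance = 1e-12)
})

test_that("bilinear upsampling preserves constants, monotonicity and range", {
  pmc <- predictionMap(matrix(0.4, 4, 4), "grid")
  up <- upsampleMap(pmc, 16)
  expect_equal(dim(up$values), c(16L, 16L))
  expect_lt(max(abs(up$values - 0.4)), 1e-12)

  pm2 <- predictionMap(matrix(c(0, 0, 1, 1), 2, 2), "grid")
  up2 <- upsampleMap(pm2, 8)
  for (i in 1:8) expect_true(all(diff(up2$values[i, ]) >= -1e-12))
  expect_lte(max(up2$values), 1 + 1e-9)
  expect_gte(min(up2$values), -1e-9)
})

test_that("adaptive thresholding lands near the target area fraction", {
  set.seed(61)
  pm <- predictionMap(matrix(runif(512 * 512), 512, 512), "working")
  t <- selectThreshold(pm, targetFraction = 0.04)
  expect_lt(abs(t - 0.96), 0.02)
  expect_lt(abs(mean(pm$values >= t) - 0.04), 0.01)
})

test_that("threshold ties resolve to the stricter threshold", {
  v <- matrix(0, 50, 50)
  v[1:10, 1:10] <- 1  # exactly 4% ones
  pm <- predictionMap(v, "working")
  expect_equal(selectThreshold(pm, targetFraction = 0.04), 1)
  expect_warning(t0 <- selectThreshold(predictionMap(matrix(0, 10, 10),
                                                     "working")),
                 "all-zero")
  expect_equal(t0, 1)
})

test_that("foreground fraction is non-increasing in the threshold", {
  set.seed(62)
  pm <- predictionMap(matrix(runif(128 * 128)^2, 128, 128), "working")
  grid <- seq(0, 1, length.out = 101)
  frac <- vapply(grid, function(t) mean(pm$values >= t), numeric(1))
  expect_true(all(diff(frac) <= 0))
})

test_that("threshold selection tracks the target for continuous maps", {
  set.seed(63)
  for (target in c(0.02, 0.04, 0.1)) {
    v <- matrix(rbeta(256 * 256, 2, 5), 256, 256)
    pm <- predictionMap(v, "working")
    t <- selectThreshold(pm, targetFraction = target)
    expect_lt(abs(mean(v >= t) - target), 0.02)
  }
})

test_that("connected components yield centroids, radii and scores", {
  n <- 200
  b <- matrix(0, n, n)
  d2 <- outer((0:(n - 1) - 100)^2, (0:(n - 1) - 100)^2, `+`)
  b[d2 <= 100] <- 1  # disc radius 10 at (x=100, y=100), 0-based
  ps <- extractParticles(b)
  expect_equal(nParticles(ps), 1L)
  expect_lt(max(abs(centers(ps)[1, ] - c(100, 100))), 0.5)
  expect_lt(abs(radii(ps)[1] - 10) / 10, 0.1)

  expect_equal(nParticles(extractParticles(matrix(0, 20, 20))), 0L)

  two <- matrix(0, 40, 40)
  two[5:10, 5:10] <- 1
  two[25:30, 25:30] <- 1
  expect_equal(nParticles(extractParticles(two)), 2L)
})

test_that("labeling is 8-connected", {
  m <- matrix(0, 6, 6)
  m[2, 2] <- 1; m[3, 3] <- 1  # touch only diagonally
  expect_equal(nParticles(extractParticles(m)), 1L)
})

test_that("particle filters apply the size, border and neighbour rules", {
  shape <- c(512L, 512L)
  # rule (i): two close particles, higher score survives
  ps <- ParticleSet(rbind(c(200, 200), c(210, 200)), radii = c(10, 10),
                    scores = c(0.9, 0.8), frame = "working")
  kept <- filterParticles(ps, diameterPx = 20, imageShape = shape)
  expect_equal(nParticles(kept), 1L)
  expect_equal(unname(centers(kept)[1, ]), c(200, 200))

  # rule (ii): oversized blob removed at the default factor 1.5
  ps2 <- ParticleSet(rbind(c(200, 200)), radii = 20, scores = 1,
                     frame = "working")
  expect_equal(nParticles(filterParticles(ps2, 20, shape)), 0L)

  # rule (iii): border particle removed
  ps3 <- ParticleSet(rbind(c(3, 250)), radii = 10, scores = 1,
                     frame = "working")
  expect_equal(
    nParticles(filterParticles(ps3, 20, shape, borderMarginPx = 40)), 0L)
})

test_that("filtered sets satisfy all three invariants jointly", {
  set.seed(64)
  n <- 60
  ps <- ParticleSet(cbind(runif(n, 0, 511), runif(n, 0, 511)),
                    radii = runif(n, 2, 30), scores = runif(n),
                    frame = "working")
  d <- 20
  kept <- filterParticles(ps, d, c(512L, 512L))
  if (nParticles(kept) > 1) {
    dd <- as.matrix(dist(centers(kept)))
    expect_gt(min(dd[upper.tri(dd)]), d)
  }
  expect_true(all(radii(kept) <= 1.5 * d / 2))
  expect_true(all(centers(kept) >= d / 2 &
                    centers(kept) <= 511 - d / 2))
})

test_that("working coordinates map back to the original frame", {
  ps <- ParticleSet(rbind(c(100, 200)), radii = 5, scores = 1,
                    frame = "working")
  back <- mapToOriginal(ps, 0.25, 0.25)
  expect_equal(unname(centers(back)[1, ]), c(400, 800))
  expect_identical(coordFrame(back), "original")

  same <- mapToOriginal(ps, 1, 1)
  expect_equal(centers(same), centers(ps))

  # round trip working -> original -> working
  rt <- centers(back) * 0.25
  expect_lt(max(abs(rt - centers(ps))), 1e-9)

  expect_error(mapToOriginal(back, 0.25, 0.25), "working frame")
  expect_error(mapToOriginal(ps, NA_real_, 0.25), "scale metadata")
})
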