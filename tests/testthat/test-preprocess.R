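test_that("local stats reproduce a constant field exactly", {
  x <- matrix(3.7, 32, 32)
  s <- localStats(x, 5)
  expect_lt(max(abs(s$mu - 3.7)), 1e-8)
  expect_lt(max(s$sigma), 1e-8)
})

test_that("FFT local stats match the sliding-window oracle with periodic wrap", {
  set.seed(10)
  for (case in list(list(n = 16, d = 5), list(n = 32, d = 7),
                    list(n = 24, d = 4))) {
    x <- matrix(rnorm(case$n^2), case$n, case$n)
    fast <- localStats(x, case$d)
    slow <- oracleLocalStats(x, case$d)
    expect_lt(max(abs(fast$mu - slow$mu)), 1e-6)
    expect_lt(max(abs(fast$sigma - slow$sigma)), 1e-6)
  }
})

test_that("local stats of white noise recover mean 0 and sd 1", {
  set.seed(11)
  x <- matrix(rnorm(512 * 512), 512, 512)
  s <- localStats(x, 24)
  expect_lt(abs(mean(s$mu)), 0.02)
  expect_lt(abs(mean(s$sigma) - 1), 0.05)
})

test_that("local normalization standardizes white noise", {
  set.seed(12)
  x <- matrix(rnorm(256 * 256), 256, 256)
  out <- localNormalize(x, 15)
  expect_gt(mean(out), -0.05)
  expect_lt(mean(out), 0.05)
  expect_gt(sd(out), 0.9)
  expect_lt(sd(out), 1.1)
})

test_that("constant images normalize to zero via the epsilon guard", {
  out <- localNormalize(matrix(5, 64, 64), 9)
  expect_true(all(out == 0))
})

test_that("local normalization is invariant to affine intensity changes", {
  set.seed(13)
  x <- matrix(rnorm(64 * 64), 64, 64)
  a <- localNormalize(x, 9)
  b <- localNormalize(3.2 * x + 17, 9)
  expect_lt(max(abs(a - b)), 1e-6)
})

test_that("local normalization suppresses a linear illumination ramp", {
  set.seed(14)
  n <- 256
  base <- matrix(rnorm(n * n), n, n)
  ramp <- outer(seq(0, 4, length.out = n), rep(1, n))
  x <- base + ramp
  fitSlope <- function(img) {
    df <- data.frame(v = as.numeric(img),
                     r = as.numeric(row(img)), c = as.numeric(col(img)))
    co <- coef(lm(v ~ r + c, data = df))
    sqrt(co[["r"]]^2 + co[["c"]]^2)
  }
  out <- localNormalize(x, 25)
  expect_gt(fitSlope(x) / fitSlope(out), 10)
})

test_that("enhancement maps any finite input into [0, 1] deterministically", {
  set.seed(15)
  x <- matrix(rnorm(128 * 128, sd = 40), 128, 128)
  a <- enhanceMicrograph(x, 20)
  b <- enhanceMicrograph(x, 20)
  expect_gte(min(a), 0)
  expect_lte(max(a), 1)
  expect_identical(a, b)
  expect_error(enhanceMicrograph(matrix(c(NA, rnorm(63)), 8, 8), 4),
               "contract violation")
})

test_that("enhancement increases disc-versus-background contrast", {
  set.seed(16)
  n <- 128
  x <- matrix(rnorm(n * n), n, n)
  cy <- 64; cx <- 64; r <- 10
  d2 <- outer((seq_len(n) - cy)^2, (seq_len(n) - cx)^2, `+`)
  inside <- d2 <= r^2
  x[inside] <- x[inside] - 2
  contrast <- function(img) {
    bg <- img[!inside]
    abs(mean(img[inside]) - mean(bg)) / sd(bg)
  }
  enh <- enhanceMicrograph(x, 2 * r)
  expect_gt(contrast(enh), contrast(x))
})

test_that("resizing records per-axis scale factors and preserves identity", {
  m <- Micrograph(matrix(rnorm(256 * 256), 256, 256))
  same <- resizeWorking(m, 256)
  expect_identical(pixels(same), pixels(m))
  expect_equal(scaleFactors(same), c(1, 1))

  big <- Micrograph(matrix(rnorm(767 * 741), 767, 741))
  small <- resizeWorking(big, 256)
  expect_identical(dim(pixels(small)), c(256L, 256L))
  expect_equal(scaleFactors(small), c(256 / 767, 256 / 741))
  expect_identical(originalShape(small), c(767L, 741L))
})

test_that("the full preprocessing chain is deterministic and shape-contracted", {
  s <- generateMicrograph(syntheticSpec(imageSize = c(192L, 160L),
                                        nParticles = 3L, diameterPx = 20,
                                        seed = 17))
  cfg <- deskProfile()
  a <- preprocessMicrograph(micrograph(s), 20, cfg)
  b <- preprocessMicrograph(micrograph(s), 20, cfg)
  expect_identical(pixels(a), pixels(b))
  expect_identical(dim(pixels(a)), c(256L, 256L))
  expect_gte(min(pixels(a)), 0)
  expect_lte(max(pixels(a)), 1)
})

test_that("degenerate masks are rejected", {
  expect_error(circularMask(0, c(16, 16)), "contract violation")
  expect_error(localStats(matrix(0, 8, 8), 20), "contract violation")
})
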