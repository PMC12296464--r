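test_that("tiling counts follow the working/tile geometry", {
  tb <- tileMicrograph(matrix(0, 1024, 1024), 64)
  expect_length(tb$tiles, 256L)

  tb2 <- tileMicrograph(matrix(rnorm(128 * 128), 128, 128), 64)
  expect_length(tb2$tiles, 4L)
  expect_equal(tb2$gridIndex,
               rbind(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L)))
  expect_error(tileMicrograph(matrix(0, 100, 100), 64),
               "contract violation")
})

test_that("untiling inverts tiling bit for bit", {
  set.seed(20)
  x <- matrix(rnorm(256 * 256), 256, 256)
  expect_identical(untileMicrograph(tileMicrograph(x, 64)), x)
  y <- matrix(rnorm(96 * 64), 96, 64)
  expect_identical(untileMicrograph(tileMicrograph(y, 32)), y)
})

test_that("mask patterns hit the exact count, reproducibly and uniformly", {
  m <- sampleMask(64, 0.5, seed = 42)
  expect_equal(sum(m), 32L)
  expect_identical(sampleMask(64, 0.5, seed = 42), m)
  expect_false(identical(sampleMask(64, 0.5, seed = 43), m))
  for (tc in c(16L, 64L)) {
    for (ratio in c(0.25, 0.5, 0.75))
      expect_equal(sum(sampleMask(tc, ratio, seed = 1)),
                   round(ratio * tc))
  }
  # Monte-Carlo uniformity of the per-token masking frequency
  set.seed(44)
  freq <- rowMeans(vapply(seq_len(10000),
                          function(i) sampleMask(64, 0.5),
                          logical(64)))
  expect_true(all(freq >= 0.47 & freq <= 0.53))
})

test_that("the reconstruction loss matches its definition", {
  set.seed(21)
  y <- matrix(rnorm(16 * 16), 16, 16)
  m <- sampleMask(16, 0.5, seed = 2)
  expect_equal(reconstructionLoss(y, y, m), 0)

  oneTok <- rep(FALSE, 16); oneTok[5] <- TRUE
  expect_equal(reconstructionLoss(y, y + 2, oneTok), 4)

  yhat <- matrix(rnorm(16 * 16), 16, 16)
  direct <- 0; n <- 0
  for (t in which(m)) for (p in 1:16) {
    direct <- direct + (y[t, p] - yhat[t, p])^2
    n <- n + 1
  }
  expect_lt(abs(reconstructionLoss(y, yhat, m) - direct / n), 1e-10)
  expect_error(reconstructionLoss(y, yhat, rep(FALSE, 16)),
               "contract violation")
})

test_that("analytic gradients agree with finite differences", {
  cfg <- tinyConfig()
  model <- initMAE(cfg, seed = 7)
  arch <- model@arch
  set.seed(8)
  B <- 2L
  tokens <- matrix(rnorm(B * arch$tokenCount * arch$tokenPixels),
                   B * arch$tokenCount)
  masks <- rbind(sampleMask(arch$tokenCount, 0.5),
                 sampleMask(arch$tokenCount, 0.5))
  res <- cryoMAE:::maeStep(model@params, arch, tokens, masks)

  lossAt <- function(params) {
    cryoMAE:::maeStep(params, arch, tokens, masks,
                      computeGrads = FALSE)$loss
  }
  # probe a scattered selection of parameters across all components
  probes <- list(
    c("patchW", "3"), c("patchB", "5"),
    c("enc", "1", "Wq", "10"), c("enc", "1", "Wo", "4"),
    c("enc", "1", "W1", "7"), c("enc", "1", "ln1g", "2"),
    c("enc", "1", "ln2b", "3"), c("encLNg", "1"),
    c("decW", "6"), c("maskTok", "2"),
    c("dec", "1", "Wv", "9"), c("dec", "1", "W2", "5"),
    c("decLNb", "4"), c("headW", "11"), c("headB", "1")
  )
  h <- 1e-5
  asKey <- function(k) if (grepl("^[0-9]+$", k)) as.integer(k) else k
  perturb <- function(params, pr, delta) {
    path <- lapply(pr[-length(pr)], asKey)
    idx <- as.integer(pr[length(pr)])
    modify <- function(p, depth) {
      if (depth > length(path)) { p[idx] <- p[idx] + delta; return(p) }
      p[[path[[depth]]]] <- modify(p[[path[[depth]]]], depth + 1)
      p
    }
    modify(params, 1)
  }
  for (pr in probes) {
    up <- lossAt(perturb(model@params, pr, h))
    dn <- lossAt(perturb(model@params, pr, -h))
    numeric_ <- (up - dn) / (2 * h)
    node <- res$grads
    for (k in pr[-length(pr)]) node <- node[[asKey(k)]]
    analytic <- node[as.integer(pr[length(pr)])]
    expect_lt(abs(numeric_ - analytic),
              1e-4 * max(1, abs(numeric_)),
              label = paste("gradient at", paste(pr, collapse = "/")))
  }
})

test_that("a tiny model overfits four tiles", {
  cfg <- tinyConfig(epochs = 20L, lr = 5e-3)
  tiles <- asTileBatch(randomTiles(4, 16, seed = 30))
  model <- trainMAE(tiles, cfg)
  log <- trainingLog(model)
  expect_equal(nrow(log), 20L)
  expect_lt(log$trainLoss[20], 0.5 * log$trainLoss[1])
})

test_that("training loss decreases in most epochs on a small dataset", {
  cfg <- tinyConfig(epochs = 15L, lr = 5e-3)
  tiles <- asTileBatch(randomTiles(8, 16, seed = 31))
  log <- trainingLog(trainMAE(tiles, cfg))
  drops <- diff(log$trainLoss) <= 0
  expect_gte(mean(drops), 0.8)
})

test_that("training is deterministic under fixed seeds", {
  cfg <- tinyConfig(epochs = 3L)
  tiles <- asTileBatch(randomTiles(6, 16, seed = 32))
  a <- trainMAE(tiles, cfg)
  b <- trainMAE(tiles, cfg)
  expect_identical(trainingLog(a)$valLoss, trainingLog(b)$valLoss)
  expect_identical(a@params$patchW, b@params$patchW)
})

test_that("embedding grids have the declared geometry and latent width", {
  cfg <- tinyConfig()
  model <- initMAE(cfg, seed = 9)
  x <- matrix(runif(32 * 32), 32, 32)
  emb <- embedMicrograph(model, x)
  # 32 px / 4 px tokens = 8 grid cells per axis
  expect_equal(dim(embeddingGrid(emb)), c(8L, 8L, 16L))
  expect_equal(stridePx(emb), 4)
  expect_identical(embeddingGrid(embedMicrograph(model, x)),
                   embeddingGrid(emb))
})

test_that("embeddings are translation-consistent at tile granularity", {
  cfg <- tinyConfig()
  model <- initMAE(cfg, seed = 10)
  set.seed(33)
  x <- matrix(runif(32 * 32), 32, 32)
  # swap the two top tiles (each 16 x 16)
  y <- x
  y[1:16, 1:16] <- x[1:16, 17:32]
  y[1:16, 17:32] <- x[1:16, 1:16]
  ex <- embeddingGrid(embedMicrograph(model, x))
  ey <- embeddingGrid(embedMicrograph(model, y))
  expect_equal(ey[1:4, 1:4, ], ex[1:4, 5:8, ], tolerance = 1e-12)
  expect_equal(ey[1:4, 5:8, ], ex[1:4, 1:4, ], tolerance = 1e-12)
  expect_equal(ey[5:8, , ], ex[5:8, , ], tolerance = 1e-12)
})

test_that("non-finite losses abort training with the epoch index", {
  tiles <- randomTiles(6, 16, seed = 34)
  tiles[[3]][5, 5] <- NaN
  expect_error(trainMAE(asTileBatch(tiles), tinyConfig(epochs = 3L)),
               "epoch")
})
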