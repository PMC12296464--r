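# Shared fixtures. The desk-scale benchmark (5 training + 5 held-out
# synthetic micrographs, 256 px, 24-px particles at ~4% area, contrast 3.5)
# and the picker trained on it are built once per test run and cached.

.fixtureCache <- new.env(parent = emptyenv())

deskSpec <- function() {
  syntheticSpec(imageSize = c(256L, 256L), nParticles = 6L,
                diameterPx = 24, contrast = 3.5)
}

deskTrainSet <- function() {
  if (is.null(.fixtureCache$train))
    .fixtureCache$train <- generateDataset(deskSpec(), 5L, baseSeed = 11L)
  .fixtureCache$train
}

deskTestSet <- function() {
  if (is.null(.fixtureCache$test))
    .fixtureCache$test <- generateDataset(deskSpec(), 5L, baseSeed = 22L)
  .fixtureCache$test
}

deskPicker <- function() {
  if (is.null(.fixtureCache$picker)) {
    .fixtureCache$picker <- trainPicker(deskTrainSet(), diameterPx = 24,
                                        cfg = deskProfile())
  }
  .fixtureCache$picker
}

# A tiny architecture for fast optimization/gradient tests.
tinyConfig <- function(...) {
  defaults <- list(workingSize = 32L, tileSize = 16L, tokenSize = 4L,
                   embedDim = 16L, encoderDepth = 1L, encoderHeads = 2L,
                   decoderDim = 8L, decoderDepth = 1L, mlpRatio = 2,
                   epochs = 5L, batchSize = 4L, lr = 1e-3)
  overrides <- list(...)
  defaults[names(overrides)] <- overrides
  do.call(runConfig, defaults)
}

# Smooth low-frequency tiles (learnable by masked reconstruction, unlike
# pure noise whose masked tokens carry irreducible error).
randomTiles <- function(n, tileSize, seed = 1, noise = 0.02) {
  set.seed(seed)
  g <- seq(0, 2 * pi, length.out = tileSize)
  lapply(seq_len(n), function(i) {
    a <- runif(3, 0.5, 2)
    ph <- runif(2, 0, 2 * pi)
    0.5 + 0.25 * outer(sin(a[1] * g + ph[1]), cos(a[2] * g + ph[2])) +
      matrix(rnorm(tileSize^2, sd = noise), tileSize, tileSize)
  })
}

asTileBatch <- function(tiles) {
  structure(list(tiles = tiles,
                 gridIndex = cbind(seq_along(tiles) - 1L, 0L),
                 tileSize = nrow(tiles[[1]]), sourceId = "fixture",
                 imageShape = c(nrow(tiles[[1]]) * length(tiles),
                                ncol(tiles[[1]]))),
            class = "TileBatch")
}
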