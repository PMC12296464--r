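## Tiling, per-tile random masking, the reconstruction objective and
## latent-map extraction.

#' Tile a working-resolution micrograph
#'
#' Cuts the image into non-overlapping `tileSize x tileSize` tiles in
#' row-major order. At the full-scale defaults (1024-px working images,
#' 64-px tiles) this yields 256 tiles per micrograph. The tiling is an
#' exact partition: [untileMicrograph()] inverts it bit-for-bit.
#'
#' @param x a working-resolution [Micrograph-class] or numeric matrix whose
#'   sides are divisible by `tileSize`.
#' @param tileSize tile side in pixels.
#' @return A `TileBatch`: list with `tiles` (list of matrices), `gridIndex`
#'   (n x 2 matrix of 0-based tile row/col), `tileSize`, `sourceId`,
#'   `imageShape`.
#' @examples
#' tb <- tileMicrograph(matrix(rnorm(128 * 128), 128, 128), 64)
#' length(tb$tiles)  # 4
#' @export
tileMicrograph <- function(x, tileSize) {
  px <- asPixels(x)
  sh <- dim(px)
  if (any(sh %% tileSize != 0))
    stop("contract violation: image shape ", sh[1], " x ", sh[2],
         " not divisible by tile size ", tileSize)
  nr <- sh[1] %/% tileSize
  nc <- sh[2] %/% tileSize
  tiles <- vector("list", nr * nc)
  gridIndex <- matrix(0L, nr * nc, 2L)
  k <- 0L
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      k <- k + 1L
      tiles[[k]] <- px[((i - 1L) * tileSize + 1L):(i * tileSize),
                       ((j - 1L) * tileSize + 1L):(j * tileSize)]
      gridIndex[k, ] <- c(i - 1L, j - 1L)
    }
  }
  structure(
    list(tiles = tiles, gridIndex = gridIndex, tileSize = tileSize,
         sourceId = if (is(x, "Micrograph")) x@id else "matrix",
         imageShape = sh),
    class = "TileBatch"
  )
}

#' Reassemble a micrograph from its tiles
#'
#' @param tb a `TileBatch` from [tileMicrograph()].
#' @return The reassembled numeric matrix.
#' @export
untileMicrograph <- function(tb) {
  stopifnot(inherits(tb, "TileBatch"))
  ts <- tb$tileSize
  out <- matrix(0, tb$imageShape[1], tb$imageShape[2])
  for (k in seq_along(tb$tiles)) {
    i <- tb$gridIndex[k, 1]; j <- tb$gridIndex[k, 2]
    out[(i * ts + 1L):((i + 1L) * ts),
        (j * ts + 1L):((j + 1L) * ts)] <- tb$tiles[[k]]
  }
  out
}

#' Sample a per-tile mask pattern
#'
#' Draws exactly `round(ratio * tokenCount)` masked tokens uniformly at
#' random without replacement. Patterns are drawn independently per tile by
#' the training loop, which spreads the masking evenly across the
#' micrograph.
#'
#' @param tokenCount number of tokens in a tile.
#' @param ratio masking ratio in (0, 1).
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used (the training loop seeds it once).
#' @return Logical vector of length `tokenCount`, `TRUE` = masked.
#' @examples
#' sum(sampleMask(64, 0.5, seed = 1))  # exactly 32
#' @export
sampleMask <- function(tokenCount, ratio, seed = NULL) {
  stopifnot(ratio > 0, ratio < 1)
  if (!is.null(seed)) set.seed(seed)
  nMask <- round(ratio * tokenCount)
  masked <- rep(FALSE, tokenCount)
  masked[sample.int(tokenCount, nMask)] <- TRUE
  masked
}

#' Masked reconstruction loss
#'
#' Mean squared error between original and reconstructed tile tokens,
#' averaged over the pixels of the masked tokens only (the standard
#' masked-autoencoder objective).
#'
#' @param y `tokenCount x tokenPixels` matrix of original token pixels.
#' @param yhat reconstruction, same shape.
#' @param mask logical vector, `TRUE` = masked token.
#' @return The scalar loss.
#' @export
reconstructionLoss <- function(y, yhat, mask) {
  stopifnot(all(dim(y) == dim(yhat)), length(mask) == nrow(y))
  if (!any(mask)) stop("contract violation: empty mask")
  d <- y[mask, , drop = FALSE] - yhat[mask, , drop = FALSE]
  mean(d^2)
}

#' Extract the latent embedding map of a micrograph
#'
#' Runs the encoder over every token of every tile (no masking at
#' inference) and arranges the latent vectors on a spatial grid: the vector
#' of token (r, c) of tile (i, j) lands at grid position
#' `(i * tokensPerSide + r, j * tokensPerSide + c)`. At the full-scale
#' defaults the grid is 128 x 128 with an 8-px stride, each cell a 192-d
#' vector.
#'
#' @param model a trained [MAEModel-class].
#' @param x a working-resolution [Micrograph-class] or matrix.
#' @return An [EmbeddingMap-class].
#' @export
embedMicrograph <- function(model, x) {
  arch <- model@arch
  px <- asPixels(x)
  if (any(dim(px) %% arch$tileSize != 0))
    stop("contract violation: image shape not divisible by the model's ",
         "tile size ", arch$tileSize)
  tb <- tileMicrograph(px, arch$tileSize)
  B <- length(tb$tiles)
  tokens <- do.call(rbind, lapply(tb$tiles, tokenizeTile, arch$tokenSize))
  lat <- maeEncode(model@params, arch, tokens, B)
  tps <- arch$tokensPerSide
  He <- (dim(px)[1] %/% arch$tileSize) * tps
  We <- (dim(px)[2] %/% arch$tileSize) * tps
  grid <- array(0, c(He, We, arch$embedDim))
  for (k in seq_len(B)) {
    i0 <- tb$gridIndex[k, 1] * tps
    j0 <- tb$gridIndex[k, 2] * tps
    rows <- ((k - 1L) * arch$tokenCount + 1L):(k * arch$tokenCount)
    tileLat <- lat[rows, , drop = FALSE]
    for (r in seq_len(tps)) {
      idx <- ((r - 1L) * tps + 1L):(r * tps)
      grid[i0 + r, (j0 + 1L):(j0 + tps), ] <- tileLat[idx, , drop = FALSE]
    }
  }
  EmbeddingMap(grid, stridePx = arch$tokenSize,
               sourceId = if (is(x, "Micrograph")) x@id else "matrix")
}
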