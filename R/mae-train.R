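## Training loop: AdamW with cosine learning-rate decay and linear
## warm-up, per-epoch train/validation reconstruction loss, and
## checkpoint selection by lowest validation loss (a label-free criterion).

## Recursive traversal of the nested parameter list; parallel lists are
## matched by name where names exist (gradient lists may order fields
## differently than the parameter list).
mapParams <- function(f, ...) {
  args <- list(...)
  p1 <- args[[1]]
  if (is.list(p1)) {
    out <- vector("list", length(p1))
    names(out) <- names(p1)
    for (i in seq_along(p1)) {
      key <- if (!is.null(names(p1)) && nzchar(names(p1)[i]))
        names(p1)[i] else i
      out[[i]] <- do.call(mapParams, c(list(f), lapply(args, `[[`, key)))
    }
    out
  } else {
    do.call(f, args)
  }
}

zerosLike <- function(params) mapParams(function(p) p * 0, params)

## One AdamW update, in place on the state environment.
adamwUpdate <- function(st, grads, lr, beta1 = 0.9, beta2 = 0.95,
                        eps = 1e-8, weightDecay = 0.05) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  st$m <- mapParams(function(m, g) beta1 * m + (1 - beta1) * g, st$m, grads)
  st$v <- mapParams(function(v, g) beta2 * v + (1 - beta2) * g^2,
                    st$v, grads)
  st$params <- mapParams(function(p, m, v) {
    upd <- (m / bc1) / (sqrt(v / bc2) + eps)
    # decouple weight decay; applied to weight matrices only
    if (is.matrix(p)) p - lr * (upd + weightDecay * p) else p - lr * upd
  }, st$params, st$m, st$v)
  invisible(st)
}

cosineLR <- function(step, totalSteps, peak, warmupFrac = 0.05) {
  warm <- max(1, round(warmupFrac * totalSteps))
  if (step <= warm) return(peak * step / warm)
  frac <- (step - warm) / max(1, totalSteps - warm)
  peak * 0.5 * (1 + cos(pi * min(frac, 1)))
}

#' Train a masked autoencoder on micrograph tiles
#'
#' Trains the transformer masked autoencoder by reconstruction only. The
#' tile set is split into training and validation parts (`valFrac`,
#' seeded); every epoch draws fresh independent per-tile mask patterns for
#' the training tiles, while the validation masks are drawn once so that
#' validation losses are comparable across epochs. The returned model is
#' the checkpoint with the lowest validation reconstruction loss and
#' carries the full per-epoch loss log.
#'
#' @param tiles a `TileBatch` (or list of them, one per micrograph) from
#'   [tileMicrograph()].
#' @param cfg a `RunConfig`; `epochs`, `batchSize`, `lr`, `maskRatio`,
#'   `valFrac` and the seeds are honoured.
#' @param verbose print a line per epoch.
#' @return A trained [MAEModel-class].
#' @export
trainMAE <- function(tiles, cfg = runConfig(), verbose = FALSE) {
  if (inherits(tiles, "TileBatch")) tiles <- list(tiles)
  stopifnot(length(tiles) >= 1)
  allTiles <- unlist(lapply(tiles, `[[`, "tiles"), recursive = FALSE)
  n <- length(allTiles)
  model <- initMAE(cfg)
  arch <- model@arch
  if (any(vapply(allTiles, nrow, integer(1)) != arch$tileSize))
    stop("contract violation: tile size does not match the configuration")
  tokens <- lapply(allTiles, tokenizeTile, arch$tokenSize)

  set.seed(cfg$maskSeed)
  nVal <- max(1L, round(cfg$valFrac * n))
  if (nVal >= n) nVal <- n - 1L
  valIdx <- sort(sample.int(n, nVal))
  trainIdx <- setdiff(seq_len(n), valIdx)
  valMasks <- t(vapply(valIdx, function(i)
    sampleMask(arch$tokenCount, cfg$maskRatio),
    logical(arch$tokenCount)))
  valTokens <- do.call(rbind, tokens[valIdx])

  st <- new.env(parent = emptyenv())
  st$params <- model@params
  st$m <- zerosLike(model@params)
  st$v <- zerosLike(model@params)
  st$t <- 0L

  stepsPerEpoch <- max(1L, ceiling(length(trainIdx) / cfg$batchSize))
  totalSteps <- stepsPerEpoch * cfg$epochs
  bestVal <- Inf
  bestParams <- st$params
  log <- data.frame(epoch = integer(0), trainLoss = numeric(0),
                    valLoss = numeric(0))
  step <- 0L
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample(trainIdx)
    epLoss <- 0
    nb <- 0L
    for (b0 in seq(1L, length(ord), by = cfg$batchSize)) {
      idx <- ord[b0:min(b0 + cfg$batchSize - 1L, length(ord))]
      masks <- t(vapply(idx, function(i)
        sampleMask(arch$tokenCount, cfg$maskRatio),
        logical(arch$tokenCount)))
      batch <- do.call(rbind, tokens[idx])
      step <- step + 1L
      res <- tryCatch(
        maeStep(st$params, arch, batch, masks),
        error = function(e)
          stop("training error at epoch ", ep, ": ", conditionMessage(e))
      )
      lr <- cosineLR(step, totalSteps, cfg$lr)
      adamwUpdate(st, res$grads, lr, weightDecay = cfg$weightDecay)
      epLoss <- epLoss + res$loss
      nb <- nb + 1L
    }
    valLoss <- maeStep(st$params, arch, valTokens, valMasks,
                       computeGrads = FALSE)$loss
    log <- rbind(log, data.frame(epoch = ep, trainLoss = epLoss / nb,
                                 valLoss = valLoss))
    if (valLoss < bestVal) {
      bestVal <- valLoss
      bestParams <- st$params
    }
    if (verbose)
      message(sprintf("epoch %3d  train %.6f  val %.6f", ep,
                      epLoss / nb, valLoss))
  }
  new("MAEModel", params = bestParams, arch = arch, trainingLog = log,
      seeds = c(train = cfg$trainSeed, mask = cfg$maskSeed))
}
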