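#' Pipeline run configuration
#'
#' Builds the validated list of tunable parameters used across the pipeline.
#' Defaults correspond to the full-scale operating point: micrographs resized
#' to 1024 x 1024, tiled into 64 x 64 images (256 per micrograph), 8 x 8
#' pixel tokens, 192-d latents, 50% masking, 400 training epochs, a 4%
#' particle-area target for adaptive thresholding and hierarchical cluster
#' refinement up to k = 5.
#'
#' @param workingSize working image size in pixels (square), divisible by
#'   `tileSize`.
#' @param tileSize side of the square tiles fed to the autoencoder.
#' @param tokenSize side of the square pixel tokens within a tile;
#'   `tileSize` must be divisible by it.
#' @param maskRatio fraction of tokens masked per tile during training.
#' @param embedDim encoder latent width.
#' @param encoderDepth,encoderHeads transformer encoder depth and head count.
#' @param decoderDim,decoderDepth decoder width and depth.
#' @param mlpRatio hidden/width ratio of the transformer MLP blocks.
#' @param epochs training epochs.
#' @param batchSize tiles per optimization step.
#' @param lr peak AdamW learning rate (cosine decay, 5% warm-up).
#' @param weightDecay AdamW weight decay.
#' @param valFrac fraction of tiles held out for validation-loss checkpoint
#'   selection.
#' @param targetFraction particle area fraction targeted by adaptive
#'   thresholding.
#' @param nThresholds number of evenly spaced candidate thresholds in [0, 1].
#' @param maxIters final cluster count of the micrograph-specific
#'   hierarchical refinement (levels k = 3 .. maxIters).
#' @param kTrain cluster count of the train-set k-means.
#' @param radiusFactor particles with radius above
#'   `radiusFactor * diameter/2` are discarded.
#' @param borderMarginPx border exclusion margin in working-frame px
#'   (`NA` = half the particle diameter).
#' @param wienerWindow window side of the adaptive Wiener filter.
#' @param claheClip,claheTiles CLAHE clip limit and tile grid.
#' @param guidedEps guided-filter regularization.
#' @param latentCap maximum number of pooled training latents used for the
#'   train-set k-means (uniform seeded subsample above the cap).
#' @param trainSeed,clusterSeed,maskSeed seeds for parameter initialization /
#'   clustering / masking.
#' @return A named list of class `RunConfig`.
#' @examples
#' cfg <- runConfig()
#' cfg$workingSize / cfg$tileSize  # tiles per axis
#' @export
runConfig <- function(workingSize = 1024L, tileSize = 64L, tokenSize = 8L,
                      maskRatio = 0.5, embedDim = 192L,
                      encoderDepth = 6L, encoderHeads = 3L,
                      decoderDim = 96L, decoderDepth = 2L, mlpRatio = 4,
                      epochs = 400L, batchSize = 64L, lr = 1.5e-4,
                      weightDecay = 0.05, valFrac = 0.2,
                      targetFraction = 0.04, nThresholds = 101L,
                      maxIters = 5L, kTrain = 4L, radiusFactor = 1.5,
                      borderMarginPx = NA_real_,
                      wienerWindow = 5L, claheClip = 2, claheTiles = 8L,
                      guidedEps = 1e-2, latentCap = 200000L,
                      trainSeed = 1L, clusterSeed = 2L, maskSeed = 3L) {
  cfg <- list(
    workingSize = as.integer(workingSize), tileSize = as.integer(tileSize),
    tokenSize = as.integer(tokenSize), maskRatio = maskRatio,
    embedDim = as.integer(embedDim), encoderDepth = as.integer(encoderDepth),
    encoderHeads = as.integer(encoderHeads),
    decoderDim = as.integer(decoderDim),
    decoderDepth = as.integer(decoderDepth), mlpRatio = mlpRatio,
    epochs = as.integer(epochs), batchSize = as.integer(batchSize),
    lr = lr, weightDecay = weightDecay, valFrac = valFrac,
    targetFraction = targetFraction, nThresholds = as.integer(nThresholds),
    maxIters = as.integer(maxIters), kTrain = as.integer(kTrain),
    radiusFactor = radiusFactor, borderMarginPx = borderMarginPx,
    wienerWindow = as.integer(wienerWindow), claheClip = claheClip,
    claheTiles = as.integer(claheTiles), guidedEps = guidedEps,
    latentCap = as.integer(latentCap),
    trainSeed = as.integer(trainSeed), clusterSeed = as.integer(clusterSeed),
    maskSeed = as.integer(maskSeed)
  )
  class(cfg) <- "RunConfig"
  validateRunConfig(cfg)
  cfg
}

validateRunConfig <- function(cfg) {
  stopifnot(
    "workingSize must be divisible by tileSize" =
      cfg$workingSize %% cfg$tileSize == 0L,
    "tileSize must be divisible by tokenSize" =
      cfg$tileSize %% cfg$tokenSize == 0L,
    "maskRatio must lie in (0, 1)" =
      cfg$maskRatio > 0 && cfg$maskRatio < 1,
    "targetFraction must lie in (0, 1)" =
      cfg$targetFraction > 0 && cfg$targetFraction < 1,
    "maxIters must be at least 3" = cfg$maxIters >= 3L,
    "embedDim must be divisible by encoderHeads" =
      cfg$embedDim %% cfg$encoderHeads == 0L,
    "radiusFactor must exceed 1" = cfg$radiusFactor > 1,
    "epochs must be positive" = cfg$epochs >= 1L
  )
  invisible(cfg)
}

#' Desk-scale configuration profile
#'
#' A reduced operating point sized for a single CPU: 256 x 256 working
#' images, 32 x 32 tiles (64 per micrograph), 8 x 8 tokens, a 3-block
#' encoder and 30 epochs. All other semantics (masking, latent width,
#' clustering, post-processing) are unchanged from [runConfig()].
#'
#' @param ... overrides passed on to [runConfig()].
#' @return A `RunConfig` list.
#' @export
deskProfile <- function(...) {
  defaults <- list(workingSize = 256L, tileSize = 32L, tokenSize = 8L,
                   epochs = 30L, encoderDepth = 3L, batchSize = 64L)
  overrides <- list(...)
  defaults[names(overrides)] <- overrides
  do.call(runConfig, defaults)
}

#' Read a run configuration from a YAML or JSON file
#'
#' Unknown keys are rejected; missing keys take their defaults.
#'
#' @param path file path, `.yaml`/`.yml` or `.json`.
#' @return A `RunConfig` list.
#' @export
readRunConfig <- function(path) {
  stopifnot(file.exists(path))
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(runConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config fields: ", paste(bad, collapse = ", "))
  do.call(runConfig, vals)
}

#' Write a run configuration to YAML
#'
#' @param cfg a `RunConfig` list.
#' @param path destination path.
#' @export
writeRunConfig <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
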