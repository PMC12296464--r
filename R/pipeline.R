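## Orchestration: train / pick / eval / simulate over the other modules.

#' PickerModel: trained pipeline artifacts
#'
#' Bundles the trained masked autoencoder, the train-set cluster model,
#' the configuration and a run manifest (seeds, tile counts, timings)
#' sufficient to re-run picking reproducibly.
#'
#' @slot mae trained [MAEModel-class].
#' @slot clusters [ReferenceClusterModel-class].
#' @slot cfg the `RunConfig` used.
#' @slot diameterPx particle diameter in original-frame pixels.
#' @slot manifest named list (seeds, nTiles, timings, versions).
#' @exportClass PickerModel
setClass("PickerModel",
  representation(mae = "MAEModel", clusters = "ReferenceClusterModel",
                 cfg = "list", diameterPx = "numeric", manifest = "list")
)

setMethod("show", "PickerModel", function(object) {
  cat(sprintf(
    "PickerModel: diameter %.1f px (original frame), working size %d\n",
    object@diameterPx, object@cfg$workingSize))
  cat(sprintf("  trained on %d tiles from %d micrographs\n",
              object@manifest$nTiles, object@manifest$nMicrographs))
  show(object@mae)
  show(object@clusters)
})

asMicrograph <- function(x, i = 1L) {
  if (is(x, "SyntheticSample")) x@micrograph
  else if (is(x, "Micrograph")) x
  else if (is.matrix(x)) Micrograph(x, id = sprintf("micrograph-%d", i))
  else if (is.character(x)) readMRC(x)
  else stop("cannot interpret input as a micrograph")
}

#' Train the particle-picking pipeline
#'
#' Preprocesses the training micrographs, tiles them, trains the masked
#' autoencoder, embeds the training set, and fits the train-set cluster
#' model anchored by the reference micrograph's particle mask
#' (Algorithm: train-set clustering). The first micrograph is the
#' reference by default; for [SyntheticSample-class] inputs its
#' ground-truth mask is used automatically.
#'
#' @param micrographs list of [Micrograph-class], [SyntheticSample-class],
#'   matrices, or MRC file paths.
#' @param diameterPx particle diameter in original-frame pixels.
#' @param cfg a `RunConfig`.
#' @param refMask binary original-frame particle mask of the reference
#'   micrograph; required unless the reference is a
#'   [SyntheticSample-class].
#' @param refIndex index of the reference micrograph.
#' @param verbose print progress.
#' @return A [PickerModel-class].
#' @export
trainPicker <- function(micrographs, diameterPx, cfg = runConfig(),
                        refMask = NULL, refIndex = 1L, verbose = FALSE) {
  stopifnot(length(micrographs) >= 1)
  if (is.null(refMask)) {
    if (is(micrographs[[refIndex]], "SyntheticSample"))
      refMask <- particleMask(micrographs[[refIndex]])
    else
      stop("configuration error: no reference mask provided and the ",
           "reference micrograph carries none")
  }
  t0 <- proc.time()[["elapsed"]]
  mics <- lapply(seq_along(micrographs), function(i)
    asMicrograph(micrographs[[i]], i))
  work <- lapply(mics, preprocessMicrograph, diameterPx = diameterPx,
                 cfg = cfg)
  tiles <- lapply(work, tileMicrograph, tileSize = cfg$tileSize)
  nTiles <- sum(vapply(tiles, function(t) length(t$tiles), integer(1)))
  tPrep <- proc.time()[["elapsed"]]
  if (verbose) message("preprocessed ", length(mics), " micrographs (",
                       nTiles, " tiles)")
  mae <- trainMAE(tiles, cfg, verbose = verbose)
  tTrain <- proc.time()[["elapsed"]]
  embs <- lapply(work, function(w) embedMicrograph(mae, w))
  refMaskWork <- resizeMaskToWorking(refMask, cfg$workingSize)
  clusters <- fitReferenceClusters(embs, embs[[refIndex]], refMaskWork, cfg)
  tEnd <- proc.time()[["elapsed"]]
  manifest <- list(
    nMicrographs = length(mics), nTiles = nTiles,
    diameterPx = diameterPx,
    seeds = c(train = cfg$trainSeed, cluster = cfg$clusterSeed,
              mask = cfg$maskSeed),
    timings = c(preprocess = tPrep - t0, train = tTrain - tPrep,
                cluster = tEnd - tTrain),
    rVersion = as.character(getRversion())
  )
  new("PickerModel", mae = mae, clusters = clusters, cfg = unclass(cfg),
      diameterPx = diameterPx, manifest = manifest)
}

resizeMaskToWorking <- function(mask, workingSize) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  if (all(dim(m) == workingSize)) return(m >= 0.5)
  as.matrix(EBImage::resize(m, w = workingSize, h = workingSize,
                            filter = "bilinear")) >= 0.5
}

#' Pick particles in micrographs
#'
#' Runs the full inference chain per micrograph: preprocess, embed,
#' initial assignment against the train-set clusters, micrograph-specific
#' hierarchical refinement, 3 x 3 smoothing, bilinear upsampling, adaptive
#' thresholding toward the target area fraction, 8-connected component
#' extraction, the size/border/neighbour filters, and mapping back to the
#' original frame. Deterministic for fixed seeds.
#'
#' @param picker a [PickerModel-class].
#' @param micrographs list of [Micrograph-class], [SyntheticSample-class],
#'   matrices or MRC paths.
#' @param maxIters final cluster count of the hierarchical refinement
#'   (default from the configuration; exposed for precision/recall
#'   trade-off studies).
#' @param outDir optional directory; when given, one STAR file per
#'   micrograph is written.
#' @param verbose print progress.
#' @return Named list of original-frame [ParticleSet-class] objects.
#' @export
pickParticles <- function(picker, micrographs, maxIters = NULL,
                          outDir = NULL, verbose = FALSE) {
  stopifnot(is(picker, "PickerModel"))
  cfg <- picker@cfg
  if (is.null(maxIters)) maxIters <- cfg$maxIters
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  out <- vector("list", length(micrographs))
  ids <- character(length(micrographs))
  for (i in seq_along(micrographs)) {
    mic <- asMicrograph(micrographs[[i]], i)
    ids[i] <- micrographId(mic)
    res <- tryCatch(
      pickOne(picker, mic, maxIters),
      error = function(e) {
        warning("picking failed for '", micrographId(mic), "': ",
                conditionMessage(e))
        NULL
      }
    )
    out[[i]] <- res
    if (!is.null(res) && !is.null(outDir))
      writeCoords(res, file.path(outDir, paste0(ids[i], ".star")))
    if (verbose && !is.null(res))
      message(ids[i], ": ", nParticles(res), " particles")
  }
  if (all(vapply(out, is.null, logical(1))))
    stop("picking failed for all micrographs")
  names(out) <- ids
  out
}

pickOne <- function(picker, mic, maxIters) {
  cfg <- picker@cfg
  work <- preprocessMicrograph(mic, picker@diameterPx, cfg)
  emb <- embedMicrograph(picker@mae, work)
  state <- assignInitial(emb, picker@clusters)
  gridMask <- withCallingHandlers(
    hierarchicalRefine(emb, state, seed = cfg$clusterSeed,
                       maxIters = maxIters),
    warning = function(w) invokeRestart("muffleWarning")
  )
  pm <- smoothMask(gridMask, stridePx = stridePx(emb))
  up <- upsampleMap(pm, cfg$workingSize)
  thr <- withCallingHandlers(
    selectThreshold(up, cfg$targetFraction, cfg$nThresholds),
    warning = function(w) invokeRestart("muffleWarning")
  )
  binary <- up$values >= thr
  cand <- extractParticles(binary, scoreMap = up)
  dWork <- diameterWorking(picker@diameterPx, work)
  kept <- filterParticles(cand, dWork, dim(up$values),
                          radiusFactor = cfg$radiusFactor,
                          borderMarginPx = cfg$borderMarginPx)
  mapToOriginal(kept, work)
}

#' Evaluate picked particles against ground truth
#'
#' Per-micrograph detection metrics via [matchAndScore()] plus the
#' unweighted aggregate across micrographs. Predictions and ground truth
#' are matched by name; unmatched ids are excluded with a warning.
#'
#' @param preds named list of predicted [ParticleSet-class] objects.
#' @param gts named list of ground-truth [ParticleSet-class] objects (for
#'   [SyntheticSample-class] inputs, pass `lapply(x, groundTruth)`).
#' @param diameterPx particle diameter in the sets' frame.
#' @param tpIoU true-positive IoU threshold.
#' @return list with `perMicrograph` (data.frame) and `aggregate` (list).
#' @export
evaluatePicks <- function(preds, gts, diameterPx, tpIoU = 0.6) {
  if (is.null(names(preds)) || is.null(names(gts))) {
    stopifnot(length(preds) == length(gts))
    names(preds) <- names(gts) <- sprintf("m%03d", seq_along(preds))
  }
  common <- intersect(names(preds), names(gts))
  missing <- setdiff(union(names(preds), names(gts)), common)
  if (length(missing))
    warning("unmatched micrograph ids excluded: ",
            paste(missing, collapse = ", "))
  stopifnot(length(common) > 0)
  common <- sort(common)
  rows <- lapply(common, function(id) {
    m <- matchAndScore(preds[[id]], gts[[id]], diameterPx, tpIoU)
    data.frame(id = id, nPred = nParticles(preds[[id]]),
               nGt = nParticles(gts[[id]]), tp = m$tp,
               iou = m$metrics$iou, precision = m$metrics$precision,
               recall = m$metrics$recall, f1 = m$metrics$f1)
  })
  per <- do.call(rbind, rows)
  list(perMicrograph = per,
       aggregate = aggregateMetrics(per[, c("iou", "precision", "recall",
                                            "f1")]))
}

#' Write a synthetic dataset to disk
#'
#' Generates `nMicrographs` seeded synthetic samples and writes each as an
#' MRC micrograph plus a STAR ground-truth coordinate file (and the
#' reference mask of the first sample as MRC), so the fixtures are
#' consumable by the ordinary file-based workflow.
#'
#' @param outDir output directory (created if needed).
#' @param spec a `SyntheticSpec`.
#' @param nMicrographs number of micrographs.
#' @param baseSeed base seed for per-micrograph seed derivation.
#' @return The list of [SyntheticSample-class] objects, invisibly.
#' @export
simulateDataset <- function(outDir, spec = syntheticSpec(),
                            nMicrographs = 5L, baseSeed = 1L) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  samples <- generateDataset(spec, nMicrographs, baseSeed)
  for (s in samples) {
    id <- micrographId(micrograph(s))
    writeMRC(micrograph(s), file.path(outDir, paste0(id, ".mrc")))
    writeCoords(groundTruth(s), file.path(outDir, paste0(id, ".star")))
  }
  writeMRC(matrix(as.numeric(particleMask(samples[[1]])),
                  nrow(particleMask(samples[[1]]))),
           file.path(outDir, "reference_mask.mrc"))
  invisible(samples)
}

#' Save / load a trained picker
#'
#' @param picker a [PickerModel-class].
#' @param path destination `.rds` path.
#' @return `path` / the restored [PickerModel-class].
#' @export
savePicker <- function(picker, path) {
  stopifnot(is(picker, "PickerModel"))
  saveRDS(picker, path)
  invisible(path)
}

#' @rdname savePicker
#' @export
loadPicker <- function(path) {
  p <- readRDS(path)
  stopifnot(is(p, "PickerModel"))
  p
}
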