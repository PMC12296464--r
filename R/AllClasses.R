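#' @import methods
#' @importFrom stats kmeans rnorm runif sd quantile
#' @importFrom utils head tail
NULL

#' Micrograph: a 2-D cryo-EM image with metadata
#'
#' Container for a single motion-corrected micrograph. Pixels are stored as a
#' numeric matrix in display convention: the first index is the row (y), the
#' second the column (x). `originalShape` keeps the shape the image had when
#' read from disk and `scaleFactors` the per-axis scale applied by
#' [resizeWorking()], so that coordinates picked in the working frame can be
#' mapped back to the original frame.
#'
#' @slot pixels numeric matrix (rows x cols), all values finite.
#' @slot id character identifier (usually the file stem).
#' @slot pixelSizeA pixel size in Angstrom per pixel, or `NA_real_` when
#'   unknown.
#' @slot originalShape integer vector (rows, cols) of the as-read image.
#' @slot scaleFactors numeric vector (rowScale, colScale); `c(1, 1)` until a
#'   resize is applied. A value of 0.25 means the working image is 4x smaller
#'   than the original along that axis.
#' @exportClass Micrograph
setClass("Micrograph",
  representation(
    pixels = "matrix",
    id = "character",
    pixelSizeA = "numeric",
    originalShape = "integer",
    scaleFactors = "numeric"
  ),
  prototype(
    id = "micrograph",
    pixelSizeA = NA_real_,
    scaleFactors = c(1, 1)
  )
)

setValidity("Micrograph", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be a numeric matrix")
  if (!all(is.finite(p))) return("pixels must be finite")
  if (nrow(p) < 64L || ncol(p) < 64L)
    return("micrograph must be at least 64 x 64")
  if (length(object@originalShape) != 2L)
    return("originalShape must have length 2")
  if (length(object@scaleFactors) != 2L || any(object@scaleFactors <= 0))
    return("scaleFactors must be two positive numbers")
  TRUE
})

#' Construct a Micrograph
#'
#' @param pixels numeric matrix of pixel values (rows x cols).
#' @param id character identifier.
#' @param pixelSizeA pixel size in Angstrom/px (`NA` if unknown).
#' @param originalShape integer (rows, cols); defaults to `dim(pixels)`.
#' @param scaleFactors per-axis working/original scale; defaults to `c(1, 1)`.
#' @return A [Micrograph-class] object.
#' @examples
#' m <- Micrograph(matrix(rnorm(64 * 64), 64, 64), id = "demo")
#' dim(pixels(m))
#' @export
Micrograph <- function(pixels, id = "micrograph", pixelSizeA = NA_real_,
                       originalShape = dim(pixels),
                       scaleFactors = c(1, 1)) {
  new("Micrograph",
    pixels = pixels, id = id, pixelSizeA = as.numeric(pixelSizeA),
    originalShape = as.integer(originalShape),
    scaleFactors = as.numeric(scaleFactors)
  )
}

#' ParticleSet: particle coordinates in a declared frame
#'
#' Particle centers are 0-based (x = column index, y = row index, origin at
#' the top-left pixel), the convention used pipeline-wide and written to
#' STAR/box files. `frame` declares whether coordinates live in the original
#' micrograph frame or the resized working frame.
#'
#' @slot centers numeric n x 2 matrix, columns `x`, `y` (0-based).
#' @slot radii numeric vector of per-particle radii in pixels (length n or 0).
#' @slot scores numeric vector of per-particle scores (length n or 0).
#' @slot frame `"original"` or `"working"`.
#' @exportClass ParticleSet
setClass("ParticleSet",
  representation(
    centers = "matrix",
    radii = "numeric",
    scores = "numeric",
    frame = "character"
  ),
  prototype(frame = "original")
)

setValidity("ParticleSet", function(object) {
  ctr <- object@centers
  if (ncol(ctr) != 2L) return("centers must have two columns (x, y)")
  if (nrow(ctr) > 0 && !all(is.finite(ctr))) return("centers must be finite")
  if (!object@frame %in% c("original", "working"))
    return("frame must be 'original' or 'working'")
  n <- nrow(ctr)
  if (length(object@radii) && length(object@radii) != n)
    return("radii must be empty or have one entry per particle")
  if (length(object@radii) && any(object@radii <= 0))
    return("radii must be positive")
  if (length(object@scores) && length(object@scores) != n)
    return("scores must be empty or have one entry per particle")
  TRUE
})

#' Construct a ParticleSet
#'
#' @param centers n x 2 matrix (or data.frame) of 0-based (x, y) centers.
#' @param radii optional per-particle radii in pixels.
#' @param scores optional per-particle scores.
#' @param frame `"original"` (default) or `"working"`.
#' @return A [ParticleSet-class] object.
#' @examples
#' ps <- ParticleSet(cbind(x = c(100, 200), y = c(50, 80)))
#' nParticles(ps)
#' @export
ParticleSet <- function(centers = matrix(numeric(0), 0, 2),
                        radii = numeric(0), scores = numeric(0),
                        frame = "original") {
  centers <- as.matrix(centers)
  if (length(centers) == 0L) centers <- matrix(numeric(0), 0, 2)
  storage.mode(centers) <- "double"
  dimnames(centers) <- list(NULL, c("x", "y"))
  new("ParticleSet",
    centers = centers, radii = as.numeric(radii),
    scores = as.numeric(scores), frame = frame
  )
}

#' EmbeddingMap: spatial grid of MAE latent vectors
#'
#' The per-token latent representations of one micrograph, arranged on a grid
#' aligned with working-frame pixels: grid cell (i, j) covers the
#' `stridePx` x `stridePx` pixel block starting at working-frame row
#' `(i-1) * stridePx`, column `(j-1) * stridePx`.
#'
#' @slot grid numeric 3-D array `H x W x D` of latent vectors.
#' @slot stridePx footprint of one grid cell in working-frame pixels.
#' @slot sourceId id of the source micrograph.
#' @exportClass EmbeddingMap
setClass("EmbeddingMap",
  representation(grid = "array", stridePx = "numeric", sourceId = "character"),
  prototype(sourceId = "micrograph")
)

setValidity("EmbeddingMap", function(object) {
  if (length(dim(object@grid)) != 3L) return("grid must be a 3-D array")
  if (!all(is.finite(object@grid))) return("grid values must be finite")
  if (object@stridePx <= 0) return("stridePx must be positive")
  TRUE
})

#' @rdname EmbeddingMap-class
#' @param grid H x W x D array of latent vectors.
#' @param stridePx grid-cell footprint in working-frame pixels.
#' @param sourceId source micrograph id.
#' @export
EmbeddingMap <- function(grid, stridePx, sourceId = "micrograph") {
  new("EmbeddingMap", grid = grid, stridePx = as.numeric(stridePx),
      sourceId = sourceId)
}

#' ReferenceClusterModel: train-set k-means model with the particle cluster
#'
#' The k = 4 cluster centers fitted on latents pooled over the training set,
#' with the index of the cluster identified as "particle" via the reference
#' micrograph's mask. Centers are stored in lexicographic order so the
#' particle index is reproducible.
#'
#' @slot centers k x D numeric matrix of cluster centers.
#' @slot particleId integer in 1..k, the particle cluster (1-based).
#' @slot fitSeed integer seed used for the fit.
#' @exportClass ReferenceClusterModel
setClass("ReferenceClusterModel",
  representation(centers = "matrix", particleId = "integer",
                 fitSeed = "integer")
)

setValidity("ReferenceClusterModel", function(object) {
  k <- nrow(object@centers)
  if (k < 2L) return("need at least two cluster centers")
  if (anyDuplicated(object@centers) > 0)
    return("cluster centers must be pairwise distinct")
  if (object@particleId < 1L || object@particleId > k)
    return("particleId out of range")
  TRUE
})

#' MAEModel: a trained masked autoencoder
#'
#' Wraps the parameter list of the transformer encoder/decoder together with
#' the architectural configuration it was built with and the per-epoch
#' training log.
#'
#' @slot params named list of parameter matrices/vectors.
#' @slot arch named list of architecture fields (tileSize, tokenSize,
#'   embedDim, encoderDepth, encoderHeads, decoderDim, decoderDepth,
#'   mlpRatio).
#' @slot trainingLog data.frame with columns epoch, trainLoss, valLoss.
#' @slot seeds named integer vector of the seeds used.
#' @exportClass MAEModel
setClass("MAEModel",
  representation(params = "list", arch = "list", trainingLog = "data.frame",
                 seeds = "integer")
)

#' SyntheticSample: a generated micrograph with ground truth
#'
#' @slot micrograph the generated [Micrograph-class].
#' @slot gt ground-truth [ParticleSet-class] (original frame).
#' @slot mask binary matrix, union of the particle discs (1 = particle).
#' @exportClass SyntheticSample
setClass("SyntheticSample",
  representation(micrograph = "Micrograph", gt = "ParticleSet",
                 mask = "matrix")
)

## ---- generics and accessors -------------------------------------------

#' @title Accessors
#' @description Accessor generics for the core classes.
#' @param object an object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setMethod("pixels", "Micrograph", function(object) object@pixels)

#' @rdname accessors
#' @export
setGeneric("micrographId", function(object) standardGeneric("micrographId"))
#' @rdname accessors
#' @export
setMethod("micrographId", "Micrograph", function(object) object@id)

#' @rdname accessors
#' @export
setGeneric("scaleFactors", function(object) standardGeneric("scaleFactors"))
#' @rdname accessors
#' @export
setMethod("scaleFactors", "Micrograph", function(object) object@scaleFactors)

#' @rdname accessors
#' @export
setGeneric("originalShape", function(object) standardGeneric("originalShape"))
#' @rdname accessors
#' @export
setMethod("originalShape", "Micrograph", function(object) object@originalShape)

#' @rdname accessors
#' @export
setGeneric("centers", function(object) standardGeneric("centers"))
#' @rdname accessors
#' @export
setMethod("centers", "ParticleSet", function(object) object@centers)
#' @rdname accessors
#' @export
setMethod("centers", "ReferenceClusterModel", function(object) object@centers)

#' @rdname accessors
#' @export
setGeneric("radii", function(object) standardGeneric("radii"))
#' @rdname accessors
#' @export
setMethod("radii", "ParticleSet", function(object) object@radii)

#' @rdname accessors
#' @export
setGeneric("scores", function(object) standardGeneric("scores"))
#' @rdname accessors
#' @export
setMethod("scores", "ParticleSet", function(object) object@scores)

#' @rdname accessors
#' @export
setGeneric("coordFrame", function(object) standardGeneric("coordFrame"))
#' @rdname accessors
#' @export
setMethod("coordFrame", "ParticleSet", function(object) object@frame)

#' @rdname accessors
#' @export
setGeneric("nParticles", function(object) standardGeneric("nParticles"))
#' @rdname accessors
#' @export
setMethod("nParticles", "ParticleSet", function(object) nrow(object@centers))

#' @rdname accessors
#' @export
setGeneric("embeddingGrid", function(object) standardGeneric("embeddingGrid"))
#' @rdname accessors
#' @export
setMethod("embeddingGrid", "EmbeddingMap", function(object) object@grid)

#' @rdname accessors
#' @export
setGeneric("stridePx", function(object) standardGeneric("stridePx"))
#' @rdname accessors
#' @export
setMethod("stridePx", "EmbeddingMap", function(object) object@stridePx)

#' @rdname accessors
#' @export
setGeneric("particleId", function(object) standardGeneric("particleId"))
#' @rdname accessors
#' @export
setMethod("particleId", "ReferenceClusterModel",
          function(object) object@particleId)

#' @rdname accessors
#' @export
setGeneric("trainingLog", function(object) standardGeneric("trainingLog"))
#' @rdname accessors
#' @export
setMethod("trainingLog", "MAEModel", function(object) object@trainingLog)

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))
#' @rdname accessors
#' @export
setMethod("groundTruth", "SyntheticSample", function(object) object@gt)

#' @rdname accessors
#' @export
setGeneric("particleMask", function(object) standardGeneric("particleMask"))
#' @rdname accessors
#' @export
setMethod("particleMask", "SyntheticSample", function(object) object@mask)

#' @rdname accessors
#' @export
setMethod("pixels", "SyntheticSample",
          function(object) object@micrograph@pixels)

#' @rdname accessors
#' @export
setGeneric("micrograph", function(object) standardGeneric("micrograph"))
#' @rdname accessors
#' @export
setMethod("micrograph", "SyntheticSample", function(object) object@micrograph)

## ---- show methods ------------------------------------------------------

setMethod("show", "Micrograph", function(object) {
  d <- dim(object@pixels)
  cat(sprintf(
    "Micrograph '%s': %d x %d px (original %d x %d, scale %.4g/%.4g)\n",
    object@id, d[1], d[2], object@originalShape[1], object@originalShape[2],
    object@scaleFactors[1], object@scaleFactors[2]
  ))
  if (!is.na(object@pixelSizeA))
    cat(sprintf("  pixel size: %.3f A/px\n", object@pixelSizeA))
  cat(sprintf("  intensity range: [%.4g, %.4g]\n",
              min(object@pixels), max(object@pixels)))
})

setMethod("show", "ParticleSet", function(object) {
  cat(sprintf("ParticleSet: %d particles in %s frame\n",
              nrow(object@centers), object@frame))
  if (length(object@radii))
    cat(sprintf("  radii: %.2f-%.2f px\n",
                min(object@radii), max(object@radii)))
})

setMethod("show", "EmbeddingMap", function(object) {
  d <- dim(object@grid)
  cat(sprintf("EmbeddingMap '%s': %d x %d grid of %d-d latents, stride %g px\n",
              object@sourceId, d[1], d[2], d[3], object@stridePx))
})

setMethod("show", "ReferenceClusterModel", function(object) {
  cat(sprintf("ReferenceClusterModel: k = %d centers of width %d, particle cluster #%d\n",
              nrow(object@centers), ncol(object@centers), object@particleId))
})

countParams <- function(p) {
  if (is.list(p)) sum(vapply(p, countParams, numeric(1))) else length(p)
}

setMethod("show", "MAEModel", function(object) {
  a <- object@arch
  np <- countParams(object@params)
  cat(sprintf(
    "MAEModel: tile %d, token %d, latent %d (encoder depth %d/%d heads; decoder %d x depth %d)\n",
    a$tileSize, a$tokenSize, a$embedDim, a$encoderDepth, a$encoderHeads,
    a$decoderDim, a$decoderDepth))
  cat(sprintf("  %d parameters; %d epochs logged\n", np,
              nrow(object@trainingLog)))
  if (nrow(object@trainingLog))
    cat(sprintf("  best val loss: %.6g\n", min(object@trainingLog$valLoss)))
})

setMethod("show", "SyntheticSample", function(object) {
  cat("SyntheticSample:\n  ")
  show(object@micrograph)
  cat(sprintf("  %d ground-truth particles, mask area fraction %.4f\n",
              nrow(object@gt@centers), mean(object@mask)))
})
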