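## Latent-space segmentation. A train-set k-means (k = 4) fitted on latents
## pooled over the training micrographs identifies the particle cluster via
## a reference micrograph's mask; each micrograph is then refined with its
## own hierarchical k-means at k = 3, 4, 5, tracking the particle cluster
## by greatest overlap with the previous level.

## Squared Euclidean distances of rows of X to rows of C.
dist2ToCenters <- function(X, C) {
  d2 <- -2 * tcrossprod(X, C)
  d2 <- d2 + rowSums(X^2)
  sweep(d2, 2L, rowSums(C^2), `+`)
}

## Nearest-center assignment; ties go to the lower center index.
nearestCenter <- function(X, C) {
  max.col(-dist2ToCenters(X, C), ties.method = "first")
}

kmeansPPInit <- function(X, k) {
  n <- nrow(X)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1L)
  d2 <- rowSums((X - matrix(X[idx[1], ], n, ncol(X), byrow = TRUE))^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (all(d2 <= 0))
      stop("contract violation: fewer than k distinct vectors")
    idx[j] <- sample.int(n, 1L, prob = d2 / sum(d2))
    dj <- rowSums((X - matrix(X[idx[j], ], n, ncol(X), byrow = TRUE))^2)
    d2 <- pmin(d2, dj)
  }
  X[idx, , drop = FALSE]
}

#' Seeded k-means with k-means++ initialization
#'
#' Lloyd's algorithm (via `stats::kmeans(algorithm = "Lloyd")`) started
#' from k-means++ seeds, repeated `nstart` times with the best
#' within-cluster sum of squares kept. Centers of the returned fit are
#' sorted lexicographically so that cluster indices are reproducible, and
#' cells are re-assigned to the sorted centers with ties going to the
#' lower index.
#'
#' @param X n x D numeric matrix of points.
#' @param k number of clusters.
#' @param seed integer seed.
#' @param nstart number of restarts.
#' @param iterMax Lloyd iteration cap.
#' @return list with `centers` (k x D, lexicographically sorted),
#'   `cluster` (assignment in 1..k), `totWithinss`.
#' @export
kmeansPP <- function(X, k, seed, nstart = 10L, iterMax = 200L) {
  stopifnot(nrow(X) >= k)
  set.seed(seed)
  best <- NULL
  for (r in seq_len(nstart)) {
    init <- kmeansPPInit(X, k)
    fit <- tryCatch(
      suppressWarnings(stats::kmeans(X, centers = init, iter.max = iterMax,
                                     algorithm = "Lloyd")),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best)) stop("k-means failed on all restarts")
  C <- unname(best$centers)
  ord <- do.call(order, as.data.frame(C))
  C <- C[ord, , drop = FALSE]
  assign <- nearestCenter(X, C)
  wss <- sum((X - C[assign, , drop = FALSE])^2)
  list(centers = C, cluster = assign, totWithinss = wss)
}

#' Downsample a pixel mask to the embedding grid
#'
#' A grid cell is particle if at least half of the `stride x stride` pixels
#' it covers are particle pixels.
#'
#' @param mask binary matrix in the working frame.
#' @param gridShape integer (rows, cols) of the embedding grid.
#' @return Logical `gridShape` matrix.
#' @export
maskToGrid <- function(mask, gridShape) {
  sr <- nrow(mask) %/% gridShape[1]
  sc <- ncol(mask) %/% gridShape[2]
  stopifnot(sr >= 1, sc >= 1)
  out <- matrix(FALSE, gridShape[1], gridShape[2])
  for (i in seq_len(gridShape[1])) {
    ri <- ((i - 1L) * sr + 1L):(i * sr)
    for (j in seq_len(gridShape[2])) {
      ci <- ((j - 1L) * sc + 1L):(j * sc)
      out[i, j] <- mean(mask[ri, ci]) >= 0.5
    }
  }
  out
}

## H x W x D array -> (H*W) x D matrix, cells in column-major order
## (consistent with as.vector() on an H x W mask).
latentMatrix <- function(emb) {
  g <- embeddingGrid(emb)
  d <- dim(g)
  matrix(g, d[1] * d[2], d[3])
}

#' Fit the train-set cluster model (reference clustering)
#'
#' Pools the latent vectors of the training micrographs (uniform seeded
#' subsample above `latentCap`), fits k-means with `kTrain` (default 4)
#' clusters, and identifies the particle cluster using the reference
#' micrograph: its mask is downsampled to the embedding grid
#' ([maskToGrid()]), the reference cells are assigned to the fitted
#' centers, and the cluster maximizing the precision-style overlap
#' `|cells in cluster & particle| / |cells in cluster|` is selected (ties:
#' larger intersection count, then lower index of the lexicographically
#' sorted centers).
#'
#' @param trainLatents n x D matrix of pooled training latents, or a list
#'   of [EmbeddingMap-class] objects to pool.
#' @param refEmb [EmbeddingMap-class] of the reference micrograph.
#' @param refMask binary working-frame particle mask of the reference
#'   micrograph.
#' @param cfg a `RunConfig` (uses `kTrain`, `latentCap`, `clusterSeed`).
#' @return A [ReferenceClusterModel-class].
#' @export
fitReferenceClusters <- function(trainLatents, refEmb, refMask,
                                 cfg = runConfig()) {
  if (is.list(trainLatents) && !is.matrix(trainLatents))
    trainLatents <- do.call(rbind, lapply(trainLatents, latentMatrix))
  stopifnot(is.matrix(trainLatents))
  seed <- cfg$clusterSeed
  if (nrow(trainLatents) > cfg$latentCap) {
    set.seed(seed)
    trainLatents <-
      trainLatents[sort(sample.int(nrow(trainLatents), cfg$latentCap)), ,
                   drop = FALSE]
  }
  gdim <- dim(embeddingGrid(refEmb))[1:2]
  gridMask <- maskToGrid(refMask, gdim)
  if (all(gridMask) || !any(gridMask))
    stop("contract violation: reference mask is all-particle or ",
         "all-background at the grid resolution")
  km <- kmeansPP(trainLatents, cfg$kTrain, seed)
  refAssign <- nearestCenter(latentMatrix(refEmb), km$centers)
  p <- as.vector(gridMask)
  k <- nrow(km$centers)
  sizes <- tabulate(refAssign, k)
  inter <- vapply(seq_len(k), function(c_) sum(p[refAssign == c_]),
                  numeric(1))
  ratio <- ifelse(sizes > 0, inter / sizes, -Inf)
  best <- which(ratio == max(ratio))
  if (length(best) > 1L) best <- best[inter[best] == max(inter[best])]
  new("ReferenceClusterModel", centers = km$centers,
      particleId = as.integer(best[1]), fitSeed = as.integer(seed))
}

#' Initial particle-cell assignment from the train-set model
#'
#' Assigns each grid cell of a micrograph's embedding map to the nearest of
#' the train-set cluster centers (Euclidean distance, ties to the lower
#' center index). Cells assigned to the particle cluster form the level-3
#' particle set that seeds the hierarchical refinement.
#'
#' @param emb [EmbeddingMap-class] of the micrograph.
#' @param model [ReferenceClusterModel-class] from
#'   [fitReferenceClusters()].
#' @return A `HierarchicalState` list: `level` (3), `cells` (logical grid
#'   matrix of particle cells).
#' @export
assignInitial <- function(emb, model) {
  X <- latentMatrix(emb)
  if (ncol(X) != ncol(centers(model)))
    stop("contract violation: latent width does not match the cluster model")
  assign <- nearestCenter(X, centers(model))
  gdim <- dim(embeddingGrid(emb))[1:2]
  cells <- matrix(assign == particleId(model), gdim[1], gdim[2])
  structure(list(level = 3L, cells = cells), class = "HierarchicalState")
}

#' Micrograph-specific hierarchical refinement
#'
#' Refines the initial particle-cell set with this micrograph's own
#' latents: for each level i = 3 .. `maxIters`, k-means with i clusters is
#' fitted on the micrograph's grid vectors and the cluster with the
#' greatest overlap with the previous particle set — scored as the
#' contained fraction `|C intersect prev| / |C|`, so that each level keeps
#' the most particle-pure cluster and the refinement acts as progressive
#' denoising — becomes the new particle set (ties: larger intersection,
#' then smaller cluster, then lower sorted-center index). With the default `maxIters = 5` this runs exactly
#' three rounds at k = 3, 4, 5. Each level's particle set is a single
#' cluster of that level's partition. An empty initial set yields an empty
#' mask with a warning rather than an error.
#'
#' @param emb [EmbeddingMap-class] of the micrograph.
#' @param state `HierarchicalState` from [assignInitial()].
#' @param seed integer seed (a per-level seed `seed + i` is derived).
#' @param maxIters final cluster count (>= 3).
#' @return Logical grid-frame matrix, `TRUE` = particle cell.
#' @export
hierarchicalRefine <- function(emb, state, seed, maxIters = 5L) {
  stopifnot(inherits(state, "HierarchicalState"), state$level == 3L,
            maxIters >= 3L)
  prev <- as.vector(state$cells)
  gdim <- dim(state$cells)
  if (!any(prev)) {
    warning("empty initial particle set; returning an empty mask")
    return(matrix(FALSE, gdim[1], gdim[2]))
  }
  X <- latentMatrix(emb)
  for (i in 3L:maxIters) {
    km <- kmeansPP(X, i, seed + i)
    prev <- selectOverlapCluster(km$cluster, prev, i)
  }
  matrix(prev, gdim[1], gdim[2])
}

## Pick the cluster with the greatest overlap with the previous particle
## set, scored as the fraction of the cluster contained in it
## (|C & prev| / |C|): at every level the most "particle-pure" cluster is
## kept, which is what makes the refinement a denoising process. Ties ->
## larger intersection, then smaller cluster, then lower index. Returns
## the logical membership vector of the selected cluster.
selectOverlapCluster <- function(assign, prev, k) {
  inter <- vapply(seq_len(k), function(c_) sum(prev[assign == c_]),
                  numeric(1))
  sizes <- tabulate(assign, k)
  purity <- ifelse(sizes > 0, inter / sizes, -Inf)
  best <- which(purity == max(purity))
  if (length(best) > 1L) best <- best[inter[best] == max(inter[best])]
  if (length(best) > 1L) best <- best[sizes[best] == min(sizes[best])]
  assign == best[1]
}
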