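## From grid-level particle masks to particle coordinates: 3x3 smoothing,
## bilinear upsampling to the working frame, adaptive thresholding toward
## the ~4% particle-area statistic, 8-connected component extraction and
## the diameter / radius / border filters.

#' Construct a prediction map
#'
#' A real-valued particle-probability map in [0, 1], either on the
#' embedding grid or upsampled to the working frame.
#'
#' @param values numeric matrix with values in [0, 1].
#' @param frame `"grid"` or `"working"`.
#' @param stridePx grid-cell footprint in working-frame pixels.
#' @return A `PredictionMap` list.
#' @export
predictionMap <- function(values, frame = c("grid", "working"),
                          stridePx = 1) {
  frame <- match.arg(frame)
  stopifnot(is.matrix(values), all(is.finite(values)),
            min(values) >= 0, max(values) <= 1)
  structure(list(values = values, frame = frame, stridePx = stridePx),
            class = "PredictionMap")
}

#' Smooth a grid-level particle mask
#'
#' Mean filtering with a uniform 3 x 3 kernel (zero padding at the
#' borders), which fills occasional single-cell holes in the segmentation
#' and grades cluster boundaries before thresholding.
#'
#' @param mask binary (or logical) matrix in the grid frame.
#' @param stridePx grid-cell footprint in working-frame pixels.
#' @return A `PredictionMap` in the grid frame with values in [0, 1].
#' @export
smoothMask <- function(mask, stridePx = 1) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  stopifnot(all(m %in% c(0, 1)))
  sm <- as.matrix(EBImage::filter2(m, matrix(1 / 9, 3, 3), boundary = 0))
  predictionMap(pmin(pmax(sm, 0), 1), "grid", stridePx)
}

#' Upsample a prediction map to the working frame
#'
#' Bilinear interpolation of the grid-frame map to
#' `workingSize x workingSize`. Values stay within the input range (convex
#' bilinear weights).
#'
#' @param pm a grid-frame `PredictionMap`.
#' @param workingSize target side in pixels.
#' @return A working-frame `PredictionMap`.
#' @export
upsampleMap <- function(pm, workingSize) {
  stopifnot(inherits(pm, "PredictionMap"), pm$frame == "grid")
  up <- as.matrix(EBImage::resize(pm$values, w = workingSize,
                                  h = workingSize, filter = "bilinear"))
  predictionMap(pmin(pmax(up, 0), 1), "working", 1)
}

#' Adaptive threshold selection toward a target area fraction
#'
#' Evaluates `nThresholds` evenly spaced thresholds in [0, 1] and returns
#' the one whose foreground fraction `mean(pm >= t)` is closest to
#' `targetFraction` (default 0.04, the particle-area statistic of typical
#' training data); ties go to the larger (stricter) threshold.
#'
#' @param pm a working-frame `PredictionMap`.
#' @param targetFraction target foreground fraction in (0, 1).
#' @param nThresholds number of candidate thresholds.
#' @return The selected threshold (scalar).
#' @examples
#' pm <- predictionMap(matrix(runif(256^2), 256), "working")
#' selectThreshold(pm)  # near 0.96 for uniform values
#' @export
selectThreshold <- function(pm, targetFraction = 0.04, nThresholds = 101L) {
  stopifnot(inherits(pm, "PredictionMap"), pm$frame == "working",
            targetFraction > 0, targetFraction < 1)
  grid <- seq(0, 1, length.out = nThresholds)
  v <- as.numeric(pm$values)
  if (all(v == 0)) {
    warning("all-zero prediction map; returning the largest threshold")
    return(grid[nThresholds])
  }
  frac <- vapply(grid, function(t) mean(v >= t), numeric(1))
  err <- abs(frac - targetFraction)
  candidates <- which(err == min(err))
  grid[max(candidates)]
}

## 8-connected labeling: EBImage::bwlabel is 4-connected, so labels that
## touch diagonally are merged with a union-find pass.
label8 <- function(binary) {
  lab <- as.matrix(EBImage::bwlabel(binary))
  nl <- max(lab)
  if (nl <= 1L) return(lab)
  parent <- seq_len(nl)
  findRoot <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  unite <- function(a, b) {
    ra <- findRoot(a); rb <- findRoot(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  nr <- nrow(lab); nc <- ncol(lab)
  for (dd in list(c(1L, 1L), c(1L, -1L))) {
    a <- lab[seq_len(nr - 1L), , drop = FALSE]
    b <- lab[seq_len(nr - 1L) + 1L, , drop = FALSE]
    if (dd[2] == 1L) {
      a <- a[, seq_len(nc - 1L), drop = FALSE]
      b <- b[, seq_len(nc - 1L) + 1L, drop = FALSE]
    } else {
      a <- a[, seq_len(nc - 1L) + 1L, drop = FALSE]
      b <- b[, seq_len(nc - 1L), drop = FALSE]
    }
    touch <- which(a > 0 & b > 0 & a != b)
    for (t_ in touch) unite(a[t_], b[t_])
  }
  roots <- vapply(seq_len(nl), findRoot, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Extract particle candidates from a binary working-frame mask
#'
#' Labels 8-connected foreground components; each becomes a candidate
#' particle with center = component centroid (0-based, x = column),
#' radius = `sqrt(area / pi)` (the radius of the equal-area disc) and
#' score = mean value of the smoothed prediction map over the component.
#'
#' @param binary logical/0-1 matrix in the working frame.
#' @param scoreMap optional working-frame `PredictionMap` (or matrix) for
#'   the per-particle scores; defaults to the binary mask itself.
#' @return A [ParticleSet-class] in the working frame.
#' @export
extractParticles <- function(binary, scoreMap = NULL) {
  b <- matrix(as.numeric(binary), nrow(binary), ncol(binary))
  lab <- label8(b)
  n <- max(lab)
  if (n == 0L)
    return(ParticleSet(frame = "working"))
  sm <- if (is.null(scoreMap)) b
        else if (inherits(scoreMap, "PredictionMap")) scoreMap$values
        else scoreMap
  idx <- which(lab > 0)
  comp <- lab[idx]
  rows <- (idx - 1L) %% nrow(lab)       # 0-based row = y
  cols <- (idx - 1L) %/% nrow(lab)      # 0-based col = x
  area <- tabulate(comp, n)
  cx <- rowsum(as.numeric(cols), comp)[, 1] / area
  cy <- rowsum(as.numeric(rows), comp)[, 1] / area
  sc <- rowsum(sm[idx], comp)[, 1] / area
  ParticleSet(cbind(cx, cy), radii = sqrt(area / pi), scores = sc,
              frame = "working")
}

#' Filter particle candidates
#'
#' Applies the three filtering rules, in the order (ii) size, (iii)
#' border, (i) neighbours:
#' \itemize{
#'   \item (ii) drop particles with radius above
#'     `radiusFactor * diameterPx / 2` (merged blobs);
#'   \item (iii) drop particles with center closer than `borderMarginPx`
#'     (default half a diameter) to any image edge, where particles are
#'     usually truncated;
#'   \item (i) greedy non-maximum suppression in descending score: a
#'     particle whose center lies within `diameterPx` of an already kept
#'     center is dropped.
#' }
#'
#' @param ps working-frame [ParticleSet-class] with scores.
#' @param diameterPx particle diameter in working-frame pixels.
#' @param imageShape integer (rows, cols) of the working frame.
#' @param radiusFactor size-filter factor (> 1).
#' @param borderMarginPx border margin; `NA` = `diameterPx / 2`.
#' @return The filtered [ParticleSet-class].
#' @export
filterParticles <- function(ps, diameterPx, imageShape,
                            radiusFactor = 1.5, borderMarginPx = NA_real_) {
  stopifnot(is(ps, "ParticleSet"), ps@frame == "working", diameterPx > 0)
  if (is.na(borderMarginPx)) borderMarginPx <- diameterPx / 2
  n <- nrow(ps@centers)
  if (n == 0L) return(ps)
  keep <- rep(TRUE, n)
  if (length(ps@radii))
    keep <- keep & ps@radii <= radiusFactor * diameterPx / 2
  x <- ps@centers[, 1]; y <- ps@centers[, 2]
  keep <- keep & x >= borderMarginPx & y >= borderMarginPx &
    x <= (imageShape[2] - 1) - borderMarginPx &
    y <= (imageShape[1] - 1) - borderMarginPx
  idx <- which(keep)
  if (length(idx) > 1L) {
    sc <- if (length(ps@scores)) ps@scores[idx] else rep(0, length(idx))
    ord <- idx[order(-sc, idx)]
    kept <- integer(0)
    for (i in ord) {
      if (!length(kept)) { kept <- i; next }
      d <- sqrt((x[kept] - x[i])^2 + (y[kept] - y[i])^2)
      if (all(d > diameterPx)) kept <- c(kept, i)
    }
    keep[] <- FALSE
    keep[kept] <- TRUE
  }
  ParticleSet(ps@centers[keep, , drop = FALSE],
              radii = if (length(ps@radii)) ps@radii[keep] else numeric(0),
              scores = if (length(ps@scores)) ps@scores[keep]
                       else numeric(0),
              frame = "working")
}

#' Map working-frame coordinates back to the original frame
#'
#' Divides centers (and radii) by the per-axis scale factors recorded by
#' [resizeWorking()].
#'
#' @param ps working-frame [ParticleSet-class].
#' @param scaleRow,scaleCol per-axis working/original scale factors (e.g.
#'   `scaleFactors(mic)`), or pass a [Micrograph-class] as `scaleRow`.
#' @return A [ParticleSet-class] in the original frame.
#' @export
mapToOriginal <- function(ps, scaleRow, scaleCol = NULL) {
  stopifnot(is(ps, "ParticleSet"))
  if (ps@frame != "working")
    stop("contract violation: particle set is not in the working frame")
  if (is(scaleRow, "Micrograph")) {
    s <- scaleFactors(scaleRow)
    scaleCol <- s[2]; scaleRow <- s[1]
  }
  if (is.null(scaleCol) || !is.finite(scaleRow) || !is.finite(scaleCol))
    stop("contract violation: missing scale metadata")
  ctr <- ps@centers
  out <- cbind(ctr[, 1] / scaleCol, ctr[, 2] / scaleRow)
  ParticleSet(out,
              radii = if (length(ps@radii))
                ps@radii / mean(c(scaleRow, scaleCol)) else numeric(0),
              scores = ps@scores, frame = "original")
}
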