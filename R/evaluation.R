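## Detection metrics: per-particle box IoU with box side = particle
## diameter, unique greedy matching, TP rule IoU >= 0.6, and
## micrograph-level aggregation.

#' Box IoU of two particle centers
#'
#' Intersection over union of the axis-aligned squares of side
#' `diameterPx` centered at the two points.
#'
#' @param c1,c2 numeric (x, y) centers, or n x 2 / m x 2 matrices (the
#'   full n x m IoU matrix is returned).
#' @param diameterPx box side.
#' @return Scalar IoU, or an n x m matrix for matrix inputs.
#' @examples
#' boxIoU(c(0, 0), c(5, 0), 10)  # offset by half a side: 1/3
#' @export
boxIoU <- function(c1, c2, diameterPx) {
  stopifnot(diameterPx > 0)
  if (!is.matrix(c1)) c1 <- matrix(c1, 1)
  if (!is.matrix(c2)) c2 <- matrix(c2, 1)
  s <- diameterPx
  ix <- pmax(s - abs(outer(c1[, 1], c2[, 1], `-`)), 0)
  iy <- pmax(s - abs(outer(c1[, 2], c2[, 2], `-`)), 0)
  inter <- ix * iy
  iou <- inter / (2 * s^2 - inter)
  if (length(iou) == 1L) iou[1, 1] else iou
}

#' Match predictions to ground truth and score the detection
#'
#' Computes all pairwise box IoUs, then greedily accepts pairs in
#' descending IoU, skipping pairs whose prediction or ground-truth
#' particle is already matched, and accepting only pairs with
#' `IoU >= tpIoU` (default 0.6). Precision is `tp / nPred` (0 when there
#' are no predictions), recall `tp / nGt` (0 when there is no ground
#' truth), and the reported IoU is the mean over accepted pairs (0 when
#' none).
#'
#' @param pred,gt [ParticleSet-class] objects in the same frame.
#' @param diameterPx particle diameter (box side) in that frame's pixels.
#' @param tpIoU IoU threshold for a true positive.
#' @return list with `pairs` (data.frame predIndex/gtIndex/iou), `tp`,
#'   `fp`, `fn` and `metrics` (list iou/precision/recall/f1).
#' @export
matchAndScore <- function(pred, gt, diameterPx, tpIoU = 0.6) {
  stopifnot(is(pred, "ParticleSet"), is(gt, "ParticleSet"))
  if (pred@frame != gt@frame)
    stop("contract violation: prediction and ground truth are in ",
         "different frames")
  np <- nrow(pred@centers)
  ng <- nrow(gt@centers)
  pairs <- data.frame(predIndex = integer(0), gtIndex = integer(0),
                      iou = numeric(0))
  if (np > 0 && ng > 0) {
    iou <- boxIoU(pred@centers, gt@centers, diameterPx)
    iou <- matrix(iou, np, ng)
    cand <- which(iou >= tpIoU, arr.ind = TRUE)
    if (nrow(cand)) {
      ord <- order(-iou[cand])
      usedP <- rep(FALSE, np); usedG <- rep(FALSE, ng)
      for (r in ord) {
        i <- cand[r, 1]; j <- cand[r, 2]
        if (usedP[i] || usedG[j]) next
        usedP[i] <- TRUE; usedG[j] <- TRUE
        pairs <- rbind(pairs, data.frame(predIndex = i, gtIndex = j,
                                         iou = iou[i, j]))
      }
    }
  }
  tp <- nrow(pairs)
  precision <- if (np > 0) tp / np else 0
  recall <- if (ng > 0) tp / ng else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(pairs = pairs, tp = tp, fp = np - tp, fn = ng - tp,
       metrics = list(iou = if (tp > 0) mean(pairs$iou) else 0,
                      precision = precision, recall = recall, f1 = f1))
}

#' Aggregate per-micrograph metrics
#'
#' Unweighted mean of each metric across micrographs.
#'
#' @param perMicrograph list of metric lists (each with iou, precision,
#'   recall, f1), or a data.frame with those columns.
#' @return list with the mean iou, precision, recall, f1.
#' @export
aggregateMetrics <- function(perMicrograph) {
  if (is.data.frame(perMicrograph))
    perMicrograph <- split(perMicrograph, seq_len(nrow(perMicrograph)))
  stopifnot(length(perMicrograph) > 0)
  get <- function(f) mean(vapply(perMicrograph,
                                 function(m) as.numeric(m[[f]]),
                                 numeric(1)))
  list(iou = get("iou"), precision = get("precision"),
       recall = get("recall"), f1 = get("f1"))
}
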