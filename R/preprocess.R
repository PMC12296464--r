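## Background normalization and contrast enhancement.
##
## Normalization follows the local-statistics scheme: at every position the
## mean and standard deviation over a particle-sized circular neighbourhood
## are computed with FFT cross-correlation (periodic boundaries), and the
## image is standardized to zero-mean/unit-sd background so that noise
## level no longer tracks ice thickness or exposure.

asPixels <- function(x) {
  if (is(x, "Micrograph")) x@pixels
  else if (is.matrix(x) && is.numeric(x)) x
  else stop("expected a Micrograph or a numeric matrix")
}

#' Circular mask offsets for local statistics
#'
#' Builds the indicator of a centered disc of the given diameter, wrapped
#' around the origin of an `shape[1] x shape[2]` array (the layout needed
#' for FFT cross-correlation with periodic boundaries).
#'
#' @param diameterPx disc diameter in pixels (current frame).
#' @param shape integer (rows, cols) of the target image.
#' @return list with `mask` (0/1 matrix, origin-wrapped) and `area`
#'   (number of 1-pixels).
#' @export
circularMask <- function(diameterPx, shape) {
  if (diameterPx <= 0)
    stop("contract violation: zero-area mask")
  stopifnot(length(shape) == 2L)
  r <- diameterPx / 2
  ri <- floor(r)
  if (2 * ri + 1 > min(shape))
    stop("contract violation: mask larger than image")
  off <- expand.grid(dy = -ri:ri, dx = -ri:ri)
  off <- off[off$dy^2 + off$dx^2 <= r^2, , drop = FALSE]
  if (nrow(off) == 0L) stop("contract violation: zero-area mask")
  m <- matrix(0, shape[1], shape[2])
  m[cbind(off$dy %% shape[1] + 1L, off$dx %% shape[2] + 1L)] <- 1
  list(mask = m, area = nrow(off))
}

#' Local mean and standard deviation under a circular mask
#'
#' Computes, for every position r of the image, the mean and standard
#' deviation of the pixels inside a particle-diameter disc centered at r,
#' via FFT cross-correlation:
#' `mu = IFT(FT(X) * conj(FT(M))) / |M|` and
#' `sigma^2 = IFT(FT(X^2) * conj(FT(M))) / |M| - mu^2`.
#' Boundaries are periodic (the FFT-native convention). Negative variances
#' from round-off are clamped to zero.
#'
#' @param x a [Micrograph-class] or numeric matrix.
#' @param diameterPx disc diameter in pixels.
#' @return list with matrices `mu` and `sigma` (same shape as the image)
#'   and the mask `area`.
#' @examples
#' s <- localStats(matrix(rnorm(32 * 32), 32, 32), 5)
#' range(s$sigma)
#' @export
localStats <- function(x, diameterPx) {
  px <- asPixels(x)
  cm <- circularMask(diameterPx, dim(px))
  fm <- Conj(stats::fft(cm$mask))
  n <- length(px)
  mu <- Re(stats::fft(stats::fft(px) * fm, inverse = TRUE)) / n / cm$area
  ex2 <- Re(stats::fft(stats::fft(px^2) * fm, inverse = TRUE)) / n / cm$area
  sigma <- sqrt(pmax(ex2 - mu^2, 0))
  list(mu = mu, sigma = sigma, area = cm$area)
}

#' Local background normalization
#'
#' Standardizes the micrograph to zero-mean / unit-sd background:
#' `out(r) = (X(r) - mu(r)) / max(sigma(r), eps)` with `mu`, `sigma` from
#' [localStats()] under a disc of the particle diameter. The guard
#' `eps = 1e-6 * sd(X)` (floored at 1e-12) maps constant regions to zero
#' instead of NaN.
#'
#' @param x a [Micrograph-class] or numeric matrix.
#' @param diameterPx particle diameter in pixels (current frame), >= 3.
#' @return Same type as the input, normalized.
#' @export
localNormalize <- function(x, diameterPx) {
  stopifnot(diameterPx >= 3)
  px <- asPixels(x)
  st <- localStats(px, diameterPx)
  eps <- max(1e-6 * stats::sd(as.numeric(px)), 1e-12)
  out <- (px - st$mu) / pmax(st$sigma, eps)
  if (is(x, "Micrograph")) { x@pixels <- out; x } else out
}

boxMean <- function(x, win) {
  EBImage::filter2(x, matrix(1 / (win * win), win, win),
                   boundary = "replicate")
}

#' Adaptive (Wiener) local denoising filter
#'
#' Classic pixel-wise adaptive Wiener filter: local mean and variance are
#' estimated in a `win x win` window, the noise power is taken as the mean
#' local variance, and each pixel is shrunk towards the local mean in
#' proportion to the local signal excess.
#'
#' @param x numeric matrix.
#' @param win odd window side (default 5).
#' @return Filtered matrix.
#' @export
wienerFilter <- function(x, win = 5L) {
  stopifnot(is.matrix(x), win %% 2 == 1)
  mu <- boxMean(x, win)
  v <- pmax(boxMean(x^2, win) - mu^2, 0)
  noise <- mean(v)
  mu + pmax(v - noise, 0) / pmax(v, noise) * (x - mu)
}

#' Edge-preserving guided filter
#'
#' Smooths `p` using the structure of the guide image `guide`: within each
#' `(2r+1)` window the output is the best local linear transform
#' `a * guide + b` of the guide, averaged over all windows covering a pixel.
#'
#' @param p image to filter (numeric matrix).
#' @param guide guide image (same shape).
#' @param r window radius in pixels.
#' @param eps regularization added to the guide variance.
#' @return Filtered matrix.
#' @export
guidedFilter <- function(p, guide, r, eps = 1e-2) {
  stopifnot(all(dim(p) == dim(guide)), r >= 1)
  win <- 2L * as.integer(r) + 1L
  mI <- boxMean(guide, win)
  mP <- boxMean(p, win)
  covIP <- boxMean(guide * p, win) - mI * mP
  varI <- pmax(boxMean(guide^2, win) - mI^2, 0)
  a <- covIP / (varI + eps)
  b <- mP - a * mI
  boxMean(a, win) * guide + boxMean(b, win)
}

rescale01 <- function(x) {
  rg <- range(x)
  if (rg[2] > rg[1]) (x - rg[1]) / (rg[2] - rg[1]) else x * 0
}

#' Denoise and enhance a normalized micrograph
#'
#' Sequential enhancement of a background-normalized micrograph: adaptive
#' Wiener denoising (5 x 5), min-max rescale to [0, 1], CLAHE (clip limit 2,
#' 8 x 8 tiles), then guided filtering of the Wiener output using the
#' CLAHE-enhanced image as guide (radius = round(diameter / 4),
#' regularization 1e-2). The output lies in [0, 1]. Deterministic.
#'
#' @param x a [Micrograph-class] or numeric matrix, already normalized.
#' @param diameterPx particle diameter in pixels (current frame).
#' @param cfg a `RunConfig` for the filter parameters.
#' @return Same type as the input, enhanced, values in [0, 1].
#' @export
enhanceMicrograph <- function(x, diameterPx, cfg = runConfig()) {
  px <- asPixels(x)
  if (!all(is.finite(px)))
    stop("contract violation: non-finite input to enhanceMicrograph")
  den <- rescale01(wienerFilter(px, cfg$wienerWindow))
  cl <- EBImage::clahe(den, nx = cfg$claheTiles, ny = cfg$claheTiles,
                       limit = cfg$claheClip)
  cl <- pmin(pmax(as.matrix(cl), 0), 1)
  r <- max(1L, as.integer(round(diameterPx / 4)))
  out <- guidedFilter(den, cl, r = r, eps = cfg$guidedEps)
  out <- pmin(pmax(out, 0), 1)
  if (is(x, "Micrograph")) { x@pixels <- out; x } else out
}

#' Resize a micrograph to the working resolution
#'
#' Bilinear resize to `workingSize x workingSize` (both axes independently,
#' so non-square inputs are accepted), with a Gaussian anti-aliasing
#' pre-blur on downscale. The per-axis scale factors are recorded on the
#' [Micrograph-class] for later coordinate mapping.
#'
#' @param x a [Micrograph-class] or numeric matrix.
#' @param workingSize target side in pixels.
#' @return A [Micrograph-class] at the working resolution with
#'   `scaleFactors` set to (workingSize/rows, workingSize/cols).
#' @export
resizeWorking <- function(x, workingSize) {
  px <- asPixels(x)
  sh <- dim(px)
  scl <- workingSize / sh
  if (all(sh == workingSize)) {
    out <- px
  } else {
    if (any(scl < 1)) {
      # anti-alias: blur at the Nyquist rate of the coarser target grid
      s <- 0.5 / min(scl[scl < 1])
      if (s > 0.6) px <- as.matrix(EBImage::gblur(px, sigma = s))
    }
    out <- as.matrix(EBImage::resize(px, w = workingSize, h = workingSize,
                                     filter = "bilinear"))
  }
  if (is(x, "Micrograph")) {
    x@pixels <- out
    x@scaleFactors <- x@scaleFactors * scl
    x
  } else {
    Micrograph(out, originalShape = sh, scaleFactors = scl)
  }
}

#' Full preprocessing chain
#'
#' [localNormalize()] and [enhanceMicrograph()] at the original resolution
#' (the local statistics are defined with respect to the physical particle
#' diameter), followed by [resizeWorking()].
#'
#' @param x a [Micrograph-class] or numeric matrix.
#' @param diameterPx particle diameter in original-frame pixels.
#' @param cfg a `RunConfig`.
#' @return A working-resolution [Micrograph-class] in [0, 1].
#' @export
preprocessMicrograph <- function(x, diameterPx, cfg = runConfig()) {
  x <- localNormalize(x, diameterPx)
  x <- enhanceMicrograph(x, diameterPx, cfg)
  resizeWorking(x, cfg$workingSize)
}

#' Particle diameter in the working frame
#'
#' @param diameterPx diameter in original-frame pixels.
#' @param mic the working-resolution [Micrograph-class] (for its scale
#'   factors).
#' @return Diameter in working-frame pixels (mean of the two axis scales).
#' @export
diameterWorking <- function(diameterPx, mic) {
  diameterPx * mean(scaleFactors(mic))
}
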