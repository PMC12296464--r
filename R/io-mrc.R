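## MRC2014 2-D image reader/writer (little-endian, modes 0/1/2/6).
## Data layout on disk is x-fastest; in memory we use display convention
## (first index = row = y), so the raster is transposed on read/write.

MRC_HEADER_BYTES <- 1024L

#' Read a 2-D MRC image
#'
#' Reads an MRC2014 single-image file into a [Micrograph-class]. Only 2-D
#' images are accepted; stacks and volumes (`nz > 1`) are rejected. Modes 0
#' (int8), 1 (int16), 2 (float32) and 6 (uint16) are supported. The pixel
#' size is derived from the header cell dimensions when present.
#'
#' @param path path to the `.mrc` file.
#' @param id micrograph id; defaults to the file stem.
#' @return A [Micrograph-class] with `pixels[row = y, col = x]`.
#' @examples
#' p <- tempfile(fileext = ".mrc")
#' m <- Micrograph(matrix(rnorm(128 * 128), 128, 128))
#' writeMRC(m, p)
#' m2 <- readMRC(p)
#' all.equal(pixels(m), pixels(m2))
#' @export
readMRC <- function(path, id = sub("\\.[^.]*$", "", basename(path))) {
  stopifnot(file.exists(path))
  if (file.size(path) < MRC_HEADER_BYTES)
    stop("malformed MRC file (shorter than the 1024-byte header): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  dims <- readBin(con, "integer", n = 3L, size = 4L, endian = "little")
  mode <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (any(dims <= 0L) || any(dims > 1e6))
    stop("malformed MRC header (implausible dimensions): ", path)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  if (nz > 1L)
    stop("unsupported input: MRC stack/volume with nz = ", nz,
         " (expected a single 2-D image)")
  invisible(readBin(con, "integer", n = 3L, size = 4L, endian = "little"))
  mxyz <- readBin(con, "integer", n = 3L, size = 4L, endian = "little")
  cella <- readBin(con, "numeric", n = 3L, size = 4L, endian = "little")
  seek(con, 92L)
  nsymbt <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (is.na(nsymbt) || nsymbt < 0L || nsymbt > file.size(path))
    stop("malformed MRC header (bad extended-header size): ", path)
  seek(con, MRC_HEADER_BYTES + nsymbt)
  n <- nx * ny
  vals <- switch(as.character(mode),
    "0" = readBin(con, "integer", n = n, size = 1L, signed = TRUE,
                  endian = "little"),
    "1" = readBin(con, "integer", n = n, size = 2L, signed = TRUE,
                  endian = "little"),
    "2" = readBin(con, "numeric", n = n, size = 4L, endian = "little"),
    "6" = readBin(con, "integer", n = n, size = 2L, signed = FALSE,
                  endian = "little"),
    stop("malformed or unsupported MRC mode ", mode, " in ", path)
  )
  if (length(vals) < n)
    stop("malformed MRC file (truncated data block): ", path)
  px <- t(matrix(as.numeric(vals), nrow = nx, ncol = ny))  # -> [y, x]
  psz <- NA_real_
  if (mxyz[1] > 0L && is.finite(cella[1]) && cella[1] > 0)
    psz <- cella[1] / mxyz[1]
  Micrograph(px, id = id, pixelSizeA = psz)
}

#' Write a 2-D image as MRC
#'
#' Writes a [Micrograph-class] (or plain matrix) as a mode-2 (float32)
#' MRC2014 file.
#'
#' @param x a [Micrograph-class] or numeric matrix (`[row = y, col = x]`).
#' @param path destination path.
#' @param pixelSizeA pixel size recorded in the header (Angstrom/px);
#'   defaults to the micrograph's own, or 1 when unknown.
#' @return `path`, invisibly.
#' @export
writeMRC <- function(x, path, pixelSizeA = NULL) {
  if (is(x, "Micrograph")) {
    if (is.null(pixelSizeA)) pixelSizeA <- x@pixelSizeA
    x <- x@pixels
  }
  stopifnot(is.matrix(x), all(is.finite(x)))
  if (is.null(pixelSizeA) || is.na(pixelSizeA)) pixelSizeA <- 1
  ny <- nrow(x); nx <- ncol(x)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(v) writeBin(as.integer(v), con, size = 4L,
                             endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4L,
                             endian = "little")
  wi(c(nx, ny, 1L))           # nx ny nz
  wi(2L)                      # mode 2 = float32
  wi(c(0L, 0L, 0L))           # nxstart nystart nzstart
  wi(c(nx, ny, 1L))           # mx my mz
  wf(c(nx, ny, 1) * pixelSizeA)  # cella
  wf(c(90, 90, 90))           # cellb
  wi(c(1L, 2L, 3L))           # mapc mapr maps
  wf(c(min(x), max(x), mean(x)))  # dmin dmax dmean
  wi(0L)                      # ispg
  wi(0L)                      # nsymbt
  writeBin(raw(100L), con)    # extra (words 26-50)
  wf(c(0, 0, 0))              # origin
  writeChar("MAP ", con, nchars = 4L, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(as.numeric(x)))  # rms
  wi(0L)                      # nlabl
  writeBin(raw(800L), con)    # labels
  writeBin(as.numeric(t(x)), con, size = 4L, endian = "little")
  invisible(path)
}
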