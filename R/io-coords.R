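## Particle coordinate I/O: RELION STAR loops and EMAN .box files.
## Pipeline-wide convention: 0-based coordinates, x = column, y = row,
## origin at the top-left pixel. Files are written/read in the original
## micrograph frame.

#' Read particle coordinates
#'
#' Parses a RELION STAR coordinate file (a `loop_` with
#' `_rlnCoordinateX`/`_rlnCoordinateY`) or an EMAN `.box` file (4 columns:
#' corner x, corner y, box width, box height; centers are recovered by
#' adding half the box size). Coordinates are returned 0-based in the
#' original frame.
#'
#' @param path file path.
#' @param fmt `"star"` or `"box"`; guessed from the extension by default.
#' @return A [ParticleSet-class] in the original frame.
#' @examples
#' p <- tempfile(fileext = ".star")
#' writeCoords(ParticleSet(cbind(c(100, 5.5), c(200, 7.5))), p)
#' centers(readCoords(p))
#' @export
readCoords <- function(path, fmt = c("auto", "star", "box")) {
  fmt <- match.arg(fmt)
  if (fmt == "auto")
    fmt <- if (grepl("\\.box$", path, ignore.case = TRUE)) "box" else "star"
  stopifnot(file.exists(path))
  if (fmt == "star") readStarCoords(path) else readBoxCoords(path)
}

readStarCoords <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  loopAt <- which(lines == "loop_")
  if (!length(loopAt))
    stop("format error: no loop_ block in STAR file ", path)
  i <- loopAt[1] + 1L
  cols <- character(0)
  while (i <= length(lines) && startsWith(lines[i], "_")) {
    cols <- c(cols, sub("\\s+#.*$", "", sub("^(_\\S+).*$", "\\1", lines[i])))
    i <- i + 1L
  }
  xi <- match("_rlnCoordinateX", cols)
  yi <- match("_rlnCoordinateY", cols)
  if (is.na(xi) || is.na(yi))
    stop("format error: STAR loop lacks _rlnCoordinateX/_rlnCoordinateY in ",
         path)
  rows <- lines[seq(i, length.out = max(0L, length(lines) - i + 1L))]
  rows <- rows[nzchar(rows) & !startsWith(rows, "data_") &
                 !startsWith(rows, "#")]
  if (!length(rows)) return(ParticleSet(frame = "original"))
  fields <- strsplit(rows, "\\s+")
  ok <- lengths(fields) >= length(cols)
  fields <- fields[ok]
  if (!length(fields)) return(ParticleSet(frame = "original"))
  xs <- as.numeric(vapply(fields, `[`, character(1), xi))
  ys <- as.numeric(vapply(fields, `[`, character(1), yi))
  if (anyNA(xs) || anyNA(ys))
    stop("format error: non-numeric coordinates in ", path)
  ParticleSet(cbind(xs, ys), frame = "original")
}

readBoxCoords <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(ParticleSet(frame = "original"))
  fields <- strsplit(lines, "\\s+")
  if (any(lengths(fields) < 4L))
    stop("format error: .box rows need 4 columns in ", path)
  m <- do.call(rbind, lapply(fields, function(f) as.numeric(f[1:4])))
  if (anyNA(m))
    stop("format error: non-numeric .box entries in ", path)
  ParticleSet(cbind(m[, 1] + m[, 3] / 2, m[, 2] + m[, 4] / 2),
              frame = "original")
}

#' Write particle coordinates
#'
#' Writes a [ParticleSet-class] as a RELION STAR coordinate file or an EMAN
#' `.box` file. The set must be in the original frame (rescale with
#' [mapToOriginal()] first); writing working-frame coordinates is an error
#' so that files on disk always share one frame.
#'
#' @param ps a [ParticleSet-class] in the original frame.
#' @param path destination path.
#' @param fmt `"star"` or `"box"`; guessed from the extension by default.
#' @param boxSize box side used for `.box` output; defaults to twice the
#'   mean particle radius (or 20 when radii are absent).
#' @return `path`, invisibly.
#' @export
writeCoords <- function(ps, path, fmt = c("auto", "star", "box"),
                        boxSize = NULL) {
  stopifnot(is(ps, "ParticleSet"))
  if (ps@frame != "original")
    stop("contract violation: coordinates must be in the original frame; ",
         "use mapToOriginal() before writing")
  fmt <- match.arg(fmt)
  if (fmt == "auto")
    fmt <- if (grepl("\\.box$", path, ignore.case = TRUE)) "box" else "star"
  ctr <- ps@centers
  if (fmt == "star") {
    hdr <- c("", "data_", "", "loop_",
             "_rlnCoordinateX #1", "_rlnCoordinateY #2")
    rows <- if (nrow(ctr)) sprintf("%.6f %.6f", ctr[, 1], ctr[, 2])
            else character(0)
    writeLines(c(hdr, rows), path)
  } else {
    if (is.null(boxSize))
      boxSize <- if (length(ps@radii)) 2 * mean(ps@radii) else 20
    rows <- if (nrow(ctr))
      sprintf("%.6f %.6f %.6f %.6f",
              ctr[, 1] - boxSize / 2, ctr[, 2] - boxSize / 2,
              boxSize, boxSize)
    else character(0)
    writeLines(rows, path)
  }
  invisible(path)
}
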