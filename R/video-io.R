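#' @include AllClasses.R
NULL

## BT.601 luma weights for collapsing color frames to grayscale.
LUMA <- c(0.299, 0.587, 0.114)

toGray8 <- function(arr) {
  # arr: numeric array in [0,1] from png/tiff readers; H x W [x channels]
  if (length(dim(arr)) == 3L) {
    ch <- dim(arr)[3L]
    if (ch >= 3L) {
      arr <- LUMA[1L] * arr[, , 1L] + LUMA[2L] * arr[, , 2L] +
             LUMA[3L] * arr[, , 3L]
    } else arr <- arr[, , 1L]
  }
  m <- round(arr * 255)
  storage.mode(m) <- "integer"
  m
}

#' Read a frame sequence from a directory of still frames
#'
#' Reads ordered PNG or TIFF frames (lexicographic filename order) into a
#' \linkS4class{FrameSequence}. Color frames are collapsed to 8-bit grayscale
#' with the standard BT.601 luma weighting (0.299 R + 0.587 G + 0.114 B). If
#' the directory contains a \code{sequence.json} sidecar written by
#' \code{\link{writeFrames}}, its fps and pixel scale are used unless
#' overridden. Video containers (AVI/MP4) are not decoded; extract frames to
#' a directory first (e.g. \command{ffmpeg -i in.avi frames/f%05d.png}).
#'
#' @param path directory containing the frames.
#' @param fps frame rate override (frames/second). Required when no sidecar
#'   metadata is present.
#' @param pixelScaleUm micrometres per pixel; default 0.2 unless a sidecar
#'   provides one.
#' @return a \linkS4class{FrameSequence}.
#' @export
readFrames <- function(path, fps = NULL, pixelScaleUm = NULL) {
  if (!dir.exists(path)) {
    if (file.exists(path) &&
        grepl("\\.(avi|mp4|mov)$", path, ignore.case = TRUE))
      stop("video containers are not decoded; extract frames to a ",
           "directory of PNG/TIFF stills first")
    stop("path must be a directory of PNG/TIFF frames: ", path)
  }
  meta <- file.path(path, "sequence.json")
  if (file.exists(meta)) {
    md <- jsonlite::read_json(meta, simplifyVector = TRUE)
    if (is.null(fps)) fps <- md$fps
    if (is.null(pixelScaleUm)) pixelScaleUm <- md$pixelScaleUm
  }
  if (is.null(fps)) stop("fps must be given (no sidecar metadata found)")
  if (is.null(pixelScaleUm)) pixelScaleUm <- 0.2
  files <- list.files(path, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE)
  files <- sort(files, method = "radix")
  if (!length(files)) stop("no PNG/TIFF frames found in ", path)
  fr <- lapply(file.path(path, files), function(f) {
    arr <- if (grepl("\\.png$", f, ignore.case = TRUE)) png::readPNG(f)
           else tiff::readTIFF(f)
    toGray8(arr)
  })
  new("FrameSequence", frames = fr, fps = as.numeric(fps),
      pixelScaleUm = as.numeric(pixelScaleUm))
}

#' Write a frame sequence as a lossless PNG directory
#'
#' One 8-bit grayscale PNG per frame with zero-padded names
#' (\code{frame_000001.png}, ...) plus a \code{sequence.json} sidecar holding
#' fps and pixel scale, so \code{\link{readFrames}} round-trips the sequence
#' pixel-identically.
#'
#' @param fseq a \linkS4class{FrameSequence}.
#' @param path output directory (created if missing).
#' @return \code{path}, invisibly.
#' @export
writeFrames <- function(fseq, path) {
  stopifnot(is(fseq, "FrameSequence"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(fseq@frames)) {
    f <- file.path(path, sprintf("frame_%06d.png", i))
    png::writePNG(fseq@frames[[i]] / 255, f)
  }
  jsonlite::write_json(list(fps = fseq@fps, pixelScaleUm = fseq@pixelScaleUm),
                       file.path(path, "sequence.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write a binary mask as PNG
#'
#' Foreground pixels are written as 255, background as 0.
#'
#' @param mask binary matrix (0/1).
#' @param path output PNG path.
#' @return \code{path}, invisibly.
#' @export
writeMask <- function(mask, path) {
  png::writePNG((mask != 0) * 1, path)
  invisible(path)
}

#' Write / read a track table as CSV
#'
#' Schema: \code{track_id,frame,x,y,area,velocity_um_s}; numeric fields keep
#' full double precision, so a write/read round trip is the identity up to
#' float printing, and repeated writes of the same table are byte-identical.
#'
#' @param table data.frame as returned by \code{\link{trackTable}}.
#' @param path CSV path.
#' @return \code{writeTracks}: \code{path} invisibly; \code{readTracks}: the
#'   track table data.frame.
#' @export
writeTracks <- function(table, path) {
  req <- c("track_id", "frame", "x", "y", "area", "velocity_um_s")
  stopifnot(all(req %in% names(table)))
  out <- table[, req, drop = FALSE]
  for (cn in c("x", "y", "area", "velocity_um_s"))
    out[[cn]] <- sprintf("%.10g", out[[cn]])
  out$velocity_um_s[out$velocity_um_s == "NA"] <- ""
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeTracks
#' @export
readTracks <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$track_id <- as.integer(df$track_id)
  df$frame <- as.integer(df$frame)
  for (cn in c("x", "y", "area", "velocity_um_s"))
    df[[cn]] <- as.numeric(df[[cn]])
  df
}
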