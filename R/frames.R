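# Video frames are stored as integer arrays of dimension (height, width, 3)
# holding 8-bit RGB values in [0, 255]. Pixel coordinates follow the trackway
# convention: x = column index along the trackway (direction of travel),
# y = row index across it, both 0-based with the origin at the top-left.

#' Construct a video frame
#'
#' Wraps an RGB pixel array as a `gait_frame`: an integer array of dimension
#' `c(height, width, 3)` with channel values in `[0, 255]` and a 0-based
#' `frame_index` attribute giving its temporal position in the run.
#'
#' @param pixels Numeric array `c(height, width, 3)`, values in `[0, 255]`.
#' @param frame_index 0-based temporal index, a non-negative integer.
#' @return A `gait_frame` object.
#' @export
new_frame <- function(pixels, frame_index = 0L) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    stop("`pixels` must be a height x width x 3 RGB array", call. = FALSE)
  }
  if (any(dim(pixels)[1:2] < 1L)) {
    stop("frame must have height >= 1 and width >= 1", call. = FALSE)
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    stop("channel values must lie in [0, 255]", call. = FALSE)
  }
  if (frame_index < 0) stop("`frame_index` must be >= 0", call. = FALSE)
  storage.mode(pixels) <- "integer"
  structure(pixels, frame_index = as.integer(frame_index),
            class = c("gait_frame", "array"))
}

#' @export
print.gait_frame <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<gait_frame> %d x %d px, frame_index = %d\n",
              d[1], d[2], frame_index(x)))
  invisible(x)
}

#' Frame index accessor
#' @param frame A `gait_frame`.
#' @return Its 0-based temporal index.
#' @export
frame_index <- function(frame) {
  idx <- attr(frame, "frame_index")
  if (is.null(idx)) 0L else idx
}

#' Green channel of a frame
#' @param frame A `gait_frame` or compatible RGB array.
#' @return Integer matrix (height x width) of G values.
#' @export
green_channel <- function(frame) {
  frame[, , 2L, drop = TRUE]
}

#' Read an image-sequence directory as frames
#'
#' Loads all PNG/JPEG files in `path` in lexicographic filename order and
#' assigns 0-based frame indices in that order. Files with unrecognized
#' extensions are ignored.
#'
#' @param path Directory containing the frame images.
#' @return A list of `gait_frame` objects.
#' @export
read_frames <- function(path) {
  if (!dir.exists(path)) stop("frame directory not found: ", path, call. = FALSE)
  files <- sort(list.files(path, full.names = TRUE))
  files <- files[grepl("\\.(png|jpg|jpeg)$", files, ignore.case = TRUE)]
  if (length(files) == 0L) {
    stop("no PNG/JPEG frames found in: ", path, call. = FALSE)
  }
  purrr::imap(files, function(f, i) {
    px <- tryCatch(png::readPNG(f), error = function(e) {
      stop("failed to read frame '", basename(f), "': ", conditionMessage(e),
           call. = FALSE)
    })
    if (length(dim(px)) == 2L) px <- array(rep(px, 3L), dim = c(dim(px), 3L))
    new_frame(round(px[, , 1:3, drop = FALSE] * 255), frame_index = i - 1L)
  })
}

#' Write frames as zero-padded PNG files
#'
#' @param frames List of `gait_frame` objects.
#' @param path Output directory (created if absent).
#' @return Invisibly, the written file paths.
#' @export
write_frames <- function(frames, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  paths <- purrr::imap_chr(frames, function(fr, i) {
    f <- file.path(path, sprintf("frame_%05d.png", i - 1L))
    png::writePNG(unclass(fr) / 255, f)
    f
  })
  invisible(paths)
}
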