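# Geometric preprocessing: single-coefficient radial undistortion, rotation,
# and crop to the trackway band. All warps share one inverse-map bilinear
# sampler with constant-black fill, so output dimensions depend only on the
# configuration, never on pixel content.

#' Preprocessing configuration
#'
#' Parameters of the per-video geometric correction. The crop band marks the
#' top and bottom walls of the glass trackway (rows, 0-based, bottom
#' exclusive); the enclosure band, given relative to the *cropped* image,
#' restricts detection to the rectangular enclosure the mouse runs in.
#'
#' @param distortion_k1 Radial distortion coefficient (dimensionless; 0 = no
#'   correction). Positive values correct barrel distortion.
#' @param rotation_deg Rotation in degrees, counter-clockwise as displayed,
#'   applied to level the trackway.
#' @param crop_y_top,crop_y_bottom Row range kept after rotation
#'   (`0 <= top < bottom <= height`).
#' @param enclosure_y_top,enclosure_y_bottom Analysis band inside the cropped
#'   image; defaults to the full cropped height.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(distortion_k1 = 0,
                              rotation_deg = 0,
                              crop_y_top = 0L,
                              crop_y_bottom = NULL,
                              enclosure_y_top = NULL,
                              enclosure_y_bottom = NULL) {
  if (!is.finite(distortion_k1)) stop("`distortion_k1` must be finite", call. = FALSE)
  if (!is.finite(rotation_deg)) stop("`rotation_deg` must be finite", call. = FALSE)
  structure(list(distortion_k1 = distortion_k1,
                 rotation_deg = rotation_deg,
                 crop_y_top = as.integer(crop_y_top),
                 crop_y_bottom = if (is.null(crop_y_bottom)) NULL else as.integer(crop_y_bottom),
                 enclosure_y_top = if (is.null(enclosure_y_top)) NULL else as.integer(enclosure_y_top),
                 enclosure_y_bottom = if (is.null(enclosure_y_bottom)) NULL else as.integer(enclosure_y_bottom)),
            class = "preprocess_config")
}

# Inverse-map bilinear sampling. `src_r`, `src_c` are 1-based fractional
# source coordinates for every output pixel (h x w matrices); pixels mapping
# outside the source are filled black.
sample_bilinear <- function(img, src_r, src_c) {
  h <- dim(img)[1]; w <- dim(img)[2]
  r0 <- floor(src_r); c0 <- floor(src_c)
  fr <- src_r - r0;   fc <- src_c - c0
  out <- array(0, dim = dim(img))
  # neighbour validity (clamp reads; weight handles the rest)
  inside <- src_r >= 1 & src_r <= h & src_c >= 1 & src_c <= w
  r0c <- pmin(pmax(r0, 1L), h); r1c <- pmin(r0c + 1L, h)
  c0c <- pmin(pmax(c0, 1L), w); c1c <- pmin(c0c + 1L, w)
  for (ch in 1:3) {
    plane <- img[, , ch]
    v <- (1 - fr) * (1 - fc) * plane[cbind(c(r0c), c(c0c))] +
         (1 - fr) * fc       * plane[cbind(c(r0c), c(c1c))] +
         fr       * (1 - fc) * plane[cbind(c(r1c), c(c0c))] +
         fr       * fc       * plane[cbind(c(r1c), c(c1c))]
    v[!inside] <- 0
    out[, , ch] <- v
  }
  pmin(pmax(round(out), 0), 255)
}

# Radius normalization for the distortion model: half the image diagonal,
# so k1 is comparable across resolutions.
radial_norm <- function(h, w) sqrt((h / 2)^2 + (w / 2)^2)

#' Correct radial (barrel) distortion
#'
#' Single-coefficient radial model about the image center: a pixel at
#' normalized undistorted radius `r` is sampled from the distorted source at
#' radius `r * (1 + k1 * r^2)`. Inverse mapping with bilinear interpolation;
#' output has the same dimensions, out-of-source pixels are black. `k1 = 0`
#' is a bit-exact identity.
#'
#' @param frame A `gait_frame`.
#' @param k1 Radial coefficient; positive corrects barrel distortion.
#' @return The corrected `gait_frame`.
#' @export
correct_distortion <- function(frame, k1) {
  if (!is.numeric(k1) || !is.finite(k1)) {
    stop("`k1` must be a finite number", call. = FALSE)
  }
  if (k1 == 0) return(frame)
  d <- dim(frame); h <- d[1]; w <- d[2]
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  s <- radial_norm(h, w)
  rr <- matrix(seq_len(h), h, w) - cy
  cc <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  r_u <- sqrt(rr^2 + cc^2) / s
  scale <- 1 + k1 * r_u^2
  out <- sample_bilinear(unclass(frame), cy + rr * scale, cx + cc * scale)
  new_frame(out, frame_index = frame_index(frame))
}

#' Apply synthetic barrel distortion
#'
#' Forward counterpart of [correct_distortion()]: renders the image as a lens
#' with coefficient `k1` would, by numerically inverting the radial model
#' (Newton iteration on the normalized radius). Used to build distorted test
#' scenes with a known coefficient.
#'
#' @inheritParams correct_distortion
#' @return The distorted `gait_frame`.
#' @export
apply_barrel_distortion <- function(frame, k1) {
  if (!is.numeric(k1) || !is.finite(k1)) {
    stop("`k1` must be a finite number", call. = FALSE)
  }
  if (k1 == 0) return(frame)
  d <- dim(frame); h <- d[1]; w <- d[2]
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  s <- radial_norm(h, w)
  rr <- matrix(seq_len(h), h, w) - cy
  cc <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  r_d <- sqrt(rr^2 + cc^2) / s
  # solve r_d = r_u (1 + k1 r_u^2) for r_u
  r_u <- r_d
  for (i in 1:25) {
    f  <- r_u * (1 + k1 * r_u^2) - r_d
    fp <- 1 + 3 * k1 * r_u^2
    r_u <- r_u - f / fp
  }
  scale <- ifelse(r_d > 0, r_u / r_d, 1)
  out <- sample_bilinear(unclass(frame), cy + rr * scale, cx + cc * scale)
  new_frame(out, frame_index = frame_index(frame))
}

#' Rotate a frame about its center
#'
#' Bilinear interpolation, constant-black fill, output dimensions unchanged.
#' Sines/cosines within 1e-12 of 0 or +/-1 are snapped exact, so quarter-turn
#' rotations are lossless.
#'
#' @param frame A `gait_frame`.
#' @param degrees Rotation angle, counter-clockwise as displayed.
#' @return The rotated `gait_frame`.
#' @export
rotate_frame <- function(frame, degrees) {
  if (!is.finite(degrees)) stop("`degrees` must be finite", call. = FALSE)
  if (degrees %% 360 == 0) return(frame)
  th <- degrees * pi / 180
  co <- cos(th); si <- sin(th)
  snap <- function(v) {
    if (abs(v) < 1e-12) return(0)
    if (abs(abs(v) - 1) < 1e-12) return(sign(v))
    v
  }
  co <- snap(co); si <- snap(si)
  d <- dim(frame); h <- d[1]; w <- d[2]
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  rr <- matrix(seq_len(h), h, w) - cy         # dy (down-positive)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  # inverse of a visually counter-clockwise rotation in row/col coordinates
  src_c <- cx + co * cc - si * rr
  src_r <- cy + si * cc + co * rr
  out <- sample_bilinear(unclass(frame), src_r, src_c)
  new_frame(out, frame_index = frame_index(frame))
}

#' Crop a frame to a row band
#'
#' @param frame A `gait_frame`.
#' @param y_top,y_bottom 0-based row range, bottom exclusive.
#' @return The cropped `gait_frame`, height `y_bottom - y_top`.
#' @export
crop_rows <- function(frame, y_top, y_bottom) {
  h <- dim(frame)[1]
  if (y_top < 0 || y_bottom > h || y_top >= y_bottom) {
    stop(sprintf("crop band [%d, %d) outside image of height %d",
                 y_top, y_bottom, h), call. = FALSE)
  }
  out <- unclass(frame)[(y_top + 1):y_bottom, , , drop = FALSE]
  new_frame(out, frame_index = frame_index(frame))
}

#' Preprocess one frame
#'
#' Applies, in order: radial distortion correction, rotation, and crop to the
#' trackway band. With an identity configuration the frame is returned
#' bit-exact.
#'
#' @param frame A `gait_frame`.
#' @param cfg A [preprocess_config()].
#' @return The preprocessed `gait_frame`.
#' @export
preprocess_frame <- function(frame, cfg) {
  stopifnot(inherits(cfg, "preprocess_config"))
  out <- correct_distortion(frame, cfg$distortion_k1)
  out <- rotate_frame(out, cfg$rotation_deg)
  bottom <- if (is.null(cfg$crop_y_bottom)) dim(out)[1] else cfg$crop_y_bottom
  crop_rows(out, cfg$crop_y_top, bottom)
}

#' Preprocess a frame sequence
#'
#' @param frames List of `gait_frame` objects.
#' @param cfg A [preprocess_config()].
#' @return List of preprocessed frames.
#' @export
preprocess_frames <- function(frames, cfg) {
  purrr::map(frames, preprocess_frame, cfg = cfg)
}
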