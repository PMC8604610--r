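# Paw classification. Frames where all four paws touch the glass anchor the
# labeling: with left-to-right locomotion the two clusters with the larger x
# centroids are the front paws, and within each front/rear pair the smaller y
# (viewed from below) is the right paw. Labels then spread recursively to
# nearby clusters in neighbouring frames until a fixpoint; whatever remains
# unlabeled (nose/tail touches, stray noise) is marked Unclassified and
# excluded from gait analysis.

#' Classification configuration
#'
#' @param propagation_distance Maximum centroid displacement (pixels) for a
#'   label to spread from a classified cluster to an unclassified one. The
#'   default of 20 px suits native 1080x1920 resolution at 60 fps, where a
#'   stationary stance centroid moves only by detection jitter.
#' @param frame_window How many frames away (both directions) one propagation
#'   hop may reach. Default 1: adjacent frames only.
#' @param direction `"left_to_right"` (the trackway convention) or
#'   `"right_to_left"`, which mirrors the front/rear and left/right rules.
#' @return A `classification_config` list.
#' @export
classification_config <- function(propagation_distance = 20,
                                  frame_window = 1L,
                                  direction = c("left_to_right",
                                                "right_to_left")) {
  direction <- match.arg(direction)
  if (propagation_distance <= 0) {
    stop("`propagation_distance` must be > 0", call. = FALSE)
  }
  if (frame_window < 1) stop("`frame_window` must be >= 1", call. = FALSE)
  structure(list(propagation_distance = propagation_distance,
                 frame_window = as.integer(frame_window),
                 direction = direction),
            class = "classification_config")
}

#' Label clusters in four-cluster frames
#'
#' Only frames containing exactly four clusters are labeled. Within such a
#' frame the two clusters with the larger x centroids become the front paws
#' and the other two the rear paws; within each pair the cluster with the
#' smaller y becomes the right paw (the camera views the glass from below).
#' Exact coordinate ties are broken by the other coordinate, then by cluster
#' size descending.
#'
#' @param detections Detection tibble from [detect_run()].
#' @param direction Locomotion direction; `"right_to_left"` mirrors both
#'   rules.
#' @return The tibble with a `label` character column (`NA` where the rule
#'   does not apply).
#' @export
classify_four_paw_frames <- function(detections,
                                     direction = "left_to_right") {
  sgn <- if (identical(direction, "right_to_left")) -1 else 1
  detections |>
    dplyr::group_by(.data$frame_index) |>
    dplyr::mutate(label = if (dplyr::n() == 4L) {
      four_paw_labels(sgn * .data$x, sgn * .data$y, .data$size)
    } else {
      NA_character_
    }) |>
    dplyr::ungroup()
}

# Rule core on (possibly mirrored) coordinates: larger x -> front; within a
# pair, smaller y -> right. Ties: other coordinate, then size descending.
four_paw_labels <- function(x, y, size) {
  front_order <- order(-x, y, -size)
  is_front <- seq_along(x) %in% front_order[1:2]
  lab <- character(length(x))
  for (front in c(TRUE, FALSE)) {
    idx <- which(is_front == front)
    right_first <- idx[order(y[idx], -x[idx], -size[idx])]
    side <- if (front) "Front" else "Rear"
    lab[right_first[1]] <- paste0("Right-", side)
    lab[right_first[2]] <- paste0("Left-", side)
  }
  lab
}

#' Propagate labels to neighbouring frames
#'
#' Iterates to a fixpoint: any unlabeled cluster whose centroid lies within
#' `propagation_distance` of a labeled cluster in a frame at most
#' `frame_window` away receives that cluster's label. When several labeled
#' clusters claim one target, or several targets in the same frame would take
#' the same label, the nearest centroid wins (ties: earlier source frame); a
#' displaced same-frame duplicate simply stays unlabeled for this pass. A
#' frame never ends up with two clusters sharing a paw label. Clusters still
#' unlabeled at the fixpoint are marked `"Unclassified"`.
#'
#' @param labeled Tibble from [classify_four_paw_frames()] (columns
#'   `frame_index`, `cluster_id`, `x`, `y`, `label`).
#' @param cfg A [classification_config()].
#' @return The tibble with `label` filled in (`"Unclassified"` for leftovers)
#'   and a logical `excluded` column flagging unclassified clusters.
#' @export
propagate_labels <- function(labeled, cfg = classification_config()) {
  stopifnot(inherits(cfg, "classification_config"))
  out <- labeled
  if (nrow(out) == 0L) {
    return(dplyr::mutate(out, label = character(0), excluded = logical(0)))
  }
  out$.row <- seq_len(nrow(out))
  repeat {
    lab <- out[!is.na(out$label), c(".row", "frame_index", "x", "y", "label")]
    unl <- out[is.na(out$label), c(".row", "frame_index", "x", "y")]
    if (nrow(lab) == 0L || nrow(unl) == 0L) break
    # candidate pairs: one row per (source hop, target frame)
    cand <- tidyr::expand_grid(
      src = seq_len(nrow(lab)),
      off = -cfg$frame_window:cfg$frame_window
    )
    cand$target_frame <- lab$frame_index[cand$src] + cand$off
    cand <- dplyr::inner_join(
      cand,
      dplyr::rename(unl, target_frame = "frame_index",
                    tx = "x", ty = "y", target = ".row"),
      by = "target_frame", relationship = "many-to-many"
    )
    if (nrow(cand) == 0L) break
    cand$dist <- sqrt((lab$x[cand$src] - cand$tx)^2 +
                        (lab$y[cand$src] - cand$ty)^2)
    cand <- cand[cand$dist <= cfg$propagation_distance, , drop = FALSE]
    if (nrow(cand) == 0L) break
    cand$label <- lab$label[cand$src]
    cand$src_frame <- lab$frame_index[cand$src]
    # deterministic greedy order: nearest first, then earlier source frame,
    # then stable keys so the result is permutation-invariant
    cand <- cand[order(cand$dist, cand$src_frame, cand$target_frame,
                       cand$label, cand$tx, cand$ty), , drop = FALSE]
    taken <- paste(out$frame_index[!is.na(out$label)],
                   out$label[!is.na(out$label)])
    assigned_any <- FALSE
    for (i in seq_len(nrow(cand))) {
      tgt <- cand$target[i]
      if (!is.na(out$label[tgt])) next
      key <- paste(cand$target_frame[i], cand$label[i])
      if (key %in% taken) next
      out$label[tgt] <- cand$label[i]
      taken <- c(taken, key)
      assigned_any <- TRUE
    }
    if (!assigned_any) break
  }
  out$excluded <- is.na(out$label)
  out$label[out$excluded] <- "Unclassified"
  out$.row <- NULL
  out
}

#' Classify detected clusters into the four paws
#'
#' Full classification stage: label all four-cluster frames, then propagate
#' to a fixpoint. Unclassified clusters are retained in the output for
#' diagnostics but flagged `excluded`.
#'
#' @param detections Detection tibble from [detect_run()].
#' @param cfg A [classification_config()].
#' @return Tibble of classified footfalls (`label`, `excluded` columns
#'   appended).
#' @export
#' @examples
#' run <- generate_run(synthetic_gait_config(n_strides = 2))
#' det <- detect_run(run$frames)
#' classify_paws(det)
classify_paws <- function(detections, cfg = classification_config()) {
  seeded <- classify_four_paw_frames(detections, direction = cfg$direction)
  if (nrow(seeded) > 0L && all(is.na(seeded$label))) {
    warning("no frame with exactly four clusters: all clusters end up ",
            "Unclassified", call. = FALSE)
  }
  propagate_labels(seeded, cfg)
}
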