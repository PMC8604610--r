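# Detection-quality evaluation. Ground truth is a set of per-frame labeled
# boxes (PascalVOC/LabelImg dialect). Predictions are matched one-to-one to
# boxes by centroid proximity; correct-label matches are hits, unmatched
# boxes are misses, and unmatched or mislabeled predictions are falses.
# The ROC analysis treats the detector as a binary classifier over the
# trackway band, counting TP/FP/FN as 20x20-px cell events and TN as the
# remaining cells.

#' Write PascalVOC-dialect annotations for one frame
#'
#' @param boxes Tibble with `label`, `xmin`, `ymin`, `xmax`, `ymax` (0-based
#'   pixel coordinates); may have zero rows.
#' @param frame_dim `c(height, width)` of the frame.
#' @param path Output XML file.
#' @param filename Image filename recorded in the annotation.
#' @return Invisibly, `path`.
#' @export
write_voc_file <- function(boxes, frame_dim, path, filename = "frame.png") {
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "folder", "frames")
  xml2::xml_add_child(doc, "filename", filename)
  size <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(size, "width", as.character(frame_dim[2]))
  xml2::xml_add_child(size, "height", as.character(frame_dim[1]))
  xml2::xml_add_child(size, "depth", "3")
  if (!is.null(boxes) && nrow(boxes) > 0) {
    for (i in seq_len(nrow(boxes))) {
      obj <- xml2::xml_add_child(doc, "object")
      xml2::xml_add_child(obj, "name", boxes$label[i])
      xml2::xml_add_child(obj, "difficult", "0")
      bb <- xml2::xml_add_child(obj, "bndbox")
      xml2::xml_add_child(bb, "xmin", as.character(boxes$xmin[i]))
      xml2::xml_add_child(bb, "ymin", as.character(boxes$ymin[i]))
      xml2::xml_add_child(bb, "xmax", as.character(boxes$xmax[i]))
      xml2::xml_add_child(bb, "ymax", as.character(boxes$ymax[i]))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a PascalVOC-dialect annotation file
#'
#' Accepts LabelImg output: `<annotation>` with `<object><name>` and
#' `<bndbox>` children.
#'
#' @param path XML file.
#' @param frame_idx Frame index to record; by default parsed from a
#'   trailing integer in the filename, else 0.
#' @return Tibble with `frame_index`, `label`, `xmin`, `ymin`, `xmax`,
#'   `ymax` (zero rows if the frame has no objects).
#' @export
read_voc_file <- function(path, frame_idx = NULL) {
  if (is.null(frame_idx)) {
    m <- regmatches(basename(path), regexpr("[0-9]+", basename(path)))
    frame_idx <- if (length(m)) as.integer(m) else 0L
  }
  doc <- xml2::read_xml(path)
  objs <- xml2::xml_find_all(doc, ".//object")
  if (length(objs) == 0L) {
    return(tibble::tibble(frame_index = integer(0), label = character(0),
                          xmin = double(0), ymin = double(0),
                          xmax = double(0), ymax = double(0)))
  }
  num <- function(node, tag) {
    as.numeric(xml2::xml_text(xml2::xml_find_first(node, paste0(".//", tag))))
  }
  tibble::tibble(
    frame_index = frame_idx,
    label = xml2::xml_text(xml2::xml_find_all(objs, ".//name")),
    xmin = vapply(objs, num, numeric(1), tag = "xmin"),
    ymin = vapply(objs, num, numeric(1), tag = "ymin"),
    xmax = vapply(objs, num, numeric(1), tag = "xmax"),
    ymax = vapply(objs, num, numeric(1), tag = "ymax")
  )
}

#' Read a directory of PascalVOC annotations
#'
#' @param path Directory of per-frame XML files (lexicographic order gives
#'   the frame order; indices parsed from filenames).
#' @return One tibble of truth boxes for the run.
#' @export
read_voc_dir <- function(path) {
  files <- sort(list.files(path, pattern = "\\.xml$", full.names = TRUE))
  if (length(files) == 0L) stop("no XML annotations in: ", path, call. = FALSE)
  purrr::map(files, read_voc_file) |> purrr::list_rbind()
}

#' Match detections to ground truth
#'
#' Greedy one-to-one matching per frame: a prediction is a candidate for a
#' truth box when its centroid lies inside the box or within
#' `max_match_dist` of the box center; closest pairs match first. A match
#' with the correct label is a *hit*; a matched-but-mislabeled prediction
#' consumes the box and counts as a *false*; an unmatched truth box is a
#' *miss*; an unmatched prediction is a *false*.
#'
#' @param predicted Tibble of detections (columns `frame_index`, `x`, `y`,
#'   optionally `label`).
#' @param truth Truth-box tibble (`frame_index`, `label`, `xmin`, `ymin`,
#'   `xmax`, `ymax`).
#' @param max_match_dist Maximum centroid-to-box-center distance (px);
#'   default 20, one evaluation cell.
#' @param use_labels If `FALSE` (detection-stage scoring, before
#'   classification), any positional match is a hit.
#' @return Per-frame tibble: `frame_index`, `hits`, `misses`, `falses`.
#' @export
match_detections <- function(predicted, truth, max_match_dist = 20,
                             use_labels = TRUE) {
  frames <- sort(unique(c(predicted$frame_index, truth$frame_index)))
  purrr::map(frames, function(t) {
    p <- predicted[predicted$frame_index == t, , drop = FALSE]
    g <- truth[truth$frame_index == t, , drop = FALSE]
    n_p <- nrow(p); n_g <- nrow(g)
    hits <- 0L; falses <- 0L
    if (n_p > 0 && n_g > 0) {
      gcx <- (g$xmin + g$xmax) / 2; gcy <- (g$ymin + g$ymax) / 2
      cand <- tidyr::expand_grid(pi_ = seq_len(n_p), gi = seq_len(n_g))
      cand$dist <- sqrt((p$x[cand$pi_] - gcx[cand$gi])^2 +
                          (p$y[cand$pi_] - gcy[cand$gi])^2)
      inside <- p$x[cand$pi_] >= g$xmin[cand$gi] &
        p$x[cand$pi_] <= g$xmax[cand$gi] &
        p$y[cand$pi_] >= g$ymin[cand$gi] &
        p$y[cand$pi_] <= g$ymax[cand$gi]
      cand <- cand[inside | cand$dist <= max_match_dist, , drop = FALSE]
      cand <- cand[order(cand$dist, cand$pi_, cand$gi), , drop = FALSE]
      used_p <- logical(n_p); used_g <- logical(n_g)
      for (i in seq_len(nrow(cand))) {
        a <- cand$pi_[i]; b <- cand$gi[i]
        if (used_p[a] || used_g[b]) next
        used_p[a] <- TRUE; used_g[b] <- TRUE
        correct <- !use_labels || (!is.null(p$label) &&
                                     identical(p$label[a], g$label[b]))
        if (correct) hits <- hits + 1L else falses <- falses + 1L
      }
      falses <- falses + sum(!used_p)
      misses <- sum(!used_g)
    } else {
      falses <- n_p
      misses <- n_g
    }
    tibble::tibble(frame_index = t, hits = hits, misses = misses,
                   falses = falses)
  }) |> purrr::list_rbind()
}

#' Hit:Miss:False score
#'
#' Percentages of hit, missed and false footfall events over a run, with
#' denominator `hits + misses + falses`, so the three components sum to 100
#' before rounding.
#'
#' @param matches Per-frame match tibble from [match_detections()].
#' @return One-row tibble `hit_pct`, `miss_pct`, `false_pct` plus the raw
#'   counts.
#' @export
#' @examples
#' hmf_score(tibble::tibble(frame_index = 1, hits = 92, misses = 2,
#'                          falses = 6))
hmf_score <- function(matches) {
  h <- sum(matches$hits); m <- sum(matches$misses); f <- sum(matches$falses)
  total <- h + m + f
  if (total == 0) stop("H:M:F undefined: no footfall events", call. = FALSE)
  tibble::tibble(hit_pct = 100 * h / total,
                 miss_pct = 100 * m / total,
                 false_pct = 100 * f / total,
                 hits = h, misses = m, falses = f)
}
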