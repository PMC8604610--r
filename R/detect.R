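# Footfall detection. On the LED-lit glass trackway a paw contact frustrates
# the internal reflection of the green side-lighting, so footfalls appear as
# bright green blobs on a red-tinted background. Detection is: G-channel
# threshold -> Euclidean proximity clustering (joins toe digits to the palm)
# -> cluster-size filter -> centroid per surviving cluster.

#' Detection thresholds
#'
#' The four tunable parameters of the detection stage. Defaults are the
#' operating point found optimal by ROC analysis on trackway video at
#' 1080x1920 / 60 fps; all comparisons are inclusive, so these defaults are
#' boundary-stable.
#'
#' @param green_threshold Minimum G value (0-255) for a pixel to count as
#'   candidate footfall.
#' @param proximity_threshold Maximum Euclidean pixel distance linking two
#'   pixels into one cluster.
#' @param min_cluster_size,max_cluster_size Inclusive bounds on cluster pixel
#'   count; smaller clusters are noise specks, larger ones tail/body contact.
#' @return A `detection_thresholds` list.
#' @export
#' @examples
#' detection_thresholds()
detection_thresholds <- function(green_threshold = 205,
                                 proximity_threshold = 2,
                                 min_cluster_size = 65,
                                 max_cluster_size = 510) {
  if (green_threshold < 0 || green_threshold > 255) {
    stop("`green_threshold` must lie in [0, 255]", call. = FALSE)
  }
  if (proximity_threshold <= 0) {
    stop("`proximity_threshold` must be > 0", call. = FALSE)
  }
  if (min_cluster_size <= 0 || min_cluster_size > max_cluster_size) {
    stop("need 0 < min_cluster_size <= max_cluster_size", call. = FALSE)
  }
  structure(list(green_threshold = green_threshold,
                 proximity_threshold = proximity_threshold,
                 min_cluster_size = min_cluster_size,
                 max_cluster_size = max_cluster_size),
            class = "detection_thresholds")
}

#' Threshold the green channel
#'
#' Returns every pixel inside the analysis band whose G value is at least
#' `green_threshold` (inclusive).
#'
#' @param frame A `gait_frame`.
#' @param green_threshold Intensity cutoff in `[0, 255]`.
#' @param band Optional `c(y_top, y_bottom)` row band (0-based, bottom
#'   exclusive) restricting the search to the rectangular enclosure; `NULL`
#'   uses the full frame.
#' @return A tibble with columns `x`, `y` (0-based pixel coordinates;
#'   x along the trackway) and `g` (the G value).
#' @export
threshold_green <- function(frame, green_threshold, band = NULL) {
  g <- green_channel(frame)
  h <- nrow(g)
  if (is.null(band)) band <- c(0L, h)
  if (band[1] < 0 || band[2] > h || band[1] >= band[2]) {
    stop(sprintf("analysis band [%d, %d) is empty or outside image height %d",
                 band[1], band[2], h), call. = FALSE)
  }
  g <- g[(band[1] + 1):band[2], , drop = FALSE]
  hits <- which(g >= green_threshold, arr.ind = TRUE)
  tibble::tibble(
    x = as.integer(hits[, 2] - 1L),
    y = as.integer(hits[, 1] - 1L + band[1]),
    g = as.integer(g[hits])
  )
}

# Half-plane set of integer offsets with 0 < dx^2 + dy^2 <= t^2, used by the
# fast clustering path (each unordered neighbour pair is visited once).
proximity_offsets <- function(threshold) {
  r <- floor(threshold)
  grid <- expand.grid(dx = -r:r, dy = -r:r)
  grid <- grid[grid$dx^2 + grid$dy^2 <= threshold^2 &
                 !(grid$dx == 0 & grid$dy == 0), ]
  grid[grid$dx > 0 | (grid$dx == 0 & grid$dy > 0), , drop = FALSE]
}

#' Proximity clustering
#'
#' Groups pixels into clusters by single-linkage transitive closure: two
#' pixels are linked when their Euclidean distance is at most
#' `proximity_threshold`, and clusters are the connected components of that
#' graph. This joins the toe digits of a paw print to the palm blob even
#' though they do not touch.
#'
#' For integer coordinates and thresholds the components are found over a
#' precomputed pixel-offset neighbourhood (every integer offset of norm <=
#' threshold); otherwise all pairwise distances are examined. Both routes
#' produce the identical partition.
#'
#' @param pixels A data frame with integer columns `x`, `y` (one row per
#'   pixel); extra columns are preserved.
#' @param proximity_threshold Linking distance in pixels (> 0).
#' @return The input tibble with a `cluster` integer column; cluster ids are
#'   consecutive from 1 in order of first appearance. Empty input gives an
#'   empty tibble.
#' @export
#' @examples
#' pts <- tibble::tibble(x = c(0, 0, 10), y = c(0, 1, 10))
#' proximity_cluster(pts, 2)
proximity_cluster <- function(pixels, proximity_threshold) {
  if (proximity_threshold <= 0) {
    stop("`proximity_threshold` must be > 0", call. = FALSE)
  }
  pixels <- tibble::as_tibble(pixels)
  n <- nrow(pixels)
  if (n == 0L) {
    return(dplyr::mutate(pixels, cluster = integer(0)))
  }
  integer_coords <- all(pixels$x == round(pixels$x)) &&
    all(pixels$y == round(pixels$y))
  if (integer_coords) {
    key <- pixels$x + 1i * pixels$y
    offs <- proximity_offsets(proximity_threshold)
    from <- integer(0); to <- integer(0)
    for (j in seq_len(nrow(offs))) {
      m <- match(key + offs$dx[j] + 1i * offs$dy[j], key)
      hit <- which(!is.na(m))
      from <- c(from, hit); to <- c(to, m[hit])
    }
  } else {
    dmat <- as.matrix(stats::dist(cbind(pixels$x, pixels$y)))
    idx <- which(dmat <= proximity_threshold & upper.tri(dmat), arr.ind = TRUE)
    from <- idx[, 1]; to <- idx[, 2]
  }
  gr <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  gr <- igraph::add_vertices(gr, max(0L, n - igraph::vcount(gr)))
  comp <- igraph::components(gr)$membership[seq_len(n)]
  # renumber in order of first appearance for determinism
  comp <- match(comp, unique(comp))
  dplyr::mutate(pixels, cluster = as.integer(comp))
}

#' Filter clusters by size
#'
#' Keeps exactly the clusters whose pixel count `N` satisfies
#' `min_cluster_size <= N <= max_cluster_size` (inclusive bounds); everything
#' else — dust specks below, tail/body streaks above — is discarded. Cluster
#' order (by id) is preserved.
#'
#' @param clustered A tibble with a `cluster` column, as returned by
#'   [proximity_cluster()].
#' @param min_cluster_size,max_cluster_size Inclusive pixel-count bounds.
#' @return The filtered tibble.
#' @export
filter_cluster_size <- function(clustered, min_cluster_size, max_cluster_size) {
  if (min_cluster_size <= 0 || min_cluster_size > max_cluster_size) {
    stop("need 0 < min_cluster_size <= max_cluster_size", call. = FALSE)
  }
  clustered |>
    dplyr::group_by(.data$cluster) |>
    dplyr::filter(dplyr::n() >= min_cluster_size,
                  dplyr::n() <= max_cluster_size) |>
    dplyr::ungroup()
}

#' Cluster centroid
#'
#' Arithmetic mean of the member pixel coordinates.
#'
#' @param pixels Data frame with columns `x`, `y`; at least one row.
#' @return Named numeric vector `c(x = , y = )`.
#' @export
#' @examples
#' compute_centroid(tibble::tibble(x = c(0, 0, 0), y = c(0, 1, 5)))
compute_centroid <- function(pixels) {
  if (nrow(pixels) == 0L) stop("cannot take the centroid of an empty cluster",
                               call. = FALSE)
  c(x = mean(pixels$x), y = mean(pixels$y))
}

#' Detect paw clusters in one frame
#'
#' Full detection stage: green thresholding, proximity clustering, size
#' filtering, and centroid extraction. Clusters are returned sorted by
#' centroid x descending (front-most first, given left-to-right locomotion)
#' and renumbered 1..K in that order.
#'
#' @param frame A preprocessed `gait_frame`.
#' @param thresholds A [detection_thresholds()].
#' @param band Optional analysis band, as in [threshold_green()].
#' @return A tibble with one row per detected cluster: `frame_index`,
#'   `cluster_id`, `x`, `y` (centroid), `size`, `g_mean`, and bounding box
#'   `xmin`, `ymin`, `xmax`, `ymax`.
#' @export
detect_paws <- function(frame, thresholds = detection_thresholds(),
                        band = NULL) {
  stopifnot(inherits(thresholds, "detection_thresholds"))
  px <- threshold_green(frame, thresholds$green_threshold, band = band)
  empty <- tibble::tibble(
    frame_index = integer(0), cluster_id = integer(0),
    x = double(0), y = double(0), size = integer(0), g_mean = double(0),
    xmin = integer(0), ymin = integer(0), xmax = integer(0), ymax = integer(0)
  )
  if (nrow(px) == 0L) return(empty)
  cl <- proximity_cluster(px, thresholds$proximity_threshold)
  cl <- filter_cluster_size(cl, thresholds$min_cluster_size,
                            thresholds$max_cluster_size)
  if (nrow(cl) == 0L) return(empty)
  out <- cl |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      x = mean(.data$x), y = mean(.data$y),
      size = dplyr::n(), g_mean = mean(.data$g),
      xmin = min(.data$x), ymin = min(.data$y),
      xmax = max(.data$x), ymax = max(.data$y),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$x), .data$y) |>
    dplyr::mutate(frame_index = frame_index(frame),
                  cluster_id = dplyr::row_number()) |>
    dplyr::select("frame_index", "cluster_id", "x", "y", "size", "g_mean",
                  "xmin", "ymin", "xmax", "ymax")
  out
}

#' Detect paw clusters across a run
#'
#' Applies [detect_paws()] to every frame and binds the results.
#'
#' @param frames List of preprocessed `gait_frame` objects.
#' @inheritParams detect_paws
#' @return One tibble of detections for the whole run.
#' @export
detect_run <- function(frames, thresholds = detection_thresholds(),
                       band = NULL) {
  purrr::map(frames, detect_paws, thresholds = thresholds, band = band) |>
    purrr::list_rbind()
}
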