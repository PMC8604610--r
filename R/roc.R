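# ROC analysis of the detection thresholds. One detection parameter is swept
# over a grid while the others are held fixed; at each value TP/FP/FN are
# counted as bounding-box events of one 20x20-px cell each within the
# analysis region, TN is the remaining cell count, and TPR/FPR follow as
# TP/(TP+FN) and FP/(FP+TN). The empirical curve is the straight-line
# interpolation of the (FPR, TPR) points; AUC is its trapezoidal area.

#' Sweep one detection threshold and score each point
#'
#' Cell accounting: per frame the region holds
#' `floor(width * height / cell_size^2)` cells (301 for the native 1720 x 70
#' trackway band at 20-px cells); TP, FP and FN each occupy one cell and
#' TN = total cells - TP - FP - FN, so all four outcomes share a unit.
#'
#' @param frames List of preprocessed `gait_frame` objects (the test set).
#' @param truth Truth-box tibble for those frames.
#' @param vary Which threshold to sweep: one of `"green_threshold"`,
#'   `"proximity_threshold"`, `"min_cluster_size"`, `"max_cluster_size"`.
#' @param grid Sorted numeric vector of values for the swept threshold.
#' @param thresholds Fixed values for the other thresholds
#'   ([detection_thresholds()]).
#' @param band Analysis band passed to detection; also defines the region
#'   dimensions unless `region_dim` is given.
#' @param region_dim `c(height, width)` of the evaluation region in px;
#'   default: the band height by the frame width.
#' @param cell_size Cell edge in px; default 20.
#' @param max_match_dist Matching radius for TP counting; default 20.
#' @return A `mousegait_roc` tibble: one row per grid value with `threshold`,
#'   `TP`, `FP`, `FN`, `TN`, `TPR`, `FPR`. `TPR` is `NA` (flagged) when no
#'   positives exist.
#' @export
roc_sweep <- function(frames, truth, vary, grid,
                      thresholds = detection_thresholds(),
                      band = NULL, region_dim = NULL, cell_size = 20,
                      max_match_dist = 20) {
  vary <- match.arg(vary, c("green_threshold", "proximity_threshold",
                            "min_cluster_size", "max_cluster_size"))
  if (length(grid) == 0L) stop("`grid` must be non-empty", call. = FALSE)
  grid <- sort(grid)
  if (is.null(region_dim)) {
    d <- dim(frames[[1]])
    region_dim <- c(if (is.null(band)) d[1] else band[2] - band[1], d[2])
  }
  cells_per_frame <- as.integer(prod(region_dim) %/% cell_size^2)
  total_cells <- cells_per_frame * length(frames)

  pts <- purrr::map(grid, function(v) {
    thr <- thresholds
    thr[[vary]] <- v
    thr <- detection_thresholds(thr$green_threshold, thr$proximity_threshold,
                                thr$min_cluster_size, thr$max_cluster_size)
    det <- detect_run(frames, thresholds = thr, band = band)
    m <- match_detections(det, truth, max_match_dist = max_match_dist,
                          use_labels = FALSE)
    tp <- sum(m$hits); fp <- sum(m$falses); fn <- sum(m$misses)
    tn <- max(0L, total_cells - tp - fp - fn)
    tibble::tibble(threshold = v, TP = tp, FP = fp, FN = fn, TN = tn,
                   TPR = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                   FPR = fp / (fp + tn))
  }) |> purrr::list_rbind()
  class(pts) <- c("mousegait_roc", class(pts))
  attr(pts, "vary") <- vary
  pts
}

#' Area under an empirical ROC curve
#'
#' Trapezoidal area of the (FPR, TPR) polyline after sorting by FPR and
#' anchoring the endpoints (0, 0) and (1, 1) — the straight-line
#' interpolation between consecutive threshold points. Points with
#' undefined TPR are dropped.
#'
#' @param points Tibble with `FPR` and `TPR` columns (e.g. from
#'   [roc_sweep()]).
#' @return The AUC, in `[0, 1]`.
#' @export
#' @examples
#' roc_auc(tibble::tibble(FPR = c(0.1, 0.3), TPR = c(0.8, 0.95)))  # 0.8975
roc_auc <- function(points) {
  pts <- points[!is.na(points$TPR) & !is.na(points$FPR), c("FPR", "TPR")]
  pts <- rbind(data.frame(FPR = 0, TPR = 0), as.data.frame(pts),
               data.frame(FPR = 1, TPR = 1))
  pts <- pts[order(pts$FPR, pts$TPR), ]
  sum(diff(pts$FPR) * (utils::head(pts$TPR, -1) + utils::tail(pts$TPR, -1)) / 2)
}

#' Optimal threshold of an ROC sweep
#'
#' The point maximizing Youden's J = TPR - FPR (the standard reading of
#' "maximum TPR and minimum FPR"); ties broken by smaller FPR, then smaller
#' threshold.
#'
#' @param points A `mousegait_roc` tibble.
#' @return One-row tibble: the selected point (including its `threshold`).
#' @export
optimal_threshold <- function(points) {
  pts <- points[!is.na(points$TPR), , drop = FALSE]
  if (nrow(pts) == 0L) stop("no ROC point with defined TPR", call. = FALSE)
  j <- pts$TPR - pts$FPR
  ord <- order(-j, pts$FPR, pts$threshold)
  pts[ord[1], , drop = FALSE]
}

#' Confusion matrix of one ROC point
#'
#' @param point One-row tibble with `TP`, `FN`, `FP`, `TN`.
#' @param normalize Also attach row-normalized rates.
#' @return A 2x2 matrix `[[TP, FN], [FP, TN]]` (rows: actual positive /
#'   negative); with `normalize = TRUE`, a list with `counts` and `rates`.
#' @export
confusion_matrix <- function(point, normalize = FALSE) {
  counts <- matrix(c(point$TP, point$FN, point$FP, point$TN),
                   nrow = 2, byrow = TRUE,
                   dimnames = list(c("positive", "negative"),
                                   c("detected", "not detected")))
  if (!normalize) return(counts)
  rs <- rowSums(counts)
  rates <- counts / ifelse(rs == 0, 1, rs)
  list(counts = counts, rates = rates)
}

#' Random-score control ROC
#'
#' A chance-level reference: positive and negative cells receive i.i.d.
#' Uniform(0, 1) scores and the score threshold is swept, giving an ROC
#' whose expected AUC is 0.5. Used to check the ROC machinery is unbiased.
#'
#' @param n_pos,n_neg Numbers of positive / negative cells.
#' @param n_thresholds Grid size of the score sweep.
#' @return A tibble of `threshold`, `TPR`, `FPR` points.
#' @export
roc_random_control <- function(n_pos = 40, n_neg = 300, n_thresholds = 21) {
  pos <- runif(n_pos); neg <- runif(n_neg)
  grid <- seq(0, 1, length.out = n_thresholds)
  tibble::tibble(
    threshold = grid,
    TPR = vapply(grid, function(t) mean(pos >= t), numeric(1)),
    FPR = vapply(grid, function(t) mean(neg >= t), numeric(1))
  )
}

#' Tidy an ROC sweep
#' @param x A `mousegait_roc` tibble.
#' @param ... Unused.
#' @return The points as a plain tibble.
#' @export
tidy.mousegait_roc <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' One-row summary of an ROC sweep
#' @param x A `mousegait_roc` tibble.
#' @param ... Unused.
#' @return Tibble with `auc`, `optimal_threshold` and the optimal point's
#'   rates and counts.
#' @export
glance.mousegait_roc <- function(x, ...) {
  ot <- optimal_threshold(x)
  tibble::tibble(auc = roc_auc(x), optimal_threshold = ot$threshold,
                 tpr_at_ot = ot$TPR, fpr_at_ot = ot$FPR,
                 fn_at_ot = ot$FN, fp_at_ot = ot$FP)
}
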