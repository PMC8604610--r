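gt_box <- function(frame, x, y, label = "Right-Front", r = 8) {
  tibble::tibble(frame_index = frame, label = label,
                 xmin = x - r, ymin = y - r, xmax = x + r, ymax = y + r)
}

pred <- function(frame, x, y, label = "Right-Front") {
  tibble::tibble(frame_index = frame, x = x, y = y, label = label)
}

test_that("matching scores hits, misses and mislabels per the event rules", {
  truth <- dplyr::bind_rows(
    gt_box(0, 100, 10, "Right-Front"), gt_box(0, 100, 50, "Left-Front"),
    gt_box(0, 50, 10, "Right-Rear"), gt_box(0, 50, 50, "Left-Rear"))
  # all four at box centers with correct labels
  p4 <- dplyr::bind_rows(
    pred(0, 100, 10, "Right-Front"), pred(0, 100, 50, "Left-Front"),
    pred(0, 50, 10, "Right-Rear"), pred(0, 50, 50, "Left-Rear"))
  m <- match_detections(p4, truth)
  expect_identical(c(m$hits, m$misses, m$falses), c(4L, 0L, 0L))
  # one prediction missing -> one miss
  m3 <- match_detections(p4[-2, ], truth)
  expect_identical(c(m3$hits, m3$misses, m3$falses), c(3L, 1L, 0L))
  # one label swapped: consumes the box, counts false (not miss)
  pswap <- p4; pswap$label[1] <- "Left-Front"; pswap$label[2] <- "Right-Front"
  msw <- match_detections(pswap, truth)
  expect_identical(c(msw$hits, msw$misses, msw$falses), c(2L, 0L, 2L))
  # spurious prediction far from any box -> false
  mfp <- match_detections(dplyr::bind_rows(p4, pred(0, 300, 30)), truth)
  expect_identical(c(mfp$hits, mfp$falses), c(4L, 1L))
  # label-agnostic mode: a swap is still a hit
  magn <- match_detections(pswap, truth, use_labels = FALSE)
  expect_identical(magn$hits, 4L)
})

test_that("H:M:F percentages use the event total and sum to 100 exactly", {
  sc <- hmf_score(tibble::tibble(frame_index = 1, hits = 92L, misses = 2L,
                                 falses = 6L))
  expect_equal(c(sc$hit_pct, sc$miss_pct, sc$false_pct), c(92, 2, 6))
  perfect <- hmf_score(tibble::tibble(frame_index = 1, hits = 10L,
                                      misses = 0L, falses = 0L))
  expect_equal(perfect$hit_pct, 100)
  set.seed(51)
  for (i in 1:20) {
    sc <- hmf_score(tibble::tibble(frame_index = 1,
                                   hits = sample(0:50, 1),
                                   misses = sample(0:50, 1),
                                   falses = sample(1:50, 1)))
    expect_equal(sc$hit_pct + sc$miss_pct + sc$false_pct, 100)
  }
  expect_error(hmf_score(tibble::tibble(frame_index = 1, hits = 0L,
                                        misses = 0L, falses = 0L)),
               "undefined")
})

test_that("PascalVOC annotations round-trip through write and read", {
  run <- generate_run(synthetic_gait_config(n_strides = 2, seed = 52))
  dir <- withr::local_tempdir()
  write_run(run, dir)
  back <- read_voc_dir(file.path(dir, "annotations"))
  orig <- dplyr::arrange(run$truth, frame_index, xmin)
  back <- dplyr::arrange(back, frame_index, xmin)
  expect_equal(as.data.frame(back),
               as.data.frame(dplyr::mutate(orig, dplyr::across(
                 c(xmin, ymin, xmax, ymax), as.numeric))))
  # frame files match the frame count
  expect_identical(length(list.files(file.path(dir, "frames"))),
                   length(run$frames))
  expect_error(read_voc_dir(withr::local_tempdir()), "no XML")
})

test_that("AUC is the anchored trapezoid area", {
  expect_equal(roc_auc(tibble::tibble(FPR = 0, TPR = 1)), 1.0)
  expect_equal(roc_auc(tibble::tibble(FPR = 0.5, TPR = 0.5)), 0.5)
  expect_equal(roc_auc(tibble::tibble(FPR = c(0.1, 0.3),
                                      TPR = c(0.8, 0.95))), 0.8975)
  # any single on-diagonal point gives chance area
  for (x in c(0.1, 0.7, 1)) {
    expect_equal(roc_auc(tibble::tibble(FPR = x, TPR = x)), 0.5)
  }
})

test_that("optimal threshold maximizes Youden's J with deterministic ties", {
  pts <- tibble::tibble(threshold = c(1, 2, 3),
                        TP = 1L, FP = 1L, FN = 1L, TN = 1L,
                        TPR = c(0.6, 0.95, 0.8),
                        FPR = c(0.1, 0.05, 0.1))
  expect_equal(optimal_threshold(pts)$threshold, 2)
  ties <- tibble::tibble(threshold = c(5, 4), TP = 1L, FP = 1L, FN = 1L,
                         TN = 1L, TPR = c(0.9, 0.9), FPR = c(0.1, 0.1))
  expect_equal(optimal_threshold(ties)$threshold, 4)
  perfect <- dplyr::bind_rows(pts, tibble::tibble(
    threshold = 9, TP = 4L, FP = 0L, FN = 0L, TN = 297L, TPR = 1, FPR = 0))
  expect_equal(optimal_threshold(perfect)$threshold, 9)
})

test_that("confusion matrices lay out [[TP, FN], [FP, TN]]", {
  pt <- tibble::tibble(TP = 4L, FN = 0L, FP = 3L, TN = 294L)
  cm <- confusion_matrix(pt)
  expect_identical(as.vector(t(cm)), c(4L, 0L, 3L, 294L))
  norm <- confusion_matrix(pt, normalize = TRUE)
  expect_equal(norm$rates[1, 1], 1)
  expect_equal(norm$rates[2, 1], 3 / 297)
  zero <- confusion_matrix(tibble::tibble(TP = 0L, FN = 7L, FP = 0L,
                                          TN = 294L))
  expect_identical(zero[1, ], c(detected = 0L, `not detected` = 7L))
})

test_that("roc_sweep counts cell events and rates per definition", {
  run <- generate_run(synthetic_gait_config(n_strides = 2, seed = 53))
  frames <- run$frames[30:39]
  truth <- dplyr::filter(run$truth,
                         frame_index %in% sapply(frames, frame_index))
  pts <- roc_sweep(frames, truth, vary = "green_threshold",
                   grid = c(100, 205), band = run$config$band)
  n_boxes <- nrow(truth)
  cells <- floor((run$config$band[2] - run$config$band[1]) *
                   run$config$frame_width / 400) * length(frames)
  expect_true(all(pts$TP + pts$FP + pts$FN + pts$TN == cells))
  expect_equal(pts$TPR, pts$TP / (pts$TP + pts$FN))
  expect_equal(pts$FPR, pts$FP / (pts$FP + pts$TN))
  # a permissive threshold on clean frames finds every box
  expect_equal(pts$TP[1], n_boxes)
  expect_equal(pts$TPR[1], 1)
})
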