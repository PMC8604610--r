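ff <- function(frames, x = 0, y = 0) {
  tibble::tibble(frame_index = as.integer(frames), x = x, y = y)
}

test_that("step segmentation splits on gaps and bridges small ones", {
  st <- segment_steps(ff(c(10:40, 70:100)), gap_tolerance = 2)
  expect_identical(nrow(st), 2L)
  expect_identical(st$t_f, c(10L, 70L))
  expect_identical(st$t_l, c(40L, 100L))
  # a 1-frame hole within tolerance merges into one step
  merged <- segment_steps(ff(c(10:20, 22:30)), gap_tolerance = 2)
  expect_identical(nrow(merged), 1L)
  expect_identical(c(merged$t_f, merged$t_l), c(10L, 30L))
  # a single detection is a degenerate one-frame step
  single <- segment_steps(ff(5))
  expect_identical(c(single$t_f, single$t_m, single$t_l), c(5L, 5L, 5L))
  expect_identical(nrow(segment_steps(ff(integer(0)))), 0L)
})

test_that("the step mean frame snaps to the nearest detected frame", {
  # frames 0..10 with the middle missing: floor midpoint 5 absent,
  # nearest member (earlier on ties) is 4
  st <- segment_steps(ff(c(0:4, 6:10)), gap_tolerance = 2)
  expect_identical(st$t_m, 4L)
  # centroid at the mean frame is that frame's centroid
  d <- ff(c(0:10)); d$x <- d$frame_index * 2
  expect_identical(segment_steps(d)$x_m, 10)
})

test_that("run duration and cadence follow their defining ratios", {
  expect_equal(run_duration(ff(c(0, 60))), 1.0)
  expect_equal(run_duration(ff(5)), 0.0)
  expect_equal(run_duration(ff(c(30, 330))), 5.0)
  expect_error(run_duration(ff(integer(0))), "no detected")
  expect_equal(cadence(10, 2.0), 5.0)
  expect_equal(cadence(0, 2.0), 0.0)
  expect_equal(cadence(7, 3.5), 2.0)
  expect_true(is.na(cadence(3, 0)))
})

test_that("stride lengths are centroid distances averaged over S-1 values", {
  steps <- tibble::tibble(x_m = c(0, 120), y_m = c(0, 0))
  expect_equal(stride_lengths(steps)$per_step, 120)
  expect_equal(stride_lengths(tibble::tibble(x_m = c(0, 3),
                                             y_m = c(0, 4)))$per_step, 5)
  three <- tibble::tibble(x_m = c(0, 100, 220), y_m = c(0, 0, 0))
  sl <- stride_lengths(three)
  expect_equal(sl$per_step, c(100, 120))
  expect_equal(sl$average, 110)
  one <- stride_lengths(tibble::tibble(x_m = 0, y_m = 0))
  expect_length(one$per_step, 0)
  expect_true(is.na(one$average))
})

test_that("stance, swing and duty cycle come from step frame spans", {
  st <- segment_steps(ff(c(10:40, 70:100)))
  ss <- swing_and_stance(st)
  expect_equal(ss$stance, c(0.5, 0.5))
  expect_equal(ss$swing, 0.5)
  expect_equal(ss$duty_cycle, 2 / 3)
  # one instantaneous step: zero stance, duty cycle 1 by convention
  one <- swing_and_stance(segment_steps(ff(5)))
  expect_equal(one$stance, 0)
  expect_equal(one$duty_cycle, 1)
  # stance-only run over frames 0-59
  long <- swing_and_stance(segment_steps(ff(0:59)))
  expect_equal(long$stance, 59 / 60)
  expect_equal(long$duty_cycle, 1)
  expect_error(swing_and_stance(segment_steps(ff(integer(0)))), "no steps")
})

test_that("paw supports count shared contact frames at-least-k", {
  mk <- function(t_f, t_l) tibble::tibble(step = 1L, t_f = t_f, t_m = t_f,
                                          t_l = t_l, x_m = 0, y_m = 0,
                                          n_frames = t_l - t_f + 1L)
  all4 <- list("Left-Front" = mk(0, 29), "Right-Front" = mk(0, 29),
               "Left-Rear" = mk(0, 29), "Right-Rear" = mk(0, 29))
  sup <- paw_support(all4, rd = 1)
  expect_equal(sup$seconds[sup$support == "four_point"], 0.5)
  # no overlap at all
  apart <- list("Left-Front" = mk(0, 5), "Right-Front" = mk(10, 15),
                "Left-Rear" = mk(20, 25), "Right-Rear" = mk(30, 35))
  expect_true(all(paw_support(apart, rd = 1)$seconds == 0))
  # diagonal pair LF + RR sharing frames 5-10
  diag <- list("Left-Front" = mk(0, 10), "Right-Rear" = mk(5, 15))
  supd <- paw_support(diag, rd = 1)
  expect_equal(supd$seconds[supd$support == "diagonal_dual"], 0.1)
  expect_equal(supd$seconds[supd$support == "three_point"], 0)
  expect_equal(supd$seconds[supd$support == "four_point"], 0)
})

test_that("four-point support never exceeds three-point support", {
  set.seed(41)
  for (i in 1:10) {
    steps <- lapply(setNames(paw_labels(), paw_labels()), function(lab) {
      t0 <- sample(0:30, 1); len <- sample(5:40, 1)
      tibble::tibble(step = 1L, t_f = t0, t_m = t0, t_l = t0 + len,
                     x_m = 0, y_m = 0, n_frames = len + 1L)
    })
    sup <- paw_support(steps, rd = 2)
    expect_lte(sup$seconds[sup$support == "four_point"],
               sup$seconds[sup$support == "three_point"])
  }
})

test_that("paw area and intensity are two-level means", {
  cl <- tibble::tibble(size = c(80L, 120L), g_mean = c(220, 255))
  ai <- paw_area_intensity(cl)
  expect_equal(ai$avg_area, 100)
  expect_equal(ai$avg_intensity, 237.5)
  expect_equal(paw_area_intensity(tibble::tibble(size = 10L,
                                                 g_mean = 255))$avg_intensity,
               255)
  expect_true(is.na(paw_area_intensity(cl[0, ])$avg_area))
})

test_that("summarize_gait assembles all parameters and handles partial data", {
  run <- generate_run(synthetic_gait_config(n_strides = 3, seed = 42))
  cls <- classify_paws(detect_run(run$frames, band = run$config$band))
  summ <- summarize_gait(cls)
  expect_s3_class(summ, "gait_summary")
  expect_identical(nrow(summ$paws), 4L)
  expect_true(all(summ$paws$duty_cycle >= 0 & summ$paws$duty_cycle <= 1))
  td <- tidy(summ); gl <- glance(summ)
  expect_identical(nrow(td), 4L)
  expect_identical(nrow(gl), 1L)
  expect_true(all(c("four_point_s", "run_duration_s") %in% names(gl)))
  # front paws only: rear fields missing, run duration still defined
  front <- dplyr::filter(cls, grepl("Front", label))
  partial <- summarize_gait(front)
  expect_true(all(is.na(partial$paws$duty_cycle[grepl("Rear",
                                                      partial$paws$label)])))
  expect_gt(partial$run$run_duration_s, 0)
  expect_error(summarize_gait(cls[0, ]), "nothing to summarize")
})

test_that("stance plus swing stays within the paw's active interval", {
  for (seed in c(43, 44)) {
    run <- generate_run(synthetic_gait_config(n_strides = 3, seed = seed))
    cls <- classify_paws(detect_run(run$frames, band = run$config$band))
    summ <- summarize_gait(cls)
    rd <- summ$run$run_duration_s
    for (lab in paw_labels()) {
      st <- dplyr::filter(summ$steps, label == lab)
      ss <- swing_and_stance(st)
      expect_lte(sum(ss$stance) + sum(ss$swing), rd + 2 / 60)
      # duty cycle equals the stance fraction of the same step set
      expect_equal(summ$paws$duty_cycle[summ$paws$label == lab],
                   sum(ss$stance) / (sum(ss$stance) + sum(ss$swing)))
    }
  }
})
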