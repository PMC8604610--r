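# Gait-parameter extraction. Each paw's footfall track is segmented into
# steps (maximal contact phases, bridging short detection gaps); stride
# length, stance, swing, duty cycle, cadence, paw supports and paw
# area/intensity are then computed from the step table. Durations use
# (last - first)/fps so they are nonnegative; averages of consecutive-pair
# quantities (stride, swing) divide by the number of values actually present
# (S - 1 for S steps), not by S.

#' Segment one paw's footfalls into steps
#'
#' A step is a maximal run of frames in which the paw is detected, where
#' gaps of at most `gap_tolerance` missing frames are bridged (a missed
#' detection otherwise splits one contact phase in two). For each step the
#' first/mean/last contact frames are recorded; the mean frame is
#' `floor((first + last) / 2)` snapped to the nearest member frame (earlier
#' on ties), and the step centroid is that frame's centroid.
#'
#' @param footfalls Tibble of one paw's classified footfalls (columns
#'   `frame_index`, `x`, `y`), any order.
#' @param gap_tolerance Maximum number of consecutive missing frames bridged
#'   within one step. Default 2.
#' @return A tibble with one row per step: `step`, `t_f`, `t_m`, `t_l`,
#'   `x_m`, `y_m` (centroid at the mean frame), `n_frames`.
#' @export
#' @examples
#' ff <- tibble::tibble(frame_index = c(10:40, 70:100), x = 0, y = 0)
#' segment_steps(ff)
segment_steps <- function(footfalls, gap_tolerance = 2L) {
  if (gap_tolerance < 0) stop("`gap_tolerance` must be >= 0", call. = FALSE)
  empty <- tibble::tibble(step = integer(0), t_f = integer(0),
                          t_m = integer(0), t_l = integer(0),
                          x_m = double(0), y_m = double(0),
                          n_frames = integer(0))
  if (nrow(footfalls) == 0L) return(empty)
  ff <- dplyr::arrange(footfalls, .data$frame_index)
  frames <- ff$frame_index
  # new step where the gap to the previous detected frame exceeds tolerance
  brk <- c(TRUE, diff(frames) > gap_tolerance + 1L)
  step_id <- cumsum(brk)
  purrr::map(split(seq_along(frames), step_id), function(ix) {
    fr <- frames[ix]
    t_f <- fr[1]; t_l <- fr[length(fr)]
    mid <- floor((t_f + t_l) / 2)
    # snap to the nearest member frame, earlier on ties
    t_m <- fr[order(abs(fr - mid), fr)][1]
    at <- ix[match(t_m, fr)]
    tibble::tibble(t_f = t_f, t_m = t_m, t_l = t_l,
                   x_m = ff$x[at], y_m = ff$y[at],
                   n_frames = length(fr))
  }) |>
    purrr::list_rbind() |>
    dplyr::mutate(step = dplyr::row_number(), .before = 1)
}

#' Run duration
#'
#' Seconds from the first to the last frame containing at least one detected
#' paw: `(t_last - t_first) / fps`.
#'
#' @param footfalls Tibble with a `frame_index` column (all paws pooled).
#' @param fps Frame rate; default 60.
#' @return Run duration in seconds.
#' @export
run_duration <- function(footfalls, fps = 60) {
  if (nrow(footfalls) == 0L) {
    stop("run duration undefined: no detected footfalls", call. = FALSE)
  }
  (max(footfalls$frame_index) - min(footfalls$frame_index)) / fps
}

#' Cadence
#'
#' Steps per second: `S / RD`.
#'
#' @param step_count Number of steps `S`.
#' @param rd Run duration in seconds.
#' @return Steps per second; `NA` when `rd` is 0 with steps present.
#' @export
cadence <- function(step_count, rd) {
  if (step_count == 0) return(0)
  if (rd <= 0) return(NA_real_)
  step_count / rd
}

#' Stride lengths
#'
#' Euclidean distance between the mean-frame centroids of consecutive steps
#' of the same paw; the average is the mean of those `S - 1` values.
#'
#' @param steps Step tibble from [segment_steps()].
#' @return List with `per_step` (numeric vector, length `S - 1`) and
#'   `average` (`NA` when fewer than two steps).
#' @export
stride_lengths <- function(steps) {
  s <- nrow(steps)
  if (s < 2L) return(list(per_step = numeric(0), average = NA_real_))
  dx <- diff(steps$x_m); dy <- diff(steps$y_m)
  per <- sqrt(dx^2 + dy^2)
  list(per_step = per, average = mean(per))
}

#' Stance, swing and duty cycle
#'
#' Per step `j`: stance `R_j = (t_l_j - t_f_j) / fps`; between consecutive
#' steps: swing `D_j = (t_f_{j+1} - t_l_j) / fps`. The duty cycle is
#' `sum(R) / (sum(R) + sum(D))`; with a single step no swing is observed and
#' the duty cycle is 1 by convention.
#'
#' @param steps Step tibble from [segment_steps()].
#' @param fps Frame rate; default 60.
#' @return List with `stance` (length `S`), `swing` (length `S - 1`),
#'   `avg_stance`, `avg_swing` (`NA` if no swing), and `duty_cycle`.
#' @export
#' @examples
#' st <- segment_steps(tibble::tibble(frame_index = c(10:40, 70:100),
#'                                    x = 0, y = 0))
#' swing_and_stance(st)  # duty cycle 2/3
swing_and_stance <- function(steps, fps = 60) {
  s <- nrow(steps)
  if (s == 0L) stop("no steps: stance/swing undefined", call. = FALSE)
  stance <- (steps$t_l - steps$t_f) / fps
  swing <- if (s >= 2L) (steps$t_f[-1] - steps$t_l[-s]) / fps else numeric(0)
  total_r <- sum(stance); total_d <- sum(swing)
  dc <- if (total_r + total_d == 0) 1 else total_r / (total_r + total_d)
  list(stance = stance, swing = swing,
       avg_stance = mean(stance),
       avg_swing = if (s >= 2L) mean(swing) else NA_real_,
       duty_cycle = dc)
}

#' Paw supports
#'
#' For every frame of the run, counts which paws are in contact (a paw is in
#' contact during each of its step intervals `[t_f, t_l]`, gap-bridged).
#' Reports the duration with a diagonal pair simultaneously down (LF+RR or
#' RF+LR), with at least three paws down, and with all four down — each as
#' `shared_frames / fps` seconds and as a fraction of the run duration.
#'
#' @param steps_by_paw Named list of step tibbles, one per paw label.
#' @param rd Run duration in seconds (denominator of the fractions).
#' @param fps Frame rate; default 60.
#' @return A tibble with columns `support`, `seconds`, `fraction`.
#' @export
paw_support <- function(steps_by_paw, rd, fps = 60) {
  contact_frames <- purrr::map(steps_by_paw, function(st) {
    if (is.null(st) || nrow(st) == 0L) return(integer(0))
    unlist(purrr::map2(st$t_f, st$t_l, seq))
  })
  for (lab in PAW_LABELS) {
    if (is.null(contact_frames[[lab]])) contact_frames[[lab]] <- integer(0)
  }
  all_frames <- sort(unique(unlist(contact_frames)))
  down <- purrr::map(contact_frames[PAW_LABELS], ~ all_frames %in% .x)
  n_down <- Reduce(`+`, down)
  diag1 <- down[["Left-Front"]] & down[["Right-Rear"]]
  diag2 <- down[["Right-Front"]] & down[["Left-Rear"]]
  counts <- c(diagonal_dual = sum(diag1 | diag2),
              three_point = sum(n_down >= 3L),
              four_point = sum(n_down == 4L))
  tibble::tibble(
    support = names(counts),
    seconds = unname(counts) / fps,
    fraction = if (rd > 0) unname(counts) / fps / rd else NA_real_
  )
}

#' Average paw area and intensity
#'
#' Area of a cluster is its green-pixel count; intensity is its mean G value.
#' Averages are taken over all clusters of the same paw.
#'
#' @param clusters Tibble of one paw's clusters with `size` and `g_mean`
#'   columns.
#' @return List with `avg_area` and `avg_intensity`.
#' @export
paw_area_intensity <- function(clusters) {
  if (nrow(clusters) == 0L) {
    return(list(avg_area = NA_real_, avg_intensity = NA_real_))
  }
  list(avg_area = mean(clusters$size),
       avg_intensity = mean(clusters$g_mean))
}

#' Summarize the gait of a classified run
#'
#' Assembles the full parameter set: run duration, per-paw step count,
#' cadence, stride length, stance, swing, duty cycle, area and intensity,
#' plus the paw supports and a pooled cadence (total steps over run
#' duration). Unclassified clusters are excluded. A paw with no steps yields
#' `NA` for its per-paw fields.
#'
#' @param classified Tibble from [classify_paws()].
#' @param fps Frame rate; default 60.
#' @param gap_tolerance Passed to [segment_steps()].
#' @param px_per_mm Optional scale; when given, lengths are also reported in
#'   mm (`avg_stride_length_mm`).
#' @return A `gait_summary` object: list with `run` (one-row tibble), `paws`
#'   (one row per paw), `supports`, and `steps` (all steps, with labels).
#' @export
#' @examples
#' run <- generate_run(synthetic_gait_config(n_strides = 2))
#' summarize_gait(classify_paws(detect_run(run$frames)))
summarize_gait <- function(classified, fps = 60, gap_tolerance = 2L,
                           px_per_mm = NULL) {
  used <- dplyr::filter(classified, .data$label %in% PAW_LABELS)
  if (nrow(used) == 0L) {
    stop("no classified footfalls: nothing to summarize", call. = FALSE)
  }
  rd <- run_duration(used, fps = fps)

  per_paw <- purrr::map(setNames(PAW_LABELS, PAW_LABELS), function(lab) {
    ff <- dplyr::filter(used, .data$label == lab)
    if (nrow(ff) == 0L) {
      return(list(steps = NULL,
                  row = tibble::tibble(
                    label = lab, step_count = 0L,
                    cadence_steps_per_s = NA_real_,
                    avg_stride_length_px = NA_real_,
                    avg_stance_s = NA_real_, avg_swing_s = NA_real_,
                    duty_cycle = NA_real_,
                    avg_area_px = NA_real_, avg_intensity = NA_real_)))
    }
    st <- segment_steps(ff, gap_tolerance = gap_tolerance)
    sl <- stride_lengths(st)
    ss <- swing_and_stance(st, fps = fps)
    ai <- paw_area_intensity(ff)
    list(steps = st,
         row = tibble::tibble(
           label = lab,
           step_count = nrow(st),
           cadence_steps_per_s = cadence(nrow(st), rd),
           avg_stride_length_px = sl$average,
           avg_stance_s = ss$avg_stance,
           avg_swing_s = ss$avg_swing,
           duty_cycle = ss$duty_cycle,
           avg_area_px = ai$avg_area,
           avg_intensity = ai$avg_intensity))
  })

  paws <- purrr::map(per_paw, "row") |> purrr::list_rbind()
  if (!is.null(px_per_mm)) {
    paws$avg_stride_length_mm <- paws$avg_stride_length_px / px_per_mm
  }
  steps_by_paw <- purrr::map(per_paw, "steps")
  supports <- paw_support(steps_by_paw, rd = rd, fps = fps)
  steps_all <- purrr::imap(steps_by_paw, function(st, lab) {
    if (is.null(st)) NULL else dplyr::mutate(st, label = lab, .before = 1)
  }) |> purrr::list_rbind()

  total_steps <- sum(paws$step_count)
  run <- tibble::tibble(
    run_duration_s = rd,
    total_steps = total_steps,
    cadence_total_steps_per_s = cadence(total_steps, rd)
  )
  structure(list(run = run, paws = paws, supports = supports,
                 steps = steps_all, fps = fps),
            class = "gait_summary")
}

#' @export
print.gait_summary <- function(x, ...) {
  cat(sprintf("<gait_summary> run %.3f s, %d steps, cadence %.2f steps/s\n",
              x$run$run_duration_s, x$run$total_steps,
              x$run$cadence_total_steps_per_s))
  print(x$paws)
  print(x$supports)
  invisible(x)
}

#' Tidy a gait summary
#'
#' @param x A `gait_summary`.
#' @param ... Unused.
#' @return The per-paw parameter tibble (one row per paw).
#' @export
tidy.gait_summary <- function(x, ...) x$paws

#' One-row run-level view of a gait summary
#'
#' @param x A `gait_summary`.
#' @param ... Unused.
#' @return One-row tibble: run duration, total steps, pooled cadence, and
#'   the three supports in seconds.
#' @export
glance.gait_summary <- function(x, ...) {
  sup <- setNames(x$supports$seconds, paste0(x$supports$support, "_s"))
  dplyr::bind_cols(x$run, tibble::as_tibble(as.list(sup)))
}

#' Per-paw distance-versus-time trace
#'
#' The x coordinate of each classified footfall over time: horizontal
#' segments are contact phases, diagonal jumps are swings.
#'
#' @param classified Tibble from [classify_paws()].
#' @param fps Frame rate; default 60.
#' @return Tibble with `label`, `time_s`, `x`, `y`.
#' @export
footfall_traces <- function(classified, fps = 60) {
  classified |>
    dplyr::filter(.data$label %in% PAW_LABELS) |>
    dplyr::transmute(label = .data$label,
                     time_s = .data$frame_index / fps,
                     x = .data$x, y = .data$y)
}
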