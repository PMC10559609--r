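# Video-level diagnosis: the consecutive-duration rule over per-frame
# cancer calls, streaming composition with the segmenter, and duration-grid
# selection.

#' Default duration-threshold candidate grid (seconds)
#' @return strictly increasing numeric vector `c(0.5, 1, 1.5, 2, 2.5, 3)`.
#' @export
duration_threshold_grid <- function() {
  c(0.5, 1, 1.5, 2, 2.5, 3)
}

#' Video-level diagnosis from per-frame decisions
#'
#' Finds the longest run of consecutive cancer frames, converts it to
#' seconds (`run_length / fps`), and diagnoses cancer exactly when that
#' duration strictly exceeds `duration_threshold`. A single negative frame
#' breaks a run unless `gap_tolerance` allows bridging short negative gaps.
#'
#' @param frame_decisions ordered logical vector of per-frame cancer calls.
#' @param fps frames per second (positive).
#' @param duration_threshold seconds; default 2.
#' @param gap_tolerance maximum number of consecutive negative frames that
#'   may be bridged inside a run (default 0: strict consecutiveness).
#' @return list of class `video_diagnosis`: `is_cancer`,
#'   `longest_run_frames`, `longest_run_seconds`, `fps`, `n_frames`.
#' @export
diagnose_video <- function(frame_decisions, fps, duration_threshold = 2,
                           gap_tolerance = 0L) {
  if (!length(frame_decisions)) stop("empty frame sequence", call. = FALSE)
  if (!is.finite(fps) || fps <= 0) stop("fps must be positive", call. = FALSE)
  d <- as.logical(frame_decisions)
  if (anyNA(d)) stop("frame decisions must be TRUE/FALSE", call. = FALSE)
  if (gap_tolerance > 0L) {
    r <- rle(d)
    bridge <- !r$values & r$lengths <= gap_tolerance
    # only interior gaps flanked by positive runs are bridged
    interior <- seq_along(r$values) > 1L & seq_along(r$values) < length(r$values)
    r$values[bridge & interior] <- TRUE
    d <- inverse.rle(r)
  }
  r <- rle(d)
  longest <- if (any(r$values)) max(r$lengths[r$values]) else 0L
  seconds <- longest / fps
  structure(list(is_cancer = seconds > duration_threshold,
                 longest_run_frames = as.integer(longest),
                 longest_run_seconds = seconds,
                 fps = fps, n_frames = length(frame_decisions),
                 duration_threshold = duration_threshold),
            class = "video_diagnosis")
}

#' Stream a video through the full diagnostic pipeline
#'
#' Composes, frame by frame and in order: segmentation
#' ([predict_frame()]), morphological cleanup ([clean_mask()]), the
#' area-threshold frame call ([classify_frame()]), and finally the
#' consecutive-duration rule ([diagnose_video()]). Per-frame latency is
#' logged for information only.
#'
#' @param video an `endo_video` (see [read_video_frames()] /
#'   [generate_video()]) or a list of frames plus `fps`.
#' @param model trained `unet_model`.
#' @param probability_threshold segmentation probability cutoff.
#' @param area_threshold frame-level area threshold (reference pixels).
#' @param structuring_element_size cleanup structuring element side.
#' @param duration_threshold video-level duration threshold (seconds).
#' @param gap_tolerance see [diagnose_video()].
#' @param fps frame rate override when `video` carries none.
#' @return list of class `video_diagnosis` with an additional `log`
#'   data.frame (one row per frame: decision, area score, latency seconds).
#' @export
stream_diagnose <- function(video, model, probability_threshold = 0.5,
                            area_threshold = 1024,
                            structuring_element_size = 5L,
                            duration_threshold = 2, gap_tolerance = 0L,
                            fps = NULL) {
  frames <- if (inherits(video, "endo_video")) video$frames else video
  fps <- fps %||% (if (inherits(video, "endo_video")) video$fps else NULL)
  if (is.null(fps)) stop("fps unknown; pass `fps` explicitly", call. = FALSE)
  n <- length(frames)
  decision <- logical(n); score <- numeric(n); latency <- numeric(n)
  for (i in seq_len(n)) {
    t0 <- proc.time()[["elapsed"]]
    seg <- predict_frame(model, frames[[i]], probability_threshold)
    cleaned <- clean_mask(seg$binary_mask, structuring_element_size)
    fd <- classify_frame(cleaned, area_threshold)
    decision[i] <- fd$is_cancer
    score[i] <- fd$score
    latency[i] <- proc.time()[["elapsed"]] - t0
  }
  out <- diagnose_video(decision, fps, duration_threshold, gap_tolerance)
  out$log <- data.frame(frame = seq_len(n) - 1L, decision = decision,
                        area_score = score, latency_s = latency)
  out
}

#' Select the video-level duration threshold on a verification set
#'
#' Evaluates every candidate duration against per-video longest-run lengths
#' and returns the best by accuracy (full table reported; ties go to the
#' smaller duration, favouring sensitivity).
#'
#' @param run_seconds per-video longest consecutive-cancer run, in seconds.
#' @param truth per-video logical cancer truth.
#' @param grid candidate durations, strictly increasing
#'   (default [duration_threshold_grid()]).
#' @return list with `selected_threshold`, `table`, `metric`.
#' @export
select_duration_threshold <- function(run_seconds, truth,
                                      grid = duration_threshold_grid()) {
  select_threshold_from_grid(run_seconds, truth, grid, "accuracy")
}
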