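# Novel-object neophobia: darting-event detection from frame-to-frame links
# and the latency-to-resume-normal-swimming rule (normal swimming resumes
# when fewer than 2 fish dart per 10 s window).

#' Latency (resumption) rule
#'
#' A window of length `window_s` qualifies when the number of distinct
#' darting fish in it is strictly below `max_darts_exclusive`. Windows start
#' at 0 and slide by `window_step_s`; optionally the first
#' `require_consecutive_windows`-long run of qualifying windows is required.
#'
#' @param window_s Window length in seconds (default 10).
#' @param max_darts_exclusive Exclusive darting-fish threshold (default 2:
#'   "less than 2 fish per 10 s").
#' @param window_step_s Window step in seconds (default 1, sliding).
#' @param require_consecutive_windows Number of consecutive qualifying
#'   windows required (default 1).
#' @return An object of class `latency_rule`.
#' @export
latency_rule <- function(window_s = 10, max_darts_exclusive = 2,
                         window_step_s = 1, require_consecutive_windows = 1) {
  assert_scalar_num(window_s, "window_s", lo = 1e-9)
  assert_scalar_num(max_darts_exclusive, "max_darts_exclusive", lo = 1)
  assert_scalar_num(window_step_s, "window_step_s", lo = 1e-9, hi = window_s)
  assert_scalar_num(require_consecutive_windows,
                    "require_consecutive_windows", lo = 1)
  structure(list(window_s = window_s,
                 max_darts_exclusive = max_darts_exclusive,
                 window_step_s = window_step_s,
                 require_consecutive_windows = as.integer(require_consecutive_windows)),
            class = "latency_rule")
}

#' Detect darting events from frame-to-frame links
#'
#' Links are chained into tracklets; a tracklet emits one dart event per
#' continuous excursion during which its instantaneous speed exceeds
#' `dart_speed_bl_per_s` body lengths per second for at least
#' `min_dart_frames` consecutive frame steps. The event time is the onset of
#' the excursion.
#'
#' @param links Match table from [link_all_frames()] (columns `frame`,
#'   `object_t`, `object_t1`, `displacement_cm`, `est_fish_count`).
#' @param size A [estimate_fish_size()] model.
#' @param fps Frame rate.
#' @param dart_speed_bl_per_s Speed threshold in body lengths/s (default 3).
#' @param min_dart_frames Minimum excursion length in frame steps
#'   (default 2).
#' @return data.frame of events: `onset_s`, `object` (tracklet id),
#'   `peak_speed_cmps`, `est_fish_count` (at onset).
#' @export
detect_darts <- function(links, size, fps, dart_speed_bl_per_s = 3,
                         min_dart_frames = 2) {
  stopifnot(inherits(size, "size_model"))
  assert_scalar_num(fps, "fps", lo = 1e-9)
  empty <- data.frame(onset_s = numeric(), object = integer(),
                      peak_speed_cmps = numeric(), est_fish_count = numeric())
  if (nrow(links) == 0) return(empty)
  thr_cmps <- dart_speed_bl_per_s * size$body_length_cm
  links <- links[order(links$frame, links$object_t), , drop = FALSE]
  links$speed_cmps <- links$displacement_cm * fps

  # chain matches into tracklets: a link at frame f ending on object j
  # continues a tracklet whose last link ended at frame f (object j at f+1
  # becomes object_t of the pair starting at f+1)
  track_of <- new.env(parent = emptyenv())  # key "frame:object" -> tracklet id
  n_tracks <- 0L
  tr_id <- integer(nrow(links))
  for (k in seq_len(nrow(links))) {
    key_in <- paste0(links$frame[k], ":", links$object_t[k])
    id <- track_of[[key_in]]
    if (is.null(id)) {
      n_tracks <- n_tracks + 1L
      id <- n_tracks
    }
    tr_id[k] <- id
    track_of[[paste0(links$frame[k] + 1L, ":", links$object_t1[k])]] <- id
  }
  links$tracklet <- tr_id

  events <- list()
  for (id in unique(tr_id)) {
    seg <- links[links$tracklet == id, , drop = FALSE]
    fast <- seg$speed_cmps > thr_cmps
    # split into runs over consecutive frames of the same tracklet
    run_id <- cumsum(c(1L, diff(seg$frame) != 1L | diff(fast) != 0L))
    for (r in unique(run_id)) {
      ri <- which(run_id == r)
      if (!fast[ri[1]] || length(ri) < min_dart_frames) next
      events[[length(events) + 1L]] <- data.frame(
        onset_s = (seg$frame[ri[1]] - 1) / fps,
        object = id,
        peak_speed_cmps = max(seg$speed_cmps[ri]),
        est_fish_count = seg$est_fish_count[ri[1]])
    }
  }
  if (length(events) == 0) return(empty)
  out <- do.call(rbind, events)
  out[order(out$onset_s), , drop = FALSE]
}

#' Darting events from ground-truth darting flags
#'
#' Rising edges of the simulator's per-agent darting flags, expressed in the
#' same event-table form as [detect_darts()] -- the oracle for latency
#' recovery checks.
#'
#' @param sim A [simulate_school()] result.
#' @return data.frame with `onset_s`, `object`, `est_fish_count` (= 1).
#' @export
gt_dart_events <- function(sim) {
  stopifnot(inherits(sim, "school_sim"))
  d <- sim$darting
  onset <- d & !rbind(FALSE, d[-nrow(d), , drop = FALSE])
  idx <- which(onset, arr.ind = TRUE)
  out <- data.frame(onset_s = (idx[, 1] - 1) / sim$fps, object = idx[, 2],
                    est_fish_count = 1)
  out[order(out$onset_s), , drop = FALSE]
}

#' Latency to resume normal swimming
#'
#' Scans windows `[s, s + window_s)` for `s = 0, step, 2 step, ...` within
#' the clip; a window qualifies when the summed fish-equivalents of distinct
#' objects with at least one dart event in it is strictly below the rule
#' threshold (an object with estimated fish count >= 2 counts with its
#' rounded count, never less than 1). The latency is the start of the first
#' qualifying window (or first run of `require_consecutive_windows`); if no
#' window qualifies the result is censored at `clip_duration_s`.
#'
#' @param events Event table ([detect_darts()] or an external scoring export
#'   with columns `onset_s`/`time_s` and `object`/`subject_id`).
#' @param rule A [latency_rule()].
#' @param clip_duration_s Clip duration in seconds.
#' @return List of class `latency_result`: `latency_s`, `censored`,
#'   `n_windows`.
#' @export
latency_to_resume <- function(events, rule = latency_rule(),
                              clip_duration_s) {
  stopifnot(inherits(rule, "latency_rule"))
  assert_scalar_num(clip_duration_s, "clip_duration_s", lo = 1e-9)
  events <- normalise_events(events)
  if (any(events$onset_s < 0)) stopf("event times must be non-negative")
  starts <- seq(0, max(0, clip_duration_s - rule$window_s),
                by = rule$window_step_s)
  counts <- vapply(starts, function(s) {
    in_w <- events$onset_s >= s & events$onset_s < s + rule$window_s
    if (!any(in_w)) return(0)
    ev <- events[in_w, , drop = FALSE]
    per_obj <- tapply(ev$est_fish_count, ev$object, max)
    sum(pmax(1, round(per_obj)))
  }, numeric(1))
  ok <- counts < rule$max_darts_exclusive
  need <- rule$require_consecutive_windows
  hit <- NA_integer_
  if (need <= 1L) {
    w <- which(ok)
    if (length(w)) hit <- w[1]
  } else {
    run <- 0L
    for (i in seq_along(ok)) {
      run <- if (ok[i]) run + 1L else 0L
      if (run >= need) { hit <- i - need + 1L; break }
    }
  }
  if (is.na(hit)) {
    res <- list(latency_s = clip_duration_s, censored = TRUE,
                n_windows = length(starts))
  } else {
    res <- list(latency_s = starts[hit], censored = FALSE,
                n_windows = length(starts))
  }
  class(res) <- "latency_result"
  res
}

#' @export
print.latency_result <- function(x, ...) {
  cat(sprintf("<latency_result> %.1f s%s (%d windows scanned)\n", x$latency_s,
              if (x$censored) " (censored)" else "", x$n_windows))
  invisible(x)
}

# accept detect_darts() output or common behavioural-observation exports
normalise_events <- function(events) {
  if (!is.data.frame(events)) stopf("events must be a data.frame")
  if (!"onset_s" %in% names(events) && "time_s" %in% names(events))
    events$onset_s <- events$time_s
  if (!"object" %in% names(events) && "subject_id" %in% names(events))
    events$object <- events$subject_id
  if (nrow(events) == 0)
    return(data.frame(onset_s = numeric(), object = integer(),
                      est_fish_count = numeric()))
  if (!all(c("onset_s", "object") %in% names(events)))
    stopf("events need columns onset_s/time_s and object/subject_id")
  if (!"est_fish_count" %in% names(events)) events$est_fish_count <- 1
  events
}

#' Read an externally scored event table
#'
#' Accepts CSV exports with columns `time_s` and `subject_id` (as produced
#' by interactive behavioural-observation scoring software), so the latency
#' rule can be applied to human annotations.
#' @param path CSV path.
#' @return Normalised event data.frame.
#' @export
read_events_csv <- function(path) normalise_events(read.csv(path))

#' Export latencies across trials with a square-root transform
#'
#' Adds the `sqrt_latency` column commonly used before Gaussian model
#' fitting. Censored trials keep their censoring flag and their
#' `sqrt_latency` is set to `NA` rather than transformed silently.
#'
#' @param latencies data.frame with columns `latency_s` and `censored`
#'   (plus any trial metadata), or a list of `latency_result` objects.
#' @return The data.frame with `sqrt_latency` added.
#' @export
sqrt_transform_export <- function(latencies) {
  if (!is.data.frame(latencies)) {
    latencies <- do.call(rbind, lapply(latencies, function(l)
      data.frame(latency_s = l$latency_s, censored = l$censored)))
  }
  if (any(latencies$latency_s < 0, na.rm = TRUE))
    stopf("latencies must be non-negative")
  latencies$sqrt_latency <- ifelse(latencies$censored, NA_real_,
                                   sqrt(latencies$latency_s))
  latencies
}
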