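# Per-clip behavioural welfare indicators: group cohesion (area ratio plus
# tight/loose/dispersed categorical score), activity (size-weighted mean
# centroid displacement) and enrichment occupation.

#' Categorical cohesion scoring rule
#'
#' Three ordered categories partitioning \[0, 1\]: tight (0) below
#' `tight_upper`, dispersed (2) above `dispersed_lower`, loose (1) in
#' between, with both boundaries belonging to "loose".
#'
#' @param tight_upper Upper bound of the tight class (default 0.25).
#' @param dispersed_lower Lower bound of the dispersed class (default 0.75).
#' @return An object of class `cohesion_rule`.
#' @export
cohesion_rule <- function(tight_upper = 0.25, dispersed_lower = 0.75) {
  if (!(0 < tight_upper && tight_upper < dispersed_lower &&
        dispersed_lower < 1))
    stopf("need 0 < tight_upper < dispersed_lower < 1")
  structure(list(tight_upper = tight_upper,
                 dispersed_lower = dispersed_lower), class = "cohesion_rule")
}

#' Categorical cohesion score of an area ratio
#'
#' @param ratio Numeric vector of group-area ratios in \[0, 1\].
#' @param rule A [cohesion_rule()] (default: tight < 0.25, dispersed > 0.75).
#' @return Integer vector of ordinal scores: 0 = tight, 1 = loose,
#'   2 = dispersed.
#' @export
cohesion_score <- function(ratio, rule = cohesion_rule()) {
  if (any(!is.finite(ratio) | ratio < 0 | ratio > 1))
    stopf("ratio must lie in [0, 1]")
  ifelse(ratio < rule$tight_upper, 0L,
         ifelse(ratio > rule$dispersed_lower, 2L, 1L))
}

#' Group cohesion ratio of a clip
#'
#' Per frame, the area occupied by the main group is the convex hull of the
#' main-group member centroids dilated by one body radius (`body_length / 2`);
#' with a single member (e.g. the whole school merged into one blob) the
#' member's own pixel area is used instead. The frame ratio is occupied area
#' over monitored area, multiplied by the growth correction factor and
#' clamped to \[0, 1\]; the clip value is the mean over frames with a
#' non-empty main group. `mode = "blob"` replaces the hull by the summed
#' member pixel areas.
#'
#' @param detections A labelled [assign_groups()] table.
#' @param monitored_area_cm2 Area of the camera field of view (cm^2), > 0.
#' @param size A [estimate_fish_size()] model.
#' @param mode `"hull"` (default) or `"blob"`.
#' @param members Labels counted as main-group members (default `"group"`;
#'   outliers are excluded per the ethogram definition).
#' @return List: `ratio` (clip mean; `NA` if no frame has a main group),
#'   `score` (ordinal, from [cohesion_score()]), `per_frame` (numeric
#'   vector), `n_frames_used`, `missing` flag.
#' @export
cohesion_ratio <- function(detections, monitored_area_cm2, size,
                           mode = c("hull", "blob"), members = "group") {
  mode <- match.arg(mode)
  stopifnot(inherits(size, "size_model"))
  assert_scalar_num(monitored_area_cm2, "monitored_area_cm2", lo = 1e-12)
  if (!"label" %in% names(detections))
    stopf("detections must be labelled; run assign_groups() first")
  g <- detections[detections$label %in% members, , drop = FALSE]
  if (nrow(g) == 0)
    return(list(ratio = NA_real_, score = NA_integer_,
                per_frame = numeric(0), n_frames_used = 0L, missing = TRUE))
  r_body <- size$body_length_cm / 2
  by_frame <- split(g, g$frame)
  per_frame <- vapply(by_frame, function(gi) {
    occ <- if (mode == "blob" || nrow(gi) == 1L) {
      sum(gi$area_cm2)
    } else {
      dilated_hull_area(cbind(gi$x_cm, gi$y_cm), r_body)
    }
    clamp(occ / monitored_area_cm2 * size$growth_correction_factor, 0, 1)
  }, numeric(1))
  ratio <- mean(per_frame)
  list(ratio = ratio, score = cohesion_score(ratio),
       per_frame = unname(per_frame), n_frames_used = length(by_frame),
       missing = FALSE)
}

#' Activity: size-weighted mean centroid displacement
#'
#' Pooled over all accepted frame-to-frame matches of a clip:
#' `sum(est_fish_count * displacement_cm) / sum(est_fish_count)`. Unmatched
#' objects contribute nothing. Reported per frame step and per second.
#'
#' @param links Match table from [link_all_frames()].
#' @param fps Frame rate, to convert to cm/s.
#' @return List: `activity_cm_per_frame`, `activity_cm_per_s`, `n_matches`,
#'   `missing` flag (no matches at all).
#' @export
activity <- function(links, fps) {
  assert_scalar_num(fps, "fps", lo = 1e-9)
  if (nrow(links) == 0)
    return(list(activity_cm_per_frame = NA_real_, activity_cm_per_s = NA_real_,
                n_matches = 0L, missing = TRUE))
  w <- links$est_fish_count
  a <- sum(w * links$displacement_cm) / sum(w)
  list(activity_cm_per_frame = a, activity_cm_per_s = a * fps,
       n_matches = nrow(links), missing = FALSE)
}

#' Standardise a vector of clip activities across clips
#'
#' Mean-centred and scaled to standard deviation units, mirroring the usual
#' analysis scaling of activity before model fitting. A reporting helper; the
#' metric itself stays in cm.
#' @param x Numeric vector (NAs kept).
#' @return Numeric vector of z-scores.
#' @export
standardise_activity <- function(x) {
  s <- sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) return(x - mean(x, na.rm = TRUE))
  (x - mean(x, na.rm = TRUE)) / s
}

#' Enrichment occupation of a clip
#'
#' Per frame, 100 times the foreground fish pixel area inside the enrichment
#' region over the total foreground fish pixel area; the clip value is the
#' mean over frames with any fish detected. An empty region gives 0.
#'
#' @param masks Foreground masks from [segment_foreground()].
#' @param region An [detect_enrichment_region()] region.
#' @return List: `occupation_pct` (`NA` with `missing = TRUE` when no fish
#'   are detected in any frame), `per_frame`, `n_frames_used`, `missing`.
#' @export
enrichment_occupation <- function(masks, region) {
  stopifnot(inherits(region, "enrichment_region"))
  ridx <- which(region$mask)
  per_frame <- vapply(masks, function(m) {
    tot <- sum(m)
    if (tot == 0) return(NA_real_)
    if (region$area_cm2 <= 0) return(0)
    100 * sum(m[ridx]) / tot
  }, numeric(1))
  used <- which(!is.na(per_frame))
  if (length(used) == 0)
    return(list(occupation_pct = NA_real_, per_frame = per_frame,
                n_frames_used = 0L, missing = TRUE))
  list(occupation_pct = mean(per_frame[used]), per_frame = per_frame,
       n_frames_used = length(used), missing = FALSE)
}

#' Assemble a per-clip behaviour record
#'
#' @param cohesion Result of [cohesion_ratio()] (or `NULL`).
#' @param act Result of [activity()] (or `NULL`).
#' @param occupation Result of [enrichment_occupation()] (or `NULL`).
#' @param clip_id,tank_id,week,timepoint Clip metadata.
#' @return One-row data.frame of class `behaviour_record` with metric
#'   columns and explicit `flag_*` missing-value flags.
#' @export
summarise_clip <- function(cohesion = NULL, act = NULL, occupation = NULL,
                           clip_id = "clip", tank_id = NA, week = NA,
                           timepoint = NA) {
  miss <- list(ratio = NA_real_, score = NA_integer_, n_frames_used = 0L,
               missing = TRUE)
  cohesion <- cohesion %||% miss
  act <- act %||% list(activity_cm_per_frame = NA_real_,
                       activity_cm_per_s = NA_real_, missing = TRUE)
  occupation <- occupation %||% list(occupation_pct = NA_real_, missing = TRUE,
                                     n_frames_used = 0L)
  rec <- data.frame(
    clip_id = clip_id, tank_id = tank_id, week = week, timepoint = timepoint,
    cohesion_ratio = cohesion$ratio, cohesion_score = cohesion$score,
    activity_cm_per_frame = act$activity_cm_per_frame,
    activity_cm_per_s = act$activity_cm_per_s,
    enrichment_occupation_pct = occupation$occupation_pct,
    n_frames_used = cohesion$n_frames_used %||% 0L,
    flag_missing_cohesion = isTRUE(cohesion$missing),
    flag_missing_activity = isTRUE(act$missing),
    flag_missing_occupation = isTRUE(occupation$missing))
  class(rec) <- c("behaviour_record", "data.frame")
  rec
}
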