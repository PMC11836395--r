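# Session orchestration: per-clip pipeline execution, multi-week study
# aggregation, and validation/merging of externally scored indicator tables.

#' Study design of a multi-week enrichment experiment
#'
#' @param tanks Character vector of tank labels.
#' @param treatments Character vector (same length) of treatment labels,
#'   e.g. `"EE"` / `"NE"`; defaults to a balanced EE/NE split.
#' @param weeks Integer vector of experiment weeks (default 0:13).
#' @param timepoints Character vector of daily recording timepoints.
#' @param trials Novel-object trial indices (default 1:6).
#' @return An object of class `study_design`.
#' @export
study_design <- function(tanks = paste0("T", 1:8),
                         treatments = rep(c("EE", "NE"), length.out = length(tanks)),
                         weeks = 0:13,
                         timepoints = c("00:00", "06:00", "12:00", "18:00"),
                         trials = 1:6) {
  if (length(treatments) != length(tanks))
    stopf("treatments must match tanks in length")
  if (anyDuplicated(tanks)) stopf("tank labels must be unique")
  structure(list(tanks = data.frame(tank_id = tanks, treatment = treatments),
                 weeks = weeks, timepoints = timepoints, trials = trials),
            class = "study_design")
}

#' Default analysis parameters of the pipeline
#'
#' All tunables in one place; every value can be overridden per call or via
#' the pipeline config.
#' @return Named list of defaults.
#' @export
default_params <- function() {
  list(k_sigma = 4, min_spread_floor = 1, r_open = 1, polarity = "dark_fish",
       sample_stride = NULL, min_blob_px = 3, connectivity = 8,
       linkage_factor = 1.5, outlier_factor = 2.5, gate_factor = 2,
       size_gate_ratio = 1.5,
       aspect_ratio = 4, cohesion_mode = "hull",
       dart_speed_bl_per_s = 3, min_dart_frames = 2)
}

#' Analyse one clip end to end
#'
#' Background fit, foreground segmentation, object labelling, size
#' estimation, group assignment, frame linking, enrichment-region detection,
#' and the three behavioural metrics; optionally the novel-object latency.
#'
#' @param seq A [frame_sequence()].
#' @param n_fish_nominal Nominal fish count in the tank.
#' @param params Parameter list (see [default_params()]); partial lists are
#'   completed with the defaults.
#' @param enrichment_region `"auto"` (detect the static dark footprint),
#'   `"none"`, or an explicit region config (see
#'   [detect_enrichment_region()]).
#' @param reference_area_cm2 Optional reference single-fish area for growth
#'   correction.
#' @param novel_object If `TRUE`, also score the latency to resume normal
#'   swimming.
#' @param latency_rule A [latency_rule()] for novel-object clips.
#' @return List: `record` (a [summarise_clip()] row), `detections`, `size`,
#'   `links`, `region`, `background`, and for novel-object clips `latency`
#'   and `dart_events`.
#' @export
analyse_clip <- function(seq, n_fish_nominal, params = list(),
                         enrichment_region = "auto",
                         reference_area_cm2 = NULL, novel_object = FALSE,
                         latency_rule = shoalwatch::latency_rule()) {
  stopifnot(inherits(seq, "frame_sequence"))
  p <- utils::modifyList(default_params(), params)
  bg <- fit_background(seq, sample_stride = p$sample_stride,
                       polarity = p$polarity)
  masks <- segment_foreground(seq, bg, k_sigma = p$k_sigma,
                              min_spread_floor = p$min_spread_floor,
                              r_open = p$r_open)
  det <- label_objects(masks, px_per_cm = seq$px_per_cm,
                       min_blob_px = p$min_blob_px,
                       connectivity = p$connectivity,
                       weight_fun = deviation_weight_fun(seq, bg),
                       monitored_mask = seq$monitored_mask)
  monitored_area <- sum(seq$monitored_mask) / seq$px_per_cm^2
  if (nrow(det) == 0) {
    rec <- summarise_clip(clip_id = seq$clip_id, tank_id = seq$tank_id,
                          week = seq$week, timepoint = seq$timepoint)
    return(list(record = rec, detections = det, size = NULL, links = NULL,
                region = NULL, background = bg))
  }
  size <- estimate_fish_size(det, n_fish_nominal,
                             aspect_ratio = p$aspect_ratio,
                             reference_area_cm2 = reference_area_cm2)
  det <- assign_groups(det, size, linkage_factor = p$linkage_factor,
                       outlier_factor = p$outlier_factor)
  links <- link_all_frames(det, size, gate_factor = p$gate_factor,
                           size_gate_ratio = p$size_gate_ratio)
  region <- if (identical(enrichment_region, "none")) {
    structure(list(mask = matrix(FALSE, seq$dim[1], seq$dim[2]),
                   area_cm2 = 0, source = "none"),
              class = "enrichment_region")
  } else if (identical(enrichment_region, "auto")) {
    detect_enrichment_region(bg, seq$monitored_mask)
  } else {
    detect_enrichment_region(bg, seq$monitored_mask,
                             region = enrichment_region, scene = seq$scene)
  }
  coh <- cohesion_ratio(det, monitored_area, size, mode = p$cohesion_mode)
  act <- activity(links, seq$fps)
  occ <- enrichment_occupation(masks, region)
  rec <- summarise_clip(coh, act, occ, clip_id = seq$clip_id,
                        tank_id = seq$tank_id, week = seq$week,
                        timepoint = seq$timepoint)
  out <- list(record = rec, detections = det, size = size, links = links,
              region = region, background = bg)
  if (novel_object) {
    ev <- detect_darts(links, size, seq$fps,
                       dart_speed_bl_per_s = p$dart_speed_bl_per_s,
                       min_dart_frames = p$min_dart_frames)
    dur <- length(seq$frames) / seq$fps
    out$dart_events <- ev
    out$latency <- latency_to_resume(ev, latency_rule, dur)
  }
  out
}

#' Run the pipeline over a configured set of clips
#'
#' The config is a list (or a YAML file path) with elements:
#' \describe{
#'   \item{calibration}{`list(fps, px_per_cm)` used for clips read from
#'     disk.}
#'   \item{params}{overrides of [default_params()].}
#'   \item{n_fish_nominal}{nominal fish count per tank.}
#'   \item{enrichment}{`"auto"`, `"none"`, or an explicit region config.}
#'   \item{clips}{list of clip entries with `clip_id`, `tank_id`, `week`,
#'     `timepoint`, and either `frames_dir` (+ optional `mask_path`) or an
#'     in-memory `seq` ([frame_sequence()]); `novel_object = TRUE` marks
#'     latency trials (optional `trial` index).}
#' }
#' Missing inputs fail fast with the offending clip named. Outputs are
#' deterministic given inputs and config.
#'
#' @param config Config list or YAML path.
#' @param out_dir Optional output directory; when given,
#'   `behaviour_records.csv`, `latency_results.csv` (if any trials) and
#'   `column_dictionary.json` are written.
#' @return List: `records` (one [summarise_clip()] row per clip),
#'   `latencies` (data.frame, possibly empty), `log` (per-clip parameter
#'   record).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  clips <- config$clips
  if (is.null(clips) || length(clips) == 0) stopf("config has no clips")
  records <- list(); latencies <- list(); log <- list()
  for (ci in seq_along(clips)) {
    cl <- clips[[ci]]
    id <- cl$clip_id %||% sprintf("clip%03d", ci)
    if (!is.null(cl$seq)) {
      seq <- cl$seq
      seq$clip_id <- id
      seq$tank_id <- cl$tank_id %||% seq$tank_id
      seq$week <- cl$week %||% seq$week
      seq$timepoint <- cl$timepoint %||% seq$timepoint
    } else if (!is.null(cl$frames_dir)) {
      if (!dir.exists(cl$frames_dir))
        stopf("clip '%s': frames_dir does not exist: %s", id, cl$frames_dir)
      cal <- config$calibration
      if (is.null(cal$fps) || is.null(cal$px_per_cm))
        stopf("clip '%s': config$calibration needs fps and px_per_cm", id)
      seq <- read_frame_dir(cl$frames_dir, fps = cal$fps,
                            px_per_cm = cal$px_per_cm,
                            mask_path = cl$mask_path, clip_id = id,
                            tank_id = cl$tank_id %||% NA,
                            week = cl$week %||% NA,
                            timepoint = cl$timepoint %||% NA)
    } else stopf("clip '%s': neither `seq` nor `frames_dir` given", id)
    res <- analyse_clip(seq, n_fish_nominal = config$n_fish_nominal %||% 1,
                        params = config$params %||% list(),
                        enrichment_region = config$enrichment %||% "auto",
                        reference_area_cm2 = config$reference_area_cm2,
                        novel_object = isTRUE(cl$novel_object))
    records[[ci]] <- res$record
    if (!is.null(res$latency)) {
      latencies[[length(latencies) + 1L]] <- data.frame(
        clip_id = id, tank_id = cl$tank_id %||% NA,
        trial = cl$trial %||% NA,
        latency_s = res$latency$latency_s,
        censored = res$latency$censored)
    }
    log[[ci]] <- list(clip_id = id,
                      params = utils::modifyList(default_params(),
                                                 config$params %||% list()),
                      n_frames = length(seq$frames))
  }
  records <- do.call(rbind, records)
  latencies <- if (length(latencies)) {
    sqrt_transform_export(do.call(rbind, latencies))
  } else {
    data.frame(clip_id = character(), tank_id = character(),
               trial = integer(), latency_s = numeric(),
               censored = logical(), sqrt_latency = numeric())
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(records, file.path(out_dir, "behaviour_records.csv"),
              row.names = FALSE)
    write.csv(latencies, file.path(out_dir, "latency_results.csv"),
              row.names = FALSE)
    jsonlite::write_json(column_dictionary(),
                         file.path(out_dir, "column_dictionary.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(records = records, latencies = latencies, log = log)
}

#' Aggregate clip records to tank-level tables
#'
#' Arithmetic means per grouping (tank x week, optionally x timepoint); the
#' categorical cohesion score is re-derived from the mean ratio; the number
#' of contributing clips is included, and groups with no usable value are
#' flagged missing rather than dropped.
#'
#' @param records Clip records from [run_pipeline()] / [summarise_clip()].
#' @param by Grouping columns (default `c("tank_id", "week")`).
#' @return data.frame with mean metrics, `cohesion_score`, `n_clips` and
#'   `flag_*` columns per group.
#' @export
aggregate_records <- function(records, by = c("tank_id", "week")) {
  if (nrow(records) == 0) stopf("no records to aggregate")
  key <- interaction(records[by], drop = TRUE, lex.order = TRUE)
  groups <- split(records, key)
  rows <- lapply(groups, function(g) {
    mr <- mean(g$cohesion_ratio[!g$flag_missing_cohesion])
    ma <- mean(g$activity_cm_per_s[!g$flag_missing_activity])
    mo <- mean(g$enrichment_occupation_pct[!g$flag_missing_occupation])
    out <- g[1, by, drop = FALSE]
    out$cohesion_ratio <- if (is.nan(mr)) NA_real_ else mr
    out$cohesion_score <- if (is.nan(mr)) NA_integer_ else cohesion_score(mr)
    out$activity_cm_per_s <- if (is.nan(ma)) NA_real_ else ma
    out$enrichment_occupation_pct <- if (is.nan(mo)) NA_real_ else mo
    out$n_clips <- nrow(g)
    out$flag_missing_cohesion <- is.nan(mr)
    out$flag_missing_activity <- is.nan(ma)
    out$flag_missing_occupation <- is.nan(mo)
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Validate and merge externally scored indicator tables
#'
#' Type and range checks on morphological (and optionally physiological)
#' indicator tables, with every violation reported by table and row number.
#' The morphological score scale is declared explicitly (the common schemes
#' use either 1-3 or 0-2 levels).
#'
#' @param morphology data.frame with columns `fish_id`, `tank`, `session`,
#'   `weight_g`, `length_cm`, `dorsal_fin_score`, `body_condition_score`.
#' @param cortisol Optional data.frame with `fish_id`, `tank`, `session`,
#'   `cortisol`.
#' @param expression Optional data.frame with `fish_id`, `tank`, `session`,
#'   `gene`, `copies`.
#' @param design A [study_design()]; tank labels are checked against it.
#' @param score_scale Length-2 numeric: inclusive score range
#'   (default `c(1, 3)`).
#' @return Long-format merged data.frame (`table`, `fish_id`, `tank`,
#'   `session`, `variable`, `value`) whose row count is the sum of input
#'   value cells; errors (listing each violation) if validation fails.
#' @export
validate_tables <- function(morphology, cortisol = NULL, expression = NULL,
                            design = study_design(),
                            score_scale = c(1, 3)) {
  problems <- character()
  note <- function(tab, rows, what) {
    if (length(rows))
      problems <<- c(problems, sprintf("%s row %d: %s", tab, rows, what))
  }
  need <- c("fish_id", "tank", "session", "weight_g", "length_cm",
            "dorsal_fin_score", "body_condition_score")
  missing_cols <- setdiff(need, names(morphology))
  if (length(missing_cols))
    stopf("morphology lacks columns: %s", paste(missing_cols, collapse = ", "))
  known <- design$tanks$tank_id
  note("morphology", which(!(morphology$tank %in% known)), "unknown tank label")
  note("morphology", which(!(morphology$weight_g > 0)), "non-positive weight_g")
  note("morphology", which(!(morphology$length_cm > 0)), "non-positive length_cm")
  for (sc in c("dorsal_fin_score", "body_condition_score")) {
    v <- morphology[[sc]]
    note("morphology",
         which(!(v >= score_scale[1] & v <= score_scale[2] & v == round(v))),
         sprintf("%s outside declared scale [%g, %g]", sc,
                 score_scale[1], score_scale[2]))
  }
  check_phys <- function(tab, name, value_col) {
    if (is.null(tab)) return(NULL)
    note(name, which(!(tab$tank %in% known)), "unknown tank label")
    note(name, which(!is.finite(tab[[value_col]]) | tab[[value_col]] < 0),
         sprintf("invalid %s", value_col))
  }
  check_phys(cortisol, "cortisol", "cortisol")
  check_phys(expression, "expression", "copies")
  if (length(problems))
    stopf("validation failed:\n%s", paste(problems, collapse = "\n"))
  long <- function(tab, name, vars) {
    if (is.null(tab)) return(NULL)
    do.call(rbind, lapply(vars, function(v)
      data.frame(table = name, fish_id = tab$fish_id, tank = tab$tank,
                 session = tab$session, variable = v, value = tab[[v]])))
  }
  out <- rbind(
    long(morphology, "morphology",
         c("weight_g", "length_cm", "dorsal_fin_score", "body_condition_score")),
    long(cortisol, "cortisol", "cortisol"),
    long(expression, "expression", "copies"))
  rownames(out) <- NULL
  out
}

#' Generate a synthetic multi-tank mini-study config
#'
#' Renders one clip per (tank, week, timepoint) cell with per-cell seeds
#' derived deterministically from `seed`, emulating the recording protocol
#' of repeated 30-min clips at fixed daily timepoints (shortened to
#' `duration_s` per clip). Week is emulated through fish growth
#' (`body_length_cm * (1 + 0.04 * week)`). The default dispersion (8)
#' keeps the school swimming about the tank: the background model requires
#' fish to transit any given pixel in under half of the sampled frames, and
#' a near-degenerate school parked on one spot (very low dispersion with an
#' enrichment anchor) is absorbed into the background -- a simulator
#' degeneracy, not a behaviour real flowing tanks exhibit.
#'
#' @param tanks Tank labels.
#' @param weeks Weeks to simulate.
#' @param timepoints Timepoints to simulate.
#' @param n_fish Fish per tank.
#' @param duration_s Clip length (s).
#' @param fps Frame rate.
#' @param image_px Image side (px).
#' @param dispersion,enrichment_affinity School parameters.
#' @param noise_sd Render noise.
#' @param seed Master seed.
#' @return A [run_pipeline()] config with in-memory clips.
#' @export
simulate_mini_study <- function(tanks = c("T1", "T2"), weeks = c(1, 2),
                                timepoints = c("06:00", "12:00"),
                                n_fish = 10, duration_s = 60, fps = 10,
                                image_px = 160, dispersion = 8,
                                enrichment_affinity = 0.3, noise_sd = 2,
                                seed = 1L) {
  scene <- tank_scene(image_size_px = c(image_px, image_px),
                      background_texture_seed = seed)
  clips <- list()
  k <- 0L
  for (ti in seq_along(tanks)) for (wi in seq_along(weeks))
    for (pi in seq_along(timepoints)) {
      k <- k + 1L
      clip_seed <- seed * 1000L + ti * 100L + wi * 10L + pi
      school <- school_params(n_fish = n_fish,
                              body_length_cm = 5 * (1 + 0.04 * weeks[wi]),
                              mean_speed_cmps = 5, dispersion = dispersion,
                              enrichment_affinity = enrichment_affinity,
                              seed = clip_seed)
      sim <- simulate_school(scene, school, duration_s = duration_s,
                             fps = fps)
      seq <- render_frames(sim, noise_sd = noise_sd)
      clips[[k]] <- list(clip_id = sprintf("%s_w%d_%s", tanks[ti], weeks[wi],
                                           timepoints[pi]),
                         tank_id = tanks[ti], week = weeks[wi],
                         timepoint = timepoints[pi], seq = seq)
    }
  list(n_fish_nominal = n_fish, enrichment = "auto", params = list(),
       clips = clips, seed = seed)
}
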