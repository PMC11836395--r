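# File interfaces: PNG image sequences, mask PNGs, background model as a
# two-plane TIFF with JSON metadata, tidy CSV outputs.

#' Read a numbered PNG image sequence as a frame sequence
#'
#' @param dir Directory of `*.png` frames (lexicographic order = time
#'   order).
#' @param fps Frame rate.
#' @param px_per_cm Pixel scale.
#' @param mask_path Optional monitored-region mask PNG (nonzero = monitored).
#' @param ... Passed to [frame_sequence()] (metadata labels).
#' @return A [frame_sequence()] with 8-bit intensities.
#' @export
read_frame_dir <- function(dir, fps, px_per_cm, mask_path = NULL, ...) {
  if (!dir.exists(dir)) stopf("frame directory does not exist: %s", dir)
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0) stopf("no PNG frames in %s", dir)
  frames <- lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3) img <- img[, , 1]
    round(img * 255)
  })
  mask <- NULL
  if (!is.null(mask_path)) {
    m <- png::readPNG(mask_path)
    if (length(dim(m)) == 3) m <- m[, , 1]
    mask <- m > 0
  }
  frame_sequence(frames, fps = fps, px_per_cm = px_per_cm,
                 monitored_mask = mask, ...)
}

#' Write a frame sequence as numbered 8-bit grayscale PNGs
#'
#' @param seq A [frame_sequence()].
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_frame_dir <- function(seq, dir) {
  stopifnot(inherits(seq, "frame_sequence"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(seq$frames)) {
    png::writePNG(seq$frames[[i]] / 255,
                  file.path(dir, sprintf("frame_%06d.png", i)))
  }
  invisible(dir)
}

#' Write a background model (two-plane TIFF + JSON metadata)
#'
#' Plane 1 is the location raster, plane 2 the spread raster, stored as
#' 32-bit float TIFF; `<path>.json` records frame count, polarity and pixel
#' scale.
#' @param model A [fit_background()] model.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_background_model <- function(model, path) {
  stopifnot(inherits(model, "background_model"))
  arr <- array(c(model$location / 255, model$spread / 255),
               c(model$dim[1], model$dim[2], 2))
  tiff::writeTIFF(list(arr[, , 1], arr[, , 2]), path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(n_frames_used = model$n_frames_used, polarity = model$polarity,
         px_per_cm = model$px_per_cm, scale = 255),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a background model written by [write_background_model()]
#' @param path TIFF path.
#' @return A `background_model`.
#' @export
read_background_model <- function(path) {
  planes <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  loc <- planes[[1]] * meta$scale
  spr <- planes[[2]] * meta$scale
  structure(list(location = loc, spread = spr,
                 n_frames_used = meta$n_frames_used, polarity = meta$polarity,
                 dim = dim(loc), px_per_cm = meta$px_per_cm),
            class = "background_model")
}

#' Write a mask as a PNG
#' @param mask Logical matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask * 1, path)
  invisible(path)
}

# machine-readable column dictionary for tidy exports
column_dictionary <- function() {
  list(
    clip_id = "clip identifier",
    tank_id = "tank label",
    week = "experiment week (0-13)",
    timepoint = "recording timepoint (HH:MM)",
    cohesion_ratio = "main-group occupied area / monitored tank area, growth-corrected, in [0,1]",
    cohesion_score = "categorical cohesion: 0 tight (<0.25), 1 loose, 2 dispersed (>0.75)",
    activity_cm_per_frame = "size-weighted mean centroid displacement per frame step (cm)",
    activity_cm_per_s = "activity scaled to cm/s",
    enrichment_occupation_pct = "fish pixel area under enrichment / total fish pixel area (%)",
    n_frames_used = "frames contributing to the cohesion mean",
    flag_missing_cohesion = "TRUE when no frame had a main group",
    flag_missing_activity = "TRUE when no frame-to-frame match was accepted",
    flag_missing_occupation = "TRUE when no fish were detected in any frame",
    latency_s = "latency to resume normal swimming (s)",
    censored = "TRUE when the resumption rule was never met within the clip",
    sqrt_latency = "square root of latency_s (NA when censored)")
}
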