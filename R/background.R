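# Background model: per-pixel temporal lower-median and scaled MAD of the
# static scene, plus one-sided (dark-fish) or two-sided background
# subtraction with morphological opening.

#' An ordered sequence of raster frames with a timebase and pixel scale
#'
#' @param frames List of numeric/integer matrices, all of identical shape
#'   (height x width intensities).
#' @param fps Frame rate (frames per second), > 0.
#' @param px_per_cm Pixel scale, > 0.
#' @param monitored_mask Optional logical matrix marking the camera field of
#'   view; defaults to the full frame.
#' @param background Optional noise-free background raster (kept by the
#'   renderer as ground truth).
#' @param scene Optional [tank_scene()] the frames were rendered from.
#' @param clip_id,tank_id,week,timepoint Clip metadata labels.
#' @return An object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, fps, px_per_cm, monitored_mask = NULL,
                           background = NULL, scene = NULL, clip_id = "clip",
                           tank_id = NA, week = NA, timepoint = NA) {
  if (!is.list(frames) || length(frames) == 0)
    stopf("frames must be a non-empty list of matrices")
  d <- dim(frames[[1]])
  ok <- vapply(frames, function(f) is.matrix(f) && identical(dim(f), d),
               logical(1))
  if (!all(ok)) stopf("all frames must be matrices of identical shape")
  assert_scalar_num(fps, "fps", lo = 1e-9)
  assert_scalar_num(px_per_cm, "px_per_cm", lo = 1e-12)
  if (is.null(monitored_mask)) monitored_mask <- matrix(TRUE, d[1], d[2])
  if (!identical(dim(monitored_mask), d))
    stopf("monitored_mask shape differs from frames")
  structure(list(frames = frames, fps = fps, px_per_cm = px_per_cm,
                 monitored_mask = monitored_mask, background = background,
                 scene = scene, clip_id = clip_id, tank_id = tank_id,
                 week = week, timepoint = timepoint, dim = d),
            class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  cat(sprintf("<frame_sequence> %d frames, %d x %d px, %g fps, %.2f px/cm [%s]\n",
              length(x$frames), x$dim[1], x$dim[2], x$fps, x$px_per_cm,
              x$clip_id))
  invisible(x)
}

#' @export
length.frame_sequence <- function(x) length(x$frames)

#' Fit a statistical background model of the static scene
#'
#' Computes the per-pixel temporal lower median and scaled MAD
#' (`1.4826 * MAD`, again with the lower-median tie rule) over every
#' `sample_stride`-th frame. The median is robust to fish transiting a pixel
#' in fewer than half of the sampled frames, so a static tank scene --
#' including a static enrichment structure -- is recovered even with fish
#' present throughout.
#'
#' @param seq A [frame_sequence()].
#' @param sample_stride Temporal subsampling stride (default: the stride that
#'   keeps about 60 frames). At least 10 sampled frames are required.
#' @param polarity `"dark_fish"` (foreground darker than background, the
#'   default for an overhead view of dark fish on a light tank floor),
#'   `"light_fish"`, or `"two_sided"`.
#' @return An object of class `background_model` with matrices `location` and
#'   `spread`, plus `n_frames_used` and `polarity`.
#' @export
fit_background <- function(seq, sample_stride = NULL,
                           polarity = c("dark_fish", "light_fish", "two_sided")) {
  stopifnot(inherits(seq, "frame_sequence"))
  polarity <- match.arg(polarity)
  nf <- length(seq$frames)
  if (is.null(sample_stride)) sample_stride <- max(1L, nf %/% 60L)
  idx <- seq.int(1L, nf, by = sample_stride)
  if (length(idx) < 10L)
    stopf("need >= 10 sampled frames to fit a background (got %d)", length(idx))
  st <- .px_median_mad(seq$frames[idx])
  structure(list(location = st$location, spread = st$spread,
                 n_frames_used = length(idx), polarity = polarity,
                 dim = seq$dim, px_per_cm = seq$px_per_cm),
            class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("<background_model> %d x %d px from %d frames, polarity %s\n",
              x$dim[1], x$dim[2], x$n_frames_used, x$polarity))
  invisible(x)
}

disc_offsets <- function(r) {
  r_int <- ceiling(r)
  g <- expand.grid(dr = -r_int:r_int, dc = -r_int:r_int)
  g <- g[g$dr^2 + g$dc^2 <= r^2 + 1e-9, ]
  as.matrix(g)
}

#' Segment foreground (fish) pixels by background subtraction
#'
#' A pixel is foreground when its deviation from the background location --
#' signed according to the model polarity, or absolute for `two_sided` --
#' exceeds `k_sigma * max(spread, min_spread_floor)`. The binary mask is then
#' cleaned by morphological opening with a disc of radius `r_open` pixels and
#' intersected with the monitored-region mask.
#'
#' @param seq A [frame_sequence()].
#' @param model A [fit_background()] model of the same geometry.
#' @param k_sigma Threshold in spread units (default 4).
#' @param min_spread_floor Lower bound on the per-pixel spread (intensity
#'   units, default 1) so noise-free scenes do not yield a zero threshold.
#' @param r_open Opening radius in px (default 1); 0 disables opening.
#' @param spread_cap_factor Upper bound on the per-pixel spread as a
#'   multiple of the median spread over the monitored region (default 3).
#'   Pixels that fish occupy in a sizeable share of the sampled frames have
#'   an inflated MAD; without the cap their threshold rises so far that the
#'   fish themselves are missed. `Inf` disables the cap.
#' @return List of logical foreground masks, one per frame, of class
#'   `foreground_masks`.
#' @export
segment_foreground <- function(seq, model, k_sigma = 4, min_spread_floor = 1,
                               r_open = 1, spread_cap_factor = 3) {
  stopifnot(inherits(seq, "frame_sequence"), inherits(model, "background_model"))
  if (!identical(seq$dim, model$dim))
    stopf("frame shape %dx%d does not match background model %dx%d",
          seq$dim[1], seq$dim[2], model$dim[1], model$dim[2])
  spread <- model$spread
  if (is.finite(spread_cap_factor)) {
    cap <- spread_cap_factor * median(spread[seq$monitored_mask])
    spread <- pmin(spread, cap)
  }
  thr <- k_sigma * pmax(spread, min_spread_floor)
  loc <- model$location
  mon <- seq$monitored_mask
  offs <- if (r_open > 0) disc_offsets(r_open) else
    matrix(integer(0), 0, 2)
  pol <- match(model$polarity, c("dark_fish", "light_fish", "two_sided")) - 1L
  masks <- lapply(seq$frames, function(fr) {
    storage.mode(fr) <- "double"
    .segment_frame(fr, loc, thr, offs, mon, pol)
  })
  structure(masks, class = "foreground_masks")
}
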