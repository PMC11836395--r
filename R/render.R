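# Rasteriser: dark fish ellipses on a brighter static textured background,
# 8-bit grayscale, with the enrichment structure drawn as a static
# semi-transparent texture so that (being static) it is absorbed into the
# background model rather than the foreground.

FISH_INTENSITY <- 40
TANK_INTENSITY <- 200
OUTSIDE_INTENSITY <- 70
ENRICHMENT_SHADE <- 0.75  # multiplicative shading of the enrichment footprint
FISH_ASPECT_RATIO <- 4    # body length / body width of the rendered ellipse

# smooth texture: coarse uniform grid bilinearly upsampled
smooth_texture <- function(hw, amplitude, coarse = 8L) {
  g <- matrix(runif((coarse + 1)^2, -amplitude, amplitude), coarse + 1)
  ry <- seq(1, coarse + 1, length.out = hw[1])
  rx <- seq(1, coarse + 1, length.out = hw[2])
  y0 <- pmin(floor(ry), coarse); x0 <- pmin(floor(rx), coarse)
  fy <- ry - y0; fx <- rx - x0
  a <- g[cbind(rep(y0, hw[2]), rep(x0, each = hw[1]))]
  b <- g[cbind(rep(y0, hw[2]), rep(x0 + 1, each = hw[1]))]
  cc <- g[cbind(rep(y0 + 1, hw[2]), rep(x0, each = hw[1]))]
  d <- g[cbind(rep(y0 + 1, hw[2]), rep(x0 + 1, each = hw[1]))]
  wfy <- rep(fy, hw[2]); wfx <- rep(fx, each = hw[1])
  v <- a * (1 - wfy) * (1 - wfx) + b * (1 - wfy) * wfx +
    cc * wfy * (1 - wfx) + d * wfy * wfx
  matrix(v, hw[1], hw[2])
}

#' Noise-free static background raster of a scene
#'
#' @param scene A [tank_scene()].
#' @return Numeric matrix (height x width) of 8-bit intensities: a bright
#'   textured tank floor, darker surround, and (if declared) the darker
#'   semi-transparent enrichment footprint.
#' @export
background_raster <- function(scene) {
  hw <- scene$image_size_px
  masks <- scene_masks(scene)
  with_seed(scene$background_texture_seed, {
    img <- matrix(OUTSIDE_INTENSITY, hw[1], hw[2])
    tex <- smooth_texture(hw, amplitude = 8)
    img[masks$tank] <- TANK_INTENSITY + tex[masks$tank]
    if (scene$enrichment && any(masks$enrichment)) {
      etex <- smooth_texture(hw, amplitude = 6)
      img[masks$enrichment] <- img[masks$enrichment] * ENRICHMENT_SHADE +
        etex[masks$enrichment]
    }
    round(clamp(img, 0, 255))
  })
}

# subpixel coverage of one fish ellipse (3x3 supersampling, emulating the
# optical blur of a real camera); returns linear indices into the image
# matrix and the covered fraction of each pixel
ellipse_coverage <- function(hw, center_px, theta, a_px, b_px) {
  x0 <- center_px[1]; y0 <- center_px[2]
  xr <- max(0, floor(x0 - a_px - 1)):min(hw[2] - 1, ceiling(x0 + a_px + 1))
  yr <- max(0, floor(y0 - a_px - 1)):min(hw[1] - 1, ceiling(y0 + a_px + 1))
  if (length(xr) == 0 || length(yr) == 0)
    return(list(idx = integer(0), alpha = numeric(0)))
  dx <- rep(xr, each = length(yr)) - x0
  dy <- rep(yr, times = length(xr)) - y0
  ct <- cos(theta); st <- sin(theta)
  u <- (dx * ct + dy * st) / a_px
  v <- (-dx * st + dy * ct) / b_px
  r <- sqrt(u * u + v * v)
  # only pixels near the ellipse boundary need supersampling
  delta <- 1.5 / min(a_px, b_px)
  alpha <- as.numeric(r <= 1)
  edge <- which(abs(r - 1) <= delta)
  if (length(edge)) {
    acc <- numeric(length(edge))
    for (ox in c(-1, 0, 1) / 3) for (oy in c(-1, 0, 1) / 3) {
      ue <- ((dx[edge] + ox) * ct + (dy[edge] + oy) * st) / a_px
      ve <- (-(dx[edge] + ox) * st + (dy[edge] + oy) * ct) / b_px
      acc <- acc + (ue * ue + ve * ve <= 1)
    }
    alpha[edge] <- acc / 9
  }
  keep <- alpha > 0
  rows <- rep(yr, times = length(xr)) + 1L
  cols <- rep(xr, each = length(yr)) + 1L
  list(idx = ((cols - 1L) * hw[1] + rows)[keep], alpha = alpha[keep])
}

#' Render simulated trajectories to an image sequence
#'
#' Fish are drawn as dark ellipses of length `body_length_cm`, oriented along
#' their velocity, over the static scene background; i.i.d. Gaussian pixel
#' noise of standard deviation `noise_sd` is added per frame and intensities
#' are rounded and clamped to 0..255.
#'
#' @param sim A [simulate_school()] result (or `NULL` to render `n_frames`
#'   fish-free frames of the background alone).
#' @param scene A [tank_scene()]; defaults to `sim$scene`.
#' @param noise_sd Additive pixel noise standard deviation (intensity units).
#' @param seed Seed for the pixel noise (default: the school seed + 1).
#' @param n_frames Number of frames when `sim` is `NULL`.
#' @return A [frame_sequence()] whose `background` element holds the
#'   noise-free background raster.
#' @export
render_frames <- function(sim, scene = NULL, noise_sd = 2, seed = NULL,
                          n_frames = NULL) {
  if (!is.null(sim)) {
    stopifnot(inherits(sim, "school_sim"))
    scene <- scene %||% sim$scene
    n_frames <- sim$n_frames
    fps <- sim$fps
    bl_px <- sim$school$body_length_cm * scene$px_per_cm
    if (bl_px < 2)
      stopf("image too small: fish body length is %.2f px (< 2 px)", bl_px)
    seed <- seed %||% (sim$school$seed + 1L)
  } else {
    if (is.null(scene) || is.null(n_frames))
      stopf("need `scene` and `n_frames` when sim is NULL")
    fps <- 10
    seed <- seed %||% 1L
  }
  hw <- scene$image_size_px
  bg <- background_raster(scene)
  masks <- scene_masks(scene)
  npx <- prod(hw)
  frames <- vector("list", n_frames)
  with_seed(as.integer(seed), {
    for (f in seq_len(n_frames)) {
      img <- bg
      if (!is.null(sim)) {
        ctr <- cm_to_px(scene, cbind(sim$positions[f, , 1],
                                     sim$positions[f, , 2]))
        a_px <- bl_px / 2
        b_px <- a_px / FISH_ASPECT_RATIO
        for (i in seq_len(sim$school$n_fish)) {
          cv <- ellipse_coverage(hw, ctr[i, ], sim$headings[f, i], a_px, b_px)
          img[cv$idx] <- img[cv$idx] * (1 - cv$alpha) +
            FISH_INTENSITY * cv$alpha
        }
      }
      if (noise_sd > 0) img <- img + rnorm(npx, 0, noise_sd)
      frames[[f]] <- round(clamp(img, 0, 255))
    }
  })
  frame_sequence(frames, fps = fps, px_per_cm = scene$px_per_cm,
                 monitored_mask = masks$monitored, background = bg,
                 scene = scene)
}

#' Ground-truth fish pixel masks
#'
#' Rasterises each frame's fish ellipses with no noise; a pixel is a fish
#' pixel when the ellipse covers more than half of it -- the oracle for
#' segmentation quality checks.
#'
#' @param sim A [simulate_school()] result.
#' @param scene A [tank_scene()]; defaults to `sim$scene`.
#' @return List of logical matrices, one per frame (not restricted to the
#'   monitored region).
#' @export
fish_pixel_masks <- function(sim, scene = NULL) {
  stopifnot(inherits(sim, "school_sim"))
  scene <- scene %||% sim$scene
  hw <- scene$image_size_px
  bl_px <- sim$school$body_length_cm * scene$px_per_cm
  a_px <- bl_px / 2
  b_px <- a_px / FISH_ASPECT_RATIO
  lapply(seq_len(sim$n_frames), function(f) {
    m <- matrix(FALSE, hw[1], hw[2])
    ctr <- cm_to_px(scene, cbind(sim$positions[f, , 1], sim$positions[f, , 2]))
    for (i in seq_len(sim$school$n_fish)) {
      cv <- ellipse_coverage(hw, ctr[i, ], sim$headings[f, i], a_px, b_px)
      m[cv$idx[cv$alpha > 0.5]] <- TRUE
    }
    m
  })
}
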