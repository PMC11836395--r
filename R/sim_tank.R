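# Agent-based tank simulator: a correlated random walk with attraction to the
# group centroid (strength decreasing in `dispersion`), optional bias towards
# the enrichment structure, and specular reflection at the tank wall. Stands
# in for overhead tank video, providing full ground truth for every stage of
# the analysis pipeline.

#' Describe a circular tank scene
#'
#' Geometry of a circular rearing tank viewed by a fixed overhead camera. The
#' camera monitors the lower part of the tank: `monitored_fraction` is the
#' fraction of the tank disc area inside the field of view (a horizontal
#' chord cut; 0.5 reproduces a camera that sees the lower half of the tank).
#' An optional enrichment structure (a suspended circular grid of artificial
#' plants) is modelled as a static disc.
#'
#' @param tank_diameter_cm Tank diameter in cm (default 100, a 0.78 m^2 tank).
#' @param monitored_fraction Fraction of tank area in the camera field of
#'   view, in (0, 1]. Default 0.5.
#' @param enrichment Logical; is an enrichment structure present?
#' @param enrichment_center_cm Centre of the enrichment disc in tank-centred
#'   cm coordinates (x right, y down).
#' @param enrichment_diameter_cm Diameter of the enrichment disc in cm
#'   (default 70, a 70 cm circular grid).
#' @param image_size_px Image size as `c(height, width)` pixels.
#' @param background_texture_seed Seed for the static background texture.
#' @return An object of class `tank_scene`.
#' @export
tank_scene <- function(tank_diameter_cm = 100, monitored_fraction = 0.5,
                       enrichment = TRUE, enrichment_center_cm = c(0, 0),
                       enrichment_diameter_cm = 70,
                       image_size_px = c(256L, 256L),
                       background_texture_seed = 1L) {
  assert_scalar_num(tank_diameter_cm, "tank_diameter_cm", lo = 1e-6)
  assert_scalar_num(monitored_fraction, "monitored_fraction", lo = 1e-9, hi = 1)
  h <- as.integer(image_size_px[1]); w <- as.integer(image_size_px[2])
  if (h < 8 || w < 8) stopf("image_size_px too small")
  margin_px <- 2
  radius_px <- min(h, w) / 2 - margin_px
  if (radius_px <= 0) stopf("image too small to contain the tank")
  px_per_cm <- 2 * radius_px / tank_diameter_cm
  R <- tank_diameter_cm / 2
  if (enrichment) {
    if (enrichment_diameter_cm <= 0)
      stopf("enrichment_diameter_cm must be positive")
    if (sqrt(sum(enrichment_center_cm^2)) + enrichment_diameter_cm / 2 > R + 1e-9)
      stopf("enrichment region must lie within the tank disc")
  }
  scene <- structure(list(
    tank_diameter_cm = tank_diameter_cm,
    monitored_fraction = monitored_fraction,
    enrichment = isTRUE(enrichment),
    enrichment_center_cm = as.numeric(enrichment_center_cm),
    enrichment_diameter_cm = enrichment_diameter_cm,
    image_size_px = c(h, w),
    background_texture_seed = as.integer(background_texture_seed),
    px_per_cm = px_per_cm,
    center_px = c((w - 1) / 2, (h - 1) / 2),   # (x, y), 0-based pixel coords
    radius_cm = R,
    monitored_y_cut_cm = chord_cut_for_fraction(R, monitored_fraction)
  ), class = "tank_scene")
  scene
}

#' @export
print.tank_scene <- function(x, ...) {
  cat(sprintf("<tank_scene> %g cm tank, %d x %d px (%.2f px/cm), %.0f%% monitored%s\n",
              x$tank_diameter_cm, x$image_size_px[1], x$image_size_px[2],
              x$px_per_cm, 100 * x$monitored_fraction,
              if (x$enrichment) sprintf(", %g cm enrichment", x$enrichment_diameter_cm) else ""))
  invisible(x)
}

#' Convert tank-centred cm coordinates to image pixel coordinates
#' @param scene A [tank_scene()].
#' @param xy_cm Two-column matrix (x, y) in cm, origin at tank centre.
#' @return Two-column matrix of 0-based pixel coordinates (x = column,
#'   y = row).
#' @export
cm_to_px <- function(scene, xy_cm) {
  xy_cm <- rbind(xy_cm)
  cbind(scene$center_px[1] + xy_cm[, 1] * scene$px_per_cm,
        scene$center_px[2] + xy_cm[, 2] * scene$px_per_cm)
}

#' Static pixel masks of a scene
#'
#' @param scene A [tank_scene()].
#' @return List of logical rasters: `tank` (tank disc), `monitored` (field of
#'   view), `enrichment` (enrichment footprint inside the field of view; all
#'   `FALSE` when no enrichment is declared).
#' @export
scene_masks <- function(scene) {
  hw <- scene$image_size_px
  ppcm <- scene$px_per_cm
  tank <- disc_mask(hw, scene$center_px, scene$radius_cm * ppcm)
  ycut_px <- scene$center_px[2] + scene$monitored_y_cut_cm * ppcm
  y <- matrix(rep(0:(hw[1] - 1), times = hw[2]), nrow = hw[1])
  monitored <- tank & (y >= ycut_px)
  if (scene$enrichment) {
    enr <- disc_mask(hw, cm_to_px(scene, scene$enrichment_center_cm),
                     scene$enrichment_diameter_cm / 2 * ppcm)
    enr <- enr & monitored
  } else {
    enr <- matrix(FALSE, hw[1], hw[2])
  }
  list(tank = tank, monitored = monitored, enrichment = enr)
}

#' School (fish group) parameters for the simulator
#'
#' @param n_fish Number of fish, >= 1.
#' @param body_length_cm Fish body length in cm.
#' @param mean_speed_cmps Cruising speed in cm/s (each agent moves exactly
#'   this far per second when not darting).
#' @param dispersion Unitless >= 0. Controls attraction to the group centroid
#'   (attraction weight 1 / (1 + dispersion)) and the initial spread; 0 packs
#'   all agents onto a single start point.
#' @param enrichment_affinity In \[0, 1\]; weight of the bias towards the
#'   enrichment structure for agents currently outside it.
#' @param seed Integer RNG seed; fixes the trajectory bit-for-bit.
#' @return An object of class `school_params`.
#' @export
school_params <- function(n_fish, body_length_cm = 5, mean_speed_cmps = 5,
                          dispersion = 1, enrichment_affinity = 0, seed = 1L) {
  if (!is.numeric(n_fish) || length(n_fish) != 1L || n_fish < 1)
    stopf("n_fish must be >= 1")
  assert_scalar_num(body_length_cm, "body_length_cm", lo = 1e-6)
  assert_scalar_num(mean_speed_cmps, "mean_speed_cmps", lo = 0)
  assert_scalar_num(dispersion, "dispersion", lo = 0)
  assert_scalar_num(enrichment_affinity, "enrichment_affinity", lo = 0, hi = 1)
  structure(list(n_fish = as.integer(n_fish), body_length_cm = body_length_cm,
                 mean_speed_cmps = mean_speed_cmps, dispersion = dispersion,
                 enrichment_affinity = enrichment_affinity,
                 seed = as.integer(seed)),
            class = "school_params")
}

#' Novel-object stimulus parameters
#'
#' After `onset_s`, each non-darting agent starts a dart as an inhomogeneous
#' Poisson process with per-fish rate
#' `initial_dart_rate_per_fish_per_s * exp(-(t - onset) / decay_timescale_s)`;
#' a dart multiplies the agent's speed by `dart_speed_multiplier` for
#' `dart_duration_s` seconds.
#'
#' @param onset_s Stimulus onset time in seconds.
#' @param initial_dart_rate_per_fish_per_s Initial dart rate (1/s per fish).
#' @param decay_timescale_s Exponential decay timescale of the rate (s).
#' @param dart_speed_multiplier Speed multiplier during a dart, > 1.
#' @param dart_duration_s Duration of a dart (s).
#' @return An object of class `stimulus_params`.
#' @export
stimulus_params <- function(onset_s = 0, initial_dart_rate_per_fish_per_s = 0.5,
                            decay_timescale_s = 10, dart_speed_multiplier = 6,
                            dart_duration_s = 0.5) {
  assert_scalar_num(onset_s, "onset_s", lo = 0)
  assert_scalar_num(initial_dart_rate_per_fish_per_s,
                    "initial_dart_rate_per_fish_per_s", lo = 0)
  assert_scalar_num(decay_timescale_s, "decay_timescale_s", lo = 0)
  assert_scalar_num(dart_speed_multiplier, "dart_speed_multiplier", lo = 1)
  assert_scalar_num(dart_duration_s, "dart_duration_s", lo = 0)
  structure(list(onset_s = onset_s,
                 initial_dart_rate_per_fish_per_s = initial_dart_rate_per_fish_per_s,
                 decay_timescale_s = decay_timescale_s,
                 dart_speed_multiplier = dart_speed_multiplier,
                 dart_duration_s = dart_duration_s),
            class = "stimulus_params")
}

#' Simulate a fish school in a circular tank
#'
#' Discrete-time correlated random walk. Each step, an agent's heading is the
#' direction of a weighted sum of (i) its previous heading (persistence),
#' (ii) the unit vector towards the group centroid with weight
#' `1 / (1 + dispersion)`, and (iii) for agents outside the enrichment disc, a
#' unit vector towards the enrichment centre with weight
#' `2.5 * enrichment_affinity`; Gaussian angular noise is then added. Agents
#' move at constant speed `mean_speed_cmps / fps` per frame (times the dart
#' multiplier while darting) and reflect specularly off the tank wall.
#'
#' @param scene A [tank_scene()].
#' @param school A [school_params()].
#' @param stimulus A [stimulus_params()] or `NULL` for undisturbed swimming.
#' @param duration_s Clip duration in seconds, > 0.
#' @param fps Frame rate, > 0 (default 10).
#' @return An object of class `school_sim` with elements `positions`
#'   (`frames x n_fish x 2` array, cm, tank-centred), `headings`
#'   (`frames x n_fish`, radians), `darting` (`frames x n_fish` logical),
#'   `hull_area_cm2`, `frac_in_enrichment` (per-frame ground truth), and the
#'   input parameter objects.
#' @export
simulate_school <- function(scene, school, stimulus = NULL, duration_s,
                            fps = 10) {
  stopifnot(inherits(scene, "tank_scene"), inherits(school, "school_params"))
  if (!is.null(stimulus) && !inherits(stimulus, "stimulus_params"))
    stopf("stimulus must be NULL or stimulus_params()")
  assert_scalar_num(duration_s, "duration_s", lo = 1e-9)
  assert_scalar_num(fps, "fps", lo = 1e-9)
  n <- school$n_fish
  n_frames <- max(1L, as.integer(round(duration_s * fps)))
  dt <- 1 / fps
  R_move <- scene$radius_cm - school$body_length_cm / 2
  if (R_move <= 0) stopf("body length exceeds tank radius")
  w_persist <- 0.6
  w_centroid <- 1 / (1 + school$dispersion)
  w_enrich <- 2.5 * school$enrichment_affinity
  noise_sd <- 0.4  # radians per step
  e_ctr <- scene$enrichment_center_cm
  e_rad <- if (scene$enrichment) scene$enrichment_diameter_cm / 2 else -1
  dart_frames_total <- 0L
  if (!is.null(stimulus))
    dart_frames_total <- max(1L, as.integer(round(stimulus$dart_duration_s * fps)))

  with_seed(school$seed, {
    # initial state: group centre uniform in the inner half-radius disc,
    # agents Gaussian about it with sd scaling with dispersion
    ctr_ang <- runif(1, 0, 2 * pi)
    ctr_rad <- sqrt(runif(1)) * R_move / 2
    ctr <- c(cos(ctr_ang), sin(ctr_ang)) * ctr_rad
    spread0 <- min(school$body_length_cm * school$dispersion, R_move / 3)
    px <- ctr[1] + rnorm(n, 0, spread0)
    py <- ctr[2] + rnorm(n, 0, spread0)
    rad <- sqrt(px^2 + py^2)
    over <- rad > 0.95 * R_move
    if (any(over)) {
      scl <- 0.95 * R_move / rad[over]
      px[over] <- px[over] * scl
      py[over] <- py[over] * scl
    }
    theta <- runif(n, 0, 2 * pi)
    dart_left <- integer(n)

    pos <- array(NA_real_, c(n_frames, n, 2))
    head_arr <- matrix(NA_real_, n_frames, n)
    dart_arr <- matrix(FALSE, n_frames, n)
    hull <- numeric(n_frames)
    frac_enr <- numeric(n_frames)
    step_len <- school$mean_speed_cmps * dt

    for (f in seq_len(n_frames)) {
      t_now <- (f - 1) * dt
      # darting bookkeeping (draw before moving so frame f reflects new darts)
      if (!is.null(stimulus) && t_now >= stimulus$onset_s &&
          stimulus$initial_dart_rate_per_fish_per_s > 0) {
        rate <- stimulus$initial_dart_rate_per_fish_per_s *
          exp(-(t_now - stimulus$onset_s) / stimulus$decay_timescale_s)
        p_start <- 1 - exp(-rate * dt)
        u <- runif(n)
        new_dart <- (dart_left == 0L) & (u < p_start)
        dart_left[new_dart] <- dart_frames_total
      }
      darting <- dart_left > 0L

      # heading update
      cx <- mean(px); cy <- mean(py)
      dxc <- cx - px; dyc <- cy - py
      nc <- sqrt(dxc^2 + dyc^2)
      ok <- nc > 1e-12
      dxc <- ifelse(ok, dxc / nc, 0); dyc <- ifelse(ok, dyc / nc, 0)
      vx <- w_persist * cos(theta) + w_centroid * dxc
      vy <- w_persist * sin(theta) + w_centroid * dyc
      if (w_enrich > 0 && e_rad > 0) {
        dxe <- e_ctr[1] - px; dye <- e_ctr[2] - py
        ne <- sqrt(dxe^2 + dye^2)
        outside <- ne > e_rad
        sel <- outside & ne > 1e-12
        vx[sel] <- vx[sel] + w_enrich * dxe[sel] / ne[sel]
        vy[sel] <- vy[sel] + w_enrich * dye[sel] / ne[sel]
      }
      nv <- sqrt(vx^2 + vy^2)
      theta <- ifelse(nv > 1e-12, atan2(vy, vx), theta) + rnorm(n, 0, noise_sd)

      # move at constant per-frame step (dart multiplier while darting)
      mult <- rep(1, n)
      if (!is.null(stimulus)) mult[darting] <- stimulus$dart_speed_multiplier
      sl <- step_len * mult
      nx <- px + sl * cos(theta)
      ny <- py + sl * sin(theta)

      # specular reflection at the wall
      r_new <- sqrt(nx^2 + ny^2)
      refl <- r_new > R_move
      if (any(refl)) {
        rr <- r_new[refl]
        scl <- (2 * R_move - rr) / rr
        scl[scl < 0] <- 0  # pathological overshoot: park at centre side
        nxx <- nx[refl] * scl
        nyy <- ny[refl] * scl
        # reflect heading across the tangent at the contact point
        nhatx <- nx[refl] / rr; nhaty <- ny[refl] / rr
        hx <- cos(theta[refl]); hy <- sin(theta[refl])
        dotp <- hx * nhatx + hy * nhaty
        theta[refl] <- atan2(hy - 2 * dotp * nhaty, hx - 2 * dotp * nhatx)
        nx[refl] <- nxx; ny[refl] <- nyy
      }
      px <- nx; py <- ny

      pos[f, , 1] <- px; pos[f, , 2] <- py
      head_arr[f, ] <- theta
      dart_arr[f, ] <- darting
      dart_left[darting] <- dart_left[darting] - 1L

      if (n >= 3) {
        h <- grDevices::chull(px, py)
        hull[f] <- polygon_area(cbind(px[h], py[h]))
      } else hull[f] <- 0
      if (e_rad > 0) {
        frac_enr[f] <- mean((px - e_ctr[1])^2 + (py - e_ctr[2])^2 <= e_rad^2)
      } else frac_enr[f] <- 0
    }

    structure(list(positions = pos, headings = head_arr, darting = dart_arr,
                   hull_area_cm2 = hull, frac_in_enrichment = frac_enr,
                   scene = scene, school = school, stimulus = stimulus,
                   fps = fps, duration_s = duration_s, n_frames = n_frames),
              class = "school_sim")
  })
}

#' @export
print.school_sim <- function(x, ...) {
  cat(sprintf("<school_sim> %d fish, %d frames at %g fps (%.1f s), seed %d%s\n",
              x$school$n_fish, x$n_frames, x$fps, x$duration_s,
              x$school$seed,
              if (!is.null(x$stimulus)) ", with novel-object stimulus" else ""))
  invisible(x)
}

#' Tidy ground-truth table of a simulation
#'
#' @param sim A [simulate_school()] result.
#' @return A data.frame with one row per (frame, agent): `frame`, `time_s`,
#'   `agent`, `x_cm`, `y_cm`, `darting`.
#' @export
ground_truth <- function(sim) {
  stopifnot(inherits(sim, "school_sim"))
  n <- sim$school$n_fish; nf <- sim$n_frames
  data.frame(
    frame = rep(seq_len(nf), times = n),
    time_s = rep((seq_len(nf) - 1) / sim$fps, times = n),
    agent = rep(seq_len(n), each = nf),
    x_cm = as.vector(sim$positions[, , 1]),
    y_cm = as.vector(sim$positions[, , 2]),
    darting = as.vector(sim$darting)
  )
}

#' Per-frame ground-truth fraction of agents under the enrichment
#'
#' @param sim A [simulate_school()] result.
#' @param monitored_only If `TRUE` (default), restrict both numerator and
#'   denominator to agents inside the camera field of view, matching what the
#'   video pipeline can measure; frames with no monitored agent give `NaN`.
#' @return Numeric vector, one value per frame, in \[0, 1\].
#' @export
gt_enrichment_fraction <- function(sim, monitored_only = TRUE) {
  scene <- sim$scene
  if (!scene$enrichment) return(rep(0, sim$n_frames))
  x <- matrix(sim$positions[, , 1], nrow = sim$n_frames)
  y <- matrix(sim$positions[, , 2], nrow = sim$n_frames)
  e <- scene$enrichment_center_cm
  inside_e <- (x - e[1])^2 + (y - e[2])^2 <= (scene$enrichment_diameter_cm / 2)^2
  if (!monitored_only) return(rowMeans(inside_e))
  monitored <- y >= scene$monitored_y_cut_cm
  rowSums(inside_e & monitored) / rowSums(monitored)
}

#' Write simulator ground truth to disk
#'
#' Writes the tidy per-(frame, agent) table as CSV and the scene/school/
#' stimulus parameters (including the seed) as a YAML sidecar
#' `<path>.meta.yaml`.
#'
#' @param sim A [simulate_school()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(sim, path) {
  gt <- ground_truth(sim)
  write.csv(gt, path, row.names = FALSE)
  meta <- list(
    scene = sim$scene[c("tank_diameter_cm", "monitored_fraction", "enrichment",
                        "enrichment_center_cm", "enrichment_diameter_cm",
                        "image_size_px", "background_texture_seed")],
    school = unclass(sim$school),
    stimulus = if (is.null(sim$stimulus)) NULL else unclass(sim$stimulus),
    fps = sim$fps, duration_s = sim$duration_s, n_frames = sim$n_frames)
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' Read a ground-truth table written by [write_ground_truth()]
#' @param path CSV path.
#' @return List with `table` (data.frame) and `meta` (list from the YAML
#'   sidecar, `NULL` if absent).
#' @export
read_ground_truth <- function(path) {
  tab <- read.csv(path)
  meta_path <- paste0(path, ".meta.yaml")
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else NULL
  list(table = tab, meta = meta)
}
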