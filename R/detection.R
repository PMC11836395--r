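# Object extraction and tracking: connected-component labelling of
# foreground masks, single-fish size estimation, single-linkage grouping with
# outlier re-labelling, static enrichment-region detection, and greedy
# mutual-nearest frame-to-frame linking.

#' Label connected foreground objects per frame
#'
#' Connected components (4- or 8-connectivity) with at least `min_blob_px`
#' pixels. Centroids are the pixel-coordinate means (x = column, y = row,
#' 0-based, real-valued); when per-pixel weights are supplied (typically the
#' background-subtraction deviation image) centroids are intensity-weighted,
#' which recovers sub-pixel positions far more stably than binary-mask means.
#' Areas are recorded in px and cm^2.
#'
#' @param masks Foreground masks from [segment_foreground()] (or any list of
#'   logical matrices).
#' @param px_per_cm Pixel scale.
#' @param min_blob_px Minimum object size in pixels (default 3).
#' @param connectivity 4 or 8 (default 8).
#' @param weight_fun Optional function(frame_index) returning a numeric
#'   matrix of non-negative centroid weights (see
#'   [deviation_weight_fun()]).
#' @param monitored_mask Optional logical field-of-view raster; objects
#'   touching its boundary are only partially visible, so they are flagged
#'   `border = TRUE` (their centroids are unreliable and they are excluded
#'   from frame-to-frame linking).
#' @return A `detections` data.frame with one row per object: `frame`,
#'   `object` (within-frame index), `x_px`, `y_px`, `x_cm`, `y_cm`,
#'   `area_px`, `area_cm2`, `border`. An empty mask contributes no rows.
#' @export
label_objects <- function(masks, px_per_cm, min_blob_px = 3,
                          connectivity = 8, weight_fun = NULL,
                          monitored_mask = NULL) {
  if (!connectivity %in% c(4, 8)) stopf("connectivity must be 4 or 8")
  assert_scalar_num(px_per_cm, "px_per_cm", lo = 1e-12)
  border_idx <- NULL
  if (!is.null(monitored_mask) && !all(monitored_mask)) {
    # monitored pixels adjacent to a non-monitored pixel
    band <- monitored_mask & .morph(!monitored_mask, disc_offsets(1), FALSE)
    border_idx <- which(band)
  }
  out <- vector("list", length(masks))
  for (f in seq_along(masks)) {
    lab <- .cc_label(masks[[f]], as.integer(connectivity))
    nlab <- max(lab)
    if (nlab == 0L) next
    if (is.null(weight_fun)) {
      st <- .blob_stats(lab, nlab)
      keep <- st[, 1] >= min_blob_px
      if (!any(keep)) next
      area_px <- st[keep, 1]
      cx <- st[keep, 2] / area_px
      cy <- st[keep, 3] / area_px
    } else {
      w <- weight_fun(f)
      st <- .blob_stats_weighted(lab, nlab, w)
      keep <- st[, 1] >= min_blob_px
      if (!any(keep)) next
      area_px <- st[keep, 1]
      sw <- st[keep, 2]
      cx <- st[keep, 3] / sw
      cy <- st[keep, 4] / sw
      if (any(sw <= 0)) {
        # fall back to the unweighted mean for zero-weight blobs
        uw <- .blob_stats(lab, nlab)[keep, , drop = FALSE]
        z <- sw <= 0
        cx[z] <- uw[z, 2] / area_px[z]
        cy[z] <- uw[z, 3] / area_px[z]
      }
    }
    border <- rep(FALSE, sum(keep))
    if (!is.null(border_idx)) {
      on_border <- unique(lab[border_idx])
      on_border <- on_border[on_border > 0L]
      border <- which(keep) %in% on_border
    }
    out[[f]] <- data.frame(frame = f, object = seq_along(area_px),
                           x_px = cx, y_px = cy,
                           x_cm = cx / px_per_cm, y_cm = cy / px_per_cm,
                           area_px = area_px,
                           area_cm2 = area_px / px_per_cm^2,
                           border = border)
  }
  det <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(det))
    det <- data.frame(frame = integer(), object = integer(), x_px = numeric(),
                      y_px = numeric(), x_cm = numeric(), y_cm = numeric(),
                      area_px = numeric(), area_cm2 = numeric(),
                      border = logical())
  attr(det, "n_frames") <- length(masks)
  attr(det, "px_per_cm") <- px_per_cm
  class(det) <- c("detections", "data.frame")
  det
}

#' Centroid weights from the background-subtraction deviation
#'
#' Returns a closure mapping a frame index to the polarity-signed deviation
#' of that frame from the background location raster, for use as
#' `weight_fun` in [label_objects()].
#' @param seq A [frame_sequence()].
#' @param model A [fit_background()] model.
#' @return `function(frame_index) -> numeric matrix`.
#' @export
deviation_weight_fun <- function(seq, model) {
  force(seq); force(model)
  function(f) {
    fr <- seq$frames[[f]]
    switch(model$polarity,
           dark_fish = model$location - fr,
           light_fish = fr - model$location,
           two_sided = abs(fr - model$location))
  }
}

#' Estimate the single-fish size from a clip's detections
#'
#' Objects whose area falls at or below the 50th percentile of all object
#' areas are treated as isolated-fish candidates; the single-fish area is the
#' binned mode of the candidate areas (bin width 10% of the candidate
#' median). When fish are never isolated (fewer than 1.5 objects per frame on
#' average, or too few candidates) the estimator falls back to the per-frame
#' total detected area divided by the nominal fish count, averaged over
#' frames. The body length is derived as
#' `sqrt(single_fish_area * aspect_ratio)`.
#'
#' Supplying `reference_area_cm2` (the single-fish area of a reference
#' session, e.g. week 0) yields a growth correction factor
#' `reference_area / current area`, clamped to (0, 1], used to normalise
#' area-based metrics as fish grow.
#'
#' @param detections A [label_objects()] table covering a clip.
#' @param n_fish_nominal Nominal number of fish in the tank.
#' @param aspect_ratio Assumed body length/width ratio (default 4).
#' @param reference_area_cm2 Optional reference single-fish area.
#' @return An object of class `size_model`: `single_fish_area_cm2`,
#'   `body_length_cm`, `reference_area_cm2`, `growth_correction_factor`.
#' @export
estimate_fish_size <- function(detections, n_fish_nominal,
                               aspect_ratio = FISH_ASPECT_RATIO,
                               reference_area_cm2 = NULL) {
  if (nrow(detections) == 0) stopf("no detections in clip; cannot size fish")
  assert_scalar_num(n_fish_nominal, "n_fish_nominal", lo = 1)
  areas <- detections$area_cm2
  n_frames <- length(unique(detections$frame))
  objs_per_frame <- nrow(detections) / n_frames
  cand <- areas[areas <= quantile(areas, 0.5, type = 1)]
  use_fallback <- objs_per_frame < 1.5 || length(cand) < 10
  if (!use_fallback) {
    binw <- 0.1 * median(cand)
    if (binw <= 0) binw <- 1e-6
    bins <- floor(cand / binw)
    tb <- table(bins)
    modal <- as.integer(names(tb)[which.max(tb)])
    single <- mean(cand[bins == modal])
  } else {
    per_frame_total <- tapply(areas, detections$frame, sum)
    single <- mean(per_frame_total) / n_fish_nominal
  }
  gcf <- 1
  if (!is.null(reference_area_cm2)) {
    assert_scalar_num(reference_area_cm2, "reference_area_cm2", lo = 1e-12)
    gcf <- clamp(reference_area_cm2 / single, 0, 1)
    if (gcf <= 0) gcf <- 1e-12
  }
  structure(list(single_fish_area_cm2 = single,
                 body_length_cm = sqrt(single * aspect_ratio),
                 aspect_ratio = aspect_ratio,
                 reference_area_cm2 = reference_area_cm2,
                 growth_correction_factor = gcf,
                 fallback_used = use_fallback),
            class = "size_model")
}

#' @export
print.size_model <- function(x, ...) {
  cat(sprintf("<size_model> single fish %.2f cm^2, body length %.2f cm, growth factor %.3f%s\n",
              x$single_fish_area_cm2, x$body_length_cm,
              x$growth_correction_factor,
              if (x$fallback_used) " (fallback: total area / nominal count)" else ""))
  invisible(x)
}

#' Label detected objects as main group, outliers or individuals
#'
#' Per frame, object centroids are clustered by single linkage with cutoff
#' `linkage_factor * body_length`; the cluster with the largest summed
#' estimated fish count is the main group (ties break towards the
#' lowest-indexed cluster). Group members whose distance to the group
#' centroid exceeds `outlier_factor` times the RMS member distance are
#' re-labelled outliers in one pass; all remaining objects are individuals.
#'
#' @param detections A [label_objects()] table.
#' @param size A [estimate_fish_size()] model.
#' @param linkage_factor Linkage cutoff in body lengths (default 1.5).
#' @param outlier_factor Outlier cutoff in RMS radii (default 2.5).
#' @return The detections table with columns `est_fish_count` and `label`
#'   (one of `"group"`, `"outlier"`, `"individual"`) added.
#' @export
assign_groups <- function(detections, size, linkage_factor = 1.5,
                          outlier_factor = 2.5) {
  stopifnot(inherits(size, "size_model"))
  det <- detections
  det$est_fish_count <- det$area_cm2 / size$single_fish_area_cm2
  det$label <- rep(NA_character_, nrow(det))
  if (nrow(det) == 0) return(det)
  cutoff <- linkage_factor * size$body_length_cm
  for (f in unique(det$frame)) {
    i <- which(det$frame == f)
    n <- length(i)
    if (n == 1L) { det$label[i] <- "group"; next }
    xy <- cbind(det$x_cm[i], det$y_cm[i])
    cl <- cutree(hclust(dist(xy), method = "single"), h = cutoff)
    counts <- tapply(det$est_fish_count[i], cl, sum)
    main_cl <- as.integer(names(counts)[which.max(counts)])
    lab <- ifelse(cl == main_cl, "group", "individual")
    gi <- which(cl == main_cl)
    if (length(gi) > 1) {
      gx <- xy[gi, 1]; gy <- xy[gi, 2]
      d <- sqrt((gx - mean(gx))^2 + (gy - mean(gy))^2)
      rms <- sqrt(mean(d^2))
      if (rms > 0) lab[gi[d > outlier_factor * rms]] <- "outlier"
    }
    det$label[i] <- lab
  }
  det
}

#' Detect the static enrichment-structure footprint
#'
#' The enrichment structure is static, so it lives in the background model,
#' not the foreground. If a region is configured explicitly (a disc or a
#' polygon in cm coordinates) it is rasterised directly; otherwise the
#' background location raster is thresholded for its dark static footprint
#' (pixels darker than `median - 3 * MAD` of the monitored background) and
#' the largest dark connected component inside the monitored region is
#' taken.
#'
#' @param model A [fit_background()] model.
#' @param monitored_mask Logical field-of-view raster.
#' @param region Optional explicit region: either
#'   `list(center_cm = c(x, y), diameter_cm = d)` (a disc, tank-centred cm)
#'   or `list(polygon_cm = <two-column matrix>)`; requires `scene`.
#' @param scene A [tank_scene()], required to rasterise a configured region.
#' @param declared_present If `TRUE` and automatic detection finds no dark
#'   component, an error is raised instead of returning an empty region.
#' @param min_contrast Minimum intensity contrast (intensity units) between
#'   the two Otsu classes for a dark footprint to count as real; guards
#'   against splitting a unimodal enrichment-free background (default 20).
#' @return An object of class `enrichment_region`: logical `mask`,
#'   `area_cm2`, `source` (`"config"`, `"auto"` or `"none"`).
#' @export
detect_enrichment_region <- function(model, monitored_mask = NULL,
                                     region = NULL, scene = NULL,
                                     declared_present = !is.null(region),
                                     min_contrast = 20) {
  stopifnot(inherits(model, "background_model"))
  hw <- model$dim
  if (is.null(monitored_mask)) monitored_mask <- matrix(TRUE, hw[1], hw[2])
  ppcm <- model$px_per_cm
  if (!is.null(region)) {
    if (is.null(scene)) stopf("a configured region needs `scene`")
    if (!is.null(region$diameter_cm)) {
      mask <- disc_mask(hw, cm_to_px(scene, region$center_cm %||% c(0, 0)),
                        region$diameter_cm / 2 * ppcm)
    } else if (!is.null(region$polygon_cm)) {
      poly <- cm_to_px(scene, region$polygon_cm)
      x <- matrix(rep(0:(hw[2] - 1), each = hw[1]), nrow = hw[1])
      y <- matrix(rep(0:(hw[1] - 1), times = hw[2]), nrow = hw[1])
      mask <- matrix(point_in_polygon(cbind(as.vector(x), as.vector(y)), poly),
                     hw[1], hw[2])
    } else stopf("region must give `diameter_cm` or `polygon_cm`")
    mask <- mask & monitored_mask
    src <- "config"
  } else if (declared_present || is.null(region)) {
    # Otsu threshold on the monitored background intensities: the static
    # scene is bimodal (bright floor vs darker enrichment footprint), and
    # Otsu stays stable whatever fraction of the view the footprint covers
    loc <- model$location[monitored_mask]
    thr <- otsu_threshold(loc)
    contrast <- mean(loc[loc >= thr]) - mean(loc[loc < thr])
    dark <- model$location < thr & monitored_mask
    lab <- .cc_label(dark, 8L)
    if (max(lab) == 0L || !is.finite(contrast) || contrast < min_contrast) {
      if (declared_present)
        stopf("enrichment declared present but no dark static footprint found")
      return(structure(list(mask = matrix(FALSE, hw[1], hw[2]), area_cm2 = 0,
                            source = "none"), class = "enrichment_region"))
    }
    sizes <- tabulate(lab[lab > 0L])
    mask <- lab == which.max(sizes)
    src <- "auto"
  }
  structure(list(mask = mask, area_cm2 = sum(mask) / ppcm^2, source = src),
            class = "enrichment_region")
}

# Otsu's threshold: maximise between-class variance over a 256-bin histogram
otsu_threshold <- function(x) {
  rng <- range(x)
  if (diff(rng) <= 0) return(rng[1])
  h <- tabulate(pmin(255L, as.integer((x - rng[1]) / diff(rng) * 256)) + 1L,
                nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(256))
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  rng[1] + k / 256 * diff(rng)
}

# even-odd ray casting; vertices as two-column matrix
point_in_polygon <- function(pts, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, nrow(pts))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > pts[, 2]) != (yj > pts[, 2])) &
      (pts[, 1] < (xj - xi) * (pts[, 2] - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Link objects between two consecutive frames
#'
#' Greedy mutual-nearest-centroid matching: repeatedly accept the globally
#' closest unmatched pair (ties broken towards lower object indices) while
#' its distance is at most `gate_factor * body_length`; each object is
#' matched at most once and unmatched objects contribute no displacement.
#'
#' @param det_t,det_t1 Detection tables (rows of one frame each), with
#'   columns `object`, `x_cm`, `y_cm` (and optionally `est_fish_count`,
#'   `area_cm2`).
#' @param size A [estimate_fish_size()] model.
#' @param gate_factor Gating distance in body lengths (default 2).
#' @param size_gate_ratio Maximum allowed area ratio between matched
#'   objects (default 1.5). A blob that doubles from one frame to the next
#'   is a merge, not a moved fish; matching across merges/splits injects
#'   spurious centroid jumps into displacement metrics. `Inf` disables the
#'   gate (it is ignored when area columns are absent).
#' @return data.frame with one row per accepted match: `object_t`,
#'   `object_t1`, `displacement_cm`, `est_fish_count` (of the earlier
#'   object; 1 if unavailable).
#' @export
link_frames <- function(det_t, det_t1, size, gate_factor = 2,
                        size_gate_ratio = 1.5) {
  stopifnot(inherits(size, "size_model"))
  gate <- gate_factor * size$body_length_cm
  n1 <- nrow(det_t); n2 <- nrow(det_t1)
  empty <- data.frame(object_t = integer(), object_t1 = integer(),
                      displacement_cm = numeric(), est_fish_count = numeric())
  if (n1 == 0 || n2 == 0) return(empty)
  dx <- outer(det_t$x_cm, det_t1$x_cm, "-")
  dy <- outer(det_t$y_cm, det_t1$y_cm, "-")
  D <- sqrt(dx^2 + dy^2)
  if (is.finite(size_gate_ratio) &&
      all(c("area_cm2") %in% names(det_t)) && "area_cm2" %in% names(det_t1)) {
    ar <- outer(det_t$area_cm2, det_t1$area_cm2,
                function(a, b) pmax(a, b) / pmin(a, b))
    D[ar > size_gate_ratio] <- Inf
  }
  used1 <- logical(n1); used2 <- logical(n2)
  oi <- integer(0); oj <- integer(0); dd <- numeric(0)
  repeat {
    D_ok <- D
    D_ok[used1, ] <- Inf
    D_ok[, used2] <- Inf
    m <- min(D_ok)
    if (!is.finite(m) || m > gate) break
    # ties: lowest earlier-frame index, then lowest later-frame index
    hits <- which(D_ok == m, arr.ind = TRUE)
    hit <- hits[order(hits[, 1], hits[, 2])[1], ]
    i <- hit[[1]]; j <- hit[[2]]
    used1[i] <- TRUE; used2[j] <- TRUE
    oi <- c(oi, i); oj <- c(oj, j); dd <- c(dd, m)
  }
  if (length(oi) == 0) return(empty)
  data.frame(object_t = det_t$object[oi], object_t1 = det_t1$object[oj],
             displacement_cm = dd,
             est_fish_count = if ("est_fish_count" %in% names(det_t))
               det_t$est_fish_count[oi] else rep(1, length(oi)))
}

#' Link all consecutive frame pairs of a clip
#'
#' Objects flagged `border` (partially visible at the field-of-view edge)
#' are excluded before matching: their centroids shift as the visible part
#' changes, which would contaminate displacement-based metrics.
#'
#' @param detections A labelled [assign_groups()] table.
#' @param size A [estimate_fish_size()] model.
#' @param gate_factor Gating distance in body lengths (default 2).
#' @param n_frames Number of frames in the clip (default: from the
#'   detections attribute).
#' @return data.frame of matches with a `frame` column (the earlier frame of
#'   each pair).
#' @export
link_all_frames <- function(detections, size, gate_factor = 2,
                            n_frames = NULL, size_gate_ratio = 1.5) {
  n_frames <- n_frames %||% attr(detections, "n_frames") %||%
    max(detections$frame, 0)
  if ("border" %in% names(detections))
    detections <- detections[!detections$border, , drop = FALSE]
  by_frame <- split(seq_len(nrow(detections)), detections$frame)
  out <- list()
  for (f in seq_len(max(n_frames - 1, 0))) {
    i1 <- by_frame[[as.character(f)]]
    i2 <- by_frame[[as.character(f + 1)]]
    if (is.null(i1) || is.null(i2)) next
    lk <- link_frames(detections[i1, , drop = FALSE],
                      detections[i2, , drop = FALSE], size, gate_factor,
                      size_gate_ratio = size_gate_ratio)
    if (nrow(lk) > 0) {
      lk$frame <- f
      out[[length(out) + 1L]] <- lk
    }
  }
  if (length(out) == 0)
    return(data.frame(object_t = integer(), object_t1 = integer(),
                      displacement_cm = numeric(), est_fish_count = numeric(),
                      frame = integer()))
  do.call(rbind, out)
}
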