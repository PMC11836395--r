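# Independent oracles used by the tests: brute-force flood fill, window-scan
# latency, and small constructors for hand-built fixtures. These deliberately
# avoid the package's own code paths.

# breadth-first flood fill on a logical matrix; returns an integer label
# matrix with labels in first-encounter (column-major) order
flood_fill_oracle <- function(mask, connectivity) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 4) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  }
  nxt <- 0L
  for (c0 in seq_len(nc)) for (r0 in seq_len(nr)) {
    if (!mask[r0, c0] || lab[r0, c0] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(r0, c0))
    lab[r0, c0] <- nxt
    while (length(queue)) {
      p <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      for (d in nb) {
        r <- p[1] + d[1]; c <- p[2] + d[2]
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- nxt
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# canonicalise a labelling so partitions can be compared between algorithms
canonical_labels <- function(lab) {
  v <- as.vector(lab)
  pos <- v > 0L
  v[pos] <- match(v[pos], unique(v[pos]))
  matrix(v, nrow(lab), ncol(lab))
}

# brute-force latency: scan every window start, count distinct darting fish
latency_oracle <- function(events, window_s = 10, step_s = 1,
                           max_darts = 2, duration_s, need = 1) {
  starts <- seq(0, max(0, duration_s - window_s), by = step_s)
  qualifies <- vapply(starts, function(s) {
    sel <- events$onset_s >= s & events$onset_s < s + window_s
    length(unique(events$object[sel])) < max_darts
  }, logical(1))
  for (i in seq_along(starts)) {
    if (i + need - 1 > length(starts)) break
    if (all(qualifies[i:(i + need - 1)])) return(list(latency_s = starts[i],
                                                      censored = FALSE))
  }
  list(latency_s = duration_s, censored = TRUE)
}

# hand-built size model (the S3 object, bypassing estimation)
make_size_model <- function(single_area_cm2, aspect = 4, gcf = 1) {
  structure(list(single_fish_area_cm2 = single_area_cm2,
                 body_length_cm = sqrt(single_area_cm2 * aspect),
                 aspect_ratio = aspect, reference_area_cm2 = NULL,
                 growth_correction_factor = gcf, fallback_used = FALSE),
            class = "size_model")
}

# hand-built school_sim with fixed positions (n_frames x n x 2, cm) so the
# renderer can be exercised with exactly known geometry
make_static_sim <- function(scene, positions_cm, body_length_cm = 5,
                            headings = NULL, fps = 10) {
  nf <- dim(positions_cm)[1]; n <- dim(positions_cm)[2]
  if (is.null(headings)) headings <- matrix(0, nf, n)
  structure(list(
    positions = positions_cm, headings = headings,
    darting = matrix(FALSE, nf, n),
    hull_area_cm2 = rep(0, nf), frac_in_enrichment = rep(0, nf),
    scene = scene,
    school = school_params(n, body_length_cm = body_length_cm, seed = 1L),
    stimulus = NULL, fps = fps, duration_s = nf / fps, n_frames = nf),
    class = "school_sim")
}

# labelled detections row builder for hand-made metric fixtures
det_row <- function(frame, object, x_cm, y_cm, area_cm2, label = "group",
                    est = 1, border = FALSE) {
  data.frame(frame = frame, object = object, x_px = x_cm * 10,
             y_px = y_cm * 10, x_cm = x_cm, y_cm = y_cm,
             area_px = area_cm2 * 100, area_cm2 = area_cm2,
             border = border, est_fish_count = est, label = label)
}
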