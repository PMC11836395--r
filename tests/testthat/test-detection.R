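# Object extraction: connected components, size model, grouping, enrichment
# region, frame linking.

test_that("diagonal pixels merge under 8-connectivity and split under 4", {
  m <- matrix(FALSE, 5, 5)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE
  det8 <- label_objects(list(m), px_per_cm = 1, min_blob_px = 1,
                        connectivity = 8)
  det4 <- label_objects(list(m), px_per_cm = 1, min_blob_px = 1,
                        connectivity = 4)
  expect_equal(nrow(det8), 1L)
  expect_equal(nrow(det4), 2L)
  expect_equal(max(canonical_labels(flood_fill_oracle(m, 8))), 1L)
  expect_equal(max(canonical_labels(flood_fill_oracle(m, 4))), 2L)
})

test_that("component labelling matches the flood-fill oracle on random grids", {
  set.seed(99)
  for (i in 1:60) {
    m <- matrix(runif(16 * 16) < 0.45, 16, 16)
    for (conn in c(4L, 8L)) {
      got <- canonical_labels(shoalwatch:::.cc_label(m, conn))
      want <- canonical_labels(flood_fill_oracle(m, conn))
      expect_identical(got, want)
    }
  }
})

test_that("labelling honours min_blob_px and empty masks", {
  m <- matrix(FALSE, 8, 8)
  m[2, 2] <- TRUE                       # 1 px speck
  m[5:6, 5:6] <- TRUE                   # 4 px blob
  det <- label_objects(list(m), px_per_cm = 2, min_blob_px = 3)
  expect_equal(nrow(det), 1L)
  expect_equal(det$area_px, 4)
  expect_equal(det$area_cm2, 1)         # 4 px / (2 px/cm)^2
  expect_equal(det$x_px, 4.5)           # 0-based mean of cols 5,6
  empty <- label_objects(list(matrix(FALSE, 4, 4)), px_per_cm = 1)
  expect_equal(nrow(empty), 0L)
})

test_that("size estimation uses the isolated-fish mode with a merged fallback", {
  # plenty of isolated objects of a common size
  det <- do.call(rbind, lapply(1:100, function(f)
    det_row(f, 1:5, x_cm = (1:5) * 10, y_cm = 5, area_cm2 = 4.0)))
  sm <- estimate_fish_size(det, n_fish_nominal = 5)
  expect_false(sm$fallback_used)
  expect_equal(sm$single_fish_area_cm2, 4, tolerance = 0.2)
  expect_equal(sm$body_length_cm, sqrt(4 * 4), tolerance = 0.2)
  # one permanent merged blob: fallback divides by the nominal count
  det2 <- do.call(rbind, lapply(1:100, function(f)
    det_row(f, 1, x_cm = 0, y_cm = 0, area_cm2 = 40)))
  sm2 <- estimate_fish_size(det2, n_fish_nominal = 10)
  expect_true(sm2$fallback_used)
  expect_equal(sm2$single_fish_area_cm2, 4)
  # growth correction: current area 4x the reference -> factor 0.25
  sm3 <- estimate_fish_size(det2, n_fish_nominal = 10,
                            reference_area_cm2 = 1)
  expect_equal(sm3$growth_correction_factor, 0.25)
  expect_error(estimate_fish_size(det[0, ], 5), "no detections")
})

test_that("the main group is the largest cluster and far points are outliers", {
  sm <- make_size_model(4)  # body length 4 cm; linkage cutoff 6 cm
  one <- assign_groups(det_row(1, 1, 0, 0, 4), sm)
  expect_equal(one$label, "group")
  # clusters of 5 vs 3 equal-sized objects, far apart
  two <- rbind(det_row(1, 1:5, x_cm = c(0, 2, 4, 0, 2), y_cm = c(0, 0, 0, 2, 2),
                       area_cm2 = 4),
               det_row(1, 6:8, x_cm = c(60, 62, 64), y_cm = 60, area_cm2 = 4))
  lab <- assign_groups(two[, setdiff(names(two), c("label", "est_fish_count"))], sm)
  expect_equal(lab$label[1:5], rep("group", 5))
  expect_equal(lab$label[6:8], rep("individual", 3))
  # 10 clustered points plus one at ~10x the RMS radius -> outlier
  set.seed(1)
  xs <- c(rnorm(10, 0, 1), 30); ys <- c(rnorm(10, 0, 1), 0)
  d11 <- det_row(1, 1:11, x_cm = xs, y_cm = ys, area_cm2 = 4)
  d11 <- d11[, setdiff(names(d11), c("label", "est_fish_count"))]
  lab11 <- assign_groups(d11, sm, linkage_factor = 10)  # keep all linked
  gx <- mean(xs); gy <- mean(ys)
  dd <- sqrt((xs - gx)^2 + (ys - gy)^2)
  expect_true(dd[11] > 2.5 * sqrt(mean(dd^2)))  # brute-force RMS check
  expect_equal(lab11$label[11], "outlier")
  expect_equal(lab11$label[1:10], rep("group", 10))
})

test_that("group assignment is invariant to object enumeration order", {
  sm <- make_size_model(4)
  set.seed(7)
  base <- det_row(1, 1:12, x_cm = c(rnorm(10, 0, 2), 40, 44),
                  y_cm = c(rnorm(10, 0, 2), 40, 44), area_cm2 = 4)
  base <- base[, setdiff(names(base), c("label", "est_fish_count"))]
  ref <- assign_groups(base, sm)
  for (i in 1:5) {
    perm <- sample(nrow(base))
    shuffled <- base[perm, ]
    shuffled$object <- seq_len(nrow(base))
    got <- assign_groups(shuffled, sm)
    expect_equal(got$label, ref$label[perm])
  }
})

test_that("configured and absent enrichment regions behave as specified", {
  scene <- tank_scene(monitored_fraction = 1, image_size_px = c(128, 128))
  frames <- replicate(12, round(background_raster(scene)), simplify = FALSE)
  seq <- frame_sequence(frames, fps = 10, px_per_cm = scene$px_per_cm)
  bg <- fit_background(seq, sample_stride = 1)
  tank_area <- sum(scene_masks(scene)$tank) / scene$px_per_cm^2
  reg <- detect_enrichment_region(bg, scene_masks(scene)$tank,
                                  region = list(center_cm = c(0, 0),
                                                diameter_cm = 70),
                                  scene = scene)
  expect_equal(reg$area_cm2 / tank_area, 0.49, tolerance = 0.02)
  none <- detect_enrichment_region(bg, declared_present = FALSE,
                                   min_contrast = 1e9)
  expect_equal(none$area_cm2, 0)
  expect_equal(none$source, "none")
})

test_that("the static dark footprint is auto-detected from the background", {
  scene <- tank_scene(image_size_px = c(160, 160))
  frames <- replicate(12, round(background_raster(scene)), simplify = FALSE)
  masks <- scene_masks(scene)
  seq <- frame_sequence(frames, fps = 10, px_per_cm = scene$px_per_cm,
                        monitored_mask = masks$monitored)
  bg <- fit_background(seq, sample_stride = 1)
  reg <- detect_enrichment_region(bg, masks$monitored)
  expect_equal(reg$source, "auto")
  iou <- sum(reg$mask & masks$enrichment) / sum(reg$mask | masks$enrichment)
  expect_gte(iou, 0.8)
  # an enrichment-free scene yields no footprint (and errors when declared)
  scene0 <- tank_scene(image_size_px = c(160, 160), enrichment = FALSE)
  frames0 <- replicate(12, round(background_raster(scene0)), simplify = FALSE)
  seq0 <- frame_sequence(frames0, fps = 10, px_per_cm = scene0$px_per_cm,
                         monitored_mask = scene_masks(scene0)$monitored)
  bg0 <- fit_background(seq0, sample_stride = 1)
  reg0 <- detect_enrichment_region(bg0, scene_masks(scene0)$monitored)
  expect_equal(reg0$source, "none")
  expect_error(detect_enrichment_region(bg0, scene_masks(scene0)$monitored,
                                        declared_present = TRUE),
               "no dark static footprint")
})

test_that("frame linking matches identically and measures a 3-4-5 move", {
  sm <- make_size_model(25)  # body length 10 cm, gate 20 cm
  a <- det_row(1, 1:2, x_cm = c(0, 5), y_cm = c(0, 0), area_cm2 = 4)
  lk <- link_frames(a, a, sm)
  expect_equal(nrow(lk), 2L)
  expect_true(all(lk$displacement_cm == 0))
  b <- det_row(2, 1, x_cm = 0.3, y_cm = 0.4, area_cm2 = 4)  # (3,4) px at 10 px/cm
  lk2 <- link_frames(det_row(1, 1, 0, 0, 4), b, sm)
  expect_equal(lk2$displacement_cm, 0.5)
})

test_that("near-swapping objects match their closer partners", {
  sm <- make_size_model(25)
  t0 <- det_row(1, 1:2, x_cm = c(0, 10), y_cm = 0, area_cm2 = 4)
  t1 <- det_row(2, 1:2, x_cm = c(9.5, 0.5), y_cm = 0, area_cm2 = 4)
  lk <- link_frames(t0, t1, sm)
  # brute force over both possible assignments: {1-1, 2-2} costs 19,
  # {1-2, 2-1} costs 1 -> the mutual-nearest pairing picks the latter
  expect_equal(nrow(lk), 2L)
  expect_equal(sort(lk$displacement_cm), c(0.5, 0.5))
  expect_equal(lk$object_t1[match(1:2, lk$object_t)], c(2L, 1L))
})

test_that("matching respects the distance gate and matches each object once", {
  sm <- make_size_model(4)  # body length 4, gate 8 cm
  t0 <- det_row(1, 1:2, x_cm = c(0, 50), y_cm = 0, area_cm2 = 4)
  t1 <- det_row(2, 1, x_cm = 2, y_cm = 0, area_cm2 = 4)
  lk <- link_frames(t0, t1, sm)
  expect_equal(nrow(lk), 1L)                   # second object unmatched (far)
  expect_equal(lk$object_t, 1L)
  far <- link_frames(det_row(1, 1, 0, 0, 4), det_row(2, 1, 30, 0, 4), sm)
  expect_equal(nrow(far), 0L)
  # size gate: a blob that doubles is not matched
  merged <- link_frames(det_row(1, 1, 0, 0, 4), det_row(2, 1, 1, 0, 8.5), sm)
  expect_equal(nrow(merged), 0L)
})

test_that("detected centroids track ground truth for separated fish", {
  scene <- tank_scene(image_size_px = c(160, 160), enrichment = FALSE)
  # static grid of 12 fish, guaranteed separation
  gx <- rep(c(-24, -8, 8, 24), 3)
  gy <- rep(c(8, 20, 32), each = 4)
  nf <- 3
  pos <- array(NA_real_, c(nf, 12, 2))
  for (f in 1:nf) { pos[f, , 1] <- gx; pos[f, , 2] <- gy }
  sim <- make_static_sim(scene, pos, body_length_cm = 10)
  bgseq <- render_frames(NULL, scene = scene, noise_sd = 2, n_frames = 12,
                         seed = 4)
  fish <- render_frames(sim, noise_sd = 2, seed = 5)
  bg <- fit_background(bgseq, sample_stride = 1)
  masks <- segment_foreground(fish, bg)
  det <- label_objects(masks, px_per_cm = scene$px_per_cm,
                       weight_fun = deviation_weight_fun(fish, bg))
  expect_equal(nrow(det), 12 * nf)
  sm <- estimate_fish_size(det, 12)
  det <- assign_groups(det, sm)
  expect_true(all(det$est_fish_count > 0.5 & det$est_fish_count < 1.5))
  gt_px <- cm_to_px(scene, cbind(gx, gy))
  for (f in 1:nf) {
    d <- det[det$frame == f, ]
    nn <- vapply(seq_len(nrow(d)), function(i)
      min(sqrt((gt_px[, 1] - d$x_px[i])^2 + (gt_px[, 2] - d$y_px[i])^2)),
      numeric(1))
    expect_true(all(nn < 0.25 * 10 * scene$px_per_cm))
  }
})
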