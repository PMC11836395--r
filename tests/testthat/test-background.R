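# Background model: median/MAD statistics and foreground segmentation.

make_seq <- function(frames, fps = 10, ppcm = 2, ...)
  frame_sequence(frames, fps = fps, px_per_cm = ppcm, ...)

test_that("constant frames give an exact background with zero spread", {
  frames <- replicate(12, matrix(137, 8, 8), simplify = FALSE)
  bg <- fit_background(make_seq(frames), sample_stride = 1)
  expect_true(all(bg$location == 137))
  expect_true(all(bg$spread == 0))
  expect_equal(bg$n_frames_used, 12L)
})

test_that("the lower-median tie rule resolves a 50/50 alternating pixel", {
  frames <- lapply(1:12, function(i) {
    m <- matrix(100, 6, 6)
    m[3, 3] <- if (i %% 2 == 0) 100 + 8 else 100
    m
  })
  bg <- fit_background(make_seq(frames), sample_stride = 1)
  expect_equal(bg$location[3, 3], 100)  # lower of the two middle values
})

test_that("fitting requires enough sampled frames and uniform shapes", {
  frames <- replicate(5, matrix(1, 4, 4), simplify = FALSE)
  expect_error(fit_background(make_seq(frames), sample_stride = 1), ">= 10")
  bad <- c(replicate(4, matrix(1, 4, 4), simplify = FALSE),
           list(matrix(1, 5, 5)))
  expect_error(frame_sequence(bad, fps = 10, px_per_cm = 1), "identical shape")
})

test_that("the fitted background matches the true scene despite moving fish", {
  scene <- tank_scene(image_size_px = c(128, 128))
  sim <- simulate_school(scene, school_params(10, dispersion = 8, seed = 21),
                         duration_s = 12)
  seq <- render_frames(sim, noise_sd = 2)
  bg <- fit_background(seq, sample_stride = 2)
  truth <- round(background_raster(scene))
  err <- abs(bg$location - truth)
  expect_gte(mean(err <= 2), 0.99)
})

test_that("segmentation is empty on background-only frames and at huge k_sigma", {
  frames <- replicate(12, matrix(50, 16, 16), simplify = FALSE)
  seq <- make_seq(frames)
  bg <- fit_background(seq, sample_stride = 1)
  masks <- segment_foreground(seq, bg)
  expect_true(all(!unlist(masks)))
  scene <- tank_scene(image_size_px = c(96, 96))
  seq2 <- render_frames(NULL, scene = scene, noise_sd = 2, n_frames = 15)
  bg2 <- fit_background(seq2, sample_stride = 1)
  masks2 <- segment_foreground(seq2, bg2, k_sigma = 1e6)
  expect_true(all(!unlist(masks2)))
})

test_that("foreground pixel count is non-increasing in k_sigma", {
  scene <- tank_scene(image_size_px = c(96, 96), enrichment = FALSE)
  pos <- array(c(0, 0, 10, 10, 8, 8, 8, 8), c(2, 2, 2))  # fish at (0,8), (10,8)
  sim <- make_static_sim(scene, pos, body_length_cm = 10)
  bgseq <- render_frames(NULL, scene = scene, noise_sd = 2, n_frames = 12,
                         seed = 2)
  fish <- render_frames(sim, noise_sd = 2, seed = 3)
  bg <- fit_background(bgseq, sample_stride = 1)
  counts <- vapply(c(0.5, 1, 2, 4, 8, 16, 1000), function(k) {
    sum(segment_foreground(fish, bg, k_sigma = k, r_open = 0)[[1]])
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("a rendered fish segments as one blob of about the ellipse area", {
  scene <- tank_scene(image_size_px = c(128, 128), enrichment = FALSE)
  pos <- array(c(0, 12), c(1, 1, 2))
  sim <- make_static_sim(scene, pos, body_length_cm = 16)
  bgseq <- render_frames(NULL, scene = scene, noise_sd = 0, n_frames = 12)
  fish <- render_frames(sim, noise_sd = 0)
  bg <- fit_background(bgseq, sample_stride = 1)
  m <- segment_foreground(fish, bg)[[1]]
  expect_equal(max(flood_fill_oracle(m, 8)), 1L)
  # at half the fish/background contrast the mask is the body contour of the
  # blurred ellipse; compare its pixel count to an independent rasterisation
  # oracle (pixel centres inside the true ellipse)
  m50 <- segment_foreground(fish, bg, k_sigma = 80)[[1]]
  expect_equal(max(flood_fill_oracle(m50, 8)), 1L)
  a_px <- 16 / 2 * scene$px_per_cm
  b_px <- a_px / 4
  ctr <- cm_to_px(scene, c(0, 12))
  px <- expand.grid(x = 0:127, y = 0:127)
  oracle <- sum(((px$x - ctr[1]) / a_px)^2 + ((px$y - ctr[2]) / b_px)^2 <= 1)
  expect_equal(sum(m50), oracle, tolerance = 0.2)
})

test_that("the static enrichment structure is absorbed into the background", {
  scene <- tank_scene(image_size_px = c(128, 128))
  sim <- simulate_school(scene, school_params(8, dispersion = 4, seed = 5),
                         duration_s = 10)
  seq <- render_frames(sim, noise_sd = 2)
  bg <- fit_background(seq, sample_stride = 2)
  masks <- segment_foreground(seq, bg)
  fish_px <- fish_pixel_masks(sim)
  enr <- scene_masks(scene)$enrichment
  flagged <- 0; total <- 0
  for (f in seq_along(masks)) {
    enr_only <- enr & !fish_px[[f]]
    flagged <- flagged + sum(masks[[f]] & enr_only)
    total <- total + sum(enr_only)
  }
  expect_lt(flagged / total, 0.01)
})

test_that("background model round-trips through TIFF + JSON", {
  frames <- replicate(12, matrix(runif(64, 0, 255), 8, 8), simplify = FALSE)
  seq <- make_seq(frames)
  bg <- fit_background(seq, sample_stride = 1)
  path <- file.path(tempdir(), "bg.tif")
  write_background_model(bg, path)
  back <- read_background_model(path)
  expect_equal(back$location, bg$location, tolerance = 1e-5)
  expect_equal(back$spread, bg$spread, tolerance = 1e-5)
  expect_equal(back$polarity, bg$polarity)
  unlink(c(path, paste0(path, ".json")))
})
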