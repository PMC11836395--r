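# Table-1 behavioural indicators: cohesion ratio + categorical score,
# activity, enrichment occupation, per-clip records.

test_that("the categorical cohesion rule scores the three reference ratios", {
  expect_identical(cohesion_score(0.10), 0L)
  expect_identical(cohesion_score(0.50), 1L)
  expect_identical(cohesion_score(0.90), 2L)
  # boundary convention: both category boundaries belong to "loose"
  expect_identical(cohesion_score(0.25), 1L)
  expect_identical(cohesion_score(0.75), 1L)
  expect_error(cohesion_score(1.2), "\\[0, 1\\]")
  expect_error(cohesion_score(-0.1), "\\[0, 1\\]")
  expect_error(cohesion_rule(0.8, 0.2), "tight_upper")
})

test_that("the score is a non-decreasing step function on a fine ratio grid", {
  grid <- seq(0, 1, length.out = 1001)
  sc <- cohesion_score(grid)
  expect_true(all(diff(sc) >= 0))
  expect_identical(sort(unique(sc)), c(0L, 1L, 2L))
  expect_true(all(sc[grid < 0.25] == 0L))
  expect_true(all(sc[grid >= 0.25 & grid <= 0.75] == 1L))
  expect_true(all(sc[grid > 0.75] == 2L))
})

test_that("cohesion ratio matches the exact dilated-hull geometry oracle", {
  sm <- make_size_model(4)  # body length 4 cm -> dilation radius 2 cm
  det <- det_row(1, 1:4, x_cm = c(0, 20, 20, 0), y_cm = c(0, 0, 20, 20),
                 area_cm2 = 4)
  res <- cohesion_ratio(det, monitored_area_cm2 = 3900, size = sm)
  # square hull 400 cm^2 + perimeter 80 x 2 cm + pi 2^2 (polygon offset)
  expect_equal(res$ratio, (400 + 160 + 4 * pi) / 3900, tolerance = 1e-9)
  expect_identical(res$score, cohesion_score(res$ratio))
})

test_that("degenerate groups give vanishing or blob-area ratios", {
  tiny <- make_size_model(1e-8)
  det <- det_row(1, 1:5, x_cm = 10, y_cm = 10, area_cm2 = 1e-8)
  expect_lt(cohesion_ratio(det, 3900, tiny)$ratio, 1e-6)
  # a single merged blob uses its own pixel area
  sm <- make_size_model(4)
  one <- det_row(1, 1, x_cm = 0, y_cm = 0, area_cm2 = 390)
  expect_equal(cohesion_ratio(one, 3900, sm)$ratio, 0.1)
  # growth correction multiplies the ratio
  sm25 <- make_size_model(4, gcf = 0.25)
  expect_equal(cohesion_ratio(one, 3900, sm25)$ratio, 0.025)
  # members spread over the whole monitored area push the ratio towards 1
  wide <- det_row(1, 1:4, x_cm = c(0, 62.5, 62.5, 0), y_cm = c(0, 0, 62.4, 62.4),
                  area_cm2 = 4)
  expect_gte(cohesion_ratio(wide, 3900, sm)$ratio, 0.999)
  # no main group at all -> flagged missing
  lone <- det_row(1, 1, 0, 0, 4, label = "individual")
  expect_true(cohesion_ratio(lone, 3900, sm)$missing)
})

test_that("cohesion ratio is invariant under frame order permutation", {
  sm <- make_size_model(4)
  set.seed(3)
  det <- do.call(rbind, lapply(1:10, function(f)
    det_row(f, 1:3, x_cm = rnorm(3, 10 + f, 2), y_cm = rnorm(3, 10, 2),
            area_cm2 = 4)))
  ref <- cohesion_ratio(det, 3900, sm)$ratio
  shuf <- det[sample(nrow(det)), ]
  shuf$frame <- match(shuf$frame, unique(shuf$frame))  # relabel frames
  expect_equal(cohesion_ratio(shuf, 3900, sm)$ratio, ref, tolerance = 1e-12)
})

test_that("activity is the fish-count-weighted mean displacement", {
  links <- data.frame(object_t = 1:2, object_t1 = 1:2,
                      displacement_cm = c(1, 11),
                      est_fish_count = c(9, 1), frame = 1L)
  act <- activity(links, fps = 10)
  expect_equal(act$activity_cm_per_frame, 2, tolerance = 1e-9)
  expect_equal(act$activity_cm_per_s, 20, tolerance = 1e-9)
  # static scene
  static <- data.frame(object_t = 1:3, object_t1 = 1:3,
                       displacement_cm = 0, est_fish_count = 1, frame = 1L)
  expect_equal(activity(static, 10)$activity_cm_per_frame, 0)
  # row order (object relabelling) does not matter
  expect_equal(activity(links[2:1, ], 10)$activity_cm_per_frame, 2)
  # no matches -> missing
  expect_true(activity(links[0, ], 10)$missing)
  # standardisation helper is a plain z-score
  expect_equal(standardise_activity(c(1, 2, 3)), c(-1, 0, 1))
})

test_that("enrichment occupation is the in-region share of fish pixels", {
  region <- structure(list(mask = matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2),
                           area_cm2 = 2, source = "config"),
                      class = "enrichment_region")
  all_in <- list(matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2))
  expect_equal(enrichment_occupation(all_in, region)$occupation_pct, 100)
  half <- list(matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2))
  expect_equal(enrichment_occupation(half, region)$occupation_pct, 50)
  none <- structure(list(mask = matrix(FALSE, 2, 2), area_cm2 = 0,
                         source = "none"), class = "enrichment_region")
  expect_equal(enrichment_occupation(half, none)$occupation_pct, 0)
  # no fish at all -> missing
  expect_true(enrichment_occupation(list(matrix(FALSE, 2, 2)),
                                    region)$missing)
})

test_that("clip records carry metrics and explicit missing flags", {
  sm <- make_size_model(4)
  det <- det_row(1, 1, 0, 0, 39)
  coh <- cohesion_ratio(det, 3900, sm)
  links <- data.frame(object_t = 1, object_t1 = 1, displacement_cm = 0.5,
                      est_fish_count = 1, frame = 1L)
  act <- activity(links, 10)
  rec <- summarise_clip(coh, act, NULL, clip_id = "c1", tank_id = "T1",
                        week = 3, timepoint = "06:00")
  expect_s3_class(rec, "behaviour_record")
  expect_false(rec$flag_missing_cohesion)
  expect_false(rec$flag_missing_activity)
  expect_true(rec$flag_missing_occupation)
  expect_equal(rec$cohesion_score, cohesion_score(rec$cohesion_ratio))
  empty <- summarise_clip(clip_id = "c2")
  expect_true(all(unlist(empty[, grep("flag_", names(empty))])))
  expect_true(is.na(empty$cohesion_ratio))
})
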