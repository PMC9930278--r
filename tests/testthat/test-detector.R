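test_that("plate localization recovers the configured circle", {
  cfg <- small_config(seed = 2)
  p <- simulate_plate(cfg)
  pl <- locate_plate(p$image)
  tol_c <- 0.02 * min(dim(p$image))
  tol_r <- 0.03 * min(dim(p$image))
  expect_lt(sqrt((pl$cx - cfg$plate_center[1])^2 + (pl$cy - cfg$plate_center[2])^2), tol_c)
  expect_lt(abs(pl$r - cfg$plate_radius), tol_r)
})

test_that("plate localization tracks an off-center dish", {
  shift <- 0.05 * 680
  cfg <- small_config(plate_center = c(350 + shift, 340 - shift),
                      plate_radius = 0.42 * 680, seed = 4)
  p <- simulate_plate(cfg)
  pl <- locate_plate(p$image)
  expect_lt(sqrt((pl$cx - cfg$plate_center[1])^2 + (pl$cy - cfg$plate_center[2])^2),
            0.02 * min(dim(p$image)))
})

test_that("a blank dark image falls back to the inscribed circle with a warning", {
  set.seed(1)
  img <- plate_image(pmax(matrix(rnorm(300 * 300, 10, 3), 300, 300), 0), "blank")
  expect_warning(pl <- locate_plate(img), "fall")
  expect_equal(pl$cx, 150)
  expect_equal(pl$cy, 150)
  expect_equal(pl$r, 0.48 * 300)
})

test_that("segmentation finds each isolated colony as one region", {
  cfg <- small_config(seed = 6)
  p <- simulate_plate(cfg)
  pl <- locate_plate(p$image)
  lab <- segment_colonies(p$image, pl)
  feats <- extract_features(lab, p$image)
  # every ground-truth colony is covered by exactly one region center
  hits <- vapply(seq_len(nrow(p$truth)), function(i) {
    tr <- p$truth[i, ]
    lb <- lab[round((tr$x_min + tr$x_max) / 2), round((tr$y_min + tr$y_max) / 2)]
    lb
  }, numeric(1))
  expect_true(all(hits > 0))
  expect_equal(length(unique(hits)), nrow(p$truth))
})

test_that("a blank plate yields an empty label map, not an error", {
  cfg <- small_config(colony_count_mean = 1e-9, seed = 3)
  p <- simulate_plate(cfg)
  lab <- segment_colonies(p$image, locate_plate(p$image))
  expect_true(all(lab == 0L))
  expect_equal(nrow(extract_features(lab, p$image)), 0L)
})

test_that("watershed splits a deliberately touching pair into two regions", {
  cfg <- small_config(noise_sigma = 2)
  colonies <- data.frame(
    cx = c(300, 355, 200, 214), cy = c(300, 300, 500, 500),
    radius = c(30, 30, 8, 8), cls = c("grande", "grande", "petite", "petite"),
    peak = c(215, 210, 135, 130), pair_id = c(1L, 1L, 2L, 2L))
  out <- render_plate(cfg, colonies, "pairs")
  lab <- segment_colonies(out$image, locate_plate(out$image))
  labels_at <- lab[cbind(round(colonies$cx), round(colonies$cy))]
  expect_true(all(labels_at > 0))
  expect_equal(length(unique(labels_at)), 4L)
})

test_that("region features match brute-force moment arithmetic", {
  img <- plate_image(matrix(100, 80, 80), "feat")
  lab <- matrix(0L, 80, 80)
  lab[11:20, 11:20] <- 1L        # 10 x 10 square
  lab[40:41, 21:60] <- 2L        # 2 x 40 bar
  f <- extract_features(lab, img)
  sq <- f[f$region_id == 1L, ]; bar <- f[f$region_id == 2L, ]
  expect_equal(sq$area, 100)
  expect_equal(c(sq$x_min, sq$y_min, sq$x_max, sq$y_max), c(10, 10, 20, 20))
  expect_lt(sq$eccentricity, 0.3)
  expect_gt(bar$eccentricity, 0.9)
  pix <- which(lab == 2L, arr.ind = TRUE)
  expect_equal(bar$eccentricity, ecc_oracle(pix[, 1], pix[, 2]), tolerance = 1e-6)
  expect_equal(sq$mean_intensity, 100)
})

test_that("rendered colonies have near-circular footprints", {
  p <- simulate_plate(small_config(seed = 8))
  f <- extract_features(segment_colonies(p$image, locate_plate(p$image)), p$image)
  f <- filter_regions(f)
  expect_true(all(f$eccentricity < 0.3))
})

test_that("area bounds are inclusive and eccentricity strict", {
  feats <- data.frame(region_id = 1:5,
                      x_min = 0, y_min = 0, x_max = 10, y_max = 10,
                      area = c(39, 40, 6000, 6001, 100),
                      eccentricity = c(0.1, 0.1, 0.1, 0.1, 0.95),
                      mean_intensity = 150)
  kept <- filter_regions(feats, filter_params())
  expect_equal(kept$region_id, c(2L, 3L))
})

test_that("widening the area interval never loses regions", {
  set.seed(12)
  feats <- data.frame(region_id = 1:50, x_min = 0, y_min = 0, x_max = 10, y_max = 10,
                      area = runif(50, 1, 8000), eccentricity = runif(50, 0, 0.5),
                      mean_intensity = 150)
  narrow <- filter_regions(feats, filter_params(min_area = 100, max_area = 3000))
  wide <- filter_regions(feats, filter_params(min_area = 40, max_area = 6000))
  expect_true(all(narrow$region_id %in% wide$region_id))
})

test_that("clustering separates the two size/intensity groups", {
  feats <- data.frame(region_id = 1:4, x_min = 0, y_min = 0, x_max = 10, y_max = 10,
                      area = c(2000, 2200, 80, 90),
                      eccentricity = 0.1,
                      mean_intensity = c(200, 210, 120, 125))
  out <- classify_regions(feats, classifier_params())
  expect_equal(out$cls, c("grande", "grande", "petite", "petite"))
})

test_that("classification is invariant to region input order", {
  set.seed(5)
  feats <- data.frame(region_id = 1:12, x_min = 0, y_min = 0, x_max = 10, y_max = 10,
                      area = c(runif(6, 1500, 4000), runif(6, 60, 300)),
                      eccentricity = 0.1,
                      mean_intensity = c(runif(6, 180, 210), runif(6, 120, 140)))
  base <- classify_regions(feats, classifier_params())
  perm <- sample(nrow(feats))
  shuffled <- classify_regions(feats[perm, ], classifier_params())
  expect_equal(shuffled$cls[order(shuffled$region_id)],
               base$cls[order(base$region_id)])
})

test_that("few regions or zero variance fall back to the size threshold", {
  one <- data.frame(region_id = 1L, x_min = 0, y_min = 0, x_max = 10, y_max = 10,
                    area = 1500, eccentricity = 0.1, mean_intensity = 180)
  expect_equal(classify_regions(one, classifier_params())$cls, "grande")
  small <- one; small$area <- 900
  expect_equal(classify_regions(small, classifier_params())$cls, "petite")
  flat <- data.frame(region_id = 1:6, x_min = 0, y_min = 0, x_max = 10, y_max = 10,
                     area = 500, eccentricity = 0.1, mean_intensity = 150)
  expect_equal(classify_regions(flat, classifier_params())$cls, rep("petite", 6))
})

test_that("the full pipeline is deterministic and accurate on an ideal plate", {
  cfg <- small_config(seed = 10)
  p <- simulate_plate(cfg)
  d1 <- detect_colonies(p$image)
  d2 <- detect_colonies(p$image)
  expect_identical(d1, d2)
  expect_true(all(d1$score == 1.0))
  m <- match_detections(d1, p$truth, 0.25)
  pr <- precision_recall(m)
  expect_true(all(pr$recall >= 0.9, na.rm = TRUE))
  expect_true(all(pr$precision >= 0.9, na.rm = TRUE))
})

test_that("detections stay inside the rim-shrunk plate disc", {
  cfg <- small_config(seed = 10)
  p <- simulate_plate(cfg)
  pl <- locate_plate(p$image)
  d <- detect_colonies(p$image, plate = pl)
  corners_r <- pmax(
    sqrt((d$x_min - pl$cx)^2 + (d$y_min - pl$cy)^2),
    sqrt((d$x_max - pl$cx)^2 + (d$y_max - pl$cy)^2))
  expect_true(all(corners_r <= pl$r * 1.02))
})

test_that("a plate containing only refraction arcs yields zero detections", {
  cfg <- small_config(colony_count_mean = 1e-9, artifact_arc_range = c(3L, 3L),
                      seed = 21)
  p <- simulate_plate(cfg)
  d <- detect_colonies(p$image)
  expect_equal(nrow(d), 0L)
})

test_that("blank plates yield an empty detection list", {
  cfg <- small_config(colony_count_mean = 1e-9, seed = 22)
  p <- simulate_plate(cfg)
  expect_equal(nrow(detect_colonies(p$image)), 0L)
})
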