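test_that("the image-resolution equation reproduces the training slice size", {
  expect_equal(compute_slice_size(2376, 2288), 512L)
  expect_equal(compute_slice_size(1000, 1000, S_A = 1), 1000L)
  # halving both dimensions halves the slice size
  expect_equal(compute_slice_size(1188, 1144), 256L)
  expect_error(compute_slice_size(0, 100), "at least 1")
})

test_that("the grande-diameter equation enforces the training size ratio", {
  expect_equal(compute_slice_size_from_diameter(60, 60), 512L)
  expect_equal(compute_slice_size_from_diameter(120, 60), 1024L)
  expect_equal(compute_slice_size_from_diameter(30, 60), 256L)
  expect_error(compute_slice_size_from_diameter(-5, 60), "positive")
})

test_that("tiling covers every pixel with unique in-bounds windows", {
  w1 <- tile_windows(512, 512, 512)
  expect_equal(nrow(w1), 1L)
  expect_equal(c(w1$x0, w1$y0), c(0L, 0L))

  w2 <- tile_windows(1024, 512, 512, overlap_ratio = 0)
  expect_equal(sort(w2$x0), c(0L, 512L))
  expect_equal(unique(w2$y0), 0L)

  w3 <- tile_windows(800, 800, 512, overlap_ratio = 0.2)
  expect_equal(nrow(w3), 4L)
  expect_setequal(unique(w3$x0), c(0L, 288L))
  expect_setequal(unique(w3$y0), c(0L, 288L))
  covered <- matrix(FALSE, 800, 800)
  for (i in seq_len(nrow(w3))) {
    covered[(w3$x0[i] + 1):(w3$x0[i] + w3$w[i]),
            (w3$y0[i] + 1):(w3$y0[i] + w3$h[i])] <- TRUE
  }
  expect_true(all(covered))
  expect_equal(anyDuplicated(w3[c("x0", "y0")]), 0L)

  expect_error(tile_windows(300, 300, 512), "exceeds")
})

test_that("nmm merges overlapping same-class detections into a union box", {
  d <- detection_table(c(0, 2), c(0, 0), c(10, 12), c(10, 10),
                       c("grande", "grande"), c(0.9, 0.8))
  out <- nmm(d)
  expect_equal(nrow(out), 1L)
  expect_equal(as.numeric(out[1, c("x_min", "y_min", "x_max", "y_max")]),
               c(0, 0, 12, 10))
  expect_equal(out$score, 0.9)

  mixed <- detection_table(c(0, 2), c(0, 0), c(10, 12), c(10, 10),
                           c("grande", "petite"), c(0.9, 0.8))
  expect_equal(nrow(nmm(mixed)), 2L)

  expect_equal(nrow(nmm(detection_table())), 0L)
})

test_that("nmm drops sub-threshold detections before merging", {
  d <- detection_table(c(0, 2), c(0, 0), c(10, 12), c(10, 10),
                       c("grande", "grande"), c(0.9, 0.4))
  out <- nmm(d)
  expect_equal(nrow(out), 1L)
  expect_equal(as.numeric(out[1, c("x_min", "x_max")]), c(0, 10))
})

test_that("greedy nmm equals the transitive-closure oracle on random instances", {
  set.seed(31)
  params <- nmm_params(score_threshold = 0.3)
  for (i in 1:300) {
    d <- random_detections(sample(0:6, 1), lim = 40, classes =
                             if (i %% 3 == 0) "grande" else COLONY_CLASSES)
    got <- canonical_dets(nmm(d, params))
    want <- nmm_oracle(d, params)
    expect_equal(got, want, tolerance = 1e-12)
    # idempotence
    expect_equal(canonical_dets(nmm(nmm(d, params), params)), got, tolerance = 1e-12)
  }
})

test_that("nmm output never exceeds input size and leaves disjoint boxes alone", {
  d <- detection_table(c(0, 50, 100), c(0, 0, 0), c(10, 60, 110), c(10, 10, 10),
                       rep("petite", 3), c(0.7, 0.8, 0.9))
  out <- nmm(d)
  expect_equal(nrow(out), 3L)
  # no surviving same-class pair overlaps above the threshold
  p <- nmm_params()
  for (i in seq_len(nrow(out))) for (j in seq_len(nrow(out))) {
    if (i >= j || out$cls[i] != out$cls[j]) next
    ios <- box_ios(do.call(bbox, as.list(as.numeric(out[i, 1:4]))),
                   do.call(bbox, as.list(as.numeric(out[j, 1:4]))))
    expect_lte(ios, p$ios_threshold)
  }
})

test_that("sliced inference with the oracle backend recovers ground truth", {
  cfg <- small_config(seed = 14)
  p <- simulate_plate(cfg)
  sl <- slicing_params(mode = "fixed", slice_px = 512L, overlap_ratio = 0.2)
  dets <- infer_sliced(p$image, oracle_backend(p$truth), sl)
  expect_equal(nrow(dets), nrow(p$truth))
  m <- match_detections(dets, p$truth, 0.5)
  pr <- precision_recall(m)
  expect_true(all(pr$recall[!is.na(pr$recall)] == 1))
  expect_true(all(pr$precision[!is.na(pr$precision)] == 1))
})

test_that("an image smaller than the slice behaves as whole-image inference", {
  cfg <- small_config(seed = 15)
  p <- simulate_plate(cfg)
  backend <- oracle_backend(p$truth)
  auto <- infer_sliced(p$image, backend)  # S clamps to min dimension
  full_win <- data.frame(x0 = 0L, y0 = 0L, w = p$image$width, h = p$image$height)
  whole <- nmm(nms(backend(p$image, full_win), 0.5))
  expect_equal(canonical_dets(auto), canonical_dets(whole))
})

test_that("raising the window overlap never reduces oracle recall", {
  cfg <- small_config(seed = 16)
  p <- simulate_plate(cfg)
  recall_at <- function(overlap) {
    sl <- slicing_params(mode = "fixed", slice_px = 400L, overlap_ratio = overlap)
    dets <- infer_sliced(p$image, oracle_backend(p$truth), sl)
    m <- match_detections(dets, p$truth, 0.5)
    pr <- precision_recall(m)
    sum(pr$TP) / (sum(pr$TP) + sum(pr$FN))
  }
  expect_gte(recall_at(0.4), recall_at(0.2))
})

test_that("window-local detections map back inside their window footprint", {
  cfg <- small_config(seed = 17)
  p <- simulate_plate(cfg)
  S <- 400L
  wins <- tile_windows(p$image$width, p$image$height, S, 0.2)
  backend <- oracle_backend(p$truth)
  for (i in seq_len(nrow(wins))) {
    win <- wins[i, ]
    local <- backend(colonyscan:::crop_region(p$image, win), win)
    if (nrow(local) == 0) next
    shifted <- colonyscan:::shift_boxes(local, win$x0, win$y0)
    expect_true(all(shifted$x_min >= win$x0 & shifted$x_max <= win$x0 + win$w))
    expect_true(all(shifted$y_min >= win$y0 & shifted$y_max <= win$y0 + win$h))
  }
})

test_that("a failing backend reports the offending slice", {
  img <- plate_image(matrix(90, 600, 600), "boom")
  bad <- function(region, window) stop("backend exploded")
  expect_error(
    infer_sliced(img, bad, slicing_params(mode = "fixed", slice_px = 512L)),
    "offset \\(0, 0\\)")
})
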