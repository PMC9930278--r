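gt_frame <- function(x_min, y_min, x_max, y_max, cls) {
  data.frame(x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max,
             cls = cls, stringsAsFactors = FALSE)
}

test_that("identical predictions and ground truth are all true positives", {
  gts <- gt_frame(c(0, 50), c(0, 50), c(10, 70), c(10, 70), c("grande", "petite"))
  preds <- detection_table(gts$x_min, gts$y_min, gts$x_max, gts$y_max, gts$cls, 1.0)
  m <- match_detections(preds, gts, 0.5)
  pr <- precision_recall(m)
  expect_equal(pr$TP, c(1L, 1L))
  expect_equal(pr$FP, c(0L, 0L))
  expect_equal(pr$FN, c(0L, 0L))
})

test_that("overlap below the threshold is a false positive plus false negative", {
  gts <- gt_frame(0, 0, 10, 10, "grande")
  preds <- detection_table(6, 0, 16, 10, "grande", 0.9)  # IOU = 4/16 = 0.25
  pr <- precision_recall(match_detections(preds, gts, 0.5))
  g <- pr[pr$cls == "grande", ]
  expect_equal(c(g$TP, g$FP, g$FN), c(0L, 1L, 1L))
})

test_that("greedy matching gives the ground truth to the higher-scoring detection", {
  gts <- gt_frame(0, 0, 10, 10, "grande")
  preds <- detection_table(c(0, 1), c(0, 0), c(10, 11), c(10, 10),
                           c("grande", "grande"), c(0.9, 0.8))
  m <- match_detections(preds, gts, 0.5)
  g <- m$per_class$grande
  expect_equal(g$TP, 1L)
  expect_equal(g$FP, 1L)
  expect_true(g$tp[1])   # the 0.9 detection, sorted first
  expect_false(g$tp[2])
})

test_that("matching is one-to-one on random instances", {
  set.seed(51)
  for (i in 1:50) {
    gts <- random_detections(sample(1:8, 1), lim = 60)[, c(1:4, 5)]
    preds <- random_detections(sample(0:8, 1), lim = 60)
    m <- match_detections(preds, gts, 0.3)
    for (cl in COLONY_CLASSES) {
      x <- m$per_class[[cl]]
      matched <- x$matched_gt[!is.na(x$matched_gt)]
      expect_equal(anyDuplicated(matched), 0L)
      expect_equal(x$TP + x$FN, x$n_gt)
      expect_equal(x$TP + x$FP, length(x$scores))
    }
  }
})

test_that("raising the IOU threshold never increases true positives", {
  set.seed(52)
  gts <- random_detections(10, lim = 50)[, c(1:4, 5)]
  preds <- random_detections(15, lim = 50)
  tps <- vapply(seq(0.1, 0.9, 0.1), function(t) {
    sum(precision_recall(match_detections(preds, gts, t))$TP)
  }, numeric(1))
  expect_true(all(diff(tps) <= 0))
})

test_that("precision and recall handle empty predictions", {
  pr0 <- precision_recall(match_detections(detection_table(),
                                           gt_frame(0, 0, 10, 10, "petite"), 0.5))
  p <- pr0[pr0$cls == "petite", ]
  expect_true(is.na(p$precision))
  expect_equal(p$recall, 0)
  expect_equal(pr0[pr0$cls == "grande", "recall"], NA_real_)
})

test_that("average precision is exact on the boundary cases", {
  gts <- gt_frame(c(0, 50), c(0, 0), c(10, 60), c(10, 10), c("grande", "grande"))
  perfect <- detection_table(gts$x_min, gts$y_min, gts$x_max, gts$y_max,
                             "grande", c(0.9, 0.8))
  expect_equal(unname(average_precision(perfect, gts, 0.5)["grande"]), 1.0)
  allfp <- detection_table(c(100, 200), c(100, 200), c(110, 210), c(110, 210),
                           "grande", c(0.9, 0.8))
  expect_equal(unname(average_precision(allfp, gts, 0.5)["grande"]), 0.0)
})

test_that("a mixed TP/FP score sweep matches hand enumeration", {
  gts <- gt_frame(c(0, 50), c(0, 0), c(10, 60), c(10, 10), c("grande", "grande"))
  preds <- detection_table(c(0, 100, 50), c(0, 100, 0), c(10, 110, 60),
                           c(10, 110, 10), "grande", c(0.9, 0.8, 0.7))
  # flags in score order: TP, FP, TP -> precision (1, 1/2, 2/3), recall (.5, .5, 1)
  # envelope: (1, 2/3, 2/3); 101-point: 51 pts at 1, 50 pts at 2/3
  expect_equal(unname(average_precision(preds, gts, 0.5)["grande"]),
               (51 * 1 + 50 * 2 / 3) / 101)
})

test_that("the 101-point AP tracks exact PR-curve integration", {
  set.seed(53)
  for (i in 1:100) {
    n <- sample(1:10, 1)
    n_gt <- sample(1:10, 1)
    scores <- runif(n)
    tp <- runif(n) < 0.6
    if (sum(tp) > n_gt) tp[which(tp)[seq_len(sum(tp) - n_gt)]] <- FALSE
    ap101 <- colonyscan:::ap_from_flags(scores[order(-scores)],
                                        tp[order(-scores)], n_gt)
    exact <- ap_exact_oracle(scores, tp, n_gt)
    expect_lt(abs(ap101 - exact), 0.01)
  }
})

test_that("AP is invariant to the input order of equal-score predictions", {
  gts <- gt_frame(c(0, 50), c(0, 0), c(10, 60), c(10, 10), c("petite", "petite"))
  preds <- detection_table(c(50, 0), c(0, 0), c(60, 10), c(10, 10),
                           "petite", c(0.8, 0.8))
  a1 <- average_precision(preds, gts, 0.5)
  a2 <- average_precision(preds[2:1, ], gts, 0.5)
  expect_equal(a1, a2)
})

test_that("the mAP report aggregates thresholds and classes", {
  gts <- gt_frame(c(0, 50, 100), c(0, 0, 0), c(20, 70, 120), c(20, 20, 20),
                  c("grande", "grande", "petite"))
  preds <- detection_table(gts$x_min, gts$y_min, gts$x_max, gts$y_max, gts$cls, 1.0)
  rep <- map_report(preds, gts)
  expect_equal(rep$map_50, 1.0)
  expect_equal(rep$map_75, 1.0)
  expect_equal(rep$map_50_95, 1.0)
  expect_true(all(rep$ap == 1.0))

  rep0 <- map_report(detection_table(), gts)
  expect_equal(rep0$map_50, 0)
  expect_true(all(precision_recall(match_detections(detection_table(), gts, 0.5))$recall == 0))
})

test_that("map_report pools matches per image when ids are present", {
  gts <- rbind(cbind(gt_frame(0, 0, 10, 10, "grande"), image_id = "a"),
               cbind(gt_frame(0, 0, 10, 10, "grande"), image_id = "b"))
  # one detection per image at the same coordinates: must both be TPs
  preds <- detection_table(c(0, 0), c(0, 0), c(10, 10), c(10, 10),
                           c("grande", "grande"), c(0.9, 0.8))
  preds$image_id <- c("a", "b")
  rep <- map_report(preds, gts)
  expect_equal(unname(rep$ap["0.50", "grande"]), 1.0)
})

test_that("the resolution sweep reports identity at factor 1 and degrades petites first", {
  cfg <- small_config(seed = 19, colony_count_mean = 12)
  plates <- lapply(1:2, function(i) {
    c2 <- cfg; c2$seed <- cfg$seed + i
    simulate_plate(c2, paste0("sw_", i))
  })
  tab <- resolution_sweep(plates, c(1, 0.5), iou_threshold = 0.25)
  expect_setequal(unique(tab$factor), c(1, 0.5))
  r1 <- tab[tab$factor == 1, ]
  expect_true(all(r1$recall > 0.8, na.rm = TRUE))
  # petites (tiny at half scale on a small frame) lose more recall than grandes
  r05 <- tab[tab$factor == 0.5, ]
  expect_lte(r05$recall[r05$cls == "petite"], r05$recall[r05$cls == "grande"])
})

test_that("sweep factors below the image floor are skipped with a warning", {
  img <- plate_image(matrix(90, 60, 60), "tiny")
  plates <- list(list(image = img,
                      truth = data.frame(image_id = "tiny", x_min = 1, y_min = 1,
                                         x_max = 5, y_max = 5, cls = "grande")))
  expect_warning(tab <- resolution_sweep(plates, c(0.05), iou_threshold = 0.5),
                 "floor")
  expect_null(tab)
})
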