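# COCO-style detection scoring: greedy one-to-one IOU matching per class,
# precision/recall, 101-point interpolated average precision, mAP
# aggregates over IOU thresholds, and the resolution-robustness sweep.

MAP_THRESHOLDS <- seq(0.50, 0.95, by = 0.05)

#' Match detections to ground truth at an IOU threshold
#'
#' Within each class, detections are processed in descending score order
#' (ties by \code{x_min}); each detection matches the still-unmatched
#' ground truth of its class with the highest IOU, provided that IOU
#' reaches the threshold (a true positive), and is otherwise a false
#' positive. Ground truths are matched at most once; leftovers are false
#' negatives.
#'
#' @param preds Detection data frame.
#' @param gts Ground-truth data frame (box columns and \code{cls}) for the
#'   same image.
#' @param iou_threshold Matching threshold in (0, 1\].
#' @return List of class \code{match_result}: per class, the detection
#'   order, TP flags and matched ground-truth indices, plus TP/FP/FN
#'   counts and the threshold used.
#' @export
match_detections <- function(preds, gts, iou_threshold = 0.5) {
  validate_detections(preds)
  per_class <- lapply(COLONY_CLASSES, function(cl) {
    p <- preds[preds$cls == cl, , drop = FALSE]
    g <- gts[gts$cls == cl, , drop = FALSE]
    ord <- order(-p$score, p$x_min)
    p <- p[ord, , drop = FALSE]
    tp <- logical(nrow(p))
    matched_gt <- rep(NA_integer_, nrow(p))
    gt_taken <- logical(nrow(g))
    if (nrow(p) > 0L && nrow(g) > 0L) {
      iou <- iou_matrix(p[box_cols], g[box_cols])
      for (i in seq_len(nrow(p))) {
        free <- which(!gt_taken)
        if (length(free) == 0L) break
        j <- free[which.max(iou[i, free])]
        if (iou[i, j] >= iou_threshold) {
          tp[i] <- TRUE; matched_gt[i] <- j; gt_taken[j] <- TRUE
        }
      }
    }
    list(scores = p$score, tp = tp, matched_gt = matched_gt,
         TP = sum(tp), FP = sum(!tp), FN = sum(!gt_taken), n_gt = nrow(g))
  })
  names(per_class) <- COLONY_CLASSES
  structure(list(per_class = per_class, iou_threshold = iou_threshold),
            class = "match_result")
}

#' Precision and recall from a match result
#'
#' \code{precision = TP / (TP + FP)}, \code{recall = TP / (TP + FN)};
#' a 0/0 ratio is reported as \code{NA}.
#'
#' @param m A \code{match_result} from [match_detections()].
#' @return Data frame with one row per class: \code{cls, TP, FP, FN,
#'   precision, recall}.
#' @export
precision_recall <- function(m) {
  stopifnot(inherits(m, "match_result"))
  do.call(rbind, lapply(names(m$per_class), function(cl) {
    x <- m$per_class[[cl]]
    data.frame(cls = cl, TP = x$TP, FP = x$FP, FN = x$FN,
               precision = if (x$TP + x$FP > 0L) x$TP / (x$TP + x$FP) else NA_real_,
               recall = if (x$TP + x$FN > 0L) x$TP / (x$TP + x$FN) else NA_real_,
               stringsAsFactors = FALSE)
  }))
}

# 101-point interpolated AP from score-ordered TP flags: precision is made
# monotone from the right (ceiling interpolation) and sampled at recalls
# 0, 0.01, ..., 1.
ap_from_flags <- function(scores, tp, n_gt) {
  if (n_gt == 0L) return(NA_real_)
  if (length(tp) == 0L) return(0)
  cum_tp <- cumsum(tp); cum_fp <- cumsum(!tp)
  prec <- cum_tp / (cum_tp + cum_fp)
  rec <- cum_tp / n_gt
  prec_env <- rev(cummax(rev(prec)))
  rpts <- seq(0, 1, by = 0.01)
  idx <- findInterval(rpts, rec, left.open = TRUE) + 1L  # first rec >= r
  p <- ifelse(idx <= length(rec), prec_env[pmin(idx, length(rec))], 0)
  mean(p)
}

#' Average precision per class at one IOU threshold
#'
#' Area under the precision-recall curve swept over the prediction scores,
#' with the COCO conventions: monotone (ceiling) interpolation of precision
#' and integration over 101 evenly spaced recall points. Classes with no
#' ground truth get \code{NA}.
#'
#' @inheritParams match_detections
#' @return Named numeric vector of AP per class.
#' @export
average_precision <- function(preds, gts, iou_threshold = 0.5) {
  m <- match_detections(preds, gts, iou_threshold)
  vapply(m$per_class, function(x) ap_from_flags(x$scores, x$tp, x$n_gt),
         numeric(1L))
}

#' Full COCO-style evaluation report
#'
#' AP per class at each IOU threshold 0.50, 0.55, ..., 0.95; class means at
#' 0.5 and 0.75; the grand mean over thresholds and classes
#' (mAP@\[0.5:0.95\]); and per-class precision/recall at IOU 0.5 with all
#' predictions retained (no score cut; apply one upstream if wanted).
#'
#' @param preds Detection data frame (may span several images if both
#'   tables carry a shared \code{image_id} column).
#' @param gts Ground-truth data frame.
#' @return List of class \code{eval_report}: \code{ap} (threshold x class
#'   matrix), \code{map_50}, \code{map_75}, \code{map_50_95},
#'   \code{pr} (precision/recall table at 0.5).
#' @export
map_report <- function(preds, gts) {
  by_image <- "image_id" %in% names(preds) && "image_id" %in% names(gts)
  eval_at <- function(thr) {
    if (!by_image) {
      m <- match_detections(preds, gts, thr)
      return(m)
    }
    # pool per-image matches: matching must never cross images
    ids <- union(unique(preds$image_id), unique(gts$image_id))
    parts <- lapply(ids, function(id) {
      match_detections(preds[preds$image_id == id, , drop = FALSE],
                       gts[gts$image_id == id, , drop = FALSE], thr)
    })
    pooled <- lapply(COLONY_CLASSES, function(cl) {
      scores <- unlist(lapply(parts, function(m) m$per_class[[cl]]$scores))
      tp <- unlist(lapply(parts, function(m) m$per_class[[cl]]$tp))
      ord <- order(-scores)
      list(scores = scores[ord], tp = tp[ord],
           TP = sum(tp), FP = sum(!tp),
           FN = sum(vapply(parts, function(m) m$per_class[[cl]]$FN, 0L)),
           n_gt = sum(vapply(parts, function(m) m$per_class[[cl]]$n_gt, 0L)))
    })
    names(pooled) <- COLONY_CLASSES
    structure(list(per_class = pooled, iou_threshold = thr), class = "match_result")
  }
  ap <- t(vapply(MAP_THRESHOLDS, function(thr) {
    m <- eval_at(thr)
    vapply(m$per_class, function(x) ap_from_flags(x$scores, x$tp, x$n_gt), numeric(1L))
  }, numeric(length(COLONY_CLASSES))))
  rownames(ap) <- sprintf("%.2f", MAP_THRESHOLDS)
  colnames(ap) <- COLONY_CLASSES
  structure(list(
    ap = ap,
    map_50 = mean(ap["0.50", ], na.rm = TRUE),
    map_75 = mean(ap["0.75", ], na.rm = TRUE),
    map_50_95 = mean(ap, na.rm = TRUE),
    pr = precision_recall(eval_at(0.5))
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("mAP@[0.5:0.95]: %.3f   mAP@0.5: %.3f   mAP@0.75: %.3f\n",
              x$map_50_95, x$map_50, x$map_75))
  cat("Precision/recall at IOU 0.5:\n")
  print(x$pr, row.names = FALSE)
  invisible(x)
}

#' Resolution-robustness sweep
#'
#' Downscales a batch of synthetic plates (images and ground-truth boxes)
#' by each factor, reruns the detector, and reports pooled per-class
#' precision and recall at IOU 0.5 together with the mean absolute
#' Petite-frequency error against the generator truth. Smaller colony
#' classes are expected to vanish first as resolution drops.
#'
#' @param plates List of [simulate_plate()] results (or any list with
#'   \code{image} and \code{truth} elements).
#' @param factors Scale factors in (0, 1\]; factors shrinking the image
#'   below 8 x 8 px are skipped with a warning.
#' @param detector Function \code{(plate_image) -> detections}; defaults to
#'   the classical pipeline.
#' @param iou_threshold Matching threshold for scoring (default 0.5).
#' @return Data frame with one row per (factor, class):
#'   \code{factor, cls, TP, FP, FN, precision, recall, mean_freq_error}.
#' @export
resolution_sweep <- function(plates, factors,
                             detector = function(img) detect_colonies(img),
                             iou_threshold = 0.5) {
  stopifnot(all(factors > 0), all(factors <= 1))
  rows <- list()
  for (f in sort(factors, decreasing = TRUE)) {
    ok <- vapply(plates, function(p) {
      round(p$image$width * f) >= 8L && round(p$image$height * f) >= 8L
    }, logical(1L))
    if (!all(ok)) {
      warning("skipping factor ", f, ": image would fall below the 8 x 8 px floor")
      next
    }
    counts <- list(grande = c(TP = 0L, FP = 0L, FN = 0L),
                   petite = c(TP = 0L, FP = 0L, FN = 0L))
    ferr <- numeric(0)
    for (p in plates) {
      img <- if (f == 1) p$image else downscale_plate(p$image, f)
      truth <- scale_boxes(p$truth, f)
      dets <- detector(img)
      m <- match_detections(dets, truth, iou_threshold)
      for (cl in COLONY_CLASSES) {
        x <- m$per_class[[cl]]
        counts[[cl]] <- counts[[cl]] + c(TP = x$TP, FP = x$FP, FN = x$FN)
      }
      true_k <- nrow(truth)
      if (true_k > 0L) {
        p_true <- sum(truth$cls == "petite") / true_k
        p_hat <- if (nrow(dets) > 0L) sum(dets$cls == "petite") / nrow(dets) else NA_real_
        if (!is.na(p_hat)) ferr <- c(ferr, abs(p_hat - p_true))
      }
    }
    for (cl in COLONY_CLASSES) {
      ct <- counts[[cl]]
      rows[[length(rows) + 1L]] <- data.frame(
        factor = f, cls = cl, TP = ct[["TP"]], FP = ct[["FP"]], FN = ct[["FN"]],
        precision = if (ct[["TP"]] + ct[["FP"]] > 0L) ct[["TP"]] / (ct[["TP"]] + ct[["FP"]]) else NA_real_,
        recall = if (ct[["TP"]] + ct[["FN"]] > 0L) ct[["TP"]] / (ct[["TP"]] + ct[["FN"]]) else NA_real_,
        mean_freq_error = if (length(ferr) > 0L) mean(ferr) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
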