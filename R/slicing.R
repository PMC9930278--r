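# Sliced inference: slice-size computation, sliding-window tiling, a
# pluggable backend contract, per-slice suppression and the global greedy
# non-maximal merging (NMM) that fuses duplicate detections from
# overlapping windows.
#
# Backend contract: a backend is a function(region, window) where `region`
# is a plate_image cropped to the window and `window` is the corresponding
# slice_window; it returns a detection table in region-local coordinates
# with scores in [0, 1]. Classical, oracle and learned detectors are
# interchangeable behind this contract.

TRAIN_SLICE_PX <- 512L
TRAIN_IMAGE_SIZE <- c(2376L, 2288L)

#' Slicing parameters
#'
#' @param S_A Relative slice area: slice area divided by whole-image area.
#'   The default is the training convention \code{(512 * 512) / (2376 *
#'   2288)}, so an image at the training resolution yields 512 px slices.
#' @param GD_t Typical Grande colony diameter in the training data, px.
#'   Used only by the \code{grande_diameter} mode; it is a recorded
#'   constant of this package (default 60), not a published value.
#' @param GD_I Typical Grande diameter in the user's images, px; required
#'   by the \code{grande_diameter} mode.
#' @param overlap_ratio Fractional overlap between adjacent windows in
#'   \[0, 0.9\] (default 0.2): any object smaller than \code{S *
#'   overlap_ratio} appears whole in at least one window.
#' @param slice_px Fixed slice size for \code{mode = "fixed"}.
#' @param mode How the slice size is computed: \code{"auto_area"} from the
#'   image-resolution equation, \code{"grande_diameter"} from the colony
#'   size ratio, or \code{"fixed"}.
#' @return List of class \code{slicing_params}.
#' @export
slicing_params <- function(S_A = (512 * 512) / (2376 * 2288),
                           GD_t = 60, GD_I = NA_real_,
                           overlap_ratio = 0.2,
                           slice_px = TRAIN_SLICE_PX,
                           mode = c("auto_area", "grande_diameter", "fixed")) {
  mode <- match.arg(mode)
  if (!(S_A > 0 && S_A <= 1)) stop("S_A must lie in (0, 1]")
  if (GD_t <= 0) stop("GD_t must be positive")
  if (overlap_ratio < 0 || overlap_ratio > 0.9) stop("overlap_ratio must lie in [0, 0.9]")
  structure(list(S_A = S_A, GD_t = GD_t, GD_I = GD_I,
                 overlap_ratio = overlap_ratio, slice_px = as.integer(slice_px),
                 mode = mode),
            class = "slicing_params")
}

#' Non-maximal merging parameters
#'
#' Detections with confidence at or above \code{score_threshold} are
#' eligible; same-class detections overlapping by more than
#' \code{ios_threshold} (intersection over smaller area) are fused into a
#' union box carrying the maximum member score.
#'
#' @param score_threshold Merge/report eligibility floor (default 0.6).
#' @param ios_threshold IOS above which detections merge (default 0.5).
#' @param class_agnostic If \code{TRUE}, merge across class labels.
#' @return List of class \code{nmm_params}.
#' @export
nmm_params <- function(score_threshold = 0.6, ios_threshold = 0.5,
                       class_agnostic = FALSE) {
  if (score_threshold < 0 || score_threshold > 1) stop("score_threshold must lie in [0, 1]")
  if (ios_threshold < 0 || ios_threshold > 1) stop("ios_threshold must lie in [0, 1]")
  structure(list(score_threshold = score_threshold,
                 ios_threshold = ios_threshold,
                 class_agnostic = isTRUE(class_agnostic)),
            class = "nmm_params")
}

#' Slice size from the image-resolution equation
#'
#' \code{S = sqrt(I_w * I_H * S_A)}, rounded to the nearest pixel and
#' clamped to \[32, min(I_w, I_H)\]. With the default relative area an
#' image at the 2376 x 2288 training resolution yields 512 px slices;
#' halving both dimensions halves the slice size, keeping colony size
#' relative to the slice constant.
#'
#' @param I_w,I_H Image width and height in px.
#' @param S_A Relative slice area in (0, 1].
#' @return Integer slice side length in px.
#' @export
compute_slice_size <- function(I_w, I_H, S_A = slicing_params()$S_A) {
  if (I_w < 1 || I_H < 1) stop("image dimensions must be at least 1 px")
  if (!(S_A > 0 && S_A <= 1)) stop("S_A must lie in (0, 1]")
  s <- round(sqrt(I_w * I_H * S_A))
  as.integer(min(max(s, 32), min(I_w, I_H)))
}

#' Slice size from the Grande-diameter equation
#'
#' \code{S = (GD_I / GD_t) * 512}: enforces the same Grande-colony to
#' slice-size ratio as the training data when colony sizes differ grossly
#' from the imaging conventions the area equation assumes.
#'
#' @param GD_I Typical Grande diameter in the input images, px.
#' @param GD_t Typical Grande diameter in the training data, px.
#' @return Integer slice side length in px (rounded).
#' @export
compute_slice_size_from_diameter <- function(GD_I, GD_t = slicing_params()$GD_t) {
  if (GD_I <= 0 || GD_t <= 0) stop("Grande diameters must be positive")
  as.integer(round(GD_I / GD_t * TRAIN_SLICE_PX))
}

#' Sliding-window tiling of an image
#'
#' Lays square windows of side \code{S} on a grid with stride
#' \code{round(S * (1 - overlap_ratio))} starting at (0, 0); a window that
#' would exceed the image boundary is shifted back to end exactly at the
#' boundary (no padding). Every pixel is covered by at least one window and
#' windows are unique.
#'
#' @param width,height Image dimensions in px.
#' @param S Window side length; must not exceed either dimension.
#' @param overlap_ratio Fractional overlap in \[0, 0.9\].
#' @return Data frame with columns \code{x0, y0, w, h} (0-based offsets).
#' @export
tile_windows <- function(width, height, S, overlap_ratio = 0.2) {
  if (S > min(width, height)) {
    stop("slice size ", S, " exceeds an image dimension (", width, " x ", height, ")")
  }
  stride <- max(1L, round(S * (1 - overlap_ratio)))
  starts <- function(L) {
    if (S >= L) return(0L)
    s <- seq(0L, L - S, by = stride)
    if (s[length(s)] + S < L) s <- c(s, L - S)
    unique(s)
  }
  g <- expand.grid(x0 = starts(width), y0 = starts(height))
  data.frame(x0 = g$x0, y0 = g$y0, w = S, h = S)
}

# Shared merge engine for NMM (overlap = IOS) and the per-slice NMS variant
# (overlap = IOU). Greedy passes run until a global fixed point: merging
# enlarges cluster boxes, which can make two previously ineligible clusters
# overlap, so passes repeat until no same-class pair in the output exceeds
# the overlap threshold (the transitive-closure semantics).
merge_greedy <- function(dets, overlap, threshold, score_threshold, class_agnostic) {
  validate_detections(dets)
  d <- dets[dets$score >= score_threshold, , drop = FALSE]
  if (nrow(d) == 0L) return(empty_detections())
  repeat {
    merged <- merge_greedy_pass(d, overlap, threshold, class_agnostic)
    if (nrow(merged) == nrow(d)) break
    d <- merged
  }
  merged
}

# One merge pass: detections are visited in descending score order (ties by
# x_min, y_min); each unvisited detection seeds a cluster that greedily
# absorbs, breadth-first, every detection reachable through the pairwise
# eligibility relation (same class unless class-agnostic, overlap above the
# threshold) evaluated on the pass-input boxes. Evaluating eligibility on
# the input boxes rather than the growing union keeps the partition
# order-independent (the connected components of the eligibility graph);
# union-induced new overlaps are handled by the outer pass iteration.
merge_greedy_pass <- function(d, overlap, threshold, class_agnostic) {
  d <- d[order(-d$score, d$x_min, d$y_min), , drop = FALSE]
  boxes <- as.matrix(d[box_cols])
  cls <- d$cls; score <- d$score
  n <- nrow(d)
  pair_overlap <- function(i, idx) {
    b <- boxes[i, ]
    w <- pmax(0, pmin(b[3L], boxes[idx, 3L]) - pmax(b[1L], boxes[idx, 1L]))
    h <- pmax(0, pmin(b[4L], boxes[idx, 4L]) - pmax(b[2L], boxes[idx, 2L]))
    inter <- w * h
    ab <- (b[3L] - b[1L]) * (b[4L] - b[2L])
    ao <- (boxes[idx, 3L] - boxes[idx, 1L]) * (boxes[idx, 4L] - boxes[idx, 2L])
    if (overlap == "ios") inter / pmin(ab, ao) else inter / (ab + ao - inter)
  }
  out <- list()
  alive <- rep(TRUE, n)
  while (any(alive)) {
    seed <- which(alive)[1L]
    alive[seed] <- FALSE
    members <- seed
    frontier <- seed
    while (length(frontier) > 0L) {
      nxt <- integer(0)
      for (i in frontier) {
        cand <- which(alive)
        if (!class_agnostic) cand <- cand[cls[cand] == cls[seed]]
        if (length(cand) == 0L) next
        absorb <- cand[pair_overlap(i, cand) > threshold]
        if (length(absorb) > 0L) {
          alive[absorb] <- FALSE
          nxt <- c(nxt, absorb)
        }
      }
      members <- c(members, nxt)
      frontier <- nxt
    }
    out[[length(out) + 1L]] <- list(
      box = c(min(boxes[members, 1L]), min(boxes[members, 2L]),
              max(boxes[members, 3L]), max(boxes[members, 4L])),
      cls = cls[seed], score = max(score[members]))
  }
  res <- detection_table(
    vapply(out, function(o) o$box[1L], 0), vapply(out, function(o) o$box[2L], 0),
    vapply(out, function(o) o$box[3L], 0), vapply(out, function(o) o$box[4L], 0),
    vapply(out, function(o) o$cls, ""), vapply(out, function(o) o$score, 0))
  res[order(-res$score, res$x_min, res$y_min), , drop = FALSE]
}

#' Greedy non-maximal merging of detections
#'
#' Unlike non-maximal suppression, overlapping same-class detections are
#' fused rather than discarded: detections below the confidence floor are
#' dropped, the rest are processed in descending score order, and each
#' cluster absorbs every remaining same-class detection whose intersection
#' over smaller area with the growing cluster box exceeds the IOS
#' threshold, until a fixed point. The merged box is the coordinate union
#' and the merged score the member maximum. The operation is idempotent.
#'
#' @param dets Detection data frame.
#' @param params An [nmm_params()].
#' @return Merged detection data frame, sorted by descending score.
#' @export
nmm <- function(dets, params = nmm_params()) {
  merge_greedy(dets, "ios", params$ios_threshold, params$score_threshold,
               params$class_agnostic)
}

#' Per-slice non-maximal suppression (merging variant)
#'
#' The within-slice cleanup applied before global merging: the same greedy
#' merge as [nmm()] but with intersection over union as the overlap
#' measure and no confidence floor, so redundant near-duplicate boxes
#' produced inside one slice are fused early.
#'
#' @param dets Detection data frame.
#' @param iou_threshold IOU above which same-class detections merge.
#' @return Detection data frame.
#' @export
nms <- function(dets, iou_threshold = 0.5) {
  merge_greedy(dets, "iou", iou_threshold, 0, FALSE)
}

crop_region <- function(image, win) {
  px <- image$pixels[(win$x0 + 1L):(win$x0 + win$w),
                     (win$y0 + 1L):(win$y0 + win$h), drop = FALSE]
  plate_image(px, paste0(image$image_id, "_slice_", win$x0, "_", win$y0))
}

#' Sliced inference with a pluggable detection backend
#'
#' Computes the slice size (per the slicing mode), tiles the image with
#' overlapping windows, runs the backend on every window, translates the
#' region-local detections by the window offsets, and merges everything
#' with global non-maximal merging. An image smaller than the slice size
#' degenerates to whole-image inference on a single window.
#'
#' @param image A [plate_image()].
#' @param backend A function \code{(region, window) -> detections} in
#'   region-local coordinates (see [classical_backend()],
#'   [oracle_backend()]).
#' @param slicing A [slicing_params()].
#' @param nmm_params An [nmm_params()].
#' @return Detection data frame in whole-image coordinates.
#' @export
infer_sliced <- function(image, backend, slicing = slicing_params(),
                         nmm_params = colonyscan::nmm_params()) {
  stopifnot(inherits(image, "plate_image"), is.function(backend))
  S <- switch(slicing$mode,
    auto_area = compute_slice_size(image$width, image$height, slicing$S_A),
    grande_diameter = {
      if (!is.finite(slicing$GD_I)) {
        stop("grande_diameter mode needs GD_I (typical Grande diameter in the input images)")
      }
      compute_slice_size_from_diameter(slicing$GD_I, slicing$GD_t)
    },
    fixed = slicing$slice_px)
  S <- min(S, image$width, image$height)
  wins <- tile_windows(image$width, image$height, S, slicing$overlap_ratio)
  all_dets <- vector("list", nrow(wins))
  for (i in seq_len(nrow(wins))) {
    win <- wins[i, ]
    region <- crop_region(image, win)
    local <- tryCatch(backend(region, win), error = function(e) {
      stop("backend failed on slice at offset (", win$x0, ", ", win$y0, "): ",
           conditionMessage(e))
    })
    validate_detections(local)
    if (nrow(local) > 0L) {
      if (any(local$x_min < 0 | local$y_min < 0 |
              local$x_max > win$w | local$y_max > win$h)) {
        stop("backend returned a box outside its slice at offset (",
             win$x0, ", ", win$y0, ")")
      }
      local <- nms(local, iou_threshold = 0.5)
      all_dets[[i]] <- shift_boxes(local, win$x0, win$y0)
    }
  }
  dets <- do.call(rbind, all_dets)
  if (is.null(dets)) return(empty_detections())
  nmm(dets, nmm_params)
}

#' Ground-truth oracle backend
#'
#' A reference backend for validating the slicing and merging machinery:
#' for each window it returns the ground-truth boxes clipped to the window
#' footprint (dropping boxes that miss it entirely) with score 1. Running
#' it through [infer_sliced()] must recover the ground truth whenever every
#' object fits inside at least one window.
#'
#' @param truth Ground-truth data frame with box columns and \code{cls}.
#' @return A backend function for [infer_sliced()].
#' @export
oracle_backend <- function(truth) {
  force(truth)
  function(region, window) {
    if (nrow(truth) == 0L) return(empty_detections())
    x0 <- window$x0; y0 <- window$y0
    cx_min <- pmax(truth$x_min, x0); cx_max <- pmin(truth$x_max, x0 + window$w)
    cy_min <- pmax(truth$y_min, y0); cy_max <- pmin(truth$y_max, y0 + window$h)
    keep <- cx_max > cx_min & cy_max > cy_min
    if (!any(keep)) return(empty_detections())
    detection_table(cx_min[keep] - x0, cy_min[keep] - y0,
                    cx_max[keep] - x0, cy_max[keep] - y0,
                    truth$cls[keep], score = 1.0)
  }
}
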