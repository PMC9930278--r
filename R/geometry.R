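# Axis-aligned boxes and overlap arithmetic shared by detection, merging and
# evaluation. Boxes are 0-based, half-open pixel intervals
# [x_min, x_max) x [y_min, y_max), origin at the top-left, x running along
# image columns. Coordinates are real-valued; rasterization happens only at
# rendering/export time.

#' Colony class labels
#'
#' The two colony phenotypes of the assay. Petite colonies (respiration
#' deficient) are smaller and more translucent than wild-type Grande
#' colonies. Serialized class names are always lower case.
#'
#' @format Character vector \code{c("grande", "petite")}.
#' @export
COLONY_CLASSES <- c("grande", "petite")

#' Construct a bounding box
#'
#' Boxes use the half-open pixel convention \code{[x_min, x_max) x
#' [y_min, y_max)} with a 0-based origin at the top-left corner, so
#' \code{box_area()} is exact for integer pixel boxes.
#'
#' @param x_min,y_min,x_max,y_max Box edges in pixels; \code{x_max > x_min}
#'   and \code{y_max > y_min} are required (strictly positive area).
#' @return Named numeric vector of length 4.
#' @examples
#' b <- bbox(0, 0, 10, 10)
#' box_area(b)  # 100
#' @export
bbox <- function(x_min, y_min, x_max, y_max) {
  b <- c(x_min = as.numeric(x_min), y_min = as.numeric(y_min),
         x_max = as.numeric(x_max), y_max = as.numeric(y_max))
  validate_bbox(b)
  b
}

validate_bbox <- function(b) {
  if (length(b) != 4L || any(!is.finite(b))) {
    stop("bounding box must be 4 finite numbers (x_min, y_min, x_max, y_max)")
  }
  if (b[[3L]] <= b[[1L]] || b[[4L]] <= b[[2L]]) {
    stop("degenerate bounding box: x_max must exceed x_min and y_max must exceed y_min")
  }
  invisible(b)
}

#' Box area in square pixels
#' @param b Box from [bbox()].
#' @return Numeric area, strictly positive for a valid box.
#' @export
box_area <- function(b) {
  validate_bbox(b)
  (b[[3L]] - b[[1L]]) * (b[[4L]] - b[[2L]])
}

intersection_area <- function(a, b) {
  w <- min(a[[3L]], b[[3L]]) - max(a[[1L]], b[[1L]])
  h <- min(a[[4L]], b[[4L]]) - max(a[[2L]], b[[2L]])
  if (w <= 0 || h <= 0) return(0)
  w * h
}

#' Intersection over union of two boxes
#'
#' The standard detection-matching overlap: intersection area divided by
#' union area. Returns 0 for disjoint boxes and 1 for identical ones.
#'
#' @param a,b Boxes from [bbox()].
#' @return Ratio in \[0, 1\].
#' @seealso [box_ios()] which normalizes by the smaller box instead.
#' @export
box_iou <- function(a, b) {
  validate_bbox(a); validate_bbox(b)
  inter <- intersection_area(a, b)
  inter / (box_area(a) + box_area(b) - inter)
}

#' Intersection over smaller area of two boxes
#'
#' Intersection area divided by the area of the smaller box. Symmetric,
#' equal to 1 whenever one box contains the other, and never smaller than
#' the IOU of the same pair. This is the overlap measure used by
#' non-maximal merging, where nested duplicate detections from overlapping
#' slices must count as full overlaps.
#'
#' @inheritParams box_iou
#' @return Ratio in \[0, 1\].
#' @export
box_ios <- function(a, b) {
  validate_bbox(a); validate_bbox(b)
  intersection_area(a, b) / min(box_area(a), box_area(b))
}

#' Smallest box containing two boxes
#'
#' Coordinate-wise min/max hull; the box-combination rule used when
#' non-maximal merging fuses overlapping detections.
#'
#' @inheritParams box_iou
#' @return A box from [bbox()].
#' @export
box_union <- function(a, b) {
  validate_bbox(a); validate_bbox(b)
  bbox(min(a[[1L]], b[[1L]]), min(a[[2L]], b[[2L]]),
       max(a[[3L]], b[[3L]]), max(a[[4L]], b[[4L]]))
}

# Pairwise IOU between the m boxes in A and n boxes in B, given as m x 4 and
# n x 4 matrices (x_min, y_min, x_max, y_max columns). Vectorized for the
# matcher; zero-area rows are rejected.
iou_matrix <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) == 0L || nrow(B) == 0L) {
    return(matrix(numeric(0), nrow(A), nrow(B)))
  }
  areaA <- (A[, 3L] - A[, 1L]) * (A[, 4L] - A[, 2L])
  areaB <- (B[, 3L] - B[, 1L]) * (B[, 4L] - B[, 2L])
  if (any(areaA <= 0) || any(areaB <= 0)) stop("degenerate box in IOU matrix input")
  ix <- pmax(0, outer(A[, 3L], B[, 3L], pmin) - outer(A[, 1L], B[, 1L], pmax))
  iy <- pmax(0, outer(A[, 4L], B[, 4L], pmin) - outer(A[, 2L], B[, 2L], pmax))
  inter <- ix * iy
  inter / (outer(areaA, areaB, "+") - inter)
}

box_cols <- c("x_min", "y_min", "x_max", "y_max")

#' Build a detection table
#'
#' Detections are plain data frames with one row per detected colony:
#' box edges (half-open pixel coordinates), class label and confidence
#' score. This is the unit that flows through sliced inference, merging,
#' frequency computation and evaluation.
#'
#' @param x_min,y_min,x_max,y_max Numeric vectors of box edges.
#' @param cls Character vector of class labels, each \code{"grande"} or
#'   \code{"petite"}.
#' @param score Confidence scores in \[0, 1\]; recycled if length 1.
#' @return A \code{data.frame} with columns \code{x_min, y_min, x_max,
#'   y_max, cls, score}.
#' @export
detection_table <- function(x_min = numeric(), y_min = numeric(),
                            x_max = numeric(), y_max = numeric(),
                            cls = character(), score = numeric()) {
  n <- length(x_min)
  if (n > 0L && length(score) == 1L) score <- rep(score, n)
  d <- data.frame(x_min = as.numeric(x_min), y_min = as.numeric(y_min),
                  x_max = as.numeric(x_max), y_max = as.numeric(y_max),
                  cls = as.character(cls), score = as.numeric(score),
                  stringsAsFactors = FALSE)
  validate_detections(d)
  d
}

validate_detections <- function(d) {
  stopifnot(is.data.frame(d), all(c(box_cols, "cls", "score") %in% names(d)))
  if (nrow(d) == 0L) return(invisible(d))
  if (any(d$x_max <= d$x_min) || any(d$y_max <= d$y_min)) {
    stop("detection table contains a degenerate box")
  }
  bad <- setdiff(unique(d$cls), COLONY_CLASSES)
  if (length(bad) > 0L) {
    stop("unknown colony class: ", paste(bad, collapse = ", "),
         " (classes are closed to 'grande' and 'petite')")
  }
  if (any(d$score < 0 | d$score > 1)) stop("detection scores must lie in [0, 1]")
  invisible(d)
}

empty_detections <- function() detection_table()

#' Rescale box coordinates
#'
#' Multiplies all box edges by a scale factor, e.g. to carry ground-truth
#' annotations along with a [downscale_plate()] resize.
#'
#' @param boxes Data frame with \code{x_min, y_min, x_max, y_max} columns
#'   (extra columns pass through).
#' @param factor Positive scale factor.
#' @return The data frame with scaled box columns.
#' @export
scale_boxes <- function(boxes, factor) {
  stopifnot(is.data.frame(boxes), is.numeric(factor), factor > 0)
  boxes[box_cols] <- boxes[box_cols] * factor
  boxes
}

shift_boxes <- function(boxes, dx, dy) {
  boxes$x_min <- boxes$x_min + dx; boxes$x_max <- boxes$x_max + dx
  boxes$y_min <- boxes$y_min + dy; boxes$y_max <- boxes$y_max + dy
  boxes
}
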