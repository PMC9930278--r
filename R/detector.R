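# The classical (semi-supervised) colony detector: circular-Hough plate
# localization, multi-level Otsu thresholding of the masked agar disc,
# watershed splitting of touching colonies on the distance transform,
# size/eccentricity filtering and unsupervised two-class classification of
# regions by size and intensity.

#' Region filtering parameters
#'
#' @param min_area,max_area Inclusive colony area bounds in px^2
#'   (defaults 40 and 6000).
#' @param max_eccentricity Regions with best-fit-ellipse eccentricity at or
#'   above this value are rejected (default 0.9); removes arc-like
#'   refraction artifacts.
#' @param rim_margin Fraction of the plate radius excluded at the rim
#'   (default 0.03), masking the refraction zone near the dish wall.
#' @return List of class \code{filter_params}.
#' @export
filter_params <- function(min_area = 40, max_area = 6000,
                          max_eccentricity = 0.9, rim_margin = 0.03) {
  if (!(min_area > 0 && min_area < max_area)) stop("need 0 < min_area < max_area")
  if (!(max_eccentricity > 0 && max_eccentricity < 1)) {
    stop("max_eccentricity must lie in (0, 1)")
  }
  if (rim_margin < 0 || rim_margin >= 1) stop("rim_margin must lie in [0, 1)")
  structure(list(min_area = min_area, max_area = max_area,
                 max_eccentricity = max_eccentricity, rim_margin = rim_margin),
            class = "filter_params")
}

#' Region classification parameters
#'
#' @param method \code{"clustering"} (average-linkage agglomerative
#'   clustering of standardized area and mean intensity, cut at two
#'   clusters) or \code{"size_threshold"} (area above the threshold is
#'   Grande).
#' @param size_threshold Area cut in px^2 for the threshold method and the
#'   clustering fallback (default 1000).
#' @param min_regions_for_clustering Below this region count clustering
#'   falls back to the size threshold (default 4).
#' @return List of class \code{classifier_params}.
#' @export
classifier_params <- function(method = c("clustering", "size_threshold"),
                              size_threshold = 1000,
                              min_regions_for_clustering = 4L) {
  method <- match.arg(method)
  if (size_threshold <= 0) stop("size_threshold must be positive")
  structure(list(method = method, size_threshold = size_threshold,
                 min_regions_for_clustering = as.integer(min_regions_for_clustering)),
            class = "classifier_params")
}

plate_circle <- function(cx, cy, r) {
  if (r <= 0) stop("plate radius must be positive")
  structure(list(cx = cx, cy = cy, r = r), class = "plate_circle")
}

#' @export
print.plate_circle <- function(x, ...) {
  cat(sprintf("<plate_circle center (%.1f, %.1f), radius %.1f px>\n", x$cx, x$cy, x$r))
  invisible(x)
}

# Sobel gradient magnitude of a [0, 1] intensity matrix.
sobel_magnitude <- function(px) {
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  gx <- as.matrix(EBImage::filter2(EBImage::Image(px), kx))
  gy <- as.matrix(EBImage::filter2(EBImage::Image(px), t(kx)))
  sqrt(gx^2 + gy^2)
}

#' Locate the petri dish with a circular Hough transform
#'
#' Runs an accumulator-based circular Hough transform on the Sobel edge map
#' (computed on a downsampled copy for speed), sweeping candidate radii over
#' 0.30-0.49 of the smaller image dimension. If no circle collects enough
#' votes -- e.g. on a blank image -- the inscribed circle (centered, radius
#' 0.48 of the smaller dimension) is returned with a warning.
#'
#' @param image A [plate_image()] of at least 100 x 100 px.
#' @return A \code{plate_circle} with center (\code{cx}, \code{cy}) and
#'   radius \code{r} in full-resolution pixels.
#' @export
locate_plate <- function(image) {
  stopifnot(inherits(image, "plate_image"))
  if (image$width < 100L || image$height < 100L) {
    stop("plate localization needs an image of at least 100 x 100 px")
  }
  target <- 256
  ds <- min(1, target / min(image$width, image$height))
  px <- if (ds < 1) {
    as.matrix(EBImage::resize(as_ebimage(image),
                              w = round(image$width * ds),
                              h = round(image$height * ds),
                              filter = "bilinear"))
  } else {
    image$pixels / 255
  }
  W <- nrow(px); H <- ncol(px); m <- min(W, H)

  grad <- sobel_magnitude(px)
  # absolute edge floor: the felt/agar step (~0.3 of full scale) gives a
  # Sobel response well above this; pure noise stays below it
  edges <- which(grad > 0.3, arr.ind = TRUE)
  n_theta <- 90L
  best <- list(votes = 0, cx = NA, cy = NA, r = NA)
  if (nrow(edges) > 20L) {
    if (nrow(edges) > 4000L) {
      edges <- edges[seq(1L, nrow(edges), length.out = 4000L), , drop = FALSE]
    }
    theta <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
    ct <- cos(theta); st <- sin(theta)
    radii <- seq(round(0.30 * m), round(0.49 * m))
    ex <- edges[, 1L]; ey <- edges[, 2L]
    for (r in radii) {
      axs <- round(outer(ex, r * ct, "-"))
      ays <- round(outer(ey, r * st, "-"))
      ok <- axs >= 1L & axs <= W & ays >= 1L & ays <= H
      idx <- (ays[ok] - 1L) * W + axs[ok]
      acc <- tabulate(idx, nbins = W * H)
      v <- max(acc)
      if (v > best$votes) {
        i <- which.max(acc)
        best <- list(votes = v, cx = (i - 1L) %% W + 1L,
                     cy = (i - 1L) %/% W + 1L, r = r)
      }
    }
  }
  if (is.na(best$cx) || best$votes < 0.2 * n_theta) {
    warning("no circle above the Hough accumulator floor; falling back to the inscribed circle")
    return(plate_circle(image$width / 2, image$height / 2,
                        0.48 * min(image$width, image$height)))
  }
  plate_circle((best$cx - 0.5) / ds, (best$cy - 0.5) / ds, best$r / ds)
}

# Exhaustive multi-level Otsu on a 256-bin histogram: maximizes the
# between-class variance over (levels - 1) thresholds. With three classes
# the lower threshold separates the agar from all colonies, including the
# translucent Petites that a two-class Otsu swallows into the background
# when their pixel mass is small.
otsu_thresholds <- function(values, levels = 3L) {
  stopifnot(levels %in% c(2L, 3L))
  h <- tabulate(pmin(255L, pmax(0L, floor(values))) + 1L, 256L)
  p <- h / sum(h)
  iv <- 0:255
  csP <- cumsum(p); csM <- cumsum(p * iv)
  total <- csM[256L]
  cls_stat <- function(lo, hi) { # classes over bins (lo, hi]
    w <- csP[hi] - if (lo > 0L) csP[lo] else 0
    msum <- csM[hi] - if (lo > 0L) csM[lo] else 0
    c(w, msum)
  }
  if (levels == 2L) {
    best <- c(-Inf, 0L)
    for (a in 1:255) {
      s0 <- cls_stat(0L, a); s1 <- cls_stat(a, 256L)
      if (s0[1L] <= 0 || s1[1L] <= 0) next
      sb <- s0[2L]^2 / s0[1L] + s1[2L]^2 / s1[1L]
      if (sb > best[1L]) best <- c(sb, a)
    }
    return(best[2L] - 1)
  }
  best <- c(-Inf, 0L, 0L)
  for (a in 1:254) {
    s0 <- cls_stat(0L, a)
    if (s0[1L] <= 0) next
    base <- s0[2L]^2 / s0[1L]
    for (b in (a + 1):255) {
      s1 <- cls_stat(a, b); s2 <- cls_stat(b, 256L)
      if (s1[1L] <= 0 || s2[1L] <= 0) next
      sb <- base + s1[2L]^2 / s1[1L] + s2[2L]^2 / s2[1L]
      if (sb > best[1L]) best <- c(sb, a, b)
    }
  }
  best[2:3] - 1
}

#' Segment colonies inside the plate
#'
#' Masks the image to the plate disc shrunk by the rim margin, separates
#' colony foreground from agar with a multi-level Otsu threshold on the
#' masked intensity histogram (the lowest threshold clearing a robust noise
#' floor of median + 6 MAD is used, so translucent Petites are kept and a
#' blank plate yields an empty foreground), and splits touching colonies by
#' watershed on the negated distance transform. Marker separation follows
#' the minimum colony scale \code{0.8 * sqrt(min_area / pi)}.
#'
#' @param image A [plate_image()].
#' @param plate A \code{plate_circle} from [locate_plate()].
#' @param params A [filter_params()].
#' @return Integer label matrix (width x height); 0 is background, regions
#'   are labelled contiguously from 1.
#' @export
segment_colonies <- function(image, plate = locate_plate(image),
                             params = filter_params()) {
  stopifnot(inherits(image, "plate_image"), inherits(plate, "plate_circle"))
  W <- image$width; H <- image$height
  xs <- matrix((seq_len(W) - 0.5) - plate$cx, W, H)
  ys <- matrix(rep((seq_len(H) - 0.5) - plate$cy, each = W), W, H)
  mask <- xs^2 + ys^2 <= ((1 - params$rim_margin) * plate$r)^2
  empty <- matrix(0L, W, H)
  if (!any(mask)) return(empty)

  v <- image$pixels[mask]
  thr <- otsu_thresholds(v, levels = 3L)
  floor_t <- stats::median(v) + 6 * stats::mad(v)
  thr <- thr[thr >= floor_t]
  if (length(thr) == 0L) return(empty)
  fg <- image$pixels > thr[1L] & mask
  if (!any(fg)) return(empty)

  dm <- EBImage::distmap(EBImage::Image(fg * 1))
  ext <- max(1L, round(0.8 * sqrt(params$min_area / pi)))
  labels <- EBImage::watershed(dm, tolerance = 1, ext = ext)
  labels <- matrix(as.integer(EBImage::imageData(labels)), W, H)
  # contiguous labels from 1
  u <- sort(unique(labels[labels > 0L]))
  if (length(u) > 0L && !identical(u, seq_along(u))) {
    remap <- integer(max(u)); remap[u] <- seq_along(u)
    pos <- labels > 0L
    labels[pos] <- remap[labels[pos]]
  }
  labels
}

#' Extract per-region features
#'
#' For each labelled region: pixel-count area, eccentricity of the best-fit
#' ellipse from central second moments (0 for a circle, approaching 1 for a
#' line), mean grayscale intensity, and the tight bounding box in half-open
#' pixel coordinates.
#'
#' @param label_map Integer label matrix from [segment_colonies()].
#' @param image The [plate_image()] the labels were computed on.
#' @return Data frame with columns \code{region_id, x_min, y_min, x_max,
#'   y_max, area, eccentricity, mean_intensity}.
#' @export
extract_features <- function(label_map, image) {
  stopifnot(is.matrix(label_map), inherits(image, "plate_image"),
            all(dim(label_map) == c(image$width, image$height)))
  empty <- data.frame(region_id = integer(), x_min = numeric(), y_min = numeric(),
                      x_max = numeric(), y_max = numeric(), area = numeric(),
                      eccentricity = numeric(), mean_intensity = numeric(),
                      stringsAsFactors = FALSE)
  if (!any(label_map > 0L)) return(empty)
  n <- max(label_map)
  mom <- EBImage::computeFeatures.moment(label_map)
  ecc <- mom[, "m.eccentricity"]
  ecc[!is.finite(ecc)] <- 0  # single-pixel regions have undefined moments
  pos <- which(label_map > 0L, arr.ind = TRUE)
  lab <- label_map[label_map > 0L]
  fl <- factor(lab, levels = seq_len(n))
  area <- as.numeric(tabulate(lab, nbins = n))
  xmin <- tapply(pos[, 1L], fl, min); xmax <- tapply(pos[, 1L], fl, max)
  ymin <- tapply(pos[, 2L], fl, min); ymax <- tapply(pos[, 2L], fl, max)
  meani <- tapply(image$pixels[label_map > 0L], fl, mean)
  data.frame(region_id = seq_len(n),
             x_min = as.numeric(xmin) - 1, y_min = as.numeric(ymin) - 1,
             x_max = as.numeric(xmax), y_max = as.numeric(ymax),
             area = area, eccentricity = as.numeric(ecc),
             mean_intensity = as.numeric(meani), stringsAsFactors = FALSE)
}

#' Filter regions by area and eccentricity
#'
#' Keeps regions with \code{min_area <= area <= max_area} (bounds
#' inclusive) and \code{eccentricity < max_eccentricity}; input order is
#' preserved. Widening the area interval can only grow the result.
#'
#' @param features Data frame from [extract_features()].
#' @param params A [filter_params()].
#' @return The surviving rows of \code{features}.
#' @export
filter_regions <- function(features, params = filter_params()) {
  keep <- features$area >= params$min_area & features$area <= params$max_area &
    features$eccentricity < params$max_eccentricity
  features[keep, , drop = FALSE]
}

#' Classify regions as Grande or Petite
#'
#' The clustering method standardizes (area, mean intensity) to zero mean
#' and unit variance across the plate's regions, runs average-linkage
#' agglomerative clustering with Euclidean distance, cuts at two clusters,
#' and names the cluster with the larger mean area Grande. With fewer than
#' \code{min_regions_for_clustering} regions, or when either feature has
#' zero variance, it falls back to the size threshold (area above
#' \code{size_threshold} px^2 is Grande).
#'
#' @param features Filtered data frame from [filter_regions()].
#' @param params A [classifier_params()].
#' @return \code{features} with an added \code{cls} column.
#' @export
classify_regions <- function(features, params = classifier_params()) {
  if (nrow(features) == 0L) {
    features$cls <- character(0)
    return(features)
  }
  use_clustering <- params$method == "clustering" &&
    nrow(features) >= params$min_regions_for_clustering &&
    stats::sd(features$area) > 0 && stats::sd(features$mean_intensity) > 0
  if (!use_clustering) {
    features$cls <- ifelse(features$area > params$size_threshold, "grande", "petite")
    return(features)
  }
  ord <- order(features$region_id)  # fixed row order for deterministic linkage
  f <- features[ord, , drop = FALSE]
  z <- scale(cbind(f$area, f$mean_intensity))
  cl <- stats::cutree(stats::hclust(stats::dist(z), method = "average"), k = 2L)
  mean_area <- tapply(f$area, cl, mean)
  grande_cluster <- as.integer(names(mean_area)[which.max(mean_area)])
  f$cls <- ifelse(cl == grande_cluster, "grande", "petite")
  # restore the caller's row order
  res <- f[match(features$region_id, f$region_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Run the full classical detection pipeline on one plate image
#'
#' Plate localization, segmentation, feature extraction, filtering and
#' classification composed end to end. Classical detections carry no
#' calibrated confidence and are emitted with score 1.0 so downstream
#' merging thresholds do not silently drop them.
#'
#' @param image A [plate_image()].
#' @param filter_params A [filter_params()].
#' @param classifier_params A [classifier_params()].
#' @param plate Optional precomputed \code{plate_circle}.
#' @param verbose Log per-stage region counts to stderr.
#' @return Detection data frame (see [detection_table()]).
#' @export
detect_colonies <- function(image, filter_params = colonyscan::filter_params(),
                            classifier_params = colonyscan::classifier_params(),
                            plate = NULL, verbose = FALSE) {
  if (is.null(plate)) plate <- locate_plate(image)
  labels <- segment_colonies(image, plate, filter_params)
  feats <- extract_features(labels, image)
  kept <- filter_regions(feats, filter_params)
  classified <- classify_regions(kept, classifier_params)
  if (verbose) {
    message(sprintf("[%s] regions segmented: %d, after filtering: %d",
                    image$image_id, nrow(feats), nrow(kept)))
  }
  if (nrow(classified) == 0L) return(empty_detections())
  detection_table(classified$x_min, classified$y_min,
                  classified$x_max, classified$y_max,
                  classified$cls, score = 1.0)
}

#' Classical detector as a sliced-inference backend
#'
#' Wraps the segmentation/classification stages (without plate
#' localization, which is meaningless on a slice: the whole region is
#' treated as in-plate) into the backend contract of [infer_sliced()].
#'
#' @inheritParams detect_colonies
#' @return A function \code{(region, window) -> detections} in region-local
#'   coordinates.
#' @export
classical_backend <- function(filter_params = colonyscan::filter_params(),
                              classifier_params = colonyscan::classifier_params()) {
  force(filter_params); force(classifier_params)
  function(region, window) {
    big_r <- 4 * max(region$width, region$height)  # disc covering the region
    fake_plate <- plate_circle(region$width / 2, region$height / 2, big_r)
    fp <- filter_params
    fp$rim_margin <- 0  # no rim inside a slice
    labels <- segment_colonies(region, fake_plate, fp)
    feats <- extract_features(labels, region)
    classified <- classify_regions(filter_regions(feats, fp), classifier_params)
    if (nrow(classified) == 0L) return(empty_detections())
    detection_table(classified$x_min, classified$y_min,
                    classified$x_max, classified$y_max,
                    classified$cls, score = 1.0)
  }
}
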