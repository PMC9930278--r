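# Seeded generator of synthetic petri-dish scans with exact ground truth.
# The scene model mirrors the imaging conditions of the assay: a dark
# (black-felt) background, a lighter circular agar disc, bright
# radially-decaying colony blobs in two well-separated size classes
# (Petites smaller and more translucent than Grandes), optional diffuse
# blur emulating low-quality agar, thin refraction arcs near the plate rim,
# and additive Gaussian pixel noise.

#' Synthetic plate generator configuration
#'
#' Defaults are pinned to the pixel scales of a 600-DPI single-dish scan:
#' a 2376 x 2288 px frame, colony radii spanning 4-44 px across the two
#' classes, and a mean of 78 colonies per plate. The Petite/Grande split is
#' a Bernoulli process with probability \code{petite_prob}.
#'
#' @param image_size Integer (width, height) in px.
#' @param plate_center (x, y) of the dish center in px; default centered.
#' @param plate_radius Dish radius in px; default 0.46 of the smaller image
#'   dimension.
#' @param background_level,agar_level Mean intensity (0-255) of the felt
#'   background and the agar disc.
#' @param colony_count_mean Poisson mean of the per-plate colony count.
#' @param petite_prob Bernoulli probability that a colony is Petite.
#' @param grande_radius_range,petite_radius_range Colony radius ranges in px;
#'   the Petite maximum must stay below the Grande minimum so the two size
#'   classes do not overlap.
#' @param grande_peak_intensity,petite_peak_intensity Peak blob intensity
#'   (0-255); the lower Petite peak encodes their translucency.
#' @param intensity_jitter Per-colony peak intensities are drawn uniformly
#'   from \[(1 - jitter) * peak, peak\].
#' @param touching_pair_fraction Fraction of colonies deliberately placed as
#'   touching same-class pairs (discs overlapping by 20-50 percent of the
#'   smaller radius) to exercise watershed splitting.
#' @param mode \code{"ideal"} (sharp colonies) or \code{"diffuse"}
#'   (Gaussian-blurred colony layer emulating non-ideal agar).
#' @param artifact_arc_range Integer range; the number of bright refraction
#'   arcs rendered just inside the plate rim is drawn uniformly from it.
#' @param noise_sigma Standard deviation of additive Gaussian pixel noise.
#' @param seed Integer seed; every stochastic step derives from it.
#' @return A validated list of class \code{synth_config}.
#' @export
synth_config <- function(image_size = c(2376L, 2288L),
                         plate_center = NULL,
                         plate_radius = NULL,
                         background_level = 10,
                         agar_level = 90,
                         colony_count_mean = 78,
                         petite_prob = 0.3,
                         grande_radius_range = c(18, 44),
                         petite_radius_range = c(4, 12),
                         grande_peak_intensity = 220,
                         petite_peak_intensity = 140,
                         intensity_jitter = 0.1,
                         touching_pair_fraction = 0.1,
                         mode = c("ideal", "diffuse"),
                         artifact_arc_range = c(0L, 3L),
                         noise_sigma = 3,
                         seed = 1L) {
  mode <- match.arg(mode)
  image_size <- as.integer(image_size)
  if (is.null(plate_center)) plate_center <- image_size / 2
  if (is.null(plate_radius)) plate_radius <- 0.46 * min(image_size)
  cfg <- list(image_size = image_size, plate_center = plate_center,
              plate_radius = plate_radius,
              background_level = background_level, agar_level = agar_level,
              colony_count_mean = colony_count_mean, petite_prob = petite_prob,
              grande_radius_range = grande_radius_range,
              petite_radius_range = petite_radius_range,
              grande_peak_intensity = grande_peak_intensity,
              petite_peak_intensity = petite_peak_intensity,
              intensity_jitter = intensity_jitter,
              touching_pair_fraction = touching_pair_fraction,
              mode = mode, artifact_arc_range = as.integer(artifact_arc_range),
              noise_sigma = noise_sigma, seed = as.integer(seed))
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  stopifnot(length(cfg$image_size) == 2L, all(cfg$image_size >= 16L))
  if (cfg$petite_prob < 0 || cfg$petite_prob > 1) stop("petite_prob must lie in [0, 1]")
  if (any(cfg$grande_radius_range <= 0) || any(cfg$petite_radius_range <= 0)) {
    stop("colony radius ranges must be positive")
  }
  if (max(cfg$petite_radius_range) >= min(cfg$grande_radius_range)) {
    stop("petite radii must stay strictly below grande radii (non-overlapping size classes)")
  }
  lv <- c(cfg$background_level, cfg$agar_level,
          cfg$grande_peak_intensity, cfg$petite_peak_intensity)
  if (any(lv < 0 | lv > 255)) stop("intensity levels must lie in [0, 255]")
  if (cfg$background_level >= cfg$agar_level) {
    stop("background must be darker than the agar disc")
  }
  if (cfg$touching_pair_fraction < 0 || cfg$touching_pair_fraction > 1) {
    stop("touching_pair_fraction must lie in [0, 1]")
  }
  if (cfg$noise_sigma < 0) stop("noise_sigma must be non-negative")
  if (cfg$plate_radius <= 0) stop("plate_radius must be positive")
  invisible(cfg)
}

class_radius_range <- function(cfg, cls) {
  if (cls == "grande") cfg$grande_radius_range else cfg$petite_radius_range
}

class_peak <- function(cfg, cls) {
  if (cls == "grande") cfg$grande_peak_intensity else cfg$petite_peak_intensity
}

# Colonies must sit clear of the dish wall: the agar meniscus and the rim
# refraction zone of real scans keep colonies inside ~97% of the dish radius.
PLACEMENT_RADIUS_FRACTION <- 0.97

#' Sample colony positions, sizes and classes for one plate
#'
#' The colony count is Poisson with mean \code{colony_count_mean}; each
#' colony's class is an independent Bernoulli(\code{petite_prob}) draw.
#' Centers are rejection-sampled so colony discs stay inside the plate and
#' pairwise non-touching, except for a configured fraction placed as
#' deliberately touching same-class pairs (disc overlap 20-50 percent of the
#' smaller radius).
#'
#' @param config A [synth_config()].
#' @param seed Seed for this draw; defaults to \code{config$seed}.
#' @return Data frame with one row per colony: \code{cx, cy, radius, cls,
#'   peak, pair_id} (\code{pair_id} is \code{NA} for isolated colonies).
#' @export
sample_colonies <- function(config, seed = config$seed) {
  validate_synth_config(config)
  withr::with_seed(seed, sample_colonies_impl(config))
}

sample_colonies_impl <- function(cfg) {
  n <- stats::rpois(1L, cfg$colony_count_mean)
  empty <- data.frame(cx = numeric(), cy = numeric(), radius = numeric(),
                      cls = character(), peak = numeric(), pair_id = integer(),
                      stringsAsFactors = FALSE)
  if (n == 0L) return(empty)

  cls <- ifelse(stats::runif(n) < cfg$petite_prob, "petite", "grande")
  n_pair <- 2L * floor(cfg$touching_pair_fraction * n / 2)
  pair_id <- rep(NA_integer_, n)
  if (n_pair >= 2L) {
    idx <- seq_len(n_pair)
    pair_id[idx] <- rep(seq_len(n_pair %/% 2L), each = 2L)
    # touching pairs are same-class: the second member copies the first
    cls[idx[c(FALSE, TRUE)]] <- cls[idx[c(TRUE, FALSE)]]
  }
  radius <- vapply(cls, function(cl) {
    rr <- class_radius_range(cfg, cl)
    stats::runif(1L, rr[1L], rr[2L])
  }, numeric(1L), USE.NAMES = FALSE)
  peak <- vapply(cls, function(cl) {
    class_peak(cfg, cl) * stats::runif(1L, 1 - cfg$intensity_jitter, 1)
  }, numeric(1L), USE.NAMES = FALSE)

  cx <- numeric(n); cy <- numeric(n)
  rmax <- PLACEMENT_RADIUS_FRACTION * cfg$plate_radius
  clearance <- 2  # px gap enforced between non-pair colony discs
  max_attempts <- 2000L
  for (i in seq_len(n)) {
    placed <- FALSE
    is_second_of_pair <- !is.na(pair_id[i]) && i %% 2L == 0L
    others <- setdiff(seq_len(i - 1L),
                      if (!is.na(pair_id[i])) which(pair_id == pair_id[i]) else integer())
    for (attempt in seq_len(max_attempts)) {
      if (is_second_of_pair) {
        mate <- i - 1L
        overlap <- stats::runif(1L, 0.2, 0.5)
        d <- radius[mate] + radius[i] - overlap * min(radius[mate], radius[i])
        theta <- stats::runif(1L, 0, 2 * pi)
        px <- cx[mate] + d * cos(theta); py <- cy[mate] + d * sin(theta)
      } else {
        theta <- stats::runif(1L, 0, 2 * pi)
        rr <- sqrt(stats::runif(1L)) * max(0, rmax - radius[i])
        px <- cfg$plate_center[1L] + rr * cos(theta)
        py <- cfg$plate_center[2L] + rr * sin(theta)
      }
      inside <- sqrt((px - cfg$plate_center[1L])^2 + (py - cfg$plate_center[2L])^2) +
        radius[i] <= rmax
      clear <- length(others) == 0L ||
        all(sqrt((cx[others] - px)^2 + (cy[others] - py)^2) >
              radius[others] + radius[i] + clearance)
      if (inside && clear) {
        cx[i] <- px; cy[i] <- py; placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("infeasible colony packing: could not place colony ", i, " of ", n,
           " after ", max_attempts, " attempts; reduce colony_count_mean or radii")
    }
  }
  data.frame(cx = cx, cy = cy, radius = radius, cls = cls, peak = peak,
             pair_id = pair_id, stringsAsFactors = FALSE)
}

# Radial blob profile: full intensity plateau out to 0.7 R, then a Gaussian
# falloff with scale 0.25 R. Soft edges make Otsu thresholding and the
# diffuse mode behave as on real scans (hard discs would not).
colony_profile <- function(r, radius, peak) {
  peak * exp(-pmax(r - 0.7 * radius, 0)^2 / (2 * (0.25 * radius)^2))
}

# Footprint of a single colony rendered into its local patch; used both for
# compositing and for the ground-truth box threshold.
render_colony_patch <- function(cfg, colony, blur_sigma = 0) {
  pad <- max(2, ceiling(1.5 * colony$radius + 3 * blur_sigma))
  x0 <- max(1L, floor(colony$cx - pad)); x1 <- min(cfg$image_size[1L], ceiling(colony$cx + pad))
  y0 <- max(1L, floor(colony$cy - pad)); y1 <- min(cfg$image_size[2L], ceiling(colony$cy + pad))
  lx <- (x0:x1) - 0.5 - colony$cx
  ly <- (y0:y1) - 0.5 - colony$cy
  r <- sqrt(outer(lx^2, ly^2, "+"))
  patch <- colony_profile(r, colony$radius, colony$peak)
  if (blur_sigma > 0) {
    patch <- as.matrix(EBImage::gblur(EBImage::Image(patch / 255), sigma = blur_sigma)) * 255
  }
  list(x0 = x0, y0 = y0, patch = patch)
}

diffuse_sigma <- function(cfg) 0.3 * mean(cfg$petite_radius_range)

#' Render a plate image and its ground truth
#'
#' Composites the background, agar disc, colony blobs, optional rim
#' refraction arcs and Gaussian pixel noise into a grayscale plate image.
#' Each ground-truth box is the tight axis-aligned box of the colony's
#' rendered footprint, thresholded at \code{agar_level + 3 * noise_sigma}
#' (what an annotator would draw on the rendered image, not the generating
#' disc). Identical \code{(config, colonies)} yield a bit-identical image.
#'
#' @param config A [synth_config()].
#' @param colonies Colony table from [sample_colonies()] drawn under the
#'   same config.
#' @param image_id Identifier for the rendered plate.
#' @return List with \code{image} (a [plate_image()]) and \code{truth}
#'   (data frame \code{image_id, x_min, y_min, x_max, y_max, cls}).
#' @export
render_plate <- function(config, colonies, image_id = "plate") {
  validate_synth_config(config)
  # Noise and arc placement re-derive their stream from the config seed so
  # rendering is a pure function of (config, colonies).
  withr::with_seed(config$seed + 1L, render_plate_impl(config, colonies, image_id))
}

render_plate_impl <- function(cfg, colonies, image_id) {
  W <- cfg$image_size[1L]; H <- cfg$image_size[2L]
  cx <- cfg$plate_center[1L]; cy <- cfg$plate_center[2L]
  xs <- matrix((seq_len(W) - 0.5) - cx, W, H)
  ys <- matrix(rep((seq_len(H) - 0.5) - cy, each = W), W, H)
  d2 <- xs^2 + ys^2
  img <- matrix(cfg$background_level, W, H)
  img[d2 <= cfg$plate_radius^2] <- cfg$agar_level

  blur_sigma <- if (cfg$mode == "diffuse") diffuse_sigma(cfg) else 0
  gt_thresh <- cfg$agar_level + 3 * cfg$noise_sigma

  truth <- vector("list", nrow(colonies))
  if (nrow(colonies) > 0L) {
    for (i in seq_len(nrow(colonies))) {
      p <- render_colony_patch(cfg, colonies[i, ], blur_sigma)
      xi <- p$x0 + seq_len(nrow(p$patch)) - 1L
      yi <- p$y0 + seq_len(ncol(p$patch)) - 1L
      img[xi, yi] <- pmax(img[xi, yi], p$patch)
      fg <- which(p$patch > gt_thresh, arr.ind = TRUE)
      if (nrow(fg) == 0L) {
        truth[[i]] <- NULL
        next
      }
      truth[[i]] <- data.frame(
        image_id = image_id,
        x_min = p$x0 + min(fg[, 1L]) - 2L, y_min = p$y0 + min(fg[, 2L]) - 2L,
        x_max = p$x0 + max(fg[, 1L]) - 1L, y_max = p$y0 + max(fg[, 2L]) - 1L,
        cls = colonies$cls[i], stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, truth)
  if (is.null(truth)) {
    truth <- data.frame(image_id = character(), x_min = numeric(),
                        y_min = numeric(), x_max = numeric(), y_max = numeric(),
                        cls = character(), stringsAsFactors = FALSE)
  }

  n_arcs <- sample_arc_count(cfg)
  if (n_arcs > 0L) img <- draw_refraction_arcs(cfg, img, n_arcs, xs, ys)

  if (cfg$noise_sigma > 0) {
    img <- img + stats::rnorm(length(img), 0, cfg$noise_sigma)
  }
  img <- pmin(pmax(img, 0), 255)
  list(image = plate_image(img, image_id), truth = truth)
}

sample_arc_count <- function(cfg) {
  rng <- cfg$artifact_arc_range
  if (rng[2L] <= rng[1L]) return(rng[1L])
  sample(seq(rng[1L], rng[2L]), 1L)
}

# Thin bright circular arcs just inside the plate rim, emulating refraction
# from neighbouring dishes. Arcs are long and thin (eccentricity near 1) so
# the classical detector's eccentricity filter can reject them.
draw_refraction_arcs <- function(cfg, img, n_arcs, xs, ys) {
  theta_px <- atan2(ys, xs)
  r_px <- sqrt(xs^2 + ys^2)
  for (a in seq_len(n_arcs)) {
    arc_r <- stats::runif(1L, 0.93, 0.98) * cfg$plate_radius
    width <- stats::runif(1L, 1.5, 3)
    mid <- stats::runif(1L, -pi, pi)
    span <- stats::runif(1L, pi / 12, pi / 3)
    level <- stats::runif(1L, 160, 200)
    dth <- abs(((theta_px - mid + pi) %% (2 * pi)) - pi)
    sel <- abs(r_px - arc_r) <= width / 2 & dth <= span / 2
    img[sel] <- pmax(img[sel], level)
  }
  img
}

#' Simulate one plate: sample colonies and render
#'
#' @inheritParams render_plate
#' @return List with \code{image}, \code{truth} and the sampled
#'   \code{colonies} table.
#' @export
simulate_plate <- function(config, image_id = "plate") {
  colonies <- sample_colonies(config)
  out <- render_plate(config, colonies, image_id)
  out$colonies <- colonies
  out
}

#' Simulate a batch of plates
#'
#' Plate \code{i} uses seed \code{config$seed + i}, so a batch is fully
#' reproducible from one seed. Optionally writes PNG images, a COCO
#' ground-truth JSON and a manifest CSV to a directory.
#'
#' @param config A [synth_config()]; its \code{seed} anchors the batch.
#' @param n_plates Number of plates.
#' @param dir Optional output directory (created if missing).
#' @param prefix Image-id prefix, default \code{"plate"}.
#' @return List with \code{plates} (list of [simulate_plate()] results) and
#'   \code{manifest} (data frame \code{image_id, n_grande, n_petite,
#'   petite_freq_true}).
#' @export
simulate_batch <- function(config, n_plates, dir = NULL, prefix = "plate") {
  stopifnot(n_plates >= 1L)
  plates <- vector("list", n_plates)
  for (i in seq_len(n_plates)) {
    cfg_i <- config
    cfg_i$seed <- config$seed + i
    plates[[i]] <- simulate_plate(cfg_i, sprintf("%s_%03d", prefix, i))
  }
  manifest <- do.call(rbind, lapply(plates, function(p) {
    ng <- sum(p$truth$cls == "grande"); np <- sum(p$truth$cls == "petite")
    data.frame(image_id = p$image$image_id, n_grande = ng, n_petite = np,
               petite_freq_true = if (ng + np > 0L) np / (ng + np) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(dir)) write_batch(plates, manifest, dir)
  list(plates = plates, manifest = manifest)
}

write_batch <- function(plates, manifest, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in plates) {
    write_plate_image(p$image, file.path(dir, paste0(p$image$image_id, ".png")))
  }
  images <- do.call(rbind, lapply(plates, function(p) {
    data.frame(image_id = p$image$image_id,
               file_name = paste0(p$image$image_id, ".png"),
               width = p$image$width, height = p$image$height,
               stringsAsFactors = FALSE)
  }))
  anns <- do.call(rbind, lapply(plates, function(p) p$truth))
  write_coco(file.path(dir, "ground_truth.json"), images, anns)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' Downscale a plate image
#'
#' Bilinear resize of both dimensions by \code{factor}; output dimensions
#' are \code{round(dim * factor)}. Minification is antialiased with a
#' Gaussian pre-blur of sigma \code{(1 / factor - 1) / 2} so sub-pixel
#' structure is averaged away rather than aliased, matching how scanners
#' and standard image libraries reduce resolution. Annotations must be
#' rescaled separately with [scale_boxes()].
#'
#' @param image A [plate_image()].
#' @param factor Scale factor in (0, 1\].
#' @return A resized [plate_image()].
#' @export
downscale_plate <- function(image, factor) {
  stopifnot(inherits(image, "plate_image"))
  if (!is.numeric(factor) || factor <= 0 || factor > 1) {
    stop("downscale factor must lie in (0, 1]")
  }
  if (factor == 1) return(image)
  w <- round(image$width * factor); h <- round(image$height * factor)
  if (w < 8L || h < 8L) stop("downscaled image would fall below the 8 x 8 px floor")
  img <- as_ebimage(image)
  aa_sigma <- (1 / factor - 1) / 2
  if (aa_sigma > 0.3) img <- EBImage::gblur(img, sigma = aa_sigma)
  px <- as.matrix(EBImage::resize(img, w = w, h = h, filter = "bilinear")) * 255
  plate_image(pmin(pmax(px, 0), 255), image$image_id)
}
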