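# Image reading/writing, annotated-image rendering, the Petite-frequency
# CSV, and the run configuration file.

#' Read a plate image from PNG/TIFF/JPEG
#'
#' RGB images are collapsed to grayscale by channel averaging; intensities
#' are scaled to \[0, 255\].
#'
#' @param path Image file path.
#' @param image_id Identifier; defaults to the file name without extension.
#' @return A [plate_image()].
#' @export
read_plate_image <- function(path, image_id = NULL) {
  if (!file.exists(path)) stop("image file not found: ", path)
  if (is.null(image_id)) image_id <- sub("\\.[A-Za-z]+$", "", basename(path))
  img <- EBImage::readImage(path)
  px <- EBImage::imageData(img)
  if (length(dim(px)) == 3L) px <- px[, , seq_len(min(3L, dim(px)[3L])), drop = FALSE]
  plate_image(pmin(pmax(px * 255, 0), 255), image_id)
}

#' Write a plate image as PNG
#' @param image A [plate_image()].
#' @param path Output path (extension selects the format).
#' @return \code{path}, invisibly.
#' @export
write_plate_image <- function(image, path) {
  stopifnot(inherits(image, "plate_image"))
  EBImage::writeImage(as_ebimage(image), path)
  invisible(path)
}

# 3 x 5 bitmap glyphs for score labels on annotated images.
GLYPHS <- list(
  "0" = c("111", "101", "101", "101", "111"),
  "1" = c("010", "110", "010", "010", "111"),
  "2" = c("111", "001", "111", "100", "111"),
  "3" = c("111", "001", "011", "001", "111"),
  "4" = c("101", "101", "111", "001", "001"),
  "5" = c("111", "100", "111", "001", "111"),
  "6" = c("111", "100", "111", "101", "111"),
  "7" = c("111", "001", "010", "010", "010"),
  "8" = c("111", "101", "111", "101", "111"),
  "9" = c("111", "101", "111", "001", "111"),
  "." = c("000", "000", "000", "000", "010"))

glyph_matrix <- function(ch) {
  g <- GLYPHS[[ch]]
  if (is.null(g)) g <- GLYPHS[["."]]
  m <- do.call(rbind, lapply(g, function(row) as.integer(strsplit(row, "")[[1L]])))
  t(m)  # [x, y]
}

draw_text <- function(rgb, text, x, y, color, scale = 2L) {
  cx <- x
  W <- dim(rgb)[1L]; H <- dim(rgb)[2L]
  for (ch in strsplit(text, "")[[1L]]) {
    gm <- glyph_matrix(ch)
    on <- which(gm == 1L, arr.ind = TRUE)
    for (k in seq_len(nrow(on))) {
      xs <- cx + (on[k, 1L] - 1L) * scale + seq_len(scale) - 1L
      ys <- y + (on[k, 2L] - 1L) * scale + seq_len(scale) - 1L
      xs <- xs[xs >= 1L & xs <= W]; ys <- ys[ys >= 1L & ys <= H]
      if (length(xs) && length(ys)) for (c in 1:3) rgb[xs, ys, c] <- color[c]
    }
    cx <- cx + 4L * scale
  }
  rgb
}

draw_rect <- function(rgb, b, color, lw) {
  W <- dim(rgb)[1L]; H <- dim(rgb)[2L]
  x0 <- max(1L, round(b[1L]) + 1L); x1 <- min(W, round(b[3L]))
  y0 <- max(1L, round(b[2L]) + 1L); y1 <- min(H, round(b[4L]))
  if (x1 <= x0 || y1 <= y0) return(rgb)
  for (c in 1:3) {
    rgb[x0:x1, y0:min(H, y0 + lw - 1L), c] <- color[c]
    rgb[x0:x1, max(1L, y1 - lw + 1L):y1, c] <- color[c]
    rgb[x0:min(W, x0 + lw - 1L), y0:y1, c] <- color[c]
    rgb[max(1L, x1 - lw + 1L):x1, y0:y1, c] <- color[c]
  }
  rgb
}

CLASS_COLORS <- list(grande = c(0.25, 0.45, 1.0),   # blue
                     petite = c(1.0, 0.60, 0.05))   # orange

#' Render an annotated copy of a plate image
#'
#' Draws detection boxes (Grande blue, Petite orange) with their
#' confidence scores printed beside the boxes, and writes the result as an
#' RGB image.
#'
#' @param image A [plate_image()].
#' @param dets Detection data frame.
#' @param path Output image path.
#' @return \code{path}, invisibly.
#' @export
write_annotated_image <- function(image, dets, path) {
  stopifnot(inherits(image, "plate_image"))
  validate_detections(dets)
  g <- image$pixels / 255
  rgb <- array(c(g, g, g), dim = c(image$width, image$height, 3L))
  lw <- max(2L, round(min(image$width, image$height) / 500))
  txt_scale <- max(1L, round(lw / 2))
  if (nrow(dets) > 0L) {
    for (i in seq_len(nrow(dets))) {
      col <- CLASS_COLORS[[dets$cls[i]]]
      b <- as.numeric(dets[i, box_cols])
      rgb <- draw_rect(rgb, b, col, lw)
      rgb <- draw_text(rgb, sprintf("%.2f", dets$score[i]),
                       round(b[1L]) + 1L, max(1L, round(b[2L]) - 6L * txt_scale),
                       col, txt_scale)
    }
  }
  EBImage::writeImage(EBImage::Image(rgb, colormode = "Color"), path)
  invisible(path)
}

FREQ_CSV_COLUMNS <- c("image_id", "n_grande", "n_petite", "k",
                      "petite_freq", "petite_pct", "binom_std")

#' Append Petite-frequency rows to a CSV
#'
#' Emits the stable schema \code{image_id, n_grande, n_petite, k,
#' petite_freq, petite_pct, binom_std}: the frequency both as a fraction
#' and as a percentage. Plates with no colonies get \code{NA} fields.
#'
#' @param freq One or more rows from [petite_frequency()] (row-bound).
#' @param path CSV path; a header is written when the file does not yet
#'   exist.
#' @return \code{path}, invisibly.
#' @export
write_frequency_csv <- function(freq, path) {
  out <- data.frame(image_id = freq$image_id, n_grande = freq$n_grande,
                    n_petite = freq$n_petite, k = freq$k,
                    petite_freq = freq$petite_freq,
                    petite_pct = 100 * freq$petite_freq,
                    binom_std = freq$binom_std, stringsAsFactors = FALSE)
  new_file <- !file.exists(path)
  utils::write.table(out, path, sep = ",", row.names = FALSE,
                     col.names = new_file, append = !new_file, qmethod = "double")
  invisible(path)
}

#' Default run configuration
#'
#' All detector, slicing, merging and output parameters in one validated
#' object, mirrored by the command-line flags and the YAML config file.
#'
#' @param backend Detection backend; only \code{"classical"} ships.
#' @param sliced Run the backend through sliced inference instead of on
#'   the whole image.
#' @param filter,classifier,slicing,nmm Parameter objects (or plain lists
#'   of arguments for the corresponding constructors).
#' @param outputs Logical toggles \code{csv}, \code{coco}, \code{viz}.
#' @param seed Integer seed for stochastic stages.
#' @return List of class \code{run_config}.
#' @export
run_config <- function(backend = "classical", sliced = FALSE,
                       filter = filter_params(), classifier = classifier_params(),
                       slicing = slicing_params(), nmm = nmm_params(),
                       outputs = list(csv = TRUE, coco = TRUE, viz = TRUE),
                       seed = 1L) {
  if (!identical(backend, "classical")) {
    stop("unknown backend '", backend, "' (only 'classical' is built in; ",
         "plug other backends in through infer_sliced())")
  }
  as_params <- function(x, ctor) if (is.list(x) && is.null(attr(x, "class"))) do.call(ctor, x) else x
  outputs <- utils::modifyList(list(csv = TRUE, coco = TRUE, viz = TRUE), outputs)
  structure(list(backend = backend, sliced = isTRUE(sliced),
                 filter = as_params(filter, filter_params),
                 classifier = as_params(classifier, classifier_params),
                 slicing = as_params(slicing, slicing_params),
                 nmm = as_params(nmm, nmm_params),
                 outputs = outputs, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a YAML run configuration
#'
#' Unknown top-level or nested keys are rejected rather than ignored, so a
#' typo in a config file cannot silently fall back to a default.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("backend", "sliced", "filter", "classifier", "slicing", "nmm",
             "outputs", "seed")
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0L) {
    stop("unknown config keys: ", paste(extra, collapse = ", "))
  }
  check_sub <- function(name, allowed) {
    bad <- setdiff(names(raw[[name]]), allowed)
    if (length(bad) > 0L) stop("unknown keys under '", name, "': ", paste(bad, collapse = ", "))
  }
  check_sub("filter", names(formals(filter_params)))
  check_sub("classifier", names(formals(classifier_params)))
  check_sub("slicing", names(formals(slicing_params)))
  check_sub("nmm", names(formals(nmm_params)))
  check_sub("outputs", c("csv", "coco", "viz"))
  do.call(run_config, raw)
}

#' Write per-plate outputs
#'
#' Per enabled toggle: appends the plate's row to the Petite-frequency
#' CSV, extends the COCO predictions JSON, and renders the annotated
#' image.
#'
#' @param image A [plate_image()].
#' @param dets Detections for the plate.
#' @param freq The plate's [petite_frequency()] row.
#' @param out_dir Output directory (created if missing).
#' @param config A [run_config()] controlling the output toggles.
#' @return \code{out_dir}, invisibly.
#' @export
write_outputs <- function(image, dets, freq, out_dir, config = run_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(out_dir, mode = 2L) != 0L) {
    stop("output directory is not writable: ", out_dir)
  }
  if (isTRUE(config$outputs$csv)) {
    write_frequency_csv(freq, file.path(out_dir, "petite_frequencies.csv"))
  }
  if (isTRUE(config$outputs$coco)) {
    pred_path <- file.path(out_dir, "predictions.json")
    img_row <- data.frame(image_id = image$image_id,
                          file_name = paste0(image$image_id, ".png"),
                          width = image$width, height = image$height,
                          stringsAsFactors = FALSE)
    ann <- dets
    if (nrow(ann) > 0L) ann$image_id <- image$image_id
    if (file.exists(pred_path)) {
      prev <- read_coco(pred_path)
      img_row <- rbind(prev$images[c("image_id", "file_name", "width", "height")],
                       img_row)
      if (nrow(prev$annotations) > 0L) {
        ann <- rbind(prev$annotations[c("image_id", box_cols, "cls", "score")],
                     if (nrow(ann) > 0L) ann[c("image_id", box_cols, "cls", "score")])
      } else if (nrow(ann) > 0L) {
        ann <- ann[c("image_id", box_cols, "cls", "score")]
      }
    }
    write_coco(pred_path, img_row,
               if (nrow(ann) > 0L) ann else
                 data.frame(image_id = character(), x_min = numeric(),
                            y_min = numeric(), x_max = numeric(),
                            y_max = numeric(), cls = character(),
                            score = numeric(), stringsAsFactors = FALSE))
  }
  if (isTRUE(config$outputs$viz)) {
    write_annotated_image(image, dets,
                          file.path(out_dir, paste0(image$image_id, "_annotated.png")))
  }
  invisible(out_dir)
}
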