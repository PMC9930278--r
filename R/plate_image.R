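# The single-dish image container. Pixels are stored as a width x height
# numeric matrix indexed [x, y] (the EBImage spatial convention) with
# intensities in [0, 255]. RGB input is converted to grayscale at read time;
# no downstream stage uses color.

#' Construct a plate image
#'
#' @param pixels Numeric matrix indexed \code{[x, y]} (width by height) with
#'   values in \[0, 255\]. An RGB array \code{[x, y, 3]} is collapsed to
#'   grayscale by channel averaging.
#' @param image_id Identifier string used in CSV/COCO output.
#' @return An object of class \code{plate_image}: a list with elements
#'   \code{pixels}, \code{image_id}, \code{width}, \code{height}.
#' @export
plate_image <- function(pixels, image_id = "plate") {
  if (length(dim(pixels)) == 3L) {
    pixels <- (pixels[, , 1L] + pixels[, , 2L] + pixels[, , 3L]) / 3
  }
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("pixels must be a numeric [x, y] matrix or [x, y, 3] array")
  }
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) stop("image must be at least 1 x 1 px")
  rng <- range(pixels)
  if (rng[1L] < 0 || rng[2L] > 255) stop("pixel intensities must lie in [0, 255]")
  structure(list(pixels = pixels, image_id = as.character(image_id),
                 width = nrow(pixels), height = ncol(pixels)),
            class = "plate_image")
}

#' @export
print.plate_image <- function(x, ...) {
  cat(sprintf("<plate_image '%s': %d x %d px, intensity [%.1f, %.1f]>\n",
              x$image_id, x$width, x$height, min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.plate_image <- function(x) c(x$width, x$height)

as_ebimage <- function(image) EBImage::Image(image$pixels / 255)
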