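# COCO-format JSON reading and writing. The dialect: categories are fixed
# (id 1 = "grande", id 2 = "petite"; names, not ids, are authoritative on
# read, matched case-insensitively), bbox is the standard [x, y, width,
# height] in pixels, and prediction confidences live in the common "score"
# extension field. Internally boxes are half-open [x, x + w) x [y, y + h).

COCO_CATEGORIES <- data.frame(id = c(1L, 2L), name = c("grande", "petite"),
                              stringsAsFactors = FALSE)

#' Write detections or ground truth as COCO JSON
#'
#' @param path Output file path.
#' @param images Data frame with \code{image_id, width, height} and
#'   optionally \code{file_name} (default \code{<image_id>.png}).
#' @param annotations Data frame with \code{image_id}, box columns
#'   (\code{x_min, y_min, x_max, y_max}), \code{cls}, and optionally
#'   \code{score}.
#' @return \code{path}, invisibly.
#' @export
write_coco <- function(path, images, annotations) {
  stopifnot(all(c("image_id", "width", "height") %in% names(images)))
  if (!"file_name" %in% names(images)) {
    images$file_name <- paste0(images$image_id, ".png")
  }
  img_ids <- seq_len(nrow(images))
  imgs <- lapply(img_ids, function(i) list(
    id = i, file_name = images$file_name[i],
    width = images$width[i], height = images$height[i]))
  has_score <- "score" %in% names(annotations)
  anns <- lapply(seq_len(nrow(annotations)), function(j) {
    a <- annotations[j, ]
    i <- match(a$image_id, images$image_id)
    if (is.na(i)) stop("annotation ", j, " references unknown image_id '", a$image_id, "'")
    cat_id <- COCO_CATEGORIES$id[match(a$cls, COCO_CATEGORIES$name)]
    if (is.na(cat_id)) stop("annotation ", j, " has unknown category '", a$cls, "'")
    w <- a$x_max - a$x_min; h <- a$y_max - a$y_min
    out <- list(id = j, image_id = i, category_id = cat_id,
                bbox = c(a$x_min, a$y_min, w, h), area = w * h)
    if (has_score && !is.na(a$score)) out$score <- a$score
    out
  })
  cats <- lapply(seq_len(nrow(COCO_CATEGORIES)), function(i) {
    list(id = COCO_CATEGORIES$id[i], name = COCO_CATEGORIES$name[i],
         supercategory = "colony")
  })
  doc <- list(images = imgs, annotations = anns, categories = cats)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a COCO JSON annotation file
#'
#' Categories are matched by name (case-insensitive) against the closed
#' class set \{grande, petite\}; unknown names, missing keys, dangling
#' image references and out-of-bounds boxes are hard errors naming the
#' offending annotation. COCO \code{[x, y, w, h]} boxes become internal
#' half-open \code{[x, x + w) x [y, y + h)} boxes.
#'
#' @param path Path to a COCO JSON file.
#' @return List with \code{images} (data frame \code{image_id, file_name,
#'   width, height}) and \code{annotations} (data frame \code{image_id,
#'   x_min, y_min, x_max, y_max, cls, score}; \code{score} is \code{NA}
#'   where absent).
#' @export
read_coco <- function(path) {
  if (!file.exists(path)) stop("COCO file not found: ", path)
  doc <- jsonlite::read_json(path)
  for (key in c("images", "annotations", "categories")) {
    if (is.null(doc[[key]])) stop("COCO document missing required key '", key, "'")
  }
  cat_name <- vapply(doc$categories, function(ct) tolower(ct$name), "")
  cat_id <- vapply(doc$categories, function(ct) as.integer(ct$id), 0L)
  bad <- setdiff(cat_name, COLONY_CLASSES)
  if (length(bad) > 0L) {
    stop("COCO document declares unknown categories: ", paste(bad, collapse = ", "))
  }
  images <- data.frame(
    id = vapply(doc$images, function(im) as.integer(im$id), 0L),
    image_id = vapply(doc$images, function(im) {
      fn <- im$file_name
      if (is.null(fn)) stop("image entry missing file_name")
      sub("\\.[A-Za-z]+$", "", fn)
    }, ""),
    file_name = vapply(doc$images, function(im) im$file_name, ""),
    width = vapply(doc$images, function(im) as.numeric(im$width), 0),
    height = vapply(doc$images, function(im) as.numeric(im$height), 0),
    stringsAsFactors = FALSE)
  anns <- lapply(doc$annotations, function(a) {
    aid <- if (!is.null(a$id)) a$id else "<unnumbered>"
    for (key in c("image_id", "category_id", "bbox")) {
      if (is.null(a[[key]])) stop("annotation ", aid, " missing required key '", key, "'")
    }
    i <- match(as.integer(a$image_id), images$id)
    if (is.na(i)) stop("annotation ", aid, " references unknown image id ", a$image_id)
    ci <- match(as.integer(a$category_id), cat_id)
    if (is.na(ci)) stop("annotation ", aid, " references unknown category id ", a$category_id)
    bb <- as.numeric(unlist(a$bbox))
    if (length(bb) != 4L || bb[3L] <= 0 || bb[4L] <= 0) {
      stop("annotation ", aid, " has a degenerate bbox")
    }
    if (bb[1L] < 0 || bb[2L] < 0 ||
        bb[1L] + bb[3L] > images$width[i] || bb[2L] + bb[4L] > images$height[i]) {
      stop("annotation ", aid, " bbox exceeds the bounds of image '",
           images$image_id[i], "'")
    }
    data.frame(image_id = images$image_id[i],
               x_min = bb[1L], y_min = bb[2L],
               x_max = bb[1L] + bb[3L], y_max = bb[2L] + bb[4L],
               cls = cat_name[ci],
               score = if (!is.null(a$score)) as.numeric(a$score) else NA_real_,
               stringsAsFactors = FALSE)
  })
  anns <- if (length(anns) > 0L) do.call(rbind, anns) else
    data.frame(image_id = character(), x_min = numeric(), y_min = numeric(),
               x_max = numeric(), y_max = numeric(), cls = character(),
               score = numeric(), stringsAsFactors = FALSE)
  list(images = images[c("image_id", "file_name", "width", "height")],
       annotations = anns)
}
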