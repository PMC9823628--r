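# YOLO-format annotations as tibbles: one row per box, normalized center
# format (class_id, cx, cy, w, h, optional conf). Reading, writing, the
# corner-format import shim, dataset splitting, and size-class
# stratification.

#' Construct a bounding-box tibble
#'
#' Boxes use the normalized center format: `cx`, `cy`, `w`, `h` are fractions
#' of the image side. `conf` is an optional detection confidence.
#'
#' @param class_id integer class (0-based, as in annotation files).
#' @param cx,cy,w,h numeric vectors in `[0, 1]`.
#' @param conf optional confidence in `[0, 1]`.
#' @return a tibble with class `pn_boxes`.
#' @export
bbox_tibble <- function(class_id = integer(), cx = numeric(), cy = numeric(),
                        w = numeric(), h = numeric(), conf = NULL) {
  out <- tibble::tibble(class_id = as.integer(class_id),
                        cx = as.numeric(cx), cy = as.numeric(cy),
                        w = as.numeric(w), h = as.numeric(h))
  out$conf <- if (is.null(conf)) rep(NA_real_, nrow(out)) else as.numeric(conf)
  class(out) <- c("pn_boxes", class(out))
  out
}

#' Read YOLO-format annotations
#'
#' Parses `class cx cy w h` lines (whitespace separated, normalized center
#' format). Values outside the unit square are clipped; the number of
#' clipped boxes is attached as attribute `"n_clipped"` and raised as a
#' warning.
#'
#' @param text path to a `.txt` annotation file, or a character vector of
#'   lines.
#' @return a `pn_boxes` tibble.
#' @export
read_annotations <- function(text) {
  lines <- if (length(text) == 1 && file.exists(text)) readLines(text, warn = FALSE) else text
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(bbox_tibble())
  parts <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(parts)
  bad <- which(nf != 5L)
  if (length(bad)) {
    stop("malformed annotation line ", bad[1], ": expected 5 fields, got ",
         nf[bad[1]], " (\"", lines[bad[1]], "\")")
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(parts))), ncol = 5, byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(apply(m, 1, anyNA))[1]
    stop("malformed annotation line ", bad, ": non-numeric field (\"",
         lines[bad], "\")")
  }
  b <- bbox_tibble(m[, 1], m[, 2], m[, 3], m[, 4], m[, 5])
  clip_boxes(b)
}

clip_boxes <- function(b) {
  x1 <- pmax(0, b$cx - b$w / 2); x2 <- pmin(1, b$cx + b$w / 2)
  y1 <- pmax(0, b$cy - b$h / 2); y2 <- pmin(1, b$cy + b$h / 2)
  clipped <- (x1 != b$cx - b$w / 2) | (x2 != b$cx + b$w / 2) |
    (y1 != b$cy - b$h / 2) | (y2 != b$cy + b$h / 2)
  n_clipped <- sum(clipped)
  if (n_clipped > 0) {
    b$cx <- (x1 + x2) / 2; b$cy <- (y1 + y2) / 2
    b$w <- pmax(x2 - x1, 0); b$h <- pmax(y2 - y1, 0)
    warning(n_clipped, " box(es) clipped to the unit square")
  }
  attr(b, "n_clipped") <- n_clipped
  b
}

#' Write YOLO-format annotations
#'
#' Inverse of [read_annotations()]; the round trip is lossless to 6 decimal
#' places.
#'
#' @param boxes a `pn_boxes` tibble.
#' @param path optional output file; when NULL the lines are returned.
#' @export
write_annotations <- function(boxes, path = NULL) {
  lines <- if (nrow(boxes) == 0) character() else
    sprintf("%d %.6f %.6f %.6f %.6f",
            boxes$class_id, boxes$cx, boxes$cy, boxes$w, boxes$h)
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Import corner-format annotations
#'
#' Shim for `class x1 y1 x2 y2` pixel-corner lines (upper-left and
#' lower-right), converted to the normalized center format.
#'
#' @param text path or character lines.
#' @param image_size image side length in pixels (square), or c(width, height).
#' @return a `pn_boxes` tibble.
#' @export
read_annotations_corners <- function(text, image_size) {
  lines <- if (length(text) == 1 && file.exists(text)) readLines(text, warn = FALSE) else text
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(bbox_tibble())
  sz <- rep(image_size, length.out = 2)
  parts <- strsplit(trimws(lines), "\\s+")
  if (any(lengths(parts) != 5L)) {
    stop("malformed corner annotation line ", which(lengths(parts) != 5L)[1])
  }
  m <- matrix(as.numeric(unlist(parts)), ncol = 5, byrow = TRUE)
  clip_boxes(bbox_tibble(
    m[, 1],
    (m[, 2] + m[, 4]) / 2 / sz[1], (m[, 3] + m[, 5]) / 2 / sz[2],
    abs(m[, 4] - m[, 2]) / sz[1], abs(m[, 5] - m[, 3]) / sz[2]))
}

#' Split a dataset into train/validation/test
#'
#' Deterministic under a fixed seed. Validation and test sizes are
#' floor-based; the remainder goes to training, so 3680 images at the
#' 80/10/10 default split give 2944/368/368.
#'
#' @param n_images number of images (>= 3).
#' @param ratios length-3 numeric summing to 1 (train, val, test).
#' @param seed integer seed.
#' @return tibble with `index` and `split` (factor train/val/test).
#' @export
#' @examples
#' table(split_dataset(3680, seed = 1)$split)
split_dataset <- function(n_images, ratios = c(0.8, 0.1, 0.1), seed = 0L) {
  if (n_images < 3) stop("need at least 3 images to form a 3-way split")
  if (abs(sum(ratios) - 1) > 1e-8) stop("ratios must sum to 1")
  n_val <- floor(n_images * ratios[2])
  n_test <- floor(n_images * ratios[3])
  n_train <- n_images - n_val - n_test
  perm <- with_seed(seed, sample.int(n_images))
  split <- rep(c("train", "val", "test"), c(n_train, n_val, n_test))
  tibble::tibble(index = seq_len(n_images),
                 split = factor(split[order(perm)],
                                levels = c("train", "val", "test")))
}

#' Size class of each box
#'
#' Pears are near-circular; the radius of a box is half its larger pixel
#' side. Radii under 5 px are omitted from evaluation, under 10 px are
#' small, 10-25 px medium, over 25 px large (boundary radii fall in the
#' lower class).
#'
#' @param boxes a `pn_boxes` tibble (normalized).
#' @param image_size image side in pixels.
#' @return factor with levels omitted/small/medium/large.
#' @export
#' @examples
#' size_class(bbox_tibble(0, .5, .5, .09, .06), image_size = 640)
size_class <- function(boxes, image_size) {
  r <- pmax(boxes$w, boxes$h) * image_size / 2
  cut(r, breaks = c(-Inf, 5, 10, 25, Inf), right = FALSE,
      labels = c("omitted", "small", "medium", "large")) |>
    (\(f) { f[r == 5] <- "small"; f[r == 10] <- "small"; f[r == 25] <- "medium"; f })()
}

# run code under a temporary RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
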