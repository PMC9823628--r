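# Synthetic orchard scenes with ground truth. Pears are shaded ellipses in
# a yellow-green hue band over a leaf/branch-textured background, partially
# covered by occluders (branch strips, leaf blobs), under four illumination
# regimes and two viewpoints. The emitted boxes are the amodal (full-fruit)
# extent clipped to image bounds; pears whose post-clip radius falls under
# 5 px are omitted from the ground truth, mirroring the annotation rule.
#
# The generator is a controllable test surface, not a photorealistic
# renderer: its axes (size mixture, occlusion, illumination, viewpoint)
# mirror the experimental axes of the dataset it stands in for.

#' Scene specification
#'
#' @param image_size square side in pixels.
#' @param n_pears number of pears to draw.
#' @param radius_mix length-3 numeric mixture weights over the small
#'   (5-10 px), medium (10-25 px) and large (25 px to image_size/4) radius
#'   classes; the default follows the 25/58/17 percent composition of the
#'   annotated size strata.
#' @param occlusion_fraction upper bound on the expected covered fraction of
#'   each pear, in `[0, 1]`.
#' @param illumination one of "weak", "normal", "strong", "artificial", or
#'   "random".
#' @param viewpoint "side", "birdseye", or "random".
#' @param seed integer seed; scenes are bit-reproducible given the spec.
#' @return a `pn_scene_spec` list.
#' @export
scene_spec <- function(image_size = 640L, n_pears = 15L,
                       radius_mix = c(small = 0.25, medium = 0.58, large = 0.17),
                       occlusion_fraction = 0.3,
                       illumination = "normal", viewpoint = "side",
                       seed = 0L) {
  stopifnot(image_size >= 32, n_pears >= 0, length(radius_mix) == 3,
            all(radius_mix >= 0), sum(radius_mix) > 0,
            occlusion_fraction >= 0, occlusion_fraction <= 1)
  illumination <- match.arg(illumination,
                            c("weak", "normal", "strong", "artificial", "random"))
  viewpoint <- match.arg(viewpoint, c("side", "birdseye", "random"))
  structure(list(image_size = as.integer(image_size),
                 n_pears = as.integer(n_pears),
                 radius_mix = radius_mix / sum(radius_mix),
                 occlusion_fraction = occlusion_fraction,
                 illumination = illumination, viewpoint = viewpoint,
                 seed = as.integer(seed)),
            class = "pn_scene_spec")
}

rad_ranges <- function(image_size) {
  list(small = c(5, 10), medium = c(10, 25),
       large = c(25, max(26, image_size / 4)))
}

draw_ellipse <- function(img, cx, cy, a, b, theta, col_fun) {
  sz <- dim(img)[1:2]
  r <- max(a, b)
  if (cx + r < 1 || cx - r > sz[2] || cy + r < 1 || cy - r > sz[1]) return(img)
  xs <- max(1L, floor(cx - r)):min(sz[2], ceiling(cx + r))
  ys <- max(1L, floor(cy - r)):min(sz[1], ceiling(cy + r))
  xg <- matrix(xs, nrow = length(ys), ncol = length(xs), byrow = TRUE) - cx
  yg <- matrix(ys, nrow = length(ys), ncol = length(xs)) - cy
  u <- xg * cos(theta) + yg * sin(theta)
  v <- -xg * sin(theta) + yg * cos(theta)
  d2 <- (u / a)^2 + (v / b)^2
  inside <- d2 <= 1
  if (!any(inside)) return(img)
  cols <- col_fun(sqrt(pmin(d2, 1)), u / a, v / b)   # list(r, g, b) matrices
  for (ch in 1:3) {
    plane <- img[ys, xs, ch]
    plane[inside] <- cols[[ch]][inside]
    img[ys, xs, ch] <- plane
  }
  img
}

pear_color_fun <- function(hue, specular) {
  # radial shading: bright near the off-center highlight, darker at the rim
  function(d, u, v) {
    shade <- 0.95 - 0.5 * d^1.5
    hl <- exp(-(((u + 0.3)^2 + (v + 0.3)^2)) / 0.08)
    val <- pmin(1, shade + specular * 0.6 * hl)
    sat <- 0.75 - 0.25 * hl
    hsv_to_rgb_num(matrix(hue, nrow(d), ncol(d)), sat, val)
  }
}

leaf_color_fun <- function(dark) {
  function(d, u, v) {
    val <- (0.45 - 0.25 * d) * dark
    hsv_to_rgb_num(matrix(0.31, nrow(d), ncol(d)), 0.65, pmax(val, 0.05))
  }
}

# numeric HSV -> RGB (h, s, v in [0,1], h as fraction of the circle)
hsv_to_rgb_num <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6)
  f <- h6 - i
  p <- v * (1 - s); q <- v * (1 - s * f); t <- v * (1 - s * (1 - f))
  r <- v; g <- t; b <- p
  sel <- i == 1; r[sel] <- q[sel]; g[sel] <- v[sel]; b[sel] <- p[sel]
  sel <- i == 2; r[sel] <- p[sel]; g[sel] <- v[sel]; b[sel] <- t[sel]
  sel <- i == 3; r[sel] <- p[sel]; g[sel] <- q[sel]; b[sel] <- v[sel]
  sel <- i == 4; r[sel] <- t[sel]; g[sel] <- p[sel]; b[sel] <- v[sel]
  sel <- i == 5; r[sel] <- v[sel]; g[sel] <- p[sel]; b[sel] <- q[sel]
  list(r, g, b)
}

draw_branch <- function(img, x0, y0, angle, len, width, shade = 0.25) {
  sz <- dim(img)[1:2]
  n <- max(2L, ceiling(len))
  tx <- x0 + cos(angle) * seq(0, len, length.out = n)
  ty <- y0 + sin(angle) * seq(0, len, length.out = n)
  for (i in seq_len(n)) {
    if (tx[i] + width < 1 || tx[i] - width > sz[2] ||
        ty[i] + width < 1 || ty[i] - width > sz[1]) next
    xs <- max(1L, floor(tx[i] - width)):min(sz[2], ceiling(tx[i] + width))
    ys <- max(1L, floor(ty[i] - width)):min(sz[1], ceiling(ty[i] + width))
    img[ys, xs, 1] <- shade * 1.3
    img[ys, xs, 2] <- shade
    img[ys, xs, 3] <- shade * 0.6
  }
  img
}

apply_illumination <- function(img, regime) {
  # NB pmin/pmax take attributes from their first argument: keep the array
  # first so the H x W x 3 dims survive
  switch(regime,
    weak = pmin(pmax(img * 0.55, 0)^1.1, 1),
    normal = img,
    strong = pmin(img * 1.45 + 0.08, 1),
    artificial = {
      sz <- dim(img)[1:2]
      yg <- matrix(seq_len(sz[1]), sz[1], sz[2])
      xg <- matrix(seq_len(sz[2]), sz[1], sz[2], byrow = TRUE)
      vign <- exp(-(((xg - sz[2] / 2)^2 + (yg - sz[1] / 2)^2) /
                      (0.35 * (sz[1]^2 + sz[2]^2))))
      out <- img
      out[, , 1] <- pmin(1, img[, , 1] * 1.2 * (0.35 + 0.65 * vign))
      out[, , 2] <- pmin(1, img[, , 2] * 0.95 * (0.35 + 0.65 * vign))
      out[, , 3] <- pmin(1, img[, , 3] * 0.65 * (0.35 + 0.65 * vign))
      out
    },
    stop("unknown illumination regime: ", regime))
}

#' Render a synthetic orchard scene
#'
#' Deterministic given the spec (including its seed): two calls return
#' bit-identical images and boxes.
#'
#' @param spec a `pn_scene_spec`.
#' @return list with `image` (H x W x 3 array in `[0, 1]`), `boxes`
#'   (`pn_boxes`, normalized, amodal-clipped), and `meta` (tibble: realized
#'   illumination, viewpoint, per-pear radii).
#' @export
#' @examples
#' sc <- render_scene(scene_spec(image_size = 96, n_pears = 3, seed = 1))
#' dim(sc$image)
render_scene <- function(spec) {
  stopifnot(inherits(spec, "pn_scene_spec"))
  sz <- spec$image_size
  rr <- rad_ranges(sz)
  if (spec$n_pears > 0) {
    min_r <- rr[[which(spec$radius_mix > 0)[1]]][1]
    if (spec$n_pears * (2 * min_r)^2 > 4 * sz^2) {
      stop("impossible scene: ", spec$n_pears, " pears of minimum radius ",
           min_r, " px cannot pack into a ", sz, "x", sz, " image")
    }
  }
  with_seed(spec$seed, {
    illum <- if (spec$illumination == "random") {
      sample(c("weak", "normal", "strong", "artificial"), 1)
    } else spec$illumination
    view <- if (spec$viewpoint == "random") {
      sample(c("side", "birdseye"), 1)
    } else spec$viewpoint

    # background: canopy texture of leaf blobs over a green-brown base
    img <- array(0, c(sz, sz, 3))
    base_v <- if (view == "side") {
      0.35 + 0.25 * matrix(rev(seq_len(sz)), sz, sz) / sz   # brighter sky-side
    } else {
      matrix(0.42, sz, sz)
    }
    noise <- matrix(stats::runif(sz * sz, -0.05, 0.05), sz)
    cols <- hsv_to_rgb_num(matrix(0.28, sz, sz), 0.55, pmax(0.05, base_v + noise))
    for (ch in 1:3) img[, , ch] <- cols[[ch]]
    for (i in seq_len(max(3L, sz %/% 24))) {
      img <- draw_ellipse(img, stats::runif(1, 1, sz), stats::runif(1, 1, sz),
                          stats::runif(1, sz / 24, sz / 8),
                          stats::runif(1, sz / 32, sz / 10),
                          stats::runif(1, 0, pi), leaf_color_fun(stats::runif(1, 0.6, 1.1)))
    }
    n_branch <- max(2L, sz %/% 80)
    for (i in seq_len(n_branch)) {
      ang <- if (view == "side") stats::runif(1, -0.4, 0.4) else stats::runif(1, 0, 2 * pi)
      img <- draw_branch(img, stats::runif(1, 1, sz), stats::runif(1, 1, sz),
                         ang, stats::runif(1, sz / 4, sz),
                         stats::runif(1, 1, max(2, sz / 160)))
    }

    # pears
    classes <- sample(names(rr), spec$n_pears, replace = TRUE,
                      prob = spec$radius_mix)
    radii <- vapply(classes, function(cl)
      stats::runif(1, rr[[cl]][1], rr[[cl]][2]), numeric(1))
    specular <- illum %in% c("strong", "artificial")
    recs <- list()
    for (i in seq_len(spec$n_pears)) {
      r <- radii[i]
      cx <- stats::runif(1, 1, sz); cy <- stats::runif(1, 1, sz)
      aspect <- stats::runif(1, 0.8, 1.1)
      a <- r; b <- r * aspect                      # horizontal/vertical semi-axes
      theta <- stats::runif(1, -0.3, 0.3)
      hue <- stats::runif(1, 30 / 360, 75 / 360)
      img <- draw_ellipse(img, cx, cy, a, b, theta, pear_color_fun(hue, specular))
      # amodal extent of the rotated ellipse
      half_w <- sqrt((a * cos(theta))^2 + (b * sin(theta))^2)
      half_h <- sqrt((a * sin(theta))^2 + (b * cos(theta))^2)
      # occluders: cover at most occlusion_fraction of this pear
      if (spec$occlusion_fraction > 0 && stats::runif(1) < 0.8) {
        frac <- stats::runif(1, 0, spec$occlusion_fraction)
        if (frac > 0.02) {
          or_ <- r * sqrt(frac)
          ox <- cx + stats::runif(1, -0.8, 0.8) * r
          oy <- cy + stats::runif(1, -0.8, 0.8) * r
          if (stats::runif(1) < 0.5) {
            img <- draw_ellipse(img, ox, oy, or_ * 1.2, or_ * 0.8,
                                stats::runif(1, 0, pi),
                                leaf_color_fun(stats::runif(1, 0.7, 1)))
          } else {
            img <- draw_branch(img, ox - or_ * 1.5, oy,
                               stats::runif(1, -0.5, 0.5), 3 * or_,
                               max(1, or_ / 2))
          }
        }
      }
      x1 <- max(0, cx - half_w); x2 <- min(sz, cx + half_w)
      y1 <- max(0, cy - half_h); y2 <- min(sz, cy + half_h)
      recs[[i]] <- c(x1, y1, x2, y2, r)
    }
    boxes <- bbox_tibble()
    kept_r <- numeric()
    if (length(recs)) {
      m <- do.call(rbind, recs)
      keep <- pmax(m[, 3] - m[, 1], m[, 4] - m[, 2]) / 2 >= 5
      m <- m[keep, , drop = FALSE]
      kept_r <- m[, 5]
      if (nrow(m)) {
        boxes <- bbox_tibble(0L,
          (m[, 1] + m[, 3]) / 2 / sz, (m[, 2] + m[, 4]) / 2 / sz,
          (m[, 3] - m[, 1]) / sz, (m[, 4] - m[, 2]) / sz)
      }
    }
    img <- apply_illumination(img, illum)
    list(image = img, boxes = boxes,
         meta = tibble::tibble(illumination = illum, viewpoint = view,
                               n_drawn = spec$n_pears, n_kept = nrow(boxes)))
  })
}

# ---- training-time augmentation --------------------------------------------

gauss_blur3 <- function(img) {
  k <- c(1, 2, 1) / 4
  pad <- function(m) cbind(m[, 1], m, m[, ncol(m)])
  padr <- function(m) rbind(m[1, ], m, m[nrow(m), ])
  for (ch in 1:3) {
    m <- img[, , ch]
    mp <- pad(m)
    m <- k[1] * mp[, seq_len(ncol(m))] + k[2] * mp[, 1 + seq_len(ncol(m))] +
      k[3] * mp[, 2 + seq_len(ncol(m))]
    mp <- padr(m)
    m <- k[1] * mp[seq_len(nrow(m)), ] + k[2] * mp[1 + seq_len(nrow(m)), ] +
      k[3] * mp[2 + seq_len(nrow(m)), ]
    img[, , ch] <- m
  }
  img
}

hsv_jitter <- function(img, h_gain = 0.015, s_gain = 0.7, v_gain = 0.4) {
  d <- dim(img)
  rgb <- matrix(aperm(img, c(3, 1, 2)), nrow = 3)
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 1)
  dh <- stats::runif(1, -h_gain, h_gain)
  ds <- 1 + stats::runif(1, -s_gain, s_gain)
  dv <- 1 + stats::runif(1, -v_gain, v_gain)
  out <- hsv_to_rgb_num((hsv[1, ] + dh) %% 1,
                        pmin(1, pmax(0, hsv[2, ] * ds)),
                        pmin(1, pmax(0, hsv[3, ] * dv)))
  res <- array(0, d)
  for (ch in 1:3) res[, , ch] <- matrix(out[[ch]], d[1], d[2])
  res
}

#' Augment an image and its boxes
#'
#' Supported operations: `lr_flip`, `ud_flip`, `hsv`, `blur`, `mosaic`.
#' Flips mirror the box centers; HSV jitter and blur leave boxes untouched;
#' mosaic composes four images into quadrants of one canvas and remaps the
#' boxes accordingly. When `ops` is NULL a random subset is drawn (mosaic
#' only when source images are supplied).
#'
#' @param image H x W x 3 array.
#' @param boxes `pn_boxes`.
#' @param ops character vector of operations, or NULL for a random draw.
#' @param seed integer seed.
#' @param mosaic_sources list of 3 extra `list(image, boxes)` entries
#'   required by mosaic (4 sources total with the primary image).
#' @return list(image, boxes).
#' @export
augment <- function(image, boxes, ops = NULL, seed = 0L,
                    mosaic_sources = NULL) {
  with_seed(seed, {
    if (is.null(ops)) {
      pool <- c("lr_flip", "ud_flip", "hsv", "blur")
      if (!is.null(mosaic_sources)) pool <- c(pool, "mosaic")
      ops <- pool[stats::runif(length(pool)) < 0.5]
    }
    bad <- setdiff(ops, c("lr_flip", "ud_flip", "hsv", "blur", "mosaic"))
    if (length(bad)) stop("unknown augmentation op(s): ", paste(bad, collapse = ", "))
    if ("mosaic" %in% ops) {
      if (length(mosaic_sources) != 3) {
        stop("mosaic requires 4 source images (3 in mosaic_sources)")
      }
      srcs <- c(list(list(image = image, boxes = boxes)), mosaic_sources)
      d <- dim(image)
      canvas <- array(0, d)
      half_h <- d[1] %/% 2L; half_w <- d[2] %/% 2L
      offs <- list(c(0, 0), c(0, 1), c(1, 0), c(1, 1))   # (row, col) quadrant
      new_boxes <- list()
      for (q in 1:4) {
        s <- srcs[[q]]
        ds <- dim(s$image)
        ri <- round(seq(1, ds[1], length.out = half_h))
        ci <- round(seq(1, ds[2], length.out = half_w))
        sub <- s$image[ri, ci, , drop = FALSE]
        rows <- offs[[q]][1] * half_h + seq_len(half_h)
        colsx <- offs[[q]][2] * half_w + seq_len(half_w)
        canvas[rows, colsx, ] <- sub
        if (nrow(s$boxes)) {
          b <- s$boxes
          new_boxes[[q]] <- bbox_tibble(b$class_id,
            b$cx / 2 + offs[[q]][2] * 0.5, b$cy / 2 + offs[[q]][1] * 0.5,
            b$w / 2, b$h / 2, b$conf)
        }
      }
      image <- canvas
      boxes <- if (length(new_boxes)) {
        suppressWarnings(clip_boxes(dplyr::bind_rows(new_boxes)))
      } else bbox_tibble()
      boxes <- boxes[boxes$w > 0 & boxes$h > 0, ]
    }
    if ("lr_flip" %in% ops) {
      image <- image[, rev(seq_len(dim(image)[2])), , drop = FALSE]
      if (nrow(boxes)) boxes$cx <- 1 - boxes$cx
    }
    if ("ud_flip" %in% ops) {
      image <- image[rev(seq_len(dim(image)[1])), , , drop = FALSE]
      if (nrow(boxes)) boxes$cy <- 1 - boxes$cy
    }
    if ("hsv" %in% ops) image <- hsv_jitter(image)
    if ("blur" %in% ops) image <- gauss_blur3(image)
    list(image = image, boxes = boxes)
  })
}

#' Write a synthetic fixture dataset to disk
#'
#' Produces the on-disk layout consumed by training and evaluation:
#' `images/*.png`, `labels/*.txt` (parallel stems), split manifests
#' (`train.txt`, `val.txt`, `test.txt`) and `manifest.json` recording the
#' spec template, seeds and per-stratum box counts.
#'
#' @param n_images number of scenes.
#' @param spec_template a `pn_scene_spec`; its seed field is replaced
#'   per-image by `seed * 1000 + i`.
#' @param seed master seed.
#' @param dir output directory (created).
#' @param ratios train/val/test split ratios.
#' @return invisible tibble index of the dataset (path, split, n_boxes).
#' @export
make_fixture_set <- function(n_images, spec_template = scene_spec(),
                             seed = 0L, dir, ratios = c(0.8, 0.1, 0.1)) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "labels"), recursive = TRUE, showWarnings = FALSE)
  strata <- c(small = 0L, medium = 0L, large = 0L, omitted = 0L)
  recs <- list()
  for (i in seq_len(n_images)) {
    sp <- spec_template
    sp$seed <- as.integer(seed * 1000 + i)
    sc <- render_scene(sp)
    stem <- sprintf("scene_%04d", i)
    png::writePNG(sc$image, file.path(dir, "images", paste0(stem, ".png")))
    write_annotations(sc$boxes, file.path(dir, "labels", paste0(stem, ".txt")))
    scl <- table(size_class(sc$boxes, sp$image_size))
    for (nm in names(scl)) strata[nm] <- strata[nm] + scl[[nm]]
    recs[[i]] <- tibble::tibble(stem = stem, n_boxes = nrow(sc$boxes),
                                illumination = sc$meta$illumination,
                                viewpoint = sc$meta$viewpoint)
  }
  idx <- if (n_images > 0) dplyr::bind_rows(recs) else
    tibble::tibble(stem = character(), n_boxes = integer(),
                   illumination = character(), viewpoint = character())
  if (n_images >= 3) {
    sp <- split_dataset(n_images, ratios, seed)
    idx$split <- as.character(sp$split)
  } else {
    idx$split <- rep("train", n_images)
  }
  for (s in c("train", "val", "test")) {
    writeLines(idx$stem[idx$split == s], file.path(dir, paste0(s, ".txt")))
  }
  jsonlite::write_json(
    list(n_images = n_images, seed = seed,
         image_size = spec_template$image_size,
         illumination = spec_template$illumination,
         viewpoint = spec_template$viewpoint,
         stratum_counts = as.list(strata)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(idx)
}

#' Load a fixture dataset written by [make_fixture_set()]
#'
#' @param dir dataset directory.
#' @param split optional split filter ("train", "val", "test").
#' @return tibble (stem, image_path, label_path, split).
#' @export
load_dataset_index <- function(dir, split = NULL) {
  stems <- list()
  for (s in c("train", "val", "test")) {
    f <- file.path(dir, paste0(s, ".txt"))
    if (file.exists(f)) {
      st <- readLines(f, warn = FALSE)
      st <- st[nzchar(st)]
      if (length(st)) stems[[s]] <- tibble::tibble(stem = st, split = s)
    }
  }
  idx <- dplyr::bind_rows(stems)
  if (!is.null(split)) idx <- idx[idx$split %in% split, ]
  idx$image_path <- file.path(dir, "images", paste0(idx$stem, ".png"))
  idx$label_path <- file.path(dir, "labels", paste0(idx$stem, ".txt"))
  missing <- !file.exists(idx$image_path)
  if (any(missing)) stop("missing image file(s): ",
                         paste(utils::head(idx$image_path[missing], 3), collapse = ", "))
  idx
}
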