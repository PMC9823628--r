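# Near-duplicate image filtering via local features: Harris corner
# keypoints with binary intensity-comparison descriptors, matched by
# Hamming distance. A greedy sequential scan drops any image whose
# descriptor-match ratio against an already-retained image exceeds the
# threshold — the acquisition-cleanup step that thins bursts of
# near-identical frames.

to_gray <- function(img) {
  if (length(dim(img)) == 3) {
    0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  } else img
}

box3 <- function(m) {
  p <- cbind(m[, 1], m, m[, ncol(m)])
  m <- (p[, seq_len(ncol(m))] + p[, 1 + seq_len(ncol(m))] + p[, 2 + seq_len(ncol(m))]) / 3
  p <- rbind(m[1, ], m, m[nrow(m), ])
  (p[seq_len(nrow(m)), ] + p[1 + seq_len(nrow(m)), ] + p[2 + seq_len(nrow(m)), ]) / 3
}

harris_keypoints <- function(gray, n_keypoints = 500L, min_dist = 5L) {
  h <- nrow(gray); w <- ncol(gray)
  dx <- (cbind(gray[, -1], gray[, w]) - cbind(gray[, 1], gray[, -w])) / 2
  dy <- (rbind(gray[-1, ], gray[h, ]) - rbind(gray[1, ], gray[-h, ])) / 2
  sxx <- box3(dx * dx); syy <- box3(dy * dy); sxy <- box3(dx * dy)
  resp <- (sxx * syy - sxy^2) - 0.04 * (sxx + syy)^2
  # exclude a border margin so descriptors fit
  margin <- 8L
  resp[c(seq_len(margin), h - seq_len(margin) + 1L), ] <- -Inf
  resp[, c(seq_len(margin), w - seq_len(margin) + 1L)] <- -Inf
  ord <- order(resp, decreasing = TRUE)
  pts <- matrix(0L, 0, 2)
  for (k in ord) {
    if (nrow(pts) >= n_keypoints) break
    if (!is.finite(resp[k]) || resp[k] <= 0) break
    r <- (k - 1L) %% h + 1L
    cc <- (k - 1L) %/% h + 1L
    if (nrow(pts) == 0 ||
        all((pts[, 1] - r)^2 + (pts[, 2] - cc)^2 >= min_dist^2)) {
      pts <- rbind(pts, c(r, cc))
    }
  }
  pts
}

# fixed intensity-comparison sampling pattern (seeded constant)
brief_pattern <- function(n_bits = 128L, radius = 7L) {
  with_seed(42L, {
    matrix(as.integer(round(stats::rnorm(n_bits * 4, sd = radius / 2))),
           ncol = 4)
  })
}

describe_keypoints <- function(gray, pts, pattern) {
  if (nrow(pts) == 0) return(matrix(FALSE, 0, nrow(pattern)))
  sm <- box3(gray)
  h <- nrow(gray); w <- ncol(gray)
  cl <- function(v, lo, hi) pmin(pmax(v, lo), hi)
  n <- nrow(pts); nb <- nrow(pattern)
  desc <- matrix(FALSE, n, nb)
  for (b in seq_len(nb)) {
    r1 <- cl(pts[, 1] + pattern[b, 1], 1L, h); c1 <- cl(pts[, 2] + pattern[b, 2], 1L, w)
    r2 <- cl(pts[, 1] + pattern[b, 3], 1L, h); c2 <- cl(pts[, 2] + pattern[b, 4], 1L, w)
    desc[, b] <- sm[cbind(r1, c1)] > sm[cbind(r2, c2)]
  }
  desc
}

match_ratio <- function(descA, descB, max_frac = 0.2) {
  if (nrow(descA) == 0 || nrow(descB) == 0) return(0)
  nb <- ncol(descA)
  a <- descA * 1; b <- descB * 1
  # Hamming distance matrix via two inner products
  ham <- nb - tcrossprod(a, b) - tcrossprod(1 - a, 1 - b)
  good <- apply(ham, 1, min) <= max_frac * nb
  mean(good)
}

#' Filter near-duplicate images
#'
#' Greedy sequential scan: each image is kept unless its keypoint-descriptor
#' match ratio against any already-retained image exceeds
#' `similarity_threshold`.
#'
#' @param images list of image arrays (H x W x 3 or grayscale) or file paths.
#' @param similarity_threshold match-ratio cutoff in `[0, 1]` (default 0.6).
#' @param n_keypoints keypoints per image (default 500).
#' @return integer vector of retained indices.
#' @export
dedup_filter <- function(images, similarity_threshold = 0.6,
                         n_keypoints = 500L) {
  stopifnot(length(images) >= 1)
  pat <- brief_pattern()
  descs <- lapply(images, function(im) {
    if (is.character(im)) im <- png::readPNG(im)
    g <- to_gray(im)
    describe_keypoints(g, harris_keypoints(g, n_keypoints), pat)
  })
  kept <- integer()
  for (i in seq_along(descs)) {
    dup <- FALSE
    for (j in kept) {
      if (match_ratio(descs[[i]], descs[[j]]) > similarity_threshold) {
        dup <- TRUE
        break
      }
    }
    if (!dup) kept <- c(kept, i)
  }
  kept
}
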