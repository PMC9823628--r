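# The synthetic scene generator and the augmentation stack.

test_that("rendering is bit-reproducible and respects the spec", {
  sp <- scene_spec(image_size = 96, n_pears = 5, seed = 9)
  a <- render_scene(sp)
  b <- render_scene(sp)
  expect_identical(a$image, b$image)
  expect_identical(a$boxes, b$boxes)
  empty <- render_scene(scene_spec(image_size = 96, n_pears = 0, seed = 1))
  expect_equal(nrow(empty$boxes), 0)
  expect_equal(dim(empty$image), c(96, 96, 3))
  expect_error(render_scene(scene_spec(image_size = 64, n_pears = 500,
                                       radius_mix = c(0, 0, 1), seed = 1)),
               "impossible scene")
})

test_that("ground truth stays inside bounds with no sub-threshold pears", {
  for (s in 1:10) {
    sc <- render_scene(scene_spec(image_size = 96, n_pears = 8,
                                  occlusion_fraction = 0.5,
                                  illumination = "random",
                                  viewpoint = "random", seed = s))
    b <- sc$boxes
    if (!nrow(b)) next
    expect_true(all(b$cx - b$w / 2 >= -1e-9 & b$cx + b$w / 2 <= 1 + 1e-9))
    expect_true(all(b$cy - b$h / 2 >= -1e-9 & b$cy + b$h / 2 <= 1 + 1e-9))
    expect_true(all(pmax(b$w, b$h) * 96 / 2 >= 5))
    expect_true(all(sc$image >= 0 & sc$image <= 1))
  }
})

test_that("an all-large radius mixture yields only large size labels", {
  for (s in 1:20) {
    sc <- render_scene(scene_spec(image_size = 256, n_pears = 4,
                                  radius_mix = c(0, 0, 1),
                                  occlusion_fraction = 0, seed = 400 + s))
    if (!nrow(sc$boxes)) next
    expect_true(all(size_class(sc$boxes, 256) == "large"))
  }
})

test_that("illumination regimes order mean brightness weak < normal < strong", {
  for (s in 1:5) {
    mk <- function(il) mean(render_scene(scene_spec(
      image_size = 96, n_pears = 5, illumination = il, seed = 500 + s))$image)
    expect_lt(mk("weak"), mk("normal"))
    expect_lt(mk("normal"), mk("strong"))
  }
})

test_that("flips are involutions that preserve box areas; blur keeps boxes", {
  sc <- render_scene(scene_spec(image_size = 96, n_pears = 5, seed = 31))
  a1 <- augment(sc$image, sc$boxes, ops = "lr_flip", seed = 1)
  a2 <- augment(a1$image, a1$boxes, ops = "lr_flip", seed = 2)
  expect_equal(a2$image, sc$image)
  expect_equal(a2$boxes$cx, sc$boxes$cx, tolerance = 1e-12)
  expect_equal(a1$boxes$w * a1$boxes$h, sc$boxes$w * sc$boxes$h)
  u1 <- augment(sc$image, sc$boxes, ops = "ud_flip", seed = 3)
  expect_equal(u1$boxes$cy, 1 - sc$boxes$cy)
  bl <- augment(sc$image, sc$boxes, ops = "blur", seed = 4)
  expect_identical(bl$boxes, sc$boxes)
  expect_false(identical(bl$image, sc$image))
  hs <- augment(sc$image, sc$boxes, ops = "hsv", seed = 5)
  expect_identical(hs$boxes, sc$boxes)
  expect_error(augment(sc$image, sc$boxes, ops = "sharpen", seed = 1),
               "unknown augmentation")
})

test_that("mosaic maps each source's boxes into its quadrant", {
  scs <- lapply(1:4, function(i) {
    sc <- render_scene(scene_spec(image_size = 64, n_pears = 1,
                                  radius_mix = c(0, 1, 0),
                                  occlusion_fraction = 0, seed = 600 + i))
    list(image = sc$image, boxes = sc$boxes)
  })
  expect_error(augment(scs[[1]]$image, scs[[1]]$boxes, ops = "mosaic",
                       mosaic_sources = scs[2:3]), "4 source")
  mo <- augment(scs[[1]]$image, scs[[1]]$boxes, ops = "mosaic", seed = 6,
                mosaic_sources = scs[2:4])
  expect_equal(dim(mo$image), c(64, 64, 3))
  expect_lte(nrow(mo$boxes), 4)
  # every composed box sits inside the canvas and within one quadrant's span
  expect_true(all(mo$boxes$cx - mo$boxes$w / 2 >= -1e-9 &
                    mo$boxes$cx + mo$boxes$w / 2 <= 1 + 1e-9))
  expect_true(all(mo$boxes$w <= 0.5 + 1e-9 & mo$boxes$h <= 0.5 + 1e-9))
  # sources 1..4 land in quadrants (TL, TR, BL, BR): source 1 maps to
  # exactly half of its original coordinates
  b1 <- scs[[1]]$boxes
  offs <- list(c(0, 0), c(0, 0.5), c(0.5, 0), c(0.5, 0.5))
  for (q in 1:4) {
    bq <- scs[[q]]$boxes
    if (!nrow(bq)) next
    expect_true(any(abs(mo$boxes$cx - (bq$cx / 2 + offs[[q]][2])) < 1e-9 &
                      abs(mo$boxes$cy - (bq$cy / 2 + offs[[q]][1])) < 1e-9))
  }
})

test_that("fixture sets are reproducible on disk with consistent manifests", {
  d1 <- file.path(tempdir(), "fx1"); d2 <- file.path(tempdir(), "fx2")
  unlink(c(d1, d2), recursive = TRUE)
  sp <- scene_spec(image_size = 64, n_pears = 4, seed = 0)
  idx1 <- make_fixture_set(6, sp, seed = 3, dir = d1)
  idx2 <- make_fixture_set(6, sp, seed = 3, dir = d2)
  expect_identical(idx1, idx2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(unname(tools::md5sum(file.path(d1, f1))),
                   unname(tools::md5sum(file.path(d2, f1))))
  # manifest stratum counts equal a recount over the emitted labels
  mf <- jsonlite::read_json(file.path(d1, "manifest.json"))
  recount <- c(small = 0L, medium = 0L, large = 0L, omitted = 0L)
  for (lf in list.files(file.path(d1, "labels"), full.names = TRUE)) {
    b <- suppressWarnings(read_annotations(lf))
    if (nrow(b)) {
      tb <- table(size_class(b, 64))
      for (nm in names(tb)) recount[nm] <- recount[nm] + tb[[nm]]
    }
  }
  expect_equal(unlist(mf$stratum_counts)[names(recount)], recount)
  # empty set still yields a valid layout
  d0 <- file.path(tempdir(), "fx0"); unlink(d0, recursive = TRUE)
  make_fixture_set(0, sp, seed = 1, dir = d0)
  expect_true(dir.exists(file.path(d0, "images")))
  expect_true(file.exists(file.path(d0, "train.txt")))
})
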