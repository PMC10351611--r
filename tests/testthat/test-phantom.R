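# Synthetic phantom generator: determinism, stone geometry, dataset
# manifests, stratified splits, and the class-separation property that makes
# the weak-localization task well-posed.

test_that("identical configs give bit-identical phantoms", {
  cfg <- phantom_config(width = 64L, height = 64L, seed = 42L)
  a <- generate_phantom(cfg, with_stone = TRUE)
  b <- generate_phantom(cfg, with_stone = TRUE)
  expect_identical(a$image, b$image)
  expect_identical(a$gt_box, b$gt_box)
  cfg2 <- phantom_config(width = 64L, height = 64L, seed = 43L)
  expect_false(identical(generate_phantom(cfg2, TRUE)$image, a$image))
})

test_that("stone geometry and labelling contracts hold", {
  for (seed in 1:20) {
    cfg <- phantom_config(width = 64L, height = 64L,
                          stone_radius_range = c(2, 4), seed = seed)
    sl <- generate_phantom(cfg, with_stone = TRUE)
    expect_identical(sl$label, 1L)
    expect_s3_class(sl$gt_box, "bounding_box")
    expect_true(all(sl$image >= 0 & sl$image <= 1))
    b <- sl$gt_box
    # box inside image bounds
    expect_gte(b$x_min, 0); expect_gte(b$y_min, 0)
    expect_lte(b$x_max, 64); expect_lte(b$y_max, 64)
    # box inside the duct region rectangle
    duct <- cfg$duct_region * 64
    expect_gte(b$x_min, duct[1] - 1e-9); expect_lte(b$x_max, duct[3] + 1e-9)
    expect_gte(b$y_min, duct[2] - 1e-9); expect_lte(b$y_max, duct[4] + 1e-9)
    # stone is brighter than a 2x-dilated ring around its box
    px <- sl$image
    inside <- px[(b$y_min + 1):b$y_max, (b$x_min + 1):b$x_max]
    bw <- b$x_max - b$x_min; bh <- b$y_max - b$y_min
    ry <- max(1, b$y_min + 1 - bh):min(64, b$y_max + bh)
    rx <- max(1, b$x_min + 1 - bw):min(64, b$x_max + bw)
    ring <- px[ry, rx]
    ring_mean <- (sum(ring) - sum(inside)) /
      (length(ring) - length(inside))
    expect_gt(mean(inside), ring_mean)
    # normals carry no box
    nl <- generate_phantom(cfg, with_stone = FALSE)
    expect_identical(nl$label, 0L)
    expect_null(nl$gt_box)
  }
})

test_that("stone pixel count agrees with the ellipse-area oracle", {
  for (seed in 1:10) {
    cfg <- phantom_config(width = 64L, height = 64L,
                          stone_radius_range = c(2, 4), noise_sd = 0,
                          seed = seed)
    with_st <- generate_phantom(cfg, TRUE)
    cfg_n <- cfg
    no_st <- generate_phantom(cfg_n, FALSE)
    # brute-force pixel scan of the added stone mass
    added <- with_st$image - no_st$image
    n_px <- sum(added > cfg$stone_contrast / 2)
    expect_gte(n_px, pi * 2^2 * 0.5)
    expect_lte(n_px, pi * 4^2 * 1.5)
  }
})

test_that("dataset generation writes a re-readable manifest with the 1:2 default", {
  dir <- withr::local_tempdir()
  cfg <- phantom_config(width = 32L, height = 32L, seed = 7L,
                        stone_radius_range = c(2, 4))
  man <- generate_dataset(10, config = cfg, out_dir = dir)
  expect_identical(nrow(man), 30L)
  expect_identical(sum(man$label == 1), 10L)
  expect_false(any(duplicated(man$image_id)))
  # round trip from disk equals the in-memory manifest
  man2 <- read_manifest(file.path(dir, "manifest.csv"))
  expect_identical(man2$image_id, man$image_id)
  expect_identical(man2$label, man$label)
  # images re-read within 8-bit quantisation
  img <- read_image(man$path[1])
  expect_true(all(img >= 0 & img <= 1))
  boxes <- read_boxes(file.path(dir, "boxes.csv"))
  expect_identical(length(boxes), 10L)
  # empty stone set
  dir2 <- withr::local_tempdir()
  man0 <- generate_dataset(0, 5, cfg, dir2)
  expect_identical(nrow(man0), 5L)
  expect_true(all(man0$label == 0))
  expect_false(file.exists(file.path(dir2, "boxes.csv")))
})

test_that("dataset generation is deterministic across calls", {
  cfg <- phantom_config(width = 32L, height = 32L, seed = 3L,
                        stone_radius_range = c(2, 4))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- generate_dataset(3, config = cfg, out_dir = d1)
  m2 <- generate_dataset(3, config = cfg, out_dir = d2)
  expect_identical(m1$image_id, m2$image_id)
  for (i in seq_len(nrow(m1)))
    expect_identical(readBin(m1$path[i], "raw", 1e6),
                     readBin(m2$path[i], "raw", 1e6))
})

test_that("stratified splits are disjoint, exhaustive and ratio-preserving", {
  man <- data.frame(image_id = sprintf("im%02d", 1:30),
                    path = sprintf("im%02d.png", 1:30),
                    label = rep(c(1L, 0L), c(10, 20)))
  sp <- split_dataset(man, train_frac = 0.7, seed = 5)
  expect_identical(nrow(sp$train), 21L)
  expect_identical(nrow(sp$test), 9L)
  expect_identical(nrow(sp$val), 0L)
  expect_lte(abs(sum(sp$train$label == 1) - 7), 1)
  expect_setequal(c(sp$train$image_id, sp$test$image_id), man$image_id)
  expect_length(intersect(sp$train$image_id, sp$test$image_id), 0)
  # full training fraction leaves the test split empty
  sp2 <- split_dataset(man, train_frac = 1.0, seed = 5)
  expect_identical(nrow(sp2$test), 0L)
  expect_error(split_dataset(man, train_frac = 0.8, val_frac = 0.4),
               "fractions")
})

test_that("stone boxes are brighter than random boxes in normal images", {
  # class-separation sanity over >= 50 phantoms
  cfg0 <- phantom_config(width = 48L, height = 48L,
                         stone_radius_range = c(2, 5))
  stone_peaks <- numeric(50)
  rand_peaks <- numeric(50)
  set.seed(99)
  for (k in 1:50) {
    cfg <- cfg0; cfg$seed <- 1000L + k
    st <- generate_phantom(cfg, TRUE)
    b <- st$gt_box
    stone_peaks[k] <- mean(st$image[(b$y_min + 1):b$y_max,
                                    (b$x_min + 1):b$x_max])
    no <- generate_phantom(cfg, FALSE)
    bw <- b$x_max - b$x_min; bh <- b$y_max - b$y_min
    x0 <- sample(48 - bw, 1); y0 <- sample(48 - bh, 1)
    rand_peaks[k] <- mean(no$image[y0 + seq_len(bh), x0 + seq_len(bw)])
  }
  expect_gt(mean(stone_peaks), mean(rand_peaks))
})

test_that("invalid phantom configs are rejected", {
  expect_error(phantom_config(width = 16), ">= 32")
  expect_error(phantom_config(stone_radius_range = c(0.5, 4)), "radius")
  expect_error(phantom_config(stone_radius_range = c(2, 40)), "radius")
  expect_error(phantom_config(stone_contrast = 0), "contrast")
  expect_error(phantom_config(noise_sd = -1), "noise")
  expect_error(phantom_config(duct_region = c(0.5, 0.2, 0.4, 0.8)),
               "duct_region")
})
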