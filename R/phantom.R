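# Synthetic phantom slices: smooth tissue-like background plus bright
# bone-like distractor structures in every image, and -- for positive images
# -- one small bright elliptical stone confined to a duct region.  The
# distractors are at least as bright as the stone and always lie outside the
# duct region, reproducing the failure mode that defeats saliency-only
# localization: the brightest structures are not the target.

local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  parent <- parent.frame()
  defer_expr <- if (is.null(old))
    quote(rm(".Random.seed", envir = globalenv())) else
    bquote(assign(".Random.seed", .(old), globalenv()))
  do.call(on.exit, list(defer_expr, add = TRUE), envir = parent)
}

#' Phantom generation configuration
#'
#' @param width,height image size in pixels (>= 32).
#' @param stone_radius_range min and max semi-axis of the stone ellipse in
#'   pixels; max must be below `min(width, height) / 4`.
#' @param stone_contrast intensity uplift of the stone over its local
#'   background (> 0).
#' @param duct_region normalised rectangle `(x_min, y_min, x_max, y_max)` in
#'   `[0, 1]` within which stones may appear.
#' @param n_distractors number of bright bone-like rings/discs placed
#'   outside the duct region.
#' @param noise_sd standard deviation of the i.i.d. Gaussian pixel noise.
#' @param seed integer seed; identical configs yield bit-identical phantoms.
#' @return validated list of class `phantom_config`.
#' @export
phantom_config <- function(width = 96L, height = 96L,
                           stone_radius_range = c(2, 6),
                           stone_contrast = 0.35,
                           duct_region = c(0.3, 0.3, 0.7, 0.7),
                           n_distractors = 3L, noise_sd = 0.02, seed = 1L) {
  if (width < 32 || height < 32)
    stop("width and height must be >= 32", call. = FALSE)
  if (stone_radius_range[1] < 1 ||
      stone_radius_range[2] >= min(width, height) / 4 ||
      stone_radius_range[2] < stone_radius_range[1])
    stop("stone_radius_range must satisfy 1 <= min <= max < min(W,H)/4",
         call. = FALSE)
  if (stone_contrast <= 0) stop("stone_contrast must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (length(duct_region) != 4 || any(duct_region < 0) ||
      any(duct_region > 1) || duct_region[1] >= duct_region[3] ||
      duct_region[2] >= duct_region[4])
    stop("duct_region must be a normalised (x_min,y_min,x_max,y_max) rect",
         call. = FALSE)
  cfg <- list(width = as.integer(width), height = as.integer(height),
              stone_radius_range = as.numeric(stone_radius_range),
              stone_contrast = stone_contrast,
              duct_region = as.numeric(duct_region),
              n_distractors = as.integer(n_distractors),
              noise_sd = noise_sd, seed = as.integer(seed))
  class(cfg) <- "phantom_config"
  cfg
}

# small separable Gaussian blur (sigma in pixels), reflecting edges
blur2d <- function(x, sigma = 0.8, radius = 2L) {
  k <- exp(-((-radius):radius)^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad_idx <- function(n) pmin(pmax(seq_len(n + 2L * radius) - radius, 1L), n)
  smooth1 <- function(m) {       # blur down columns
    mp <- m[pad_idx(nrow(m)), , drop = FALSE]
    out <- 0 * m
    for (t in seq_along(k))
      out <- out + k[t] * mp[t:(t + nrow(m) - 1L), , drop = FALSE]
    out
  }
  t(smooth1(t(smooth1(x))))
}

# low-frequency random field in [0, 1] from a few random cosine waves
smooth_field <- function(h, w) {
  yy <- matrix(seq_len(h) / h, h, w)
  xx <- matrix(rep(seq_len(w) / w, each = h), h, w)
  f <- matrix(0, h, w)
  for (k in 1:3) {
    fr <- stats::runif(2, 0.5, 2.5)
    ph <- stats::runif(2, 0, 2 * pi)
    f <- f + cos(2 * pi * fr[1] * xx + ph[1]) * cos(2 * pi * fr[2] * yy + ph[2])
  }
  (f - min(f)) / (max(f) - min(f) + 1e-12)
}

duct_rect_px <- function(config) {
  c(x_min = config$duct_region[1] * config$width,
    y_min = config$duct_region[2] * config$height,
    x_max = config$duct_region[3] * config$width,
    y_max = config$duct_region[4] * config$height)
}

#' Generate one phantom slice
#'
#' Deterministic given `config$seed`.  Positive slices contain exactly one
#' elliptical stone (Gaussian-smoothed edge, intensity
#' `local background + stone_contrast`) inside the duct region; its tight
#' bounding box (0-based, half-open) is recorded as ground truth.  Bright
#' distractors appear in both classes.
#'
#' @param config a [phantom_config()].
#' @param with_stone logical; place a stone and set the label to 1.
#' @return object of class `labeled_slice`: list with `image` (H x W matrix
#'   in `[0, 1]`), `label`, `gt_box` (`NULL` for normals) and `image_id`.
#' @export
generate_phantom <- function(config, with_stone = FALSE) {
  stopifnot(inherits(config, "phantom_config"))
  local_seed(config$seed)
  h <- config$height; w <- config$width
  img <- 0.15 + 0.3 * smooth_field(h, w)

  # pixel-centre coordinates, 0-based (x = column, y = row)
  xs <- matrix(rep(seq_len(w) - 1, each = h), h, w)
  ys <- matrix(seq_len(h) - 1, h, w)
  duct <- duct_rect_px(config)

  # bone-like distractors fully outside the duct region; the preferred
  # clearance (radius + 4 px) relaxes to the bare radius when the image is
  # too small to honour it
  for (k in seq_len(config$n_distractors)) {
    r <- stats::runif(1, 2.5, max(3, min(h, w) / 10))
    clear <- r + 4
    tries <- 0L
    repeat {
      cx <- stats::runif(1, r, w - 1 - r)
      cy <- stats::runif(1, r, h - 1 - r)
      if (cx < duct["x_min"] - clear || cx > duct["x_max"] + clear ||
          cy < duct["y_min"] - clear || cy > duct["y_max"] + clear) break
      tries <- tries + 1L
      if (tries %% 100L == 0L) clear <- max(r, clear * 0.8)
      if (tries > 1000L) { r <- r * 0.8; clear <- r }
    }
    dist <- sqrt((xs - cx)^2 + (ys - cy)^2)
    amp <- stats::runif(1, 0.85, 1)
    mask <- if (stats::runif(1) < 0.5) dist <= r else
      (dist <= r & dist >= r - 2.5)
    img[mask] <- amp
  }

  gt_box <- NULL
  if (with_stone) {
    rr <- config$stone_radius_range
    a <- stats::runif(1, rr[1], rr[2])
    b <- stats::runif(1, rr[1], rr[2])
    th <- stats::runif(1, 0, pi)
    m <- max(a, b) + 1
    cx <- stats::runif(1, duct["x_min"] + m, duct["x_max"] - m)
    cy <- stats::runif(1, duct["y_min"] + m, duct["y_max"] - m)
    u <- (xs - cx) * cos(th) + (ys - cy) * sin(th)
    v <- -(xs - cx) * sin(th) + (ys - cy) * cos(th)
    mask <- (u / a)^2 + (v / b)^2 <= 1
    img <- img + config$stone_contrast * blur2d(mask + 0)
    cols <- range(xs[mask]); rows <- range(ys[mask])
    gt_box <- bounding_box(cols[1], rows[1], cols[2] + 1, rows[2] + 1)
  }

  if (config$noise_sd > 0)
    img <- img + stats::rnorm(h * w, sd = config$noise_sd)
  img <- pmin(pmax(img, 0), 1)
  structure(list(image = img, label = as.integer(with_stone),
                 gt_box = gt_box,
                 image_id = sprintf("phantom_%d_%d", config$seed,
                                    as.integer(with_stone))),
            class = "labeled_slice")
}

#' Generate a phantom dataset on disk
#'
#' Writes 8-bit grayscale PNGs, a manifest CSV (`image_id,path,label`) and a
#' ground-truth box CSV (`image_id,x_min,y_min,x_max,y_max`) to `out_dir`.
#' Following the curated 1:2 class ratio, `n_normal` defaults to
#' `2 * n_stone`.
#'
#' @param n_stone number of stone-containing slices.
#' @param n_normal number of normal slices; default `2 * n_stone`.
#' @param config a [phantom_config()]; per-image seeds are derived from
#'   `config$seed`.
#' @param out_dir output directory (created if needed).
#' @return the manifest `data.frame` (`image_id`, `path`, `label`), with the
#'   ground-truth boxes attached as attribute `"boxes"`.
#' @export
generate_dataset <- function(n_stone, n_normal = NULL, config = phantom_config(),
                             out_dir) {
  stopifnot(n_stone >= 0)
  if (is.null(n_normal)) n_normal <- 2L * n_stone
  stopifnot(n_normal >= 0)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  n <- n_stone + n_normal
  labels <- rep(c(1L, 0L), c(n_stone, n_normal))
  ids <- sprintf("slice_%03d_%s", seq_len(n), ifelse(labels == 1, "s", "n"))
  paths <- file.path(out_dir, paste0(ids, ".png"))
  boxes <- NULL
  for (i in seq_len(n)) {
    ci <- config
    ci$seed <- (config$seed %% 20000L) * 100000L + i
    sl <- generate_phantom(ci, with_stone = labels[i] == 1L)
    png::writePNG(sl$image, paths[i])
    if (labels[i] == 1L)
      boxes <- rbind(boxes, data.frame(image_id = ids[i],
                                       x_min = sl$gt_box$x_min,
                                       y_min = sl$gt_box$y_min,
                                       x_max = sl$gt_box$x_max,
                                       y_max = sl$gt_box$y_max))
  }
  manifest <- data.frame(image_id = ids, path = paths, label = labels,
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  if (!is.null(boxes))
    utils::write.csv(boxes, file.path(out_dir, "boxes.csv"),
                     row.names = FALSE)
  attr(manifest, "boxes") <- boxes
  manifest
}

#' Stratified dataset split
#'
#' Splits a manifest into train/val/test partitions, stratified by label,
#' disjoint and exhaustive.
#'
#' @param manifest manifest `data.frame` with columns `image_id`, `path`,
#'   `label`.
#' @param train_frac,val_frac positive fractions with
#'   `train_frac + val_frac <= 1`; the remainder is the test split.
#' @param seed integer seed for the shuffle.
#' @return list of manifests `train`, `val`, `test`.
#' @export
split_dataset <- function(manifest, train_frac = 0.7, val_frac = 0,
                          seed = 1L) {
  if (train_frac <= 0 || val_frac < 0 || train_frac + val_frac > 1)
    stop("fractions must be positive and sum to at most 1", call. = FALSE)
  local_seed(seed)
  idx_tr <- integer(0); idx_va <- integer(0)
  for (lab in unique(manifest$label)) {
    ii <- sample(which(manifest$label == lab))
    n_tr <- round(length(ii) * train_frac)
    n_va <- round(length(ii) * val_frac)
    n_va <- min(n_va, length(ii) - n_tr)
    idx_tr <- c(idx_tr, ii[seq_len(n_tr)])
    if (n_va > 0) idx_va <- c(idx_va, ii[n_tr + seq_len(n_va)])
  }
  idx_te <- setdiff(seq_len(nrow(manifest)), c(idx_tr, idx_va))
  keep <- function(ii) {
    m <- manifest[sort(ii), , drop = FALSE]
    rownames(m) <- NULL
    attr(m, "boxes") <- attr(manifest, "boxes")
    m
  }
  list(train = keep(idx_tr), val = keep(idx_va), test = keep(idx_te))
}
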