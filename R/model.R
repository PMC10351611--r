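# Network definition: parameter initialisation, forward pass through the
# multiple field-of-view encoder, attention-driven decoder and classification
# head, and the exact hand-derived backward pass used for training.

## ---- broadcasting helpers ----------------------------------------------

# multiply every channel c of an H x W x C cube by scalar v[c]
mul_channel <- function(x, v) {
  stopifnot(length(v) == dim(x)[3])
  cpp_scale_channels(x, v)
}

# multiply every channel of an H x W x C cube elementwise by an H x W map
mul_spatial <- function(x, m) {
  stopifnot(length(m) == dim(x)[1] * dim(x)[2])
  cpp_scale_spatial(x, m)
}

sum_channels <- function(x) {     # H x W x C -> H x W
  d <- dim(x)
  matrix(rowSums(matrix(x, d[1] * d[2], d[3])), d[1], d[2])
}

sum_pixels <- function(x) {       # H x W x C -> length-C vector
  d <- dim(x)
  colSums(matrix(x, d[1] * d[2], d[3]))
}

gap_vec <- function(x) {          # spatial global average pooling
  d <- dim(x)
  colMeans(matrix(x, d[1] * d[2], d[3]))
}

# non-overlapping p x p adaptive average pooling of an H x H map
avgpool2d <- function(x, p) {
  f <- nrow(x) %/% p
  r <- matrix(colMeans(matrix(x, f)), p, ncol(x))
  t(matrix(colMeans(matrix(t(r), f)), p, p))
}

avgpool2d_bwd <- function(dz, H) {
  f <- H %/% nrow(dz)
  dz[rep(seq_len(nrow(dz)), each = f), rep(seq_len(ncol(dz)), each = f)] / f^2
}

## ---- parameters ---------------------------------------------------------

# every tensor draws from its own seed stream so that resizing or removing
# one component (an ablation) leaves all other initial weights bit-identical
tensor_registry <- c("b1c1", "b1c2", "b2c1", "b2c2", "b3c1", "b3c2",
                     "md1", "md2", "md3", "md4",
                     "u1", "u2", "u3", "u4", "fc2", "sa", "pm",
                     "cls1", "cls2", "cls3", "fc1")

with_tensor_seed <- function(config, name, expr) {
  idx <- match(name, tensor_registry)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                     globalenv()) else NULL
  set.seed((config$seed %% 1000000L) * 1000L + idx)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  force(expr)
}

param_shapes <- function(config) {
  ch <- config$channels
  cd <- config$cd
  ce <- if (config$use_mfov) 4L * cd + ch[3] else ch[3]
  n_in <- if (is.null(config$classifier_pool)) config$image_size^2 else
    config$classifier_pool^2
  hid <- config$classifier_hidden
  sh <- list(
    b1c1 = c(3, 3, 1, ch[1]),  b1c2 = c(3, 3, ch[1], ch[1]),
    b2c1 = c(3, 3, ch[1], ch[2]), b2c2 = c(3, 3, ch[2], ch[2]),
    b3c1 = c(3, 3, ch[2], ch[3]), b3c2 = c(3, 3, ch[3], ch[3]),
    u1 = c(3, 3, ce, 64), u2 = c(3, 3, 64, 64), u3 = c(3, 3, 64, 64),
    u4 = c(1, 1, 64, 64),
    fc2 = c(ch[2], 64),
    sa = c(7, 7, 2, 1), pm = c(1, 1, 64, 1),
    cls1 = c(n_in, hid), cls2 = c(hid, hid), cls3 = c(hid, 2))
  # the block-1 connection is a plain GAP when block 1 already has 64
  # channels; otherwise a dense map matches the dimension (as for block 2)
  if (ch[1] != 64L) sh$fc1 <- c(ch[1], 64)
  if (config$use_mfov) {
    md <- list(md1 = c(3, 3, ch[3], cd), md2 = c(3, 3, ch[3] + cd, cd),
               md3 = c(3, 3, ch[3] + cd, cd), md4 = c(3, 3, ch[3] + cd, cd))
    sh <- c(sh, md)
  }
  sh
}

#' Initialise network parameters
#'
#' He-normal initialisation of every trainable tensor, each from its own
#' seed stream derived from `config$seed`, so two configs differing only in
#' one component share bit-identical initial weights elsewhere.
#'
#' @param config a [model_config()].
#' @return named list of weight matrices/vectors.
#' @export
init_params <- function(config) {
  sh <- param_shapes(config)
  params <- list()
  for (nm in names(sh)) {
    s <- sh[[nm]]
    if (length(s) == 4L) {          # convolution
      params[[paste0(nm, "_w")]] <- with_tensor_seed(config, nm,
        init_conv(s[1], s[2], s[3], s[4]))
      params[[paste0(nm, "_b")]] <- numeric(s[4])
    } else {                        # dense
      params[[paste0(nm, "_w")]] <- with_tensor_seed(config, nm,
        init_dense(s[1], s[2]))
      params[[paste0(nm, "_b")]] <- numeric(s[2])
    }
  }
  for (k in 1:3) {                  # instance-norm affine parameters
    params[[paste0("in", k, "_g")]] <- rep(1, 64)
    params[[paste0("in", k, "_b")]] <- numeric(64)
  }
  params
}

#' Count trainable parameters
#'
#' @param config a [model_config()].
#' @param by_tensor return the per-tensor counts instead of the total.
#' @return integer total (or named integer vector).
#' @export
count_parameters <- function(config, by_tensor = FALSE) {
  sh <- param_shapes(config)
  n <- integer(0)
  for (nm in names(sh)) {
    s <- sh[[nm]]
    n[paste0(nm, "_w")] <- prod(s)
    n[paste0(nm, "_b")] <- s[length(s)]
  }
  for (k in 1:3) {
    n[paste0("in", k, "_g")] <- 64L
    n[paste0("in", k, "_b")] <- 64L
  }
  if (by_tensor) n else sum(n)
}

## ---- backbone -----------------------------------------------------------

#' Backbone forward pass
#'
#' Three VGG-style blocks of two same-padded 3x3 convolutions with ReLU,
#' 2x2 max pooling after the first two blocks and dropout after each block
#' (training mode only).  The block-1 and block-2 outputs are kept for the
#' decoder's forward connections.
#'
#' @param image H x W matrix with intensities in `[0, 1]`, H and W divisible
#'   by 4.
#' @param params parameter list from [init_params()].
#' @param config a [model_config()].
#' @param train logical; activates dropout (draws from the current RNG
#'   stream).
#' @return list with `f_b` (H/4 x W/4 x C3), `block1` (H x W x C1),
#'   `block2` (H/2 x W/2 x C2) and an internal cache.
#' @export
backbone_forward <- function(image, params, config, train = FALSE) {
  d <- dim(image)
  if (d[1] %% 4 != 0 || d[2] %% 4 != 0)
    stop("image height and width must be divisible by 4", call. = FALSE)
  p <- config$dropout
  cache <- list()
  block <- function(x, w1, b1, w2, b2, tag) {
    c1 <- conv_fwd(x, w1, b1, 3, 3)
    r1 <- relu_fwd(c1$out)
    c2 <- conv_fwd(r1$out, w2, b2, 3, 3)
    r2 <- relu_fwd(c2$out)
    cache[[tag]] <<- list(c1 = c1$cache, r1 = r1$cache, c2 = c2$cache,
                          r2 = r2$cache)
    r2$out
  }
  block1 <- block(image, params$b1c1_w, params$b1c1_b, params$b1c2_w,
                  params$b1c2_b, "b1")
  do1 <- dropout_fwd(block1, p, train)
  p1 <- maxpool_fwd(do1$out, 2L)
  block2 <- block(p1$out, params$b2c1_w, params$b2c1_b, params$b2c2_w,
                  params$b2c2_b, "b2")
  do2 <- dropout_fwd(block2, p, train)
  p2 <- maxpool_fwd(do2$out, 2L)
  block3 <- block(p2$out, params$b3c1_w, params$b3c1_b, params$b3c2_w,
                  params$b3c2_b, "b3")
  do3 <- dropout_fwd(block3, p, train)
  cache$do1 <- do1$cache; cache$do2 <- do2$cache; cache$do3 <- do3$cache
  cache$p1 <- p1$cache; cache$p2 <- p2$cache
  list(f_b = do3$out, block1 = block1, block2 = block2, cache = cache)
}

backbone_backward <- function(df_b, dblock1_extra, dblock2_extra, bb, params) {
  cc <- bb$cache
  block_bwd <- function(dy, tag, w1, w2) {
    dy <- relu_bwd(dy, cc[[tag]]$r2)
    g2 <- conv_bwd(dy, cc[[tag]]$c2)
    dy <- relu_bwd(g2$dx, cc[[tag]]$r1)
    g1 <- conv_bwd(dy, cc[[tag]]$c1)
    list(dx = g1$dx, g1 = g1, g2 = g2)
  }
  grads <- list()
  d3 <- dropout_bwd(df_b, cc$do3)
  r3 <- block_bwd(d3, "b3")
  grads$b3c1_w <- r3$g1$dw; grads$b3c1_b <- r3$g1$db
  grads$b3c2_w <- r3$g2$dw; grads$b3c2_b <- r3$g2$db
  dp2 <- maxpool_bwd(r3$dx, cc$p2)
  dblock2 <- dropout_bwd(dp2, cc$do2) + dblock2_extra
  r2 <- block_bwd(dblock2, "b2")
  grads$b2c1_w <- r2$g1$dw; grads$b2c1_b <- r2$g1$db
  grads$b2c2_w <- r2$g2$dw; grads$b2c2_b <- r2$g2$db
  dp1 <- maxpool_bwd(r2$dx, cc$p1)
  dblock1 <- dropout_bwd(dp1, cc$do1) + dblock1_extra
  r1 <- block_bwd(dblock1, "b1")
  grads$b1c1_w <- r1$g1$dw; grads$b1c1_b <- r1$g1$db
  grads$b1c2_w <- r1$g2$dw; grads$b1c2_b <- r1$g2$db
  grads
}

## ---- multiple field-of-view encoder ------------------------------------

cat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  array(c(a, b), c(da[1], da[2], da[3] + db[3]))
}

#' Multiple field-of-view encoder forward pass
#'
#' Four cascaded same-padded 3x3 dilated convolutions (rates 1, 2, 4, 8 by
#' default): the first sees the backbone feature alone, each later one sees
#' the backbone feature concatenated with the previous dilated feature.  A
#' 2x2 max pooling of the backbone feature (stride 1, same padding by
#' default, so shapes match) is concatenated as a fifth part.  With
#' `use_mfov = FALSE` the encoder is bypassed and the backbone feature is
#' returned unchanged.
#'
#' @param f_b backbone feature, h x w x C3.
#' @inheritParams backbone_forward
#' @return list with `f_d` (list of four dilated features), `f_p`, `f_E`
#'   and an internal cache.
#' @export
mfov_forward <- function(f_b, params, config) {
  if (!config$use_mfov)
    return(list(f_d = NULL, f_p = NULL, f_E = f_b, cache = NULL))
  rates <- config$dilation_rates
  cache <- list()
  f_d <- vector("list", 4L)
  x <- f_b
  for (k in 1:4) {
    nm <- paste0("md", k)
    cv <- conv_fwd(x, params[[paste0(nm, "_w")]], params[[paste0(nm, "_b")]],
                   3, 3, rates[k])
    rl <- relu_fwd(cv$out)
    f_d[[k]] <- rl$out
    cache[[nm]] <- list(conv = cv$cache, relu = rl$cache)
    if (k < 4) x <- cat_channels(f_b, f_d[[k]])
  }
  if (config$fp_mode == "stride1") {
    pl <- maxpool_fwd(f_b, 1L)
    f_p <- pl$out
    cache$pool <- pl$cache
  } else {
    pl <- maxpool_fwd(f_b, 2L)
    f_p <- upsample_fwd(pl$out)
    cache$pool <- pl$cache
    cache$pool_up <- TRUE
  }
  f_E <- cat_channels(cat_channels(cat_channels(
    cat_channels(f_d[[1]], f_d[[2]]), f_d[[3]]), f_d[[4]]), f_p)
  list(f_d = f_d, f_p = f_p, f_E = f_E, cache = cache)
}

mfov_backward <- function(df_E, mf, params, config) {
  if (!config$use_mfov) return(list(df_b = df_E, grads = list()))
  cd <- config$cd
  cb <- dim(df_E)[3] - 4L * cd
  sl <- function(x, from, n) x[, , from:(from + n - 1L), drop = FALSE]
  dd <- lapply(0:3, function(k) sl(df_E, 1L + k * cd, cd))
  dfp <- sl(df_E, 4L * cd + 1L, cb)
  grads <- list()
  df_b <- if (isTRUE(mf$cache$pool_up))
    maxpool_bwd(upsample_bwd(dfp), mf$cache$pool) else
    maxpool_bwd(dfp, mf$cache$pool)
  for (k in 4:1) {
    nm <- paste0("md", k)
    dy <- relu_bwd(dd[[k]], mf$cache[[nm]]$relu)
    g <- conv_bwd(dy, mf$cache[[nm]]$conv)
    grads[[paste0(nm, "_w")]] <- g$dw
    grads[[paste0(nm, "_b")]] <- g$db
    if (k > 1) {
      df_b <- df_b + sl(g$dx, 1L, dim(df_b)[3])
      dd[[k - 1L]] <- dd[[k - 1L]] + sl(g$dx, dim(df_b)[3] + 1L, cd)
    } else {
      df_b <- df_b + g$dx
    }
  }
  list(df_b = df_b, grads = grads)
}

## ---- attention-driven decoder ------------------------------------------

#' Decoder forward pass
#'
#' Upsamples the encoder feature back to input resolution through three
#' same-padded 3x3 convolutions with instance normalisation and ReLU
#' (bilinear x2 upsampling before the first and third), followed by a 1x1
#' convolution with ReLU giving the 64-channel decoder feature.  Two forward
#' connections modulate the decoder: the spatial global average pooling of
#' the backbone block-2 feature, mapped to 64 dimensions by a dense layer,
#' multiplies the channels of the first decoder stage; the global average
#' pooling of the block-1 feature (already 64-dimensional) multiplies the
#' channels of the stage at full resolution.
#'
#' @param f_E encoder feature, h x w x C_E.
#' @param block1,block2 backbone block outputs from [backbone_forward()].
#' @inheritParams backbone_forward
#' @return list with `f_U` (H x W x 64) and an internal cache.
#' @export
decoder_forward <- function(f_E, block1, block2, params, config) {
  if (dim(f_E)[1] * 4L != dim(block1)[1] ||
      dim(block2)[1] * 2L != dim(block1)[1])
    stop("encoder and block features disagree on spatial provenance",
         call. = FALSE)
  up1 <- upsample_fwd(f_E)
  c1 <- conv_fwd(up1, params$u1_w, params$u1_b, 3, 3)
  n1 <- instnorm_fwd(c1$out, params$in1_g, params$in1_b)
  r1 <- relu_fwd(n1$out)
  t1 <- r1$out
  gap2 <- gap_vec(block2)
  dw2 <- dense_fwd(gap2, params$fc2_w, params$fc2_b)
  w2 <- dw2$out
  s1 <- mul_channel(t1, w2)
  c2 <- conv_fwd(s1, params$u2_w, params$u2_b, 3, 3)
  n2 <- instnorm_fwd(c2$out, params$in2_g, params$in2_b)
  r2 <- relu_fwd(n2$out)
  up2 <- upsample_fwd(r2$out)
  c3 <- conv_fwd(up2, params$u3_w, params$u3_b, 3, 3)
  n3 <- instnorm_fwd(c3$out, params$in3_g, params$in3_b)
  r3 <- relu_fwd(n3$out)
  t3 <- r3$out
  gap1 <- gap_vec(block1)
  dw1c <- NULL
  if (is.null(params$fc1_w)) {
    w1 <- gap1
  } else {
    dw1c <- dense_fwd(gap1, params$fc1_w, params$fc1_b)
    w1 <- dw1c$out
  }
  s3 <- mul_channel(t3, w1)
  c4 <- conv_fwd(s3, params$u4_w, params$u4_b, 1, 1)
  r4 <- relu_fwd(c4$out)
  cache <- list(c1 = c1$cache, n1 = n1$cache, r1 = r1$cache, t1 = t1,
                gap2 = gap2, dw2 = dw2$cache, w2 = w2,
                c2 = c2$cache, n2 = n2$cache, r2 = r2$cache,
                c3 = c3$cache, n3 = n3$cache, r3 = r3$cache, t3 = t3,
                w1 = w1, dw1c = if (is.null(dw1c)) NULL else dw1c$cache,
                c4 = c4$cache, r4 = r4$cache,
                dim1 = dim(block1), dim2 = dim(block2))
  list(f_U = r4$out, cache = cache)
}

decoder_backward <- function(df_U, dc, params) {
  grads <- list()
  dy <- relu_bwd(df_U, dc$r4)
  g4 <- conv_bwd(dy, dc$c4)
  grads$u4_w <- g4$dw; grads$u4_b <- g4$db
  ds3 <- g4$dx
  dw1 <- sum_pixels(ds3 * dc$t3)
  dt3 <- mul_channel(ds3, dc$w1)
  n1pix <- dc$dim1[1] * dc$dim1[2]
  if (is.null(dc$dw1c)) {
    dgap1 <- dw1
  } else {
    gd1 <- dense_bwd(dw1, dc$dw1c)
    grads$fc1_w <- gd1$dw; grads$fc1_b <- gd1$db
    dgap1 <- gd1$dx
  }
  dblock1_extra <- array(rep(dgap1 / n1pix, each = n1pix), dc$dim1)
  dy <- relu_bwd(dt3, dc$r3)
  gn3 <- instnorm_bwd(dy, dc$n3)
  grads$in3_g <- gn3$dgamma; grads$in3_b <- gn3$dbeta
  g3 <- conv_bwd(gn3$dx, dc$c3)
  grads$u3_w <- g3$dw; grads$u3_b <- g3$db
  dr2 <- upsample_bwd(g3$dx)
  dy <- relu_bwd(dr2, dc$r2)
  gn2 <- instnorm_bwd(dy, dc$n2)
  grads$in2_g <- gn2$dgamma; grads$in2_b <- gn2$dbeta
  g2 <- conv_bwd(gn2$dx, dc$c2)
  grads$u2_w <- g2$dw; grads$u2_b <- g2$db
  ds1 <- g2$dx
  dw2vec <- sum_pixels(ds1 * dc$t1)
  dt1 <- mul_channel(ds1, dc$w2)
  gd <- dense_bwd(dw2vec, dc$dw2)
  grads$fc2_w <- gd$dw; grads$fc2_b <- gd$db
  n2pix <- dc$dim2[1] * dc$dim2[2]
  dblock2_extra <- array(rep(gd$dx / n2pix, each = n2pix), dc$dim2)
  dy <- relu_bwd(dt1, dc$r1)
  gn1 <- instnorm_bwd(dy, dc$n1)
  grads$in1_g <- gn1$dgamma; grads$in1_b <- gn1$dbeta
  g1 <- conv_bwd(gn1$dx, dc$c1)
  grads$u1_w <- g1$dw; grads$u1_b <- g1$db
  df_E <- upsample_bwd(g1$dx)
  list(df_E = df_E, dblock1_extra = dblock1_extra,
       dblock2_extra = dblock2_extra, grads = grads)
}

## ---- spatial-channel attention ------------------------------------------

#' Channel attention map
#'
#' Per-channel sigmoid of the sum of the spatial-wise max pooling and
#' spatial-wise average pooling of the decoder feature.  When disabled
#' (ablation) an all-ones vector is returned so the multiplication is the
#' identity.
#'
#' @param f_U decoder feature, H x W x 64.
#' @param enabled ablation switch.
#' @return length-64 vector in `(0, 1)` (or all ones when disabled).
#' @export
channel_attention <- function(f_U, enabled = TRUE) {
  if (!enabled) return(rep(1, dim(f_U)[3]))
  sp <- spatial_pool_fwd(f_U)
  sigmoid(sp$smax + sp$smean)
}

#' Spatial attention map
#'
#' Per-pixel channel-wise max and average pooling of the decoder feature,
#' concatenated into a 2-channel map, passed through a same-padded 7x7
#' convolution and a sigmoid.  When disabled an all-ones map is returned.
#'
#' @inheritParams channel_attention
#' @param w,b 7x7 convolution weight ((7*7*2) x 1 matrix) and bias.
#' @return H x W map with values in `(0, 1)` (or all ones when disabled).
#' @export
spatial_attention <- function(f_U, w, b, enabled = TRUE) {
  if (!enabled) return(matrix(1, dim(f_U)[1], dim(f_U)[2]))
  cp <- channel_pool_fwd(f_U)
  cv <- conv_fwd(cp$out, w, b, 7, 7)
  sigmoid(cv$out[, , 1])
}

#' Probability map
#'
#' Sigmoid of a 1x1 convolution of the attended decoder feature
#' `m_s * (m_c * f_U)` (channel weights broadcast over pixels, the spatial
#' map over channels).
#'
#' @inheritParams channel_attention
#' @param m_c channel attention vector.
#' @param m_s spatial attention map.
#' @param w,b 1x1 convolution weight (64 x 1 matrix) and bias.
#' @return H x W map with values in `(0, 1)`.
#' @export
probability_map <- function(f_U, m_c, m_s, w, b) {
  a <- mul_spatial(mul_channel(f_U, m_c), m_s)
  cv <- conv_fwd(a, w, b, 1, 1)
  sigmoid(cv$out[, , 1])
}

attention_forward <- function(f_U, params, config) {
  d <- dim(f_U)
  cache <- list()
  if (config$use_channel_attention) {
    sp <- spatial_pool_fwd(f_U)
    z_c <- sp$smax + sp$smean
    m_c <- sigmoid(z_c)
    cache$sp <- sp$cache
  } else m_c <- rep(1, d[3])
  if (config$use_spatial_attention) {
    cp <- channel_pool_fwd(f_U)
    cv <- conv_fwd(cp$out, params$sa_w, params$sa_b, 7, 7)
    m_s <- sigmoid(cv$out[, , 1])
    cache$cp <- cp$cache
    cache$sa <- cv$cache
  } else m_s <- matrix(1, d[1], d[2])
  a1 <- mul_channel(f_U, m_c)
  a <- mul_spatial(a1, m_s)
  pv <- conv_fwd(a, params$pm_w, params$pm_b, 1, 1)
  m_p <- sigmoid(pv$out[, , 1])
  cache$a1 <- a1; cache$a <- a; cache$pm <- pv$cache
  cache$f_U <- f_U; cache$m_c <- m_c; cache$m_s <- m_s
  list(m_c = m_c, m_s = m_s, m_p = m_p, attended = a, cache = cache)
}

# dm_p, dm_s_direct: gradients of the loss w.r.t. the maps themselves
attention_backward <- function(dm_p, dm_s_direct, at, params, config) {
  ac <- at$cache
  m_p <- at$m_p
  grads <- list()
  dz_p <- dm_p * m_p * (1 - m_p)
  gp <- conv_bwd(array(dz_p, c(dim(dz_p), 1L)), ac$pm)
  grads$pm_w <- gp$dw; grads$pm_b <- gp$db
  da <- gp$dx
  da1 <- mul_spatial(da, ac$m_s)
  dm_s <- dm_s_direct + sum_channels(da * ac$a1)
  df_U <- mul_channel(da1, ac$m_c)
  dm_c <- sum_pixels(da1 * ac$f_U)
  if (config$use_spatial_attention) {
    dz_s <- dm_s * ac$m_s * (1 - ac$m_s)
    gs <- conv_bwd(array(dz_s, c(dim(dz_s), 1L)), ac$sa)
    grads$sa_w <- gs$dw; grads$sa_b <- gs$db
    df_U <- df_U + channel_pool_bwd(gs$dx, ac$cp)
  }
  if (config$use_channel_attention) {
    dz_c <- dm_c * ac$m_c * (1 - ac$m_c)
    df_U <- df_U + spatial_pool_bwd(dz_c, dz_c, ac$sp)
  }
  list(df_U = df_U, grads = grads)
}

## ---- classification head ------------------------------------------------

#' Classification head
#'
#' Flattens the probability map (optionally after adaptive average pooling),
#' applies two fully connected ReLU layers and a 2-way softmax; the returned
#' score is the probability of the stone class.
#'
#' @param m_p probability map, H x W.
#' @inheritParams backbone_forward
#' @return list with `y_hat`, class probabilities `prob` and logits.
#' @export
classify <- function(m_p, params, config) {
  fw <- classify_forward(m_p, params, config)
  list(y_hat = fw$y_hat, prob = fw$prob, logits = fw$logits)
}

classify_forward <- function(m_p, params, config, train = FALSE) {
  pooled <- if (is.null(config$classifier_pool)) m_p else
    avgpool2d(m_p, config$classifier_pool)
  x <- as.numeric(pooled)
  if (length(x) != nrow(params$cls1_w))
    stop(sprintf("classification head expects %d inputs, got %d",
                 nrow(params$cls1_w), length(x)), call. = FALSE)
  pfc <- if (is.null(config$fc_dropout)) 0 else config$fc_dropout
  d1 <- dense_fwd(x, params$cls1_w, params$cls1_b)
  a1 <- relu_fwd(d1$out)
  o1 <- dropout_fwd(a1$out, pfc, train)
  d2 <- dense_fwd(o1$out, params$cls2_w, params$cls2_b)
  a2 <- relu_fwd(d2$out)
  o2 <- dropout_fwd(a2$out, pfc, train)
  d3 <- dense_fwd(o2$out, params$cls3_w, params$cls3_b)
  z <- d3$out - max(d3$out)
  prob <- exp(z) / sum(exp(z))
  list(y_hat = prob[2], prob = prob, logits = d3$out,
       cache = list(d1 = d1$cache, a1 = a1$cache, o1 = o1$cache,
                    d2 = d2$cache, a2 = a2$cache, o2 = o2$cache,
                    d3 = d3$cache, Hp = dim(m_p)[1]))
}

# dlogits -> gradients and gradient w.r.t. the (pre-pool) probability map
classify_backward <- function(dlogits, cc, config) {
  grads <- list()
  g3 <- dense_bwd(dlogits, cc$d3)
  grads$cls3_w <- g3$dw; grads$cls3_b <- g3$db
  dy <- relu_bwd(dropout_bwd(g3$dx, cc$o2), cc$a2)
  g2 <- dense_bwd(dy, cc$d2)
  grads$cls2_w <- g2$dw; grads$cls2_b <- g2$db
  dy <- relu_bwd(dropout_bwd(g2$dx, cc$o1), cc$a1)
  g1 <- dense_bwd(dy, cc$d1)
  grads$cls1_w <- g1$dw; grads$cls1_b <- g1$db
  dpool <- g1$dx
  dm_p <- if (is.null(config$classifier_pool))
    matrix(dpool, cc$Hp) else
    avgpool2d_bwd(matrix(dpool, config$classifier_pool), cc$Hp)
  list(dm_p = dm_p, grads = grads)
}

## ---- full model ---------------------------------------------------------

#' Full forward pass
#'
#' Runs the backbone, multiple field-of-view encoder, attention-driven
#' decoder, spatial-channel attention and classification head, returning
#' every intermediate needed for loss computation, localization and
#' inspection.
#'
#' @inheritParams backbone_forward
#' @return object of class `mfadnet_outputs`: a list with `f_b`, `block1`,
#'   `block2`, `f_d`, `f_p`, `f_E`, `f_U`, `m_c`, `m_s`, `m_p`, `y_hat`,
#'   `prob` and internal caches.
#' @export
model_forward <- function(image, params, config, train = FALSE) {
  bb <- backbone_forward(image, params, config, train)
  mf <- mfov_forward(bb$f_b, params, config)
  de <- decoder_forward(mf$f_E, bb$block1, bb$block2, params, config)
  at <- attention_forward(de$f_U, params, config)
  cl <- classify_forward(at$m_p, params, config, train)
  out <- list(f_b = bb$f_b, block1 = bb$block1, block2 = bb$block2,
              f_d = mf$f_d, f_p = mf$f_p, f_E = mf$f_E, f_U = de$f_U,
              m_c = at$m_c, m_s = at$m_s, m_p = at$m_p,
              y_hat = cl$y_hat, prob = cl$prob, logits = cl$logits,
              cache = list(bb = bb, mf = mf, de = de, at = at, cl = cl))
  class(out) <- "mfadnet_outputs"
  out
}

# full backward pass from per-map loss gradients; returns the parameter
# gradient list (same names as params, instance norms included)
model_backward <- function(out, dm_p, dm_s_direct, dlogits, params, config) {
  cb <- classify_backward(dlogits, out$cache$cl$cache, config)
  dm_p_total <- dm_p + cb$dm_p
  ab <- attention_backward(dm_p_total, dm_s_direct, out$cache$at, params,
                           config)
  db <- decoder_backward(ab$df_U, out$cache$de$cache, params)
  mb <- mfov_backward(db$df_E, out$cache$mf, params, config)
  gb <- backbone_backward(mb$df_b, db$dblock1_extra, db$dblock2_extra,
                          out$cache$bb, params)
  c(gb, mb$grads, db$grads, ab$grads, cb$grads)
}
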