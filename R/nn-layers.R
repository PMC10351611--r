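# Internal neural-network primitives.  Every layer has a forward returning
# list(out, cache) and a backward mapping the upstream gradient plus the cache
# to gradients w.r.t. inputs and parameters.  Feature maps are H x W x C
# arrays; convolution weights are (kh*kw*Cin) x Cout matrices whose row order
# is the column-major flattening of dim c(kh, kw, Cin, Cout).

as_cube <- function(x) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  x
}

#' @useDynLib mfadnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## ---- initialisation ----------------------------------------------------

# He-normal initialisation for a conv kernel, stored flat as a matrix
init_conv <- function(kh, kw, cin, cout) {
  fan_in <- kh * kw * cin
  w <- matrix(stats::rnorm(fan_in * cout, sd = sqrt(2 / fan_in)), fan_in, cout)
  attr(w, "kspec") <- c(kh = kh, kw = kw, cin = cin, cout = cout)
  w
}

init_dense <- function(n_in, n_out) {
  matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out)
}

## ---- convolution -------------------------------------------------------

conv_fwd <- function(x, w, b, kh, kw, dil = 1L) {
  x <- as_cube(x)
  if (kh == 1L && kw == 1L) {       # a 1x1 conv is a plain GEMM
    d <- dim(x)
    xm <- matrix(x, d[1] * d[2], d[3])
    y <- xm %*% w
    y <- y + rep(b, each = nrow(y))
    return(list(out = array(y, c(d[1], d[2], ncol(w))),
                cache = list(xm = xm, d = d, w = w, kh = 1L)))
  }
  r <- cpp_conv2d_fwd(x, w, as.numeric(b), kh, kw, dil)
  list(out = r$out,
       cache = list(col = r$col, d = dim(x), w = w, kh = kh, kw = kw,
                    dil = dil))
}

conv_bwd <- function(dy, cache) {
  if (cache$kh == 1L) {
    d <- cache$d
    dym <- matrix(dy, d[1] * d[2], length(dy) / (d[1] * d[2]))
    dw <- crossprod(cache$xm, dym)
    attributes(dw) <- attributes(cache$w)
    return(list(dx = array(tcrossprod(dym, cache$w), d), dw = dw,
                db = colSums(dym)))
  }
  g <- cpp_conv2d_bwd(cache$col, cache$w, as_cube(dy), cache$d[1],
                      cache$d[2], cache$d[3], cache$kh, cache$kw, cache$dil)
  dim(g$dw) <- dim(cache$w)
  list(dx = g$dx, dw = g$dw, db = as.numeric(g$db))
}

## ---- pooling / upsampling ----------------------------------------------

maxpool_fwd <- function(x, stride) {
  x <- as_cube(x)
  r <- cpp_maxpool2_fwd(x, stride)
  list(out = r$out, cache = list(idx = r$idx, H = dim(x)[1], W = dim(x)[2]))
}

maxpool_bwd <- function(dy, cache) {
  cpp_maxpool2_bwd(cache$idx, as_cube(dy), cache$H, cache$W)
}

upsample_fwd <- function(x) cpp_upsample2_fwd(as_cube(x))
upsample_bwd <- function(dy) cpp_upsample2_bwd(as_cube(dy))

## ---- pointwise ---------------------------------------------------------

relu_fwd <- function(x) {
  out <- if (is.null(dim(x))) pmax(x, 0) else cpp_relu_fwd(x)
  list(out = out, cache = out)
}
relu_bwd <- function(dy, cache) {
  if (is.null(dim(dy))) dy * (cache > 0) else cpp_relu_bwd(dy, cache)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# inverted dropout; draws from the current RNG stream so one seed controls it
dropout_fwd <- function(x, p, train) {
  if (!train || p <= 0) return(list(out = x, cache = NULL))
  keep <- stats::rbinom(length(x), 1L, 1 - p) / (1 - p)
  if (!is.null(dim(x))) dim(keep) <- dim(x)
  list(out = x * keep, cache = keep)
}

dropout_bwd <- function(dy, cache) if (is.null(cache)) dy else dy * cache

## ---- instance normalisation --------------------------------------------

# per-channel standardisation over pixels with affine parameters
instnorm_fwd <- function(x, gamma, beta, eps = 1e-5) {
  r <- cpp_instnorm_fwd(x, gamma, beta, eps)
  list(out = r$out,
       cache = list(xhat = r$xhat, istd = r$istd, gamma = gamma))
}

instnorm_bwd <- function(dy, cache) {
  g <- cpp_instnorm_bwd(dy, cache$xhat, cache$istd, cache$gamma)
  list(dx = g$dx, dgamma = g$dgamma, dbeta = g$dbeta)
}

## ---- channel / spatial pooling used by the attention blocks ------------

# per-pixel max and mean across channels: H x W x C -> H x W x 2
channel_pool_fwd <- function(x) {
  d <- dim(x)
  xm <- matrix(x, d[1] * d[2], d[3])
  amax <- max.col(xm, ties.method = "first")
  pmaxv <- xm[cbind(seq_len(nrow(xm)), amax)]
  pmean <- rowMeans(xm)
  out <- array(c(pmaxv, pmean), dim = c(d[1], d[2], 2L))
  list(out = out, cache = list(amax = amax, d = d))
}

channel_pool_bwd <- function(dy, cache) {
  d <- cache$d
  n <- d[1] * d[2]
  dym <- matrix(dy, n, 2L)
  dx <- matrix(dym[, 2] / d[3], n, d[3])       # mean path
  ix <- cbind(seq_len(n), cache$amax)
  dx[ix] <- dx[ix] + dym[, 1]                  # max path
  array(dx, d)
}

# per-channel max and mean across pixels: H x W x C -> list(max, mean)
spatial_pool_fwd <- function(x) {
  d <- dim(x)
  xm <- matrix(x, d[1] * d[2], d[3])
  amax <- max.col(t(xm), ties.method = "first")
  list(smax = xm[cbind(amax, seq_len(d[3]))], smean = colMeans(xm),
       cache = list(amax = amax, d = d))
}

spatial_pool_bwd <- function(dmax, dmean, cache) {
  d <- cache$d
  n <- d[1] * d[2]
  dx <- matrix(rep(dmean / n, each = n), n, d[3])
  ix <- cbind(cache$amax, seq_len(d[3]))
  dx[ix] <- dx[ix] + dmax
  array(dx, d)
}

## ---- dense -------------------------------------------------------------

dense_fwd <- function(x, w, b) {
  list(out = as.numeric(x %*% w + b), cache = list(x = x, w = w))
}

dense_bwd <- function(dy, cache) {
  list(dx = as.numeric(cache$w %*% dy),
       dw = outer(as.numeric(cache$x), dy), db = dy)
}
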