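# Independent brute-force oracles used to cross-check the implementation.
# These are deliberately written as naive scalar loops, sharing no code with
# the package internals.

# same-padded dilated 2-D convolution, quadruple loop
oracle_conv2d <- function(x, warr, b, dil = 1L) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  kh <- dim(warr)[1]; kw <- dim(warr)[2]
  cin <- dim(warr)[3]; cout <- dim(warr)[4]
  H <- dim(x)[1]; W <- dim(x)[2]
  ph <- dil * (kh - 1) %/% 2; pw <- dil * (kw - 1) %/% 2
  out <- array(0, c(H, W, cout))
  for (co in seq_len(cout)) {
    for (j in seq_len(W)) {
      for (i in seq_len(H)) {
        acc <- b[co]
        for (ci in seq_len(cin)) {
          for (kj in seq_len(kw)) {
            for (ki in seq_len(kh)) {
              ii <- i + (ki - 1) * dil - ph
              jj <- j + (kj - 1) * dil - pw
              if (ii >= 1 && ii <= H && jj >= 1 && jj <= W)
                acc <- acc + x[ii, jj, ci] * warr[ki, kj, ci, co]
            }
          }
        }
        out[i, j, co] <- acc
      }
    }
  }
  out
}

# conv weight array -> the flat matrix layout the package uses
flat_w <- function(warr) {
  d <- dim(warr)
  w <- matrix(warr, d[1] * d[2] * d[3], d[4])
  attr(w, "kspec") <- c(kh = d[1], kw = d[2], cin = d[3], cout = d[4])
  w
}

# recursive-style flood fill (explicit stack), 8-connectivity
oracle_components <- function(bin) {
  h <- nrow(bin); w <- ncol(bin)
  lab <- matrix(0L, h, w)
  nxt <- 0L
  for (sj in seq_len(w)) for (si in seq_len(h)) {
    if (!bin[si, sj] || lab[si, sj] != 0L) next
    nxt <- nxt + 1L
    stack <- list(c(si, sj))
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      if (p[1] < 1 || p[1] > h || p[2] < 1 || p[2] > w) next
      if (!bin[p[1], p[2]] || lab[p[1], p[2]] != 0L) next
      lab[p[1], p[2]] <- nxt
      for (di in -1:1) for (dj in -1:1)
        if (di != 0 || dj != 0)
          stack[[length(stack) + 1L]] <- c(p[1] + di, p[2] + dj)
    }
  }
  lab
}

# largest component box from the flood-fill labelling (ties: higher peak)
oracle_box <- function(m, th) {
  bin <- m > th
  if (!any(bin)) return(NULL)
  lab <- oracle_components(bin)
  sizes <- tabulate(lab)
  cand <- which(sizes == max(sizes))
  if (length(cand) > 1) {
    pk <- vapply(cand, function(l) max(m[lab == l]), numeric(1))
    cand <- cand[which.max(pk)]
  }
  hits <- which(lab == cand, arr.ind = TRUE)
  c(x_min = min(hits[, 2]) - 1, y_min = min(hits[, 1]) - 1,
    x_max = max(hits[, 2]), y_max = max(hits[, 1]))
}

# all-point interpolated AP by direct enumeration over recall levels
oracle_ap <- function(scores, hits, n_pos) {
  ord <- order(scores, decreasing = TRUE)
  hits <- hits[ord]
  prec <- cumsum(hits) / seq_along(hits)
  rec <- cumsum(hits) / n_pos
  ap <- 0
  prev_r <- 0
  for (k in seq_along(rec)) {
    if (rec[k] > prev_r) {
      ap <- ap + (rec[k] - prev_r) * max(prec[k:length(prec)])
      prev_r <- rec[k]
    }
  }
  ap
}

# small fully specified configs used across tests
tiny_model_config <- function(...) {
  model_config(image_size = 8L, channels = c(2L, 3L, 4L), cd = 2L,
               dropout = 0, classifier_hidden = 5L, seed = 3L, ...)
}

slim_model_config <- function(image_size = 32L, ...) {
  model_config(image_size = image_size, channels = c(4L, 8L, 8L), cd = 4L,
               dropout = 0.3, classifier_hidden = 16L, seed = 5L, ...)
}

rand_image <- function(n, seed = 1) {
  set.seed(seed)
  matrix(runif(n * n), n, n)
}
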