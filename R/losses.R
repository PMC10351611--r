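# The four weak-supervision losses and their weighted combination.  All are
# means over pixels (or scalars), non-negative on their domains, and each has
# a closed-form gradient used by the trainer.

LOG_EPS <- 1e-7

clamp01 <- function(p) pmin(pmax(p, LOG_EPS), 1 - LOG_EPS)

check_label <- function(y) {
  if (length(y) != 1L || !(y %in% c(0, 1)))
    stop("label y must be a single 0 or 1", call. = FALSE)
  as.numeric(y)
}

#' Foreground loss
#'
#' Mean over pixels of `(1 - m_s) * m_p`: pixels where the probability map
#' responds but the spatial attention map does not are penalised, coupling
#' the two maps so that the spatial attention learns candidate stone
#' locations.
#'
#' @param m_s spatial attention map in `[0, 1]`.
#' @param m_p probability map in `[0, 1]`, same shape.
#' @return scalar in `[0, 1]`.
#' @export
foreground_loss <- function(m_s, m_p) {
  if (!identical(dim(m_s), dim(m_p)))
    stop("m_s and m_p must have identical shape", call. = FALSE)
  mean((1 - m_s) * m_p)
}

#' Background loss
#'
#' Mean over pixels of `(1 - y) * m_p`, with the image-level label broadcast
#' to every pixel: on normal images every probability-map response is
#' penalised; on stone images the loss is exactly zero so the stone is never
#' learned as background.
#'
#' @param m_p probability map in `[0, 1]`.
#' @param y image-level label, 0 or 1.
#' @return scalar in `[0, 1]`; exactly 0 when `y = 1`.
#' @export
background_loss <- function(m_p, y) {
  y <- check_label(y)
  (1 - y) * mean(m_p)
}

#' Consistency loss
#'
#' Binary cross-entropy between the image-level label and the global average
#' pooling of the probability map, so the dominant response of the map
#' agrees with the label.  The pooled value is clamped to
#' `[1e-7, 1 - 1e-7]` before the logarithm.
#'
#' @inheritParams background_loss
#' @param literal_sign audit flag: use the sign-uncorrected form
#'   `-y*log(p) + (1-y)*log(1-p)` (unbounded below; not used for training).
#' @return non-negative scalar (may be negative only under `literal_sign`).
#' @export
consistency_loss <- function(m_p, y, literal_sign = FALSE) {
  y <- check_label(y)
  p <- clamp01(mean(m_p))
  if (literal_sign) -y * log(p) + (1 - y) * log(1 - p) else
    -y * log(p) - (1 - y) * log(1 - p)
}

#' Classification loss
#'
#' Binary cross-entropy between the image-level label and the stone-class
#' probability of the classification head, clamped as in
#' [consistency_loss()].
#'
#' @param y_hat predicted stone probability in `(0, 1)`.
#' @param y image-level label, 0 or 1.
#' @param literal_sign audit flag as in [consistency_loss()].
#' @return non-negative scalar (under the default sign).
#' @export
classification_loss <- function(y_hat, y, literal_sign = FALSE) {
  y <- check_label(y)
  p <- clamp01(y_hat)
  if (literal_sign) -y * log(p) + (1 - y) * log(1 - p) else
    -y * log(p) - (1 - y) * log(1 - p)
}

#' Combined weakly-supervised loss
#'
#' Weighted sum of the four losses with defaults (1, 0.5, 1, 1).
#'
#' @param fg,bg,con,cls the four loss components.
#' @param weights a [loss_weights()].
#' @return scalar.
#' @export
total_loss <- function(fg, bg, con, cls, weights = loss_weights()) {
  stopifnot(inherits(weights, "mfadnet_loss_weights"))
  weights$fg * fg + weights$bg * bg + weights$con * con + weights$cls * cls
}

# loss bundle + gradients w.r.t. m_p, m_s and the classifier logits for one
# image; `prob` is the 2-way softmax output, y_hat = prob[2]
loss_bundle <- function(out, y, weights) {
  y <- check_label(y)
  m_p <- out$m_p
  m_s <- out$m_s
  n <- length(m_p)
  fg <- foreground_loss(m_s, m_p)
  bg <- background_loss(m_p, y)
  con <- consistency_loss(m_p, y, weights$literal_sign)
  cls <- classification_loss(out$y_hat, y, weights$literal_sign)
  tot <- total_loss(fg, bg, con, cls, weights)

  dm_p <- weights$fg * (1 - m_s) / n + weights$bg * (1 - y) / n
  pbar <- mean(m_p)
  if (pbar > LOG_EPS && pbar < 1 - LOG_EPS) {
    s <- if (weights$literal_sign && y == 0) -1 else 1
    dm_p <- dm_p + weights$con * s * (pbar - y) / (pbar * (1 - pbar)) / n
  }
  dm_s <- -weights$fg * m_p / n
  target <- c(1 - y, y)
  s_cls <- if (weights$literal_sign && y == 0) -1 else 1
  dlogits <- weights$cls * s_cls * (out$prob - target)
  list(bundle = list(fg = fg, bg = bg, con = con, cls = cls, total = tot),
       dm_p = dm_p, dm_s = dm_s, dlogits = dlogits)
}
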