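# Inference-time localization: stone attention map, max-normalisation,
# thresholding at th = 0.6, largest 8-connected component, tight bounding
# box, gated by the classification score.

#' Stone attention map
#'
#' Channel-wise average of the attended decoder feature
#' `m_s * (m_c * f_U)`, weighted elementwise by `1 - m_p` (default) or by
#' `m_p`.  The probability-map factor exists to suppress responses the
#' network attributes to the other class; because the narrative meaning of
#' `m_p` (stone vs background probability) is ambiguous, both polarities
#' are available and the choice is recorded in run summaries.
#'
#' @param f_U decoder feature, H x W x 64 (non-negative).
#' @param m_c channel attention vector.
#' @param m_s spatial attention map.
#' @param m_p probability map.
#' @param polarity `"one_minus_p"` (default) weights by `1 - m_p`;
#'   `"p"` weights by `m_p`.
#' @return H x W non-negative attention map.
#' @export
stone_attention_map <- function(f_U, m_c, m_s, m_p,
                                polarity = c("one_minus_p", "p")) {
  polarity <- match.arg(polarity)
  a <- mul_spatial(mul_channel(f_U, m_c), m_s)
  d <- dim(a)
  avg <- matrix(rowMeans(matrix(a, d[1] * d[2], d[3])), d[1], d[2])
  if (polarity == "one_minus_p") avg * (1 - m_p) else avg * m_p
}

#' Normalise an attention map by its maximum
#'
#' Divides by the maximal value; an all-zero map is returned unchanged.
#' Negative entries indicate a polarity misuse and raise an error.
#'
#' @param m_a non-negative H x W map.
#' @return map in `[0, 1]` with maximum 1 (or all zeros).
#' @export
normalize_map <- function(m_a) {
  if (any(!is.finite(m_a)) || any(m_a < 0))
    stop("attention map must be finite and non-negative", call. = FALSE)
  mx <- max(m_a)
  if (mx == 0) m_a else m_a / mx
}

# 8-connected component labelling by iterative flood fill
label_components <- function(bin) {
  h <- nrow(bin); w <- ncol(bin)
  lab <- matrix(0L, h, w)
  cur <- 0L
  queue <- integer(h * w)
  for (start in which(bin)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    lab[start] <- cur
    queue[1] <- start
    head <- 1L; tail <- 1L
    while (head <= tail) {
      p <- queue[head]; head <- head + 1L
      i <- (p - 1L) %% h + 1L
      j <- (p - 1L) %/% h + 1L
      for (dj in -1:1) {
        jj <- j + dj
        if (jj < 1L || jj > w) next
        for (di in -1:1) {
          ii <- i + di
          if (ii < 1L || ii > h) next
          q <- ii + (jj - 1L) * h
          if (bin[q] && lab[q] == 0L) {
            lab[q] <- cur
            tail <- tail + 1L
            queue[tail] <- q
          }
        }
      }
    }
  }
  lab
}

#' Extract a bounding box from a normalised attention map
#'
#' Returns a box only when the classification score passes the decision
#' threshold and some pixel exceeds `th`.  Pixels above `th` are labelled
#' into 8-connected components; the largest by pixel count (ties broken by
#' the higher peak attention value inside) yields a tight half-open box.
#'
#' @param m_a normalised attention map (max 1, or all zeros).
#' @param th attention threshold in `(0, 1)`; default 0.6.
#' @param score classification score.
#' @param decision_threshold score gate in `(0, 1)`; default 0.5.
#' @return a [bounding_box()], or `NULL` when gated out or nothing exceeds
#'   `th`.
#' @export
extract_box <- function(m_a, th = 0.6, score = 1,
                        decision_threshold = 0.5) {
  if (any(m_a < 0) || max(m_a) > 1 + 1e-9)
    stop("extract_box expects a normalised map; run normalize_map() first",
         call. = FALSE)
  stopifnot(th > 0, th < 1, decision_threshold > 0, decision_threshold < 1)
  if (score < decision_threshold) return(NULL)
  bin <- m_a > th
  if (!any(bin)) return(NULL)
  lab <- label_components(bin)
  sizes <- tabulate(lab)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    peaks <- vapply(best, function(l) max(m_a[lab == l]), numeric(1))
    best <- best[which.max(peaks)]
  }
  px <- which(lab == best)
  h <- nrow(m_a)
  rows <- (px - 1L) %% h          # 0-based y
  cols <- (px - 1L) %/% h         # 0-based x
  bounding_box(min(cols), min(rows), max(cols) + 1, max(rows) + 1)
}

#' Detect a stone in one image
#'
#' Runs the full model in evaluation mode, builds and normalises the stone
#' attention map, and extracts a bounding box gated by the classification
#' score.
#'
#' @param image H x W matrix in `[0, 1]`.
#' @param params parameter list.
#' @param config a [model_config()].
#' @param image_id identifier recorded in the detection.
#' @param th,decision_threshold,polarity localization settings, see
#'   [extract_box()] and [stone_attention_map()].
#' @return a detection record: list with `image_id`, `score` and `box`
#'   (`NULL` when predicted negative).
#' @export
detect <- function(image, params, config, image_id = "image",
                   th = 0.6, decision_threshold = 0.5,
                   polarity = c("one_minus_p", "p")) {
  polarity <- match.arg(polarity)
  out <- model_forward(image, params, config, train = FALSE)
  m_a <- normalize_map(stone_attention_map(out$f_U, out$m_c, out$m_s,
                                           out$m_p, polarity))
  box <- extract_box(m_a, th, out$y_hat, decision_threshold)
  detection_record(image_id, out$y_hat, box)
}
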