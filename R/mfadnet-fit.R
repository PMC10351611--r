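#' Fit the weakly-supervised stone detection network
#'
#' Trains the full network (backbone, multiple field-of-view encoder,
#' attention-driven decoder, classification head) end-to-end from
#' image-level labels with the four weak-supervision losses, RMSProp, a
#' reduce-on-plateau learning-rate schedule and early stopping.  The
#' returned fit holds the weights of the epoch with the best validation
#' loss.
#'
#' @param manifest training manifest: a `data.frame` with columns
#'   `image_id`, `path`, `label`, or the path of a manifest CSV.
#' @param val_manifest optional validation manifest; when `NULL` a
#'   stratified fraction `training$val_fraction` of `manifest` is carved
#'   out.
#' @param model a [model_config()].
#' @param training a [train_config()].
#' @param weights a [loss_weights()].
#' @param images optional named list of in-memory `H x W` matrices keyed by
#'   `image_id`, used instead of reading `path` from disk.
#' @param verbose print one line per epoch.
#' @return an object of class `mfadnet` with elements `params`, `model`,
#'   `training`, `weights`, `history` (per-epoch losses and learning rate),
#'   `best_epoch` and `best_val_loss`.
#' @seealso [predict.mfadnet()], [detect()], [run_synthetic_experiment()]
#' @export
mfadnet <- function(manifest, val_manifest = NULL, model = model_config(),
                    training = train_config(), weights = loss_weights(),
                    images = NULL, verbose = FALSE) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (is.character(val_manifest)) val_manifest <- read_manifest(val_manifest)
  if (nrow(manifest) == 0) stop("empty training manifest", call. = FALSE)
  if (is.null(val_manifest)) {
    sp <- make_validation_split(manifest, training$val_fraction,
                                training$seed)
    manifest <- sp$train
    val_manifest <- sp$val
  }
  if (nrow(val_manifest) == 0)
    stop("empty validation manifest", call. = FALSE)
  slices_tr <- load_slices(manifest, model$image_size, images)
  slices_va <- load_slices(val_manifest, model$image_size, images)
  params <- init_params(model)
  res <- train_loop(slices_tr, slices_va, params, model, training, weights,
                    verbose)
  fit <- list(params = res$params, model = model, training = training,
              weights = weights, history = res$history,
              best_epoch = res$best_epoch,
              best_val_loss = res$best_val_loss,
              n_train = nrow(manifest), n_val = nrow(val_manifest),
              call = match.call())
  class(fit) <- "mfadnet"
  fit
}

#' Predict from a fitted network
#'
#' @param object an `mfadnet` fit.
#' @param newdata a manifest `data.frame` (columns `image_id`, `path`,
#'   `label` optional), a single `H x W` matrix, or a list of matrices.
#' @param type `"detections"` (list of detection records with score and
#'   optional box), `"response"` (named vector of stone probabilities) or
#'   `"map"` (list of normalised stone attention maps).
#' @param th,decision_threshold,polarity localization settings, see
#'   [extract_box()] and [stone_attention_map()].
#' @param images optional named list of in-memory images, as in
#'   [mfadnet()].
#' @param ... unused.
#' @return see `type`.
#' @export
predict.mfadnet <- function(object, newdata,
                            type = c("detections", "response", "map"),
                            th = 0.6, decision_threshold = 0.5,
                            polarity = c("one_minus_p", "p"),
                            images = NULL, ...) {
  type <- match.arg(type)
  polarity <- match.arg(polarity)
  if (is.matrix(newdata))
    newdata <- stats::setNames(list(newdata), "image")
  if (is.data.frame(newdata)) {
    slices <- load_slices(newdata, object$model$image_size, images)
  } else {
    ids <- if (is.null(names(newdata)))
      sprintf("image_%03d", seq_along(newdata)) else names(newdata)
    slices <- Map(function(im, id) list(image = im, image_id = id),
                  newdata, ids)
  }
  if (type == "map") {
    return(stats::setNames(lapply(slices, function(sl) {
      out <- model_forward(sl$image, object$params, object$model)
      normalize_map(stone_attention_map(out$f_U, out$m_c, out$m_s, out$m_p,
                                        polarity))
    }), vapply(slices, `[[`, character(1), "image_id")))
  }
  recs <- lapply(slices, function(sl)
    detect(sl$image, object$params, object$model, sl$image_id, th,
           decision_threshold, polarity))
  if (type == "response")
    return(stats::setNames(vapply(recs, `[[`, numeric(1), "score"),
                           vapply(recs, `[[`, character(1), "image_id")))
  recs
}

#' @export
print.mfadnet <- function(x, ...) {
  cat("Weakly-supervised stone detection network (MFADNet)\n")
  cat(sprintf("  input %dx%d, backbone channels %s, C_d = %d\n",
              x$model$image_size, x$model$image_size,
              paste(x$model$channels, collapse = "/"), x$model$cd))
  cat(sprintf("  %s trainable parameters\n",
              format(count_parameters(x$model), big.mark = ",")))
  cat(sprintf("  trained %d epochs on %d images (%d validation); best epoch %d, val loss %.4f\n",
              nrow(x$history), x$n_train, x$n_val, x$best_epoch,
              x$best_val_loss))
  invisible(x)
}

#' @export
summary.mfadnet <- function(object, ...) {
  print(object)
  h <- object$history
  cat("\nLoss components at first / best epoch:\n")
  rows <- h[c(1, object$best_epoch), ]
  print(round(rows[, c("epoch", "loss_fg", "loss_bg", "loss_con",
                       "loss_cls", "train_loss", "val_loss")], 4),
        row.names = FALSE)
  ab <- c(mfov = object$model$use_mfov,
          channel_attention = object$model$use_channel_attention,
          spatial_attention = object$model$use_spatial_attention)
  if (!all(ab)) cat("\nDisabled components:",
                    paste(names(ab)[!ab], collapse = ", "), "\n")
  invisible(object)
}

#' @export
coef.mfadnet <- function(object, ...) object$params

#' Plot training history
#'
#' Training and validation loss per epoch on a log scale, with the
#' learning-rate steps marked.
#'
#' @param x an `mfadnet` fit.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.mfadnet <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "epoch", ylab = "loss", log = "y", ...)
  drops <- which(diff(h$lr) < 0) + 1
  if (length(drops)) graphics::abline(v = drops, lty = 3, col = "grey40")
  graphics::abline(v = x$best_epoch, lty = 2, col = "grey60")
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' The checkpoint stores the trained weights together with an echo of the
#' model configuration and its seed so inference is reproducible.
#'
#' @param fit an `mfadnet` fit.
#' @param path checkpoint file (RDS).
#' @return `load_checkpoint()` returns the `mfadnet` fit.
#' @export
save_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "mfadnet"))
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  fit <- readRDS(path)
  stopifnot(inherits(fit, "mfadnet"))
  fit
}
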