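#' Model architecture configuration
#'
#' Assembles and validates the architecture hyper-parameters of the network:
#' a VGG-style feature backbone (three blocks, 2x2 max-pooling after the
#' first two, dropout after each), a cascaded dilated-convolution encoder
#' operating at 1/4 resolution, an attention-driven decoder that restores
#' full resolution, and a two-layer fully connected classification head fed
#' by the probability map.
#'
#' @param image_size input side length in pixels; must be divisible by 4
#'   (two backbone pools) and, when `classifier_pool` is set, by
#'   `classifier_pool`.
#' @param channels integer vector of the three backbone block widths.
#' @param cd output channels of each dilated convolution in the
#'   multiple field-of-view encoder.
#' @param dilation_rates strictly increasing positive dilation rates of the
#'   four cascaded dilated convolutions.
#' @param dropout dropout probability applied after each backbone block
#'   during training.
#' @param fc_dropout dropout probability applied after each hidden fully
#'   connected layer of the classification head during training (the VGG
#'   convention); 0 disables it.
#' @param classifier_hidden width of the two fully connected layers of the
#'   classification head.
#' @param classifier_pool optional side length of an adaptive average pool
#'   applied to the probability map before flattening; `NULL` flattens the
#'   full-resolution map.
#' @param use_mfov,use_channel_attention,use_spatial_attention ablation
#'   switches; disabling replaces the component by its identity
#'   (encoder bypass, all-ones channel weights, all-ones spatial map).
#' @param fp_mode how the encoder pooling feature keeps the spatial shape of
#'   the backbone feature: `"stride1"` (2x2 max pool, stride 1, same
#'   padding) or `"stride2up"` (stride-2 pool followed by x2 bilinear
#'   upsampling).
#' @param seed integer seed controlling weight initialisation.
#' @return a validated list of class `mfadnet_config`.
#' @export
model_config <- function(image_size = 96L,
                         channels = c(64L, 128L, 256L),
                         cd = 64L,
                         dilation_rates = c(1L, 2L, 4L, 8L),
                         dropout = 0.3,
                         fc_dropout = 0,
                         classifier_hidden = 256L,
                         classifier_pool = NULL,
                         use_mfov = TRUE,
                         use_channel_attention = TRUE,
                         use_spatial_attention = TRUE,
                         fp_mode = c("stride1", "stride2up"),
                         seed = 1L) {
  fp_mode <- match.arg(fp_mode)
  stopifnot(length(channels) == 3L, all(channels >= 1))
  if (image_size < 8 || image_size %% 4 != 0)
    stop("image_size must be >= 8 and divisible by 4", call. = FALSE)
  if (!is.null(classifier_pool) && image_size %% classifier_pool != 0)
    stop("classifier_pool must divide image_size", call. = FALSE)
  if (length(dilation_rates) != 4L || any(dilation_rates <= 0) ||
      any(diff(dilation_rates) <= 0))
    stop("dilation_rates must be 4 strictly increasing positive integers",
         call. = FALSE)
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0,1)",
                                        call. = FALSE)
  if (fc_dropout < 0 || fc_dropout >= 1) stop("fc_dropout must be in [0,1)",
                                              call. = FALSE)
  for (fl in c(use_mfov, use_channel_attention, use_spatial_attention))
    stopifnot(is.logical(fl), length(fl) == 1L)
  cfg <- list(image_size = as.integer(image_size),
              channels = as.integer(channels), cd = as.integer(cd),
              dilation_rates = as.integer(dilation_rates), dropout = dropout,
              fc_dropout = fc_dropout,
              classifier_hidden = as.integer(classifier_hidden),
              classifier_pool = if (is.null(classifier_pool)) NULL else
                as.integer(classifier_pool),
              use_mfov = use_mfov,
              use_channel_attention = use_channel_attention,
              use_spatial_attention = use_spatial_attention,
              fp_mode = fp_mode, seed = as.integer(seed))
  class(cfg) <- "mfadnet_config"
  cfg
}

#' Training configuration
#'
#' Optimisation schedule for weakly-supervised end-to-end training:
#' RMSProp (`rho` = 0.9, `eps` = 1e-8), batch size 3, initial learning rate
#' 1e-4, learning rate divided by 10 when the validation loss has not
#' improved for 5 consecutive epochs, early stop after 10 non-improving
#' epochs, at most 100 epochs.
#'
#' @param batch_size images per optimisation step.
#' @param initial_lr initial learning rate.
#' @param rho,eps RMSProp decay and numerical guard.
#' @param plateau_patience epochs without validation improvement before the
#'   learning rate is divided by `plateau_factor`.
#' @param plateau_factor learning-rate division factor (> 1).
#' @param early_stop_patience epochs without validation improvement before
#'   training ends early.
#' @param max_epochs maximum number of epochs.
#' @param improve_tol minimum validation-loss decrease counted as an
#'   improvement.
#' @param val_fraction fraction of the training manifest carved out for
#'   validation when no validation manifest is supplied.
#' @param seed integer seed controlling data order and dropout.
#' @return a validated list of class `mfadnet_train_config`.
#' @export
train_config <- function(batch_size = 3L, initial_lr = 1e-4, rho = 0.9,
                         eps = 1e-8, plateau_patience = 5L,
                         plateau_factor = 10, early_stop_patience = 10L,
                         max_epochs = 100L, improve_tol = 1e-5,
                         val_fraction = 0.1, seed = 1L) {
  stopifnot(batch_size >= 1, initial_lr > 0, rho > 0, rho < 1, eps > 0,
            plateau_patience >= 1, plateau_factor > 1,
            early_stop_patience >= 1, max_epochs >= 1, improve_tol >= 0,
            val_fraction > 0, val_fraction < 1)
  cfg <- list(batch_size = as.integer(batch_size), initial_lr = initial_lr,
              rho = rho, eps = eps,
              plateau_patience = as.integer(plateau_patience),
              plateau_factor = plateau_factor,
              early_stop_patience = as.integer(early_stop_patience),
              max_epochs = as.integer(max_epochs), improve_tol = improve_tol,
              val_fraction = val_fraction, seed = as.integer(seed))
  class(cfg) <- "mfadnet_train_config"
  cfg
}

#' Loss weights
#'
#' Non-negative weights of the four weak-supervision losses in the combined
#' objective.  The defaults (1, 0.5, 1, 1) down-weight the background loss,
#' which empirically favours stone detection rate.
#'
#' @param fg,bg,con,cls weights of the foreground, background, consistency
#'   and classification losses.
#' @param literal_sign audit flag: when `TRUE`, the consistency and
#'   classification losses use the sign-uncorrected form
#'   `-y*log(p) + (1-y)*log(1-p)` instead of binary cross-entropy.  The
#'   uncorrected form is unbounded below and unsuitable for training; it
#'   exists only for side-by-side inspection.
#' @return a list of class `mfadnet_loss_weights`.
#' @export
loss_weights <- function(fg = 1, bg = 0.5, con = 1, cls = 1,
                         literal_sign = FALSE) {
  w <- c(fg = fg, bg = bg, con = con, cls = cls)
  if (any(!is.finite(w)) || any(w < 0))
    stop("loss weights must be finite and non-negative", call. = FALSE)
  out <- list(fg = fg, bg = bg, con = con, cls = cls,
              literal_sign = isTRUE(literal_sign))
  class(out) <- "mfadnet_loss_weights"
  out
}
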