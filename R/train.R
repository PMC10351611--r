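# Weakly-supervised end-to-end training: RMSProp, reduce-on-plateau
# learning rate, early stopping, best-validation checkpointing.
#
# Improvement bookkeeping: epoch t improves iff its validation loss is at
# least `improve_tol` below the best of all earlier epochs; the first epoch
# never counts as an improvement (there is nothing to improve on).  The
# plateau and early-stop rules both act on the count of consecutive
# non-improving epochs at the end of the history.

nonimprove_streak <- function(val_losses, improve_tol = 1e-5) {
  n <- length(val_losses)
  if (n == 0) return(0L)
  improved <- logical(n)
  improved[1] <- FALSE
  if (n > 1) for (t in 2:n)
    improved[t] <- val_losses[t] <= min(val_losses[1:(t - 1)]) - improve_tol
  streak <- 0L
  for (t in n:1) {
    if (improved[t]) break
    streak <- streak + 1L
  }
  streak
}

#' Learning-rate plateau step
#'
#' Divides the learning rate by `plateau_factor` when the validation loss
#' has not improved for `plateau_patience` consecutive epochs; otherwise
#' returns it unchanged.
#'
#' @param val_losses per-epoch validation losses, oldest first.
#' @param current_lr current learning rate.
#' @param plateau_patience,plateau_factor,improve_tol see [train_config()].
#' @return the (possibly reduced) learning rate.
#' @export
lr_schedule_step <- function(val_losses, current_lr, plateau_patience = 5L,
                             plateau_factor = 10, improve_tol = 1e-5) {
  if (nonimprove_streak(val_losses, improve_tol) >= plateau_patience)
    current_lr / plateau_factor else current_lr
}

#' Early-stopping check
#'
#' `TRUE` iff the validation loss has not improved for
#' `early_stop_patience` consecutive epochs.
#'
#' @inheritParams lr_schedule_step
#' @param early_stop_patience see [train_config()].
#' @return logical.
#' @export
early_stop_check <- function(val_losses, early_stop_patience = 10L,
                             improve_tol = 1e-5) {
  nonimprove_streak(val_losses, improve_tol) >= early_stop_patience
}

#' Stratified validation carve-out
#'
#' @param manifest training manifest.
#' @param val_fraction fraction moved to validation, in `(0, 1)`.
#' @param seed shuffle seed.
#' @return list of manifests `train` and `val`, disjoint and exhaustive.
#' @export
make_validation_split <- function(manifest, val_fraction = 0.1, seed = 1L) {
  if (val_fraction <= 0 || val_fraction >= 1)
    stop("val_fraction must be in (0, 1)", call. = FALSE)
  sp <- split_dataset(manifest, train_frac = 1 - val_fraction,
                      val_frac = val_fraction, seed = seed)
  list(train = sp$train, val = sp$val)
}

# read every image of a manifest into memory as labeled slices
load_slices <- function(manifest, image_size = NULL, images = NULL) {
  lapply(seq_len(nrow(manifest)), function(i) {
    id <- manifest$image_id[i]
    img <- if (!is.null(images) && !is.null(images[[id]])) images[[id]] else
      read_image(manifest$path[i], image_size)
    list(image = img, label = manifest$label[i], image_id = id)
  })
}

# mean total loss over a slice list (evaluation mode)
eval_loss <- function(slices, params, config, weights) {
  mean(vapply(slices, function(sl) {
    out <- model_forward(sl$image, params, config, train = FALSE)
    loss_bundle(out, sl$label, weights)$bundle$total
  }, numeric(1)))
}

rmsprop_update <- function(params, grads, state, lr, rho, eps) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    v <- if (is.null(state[[nm]])) 0 * g else state[[nm]]
    v <- rho * v + (1 - rho) * g^2
    state[[nm]] <- v
    params[[nm]] <- params[[nm]] - lr * g / (sqrt(v) + eps)
  }
  list(params = params, state = state)
}

add_grads <- function(acc, g) {
  if (is.null(acc)) return(g)
  for (nm in names(g)) acc[[nm]] <- acc[[nm]] + g[[nm]]
  acc
}

# core training loop over in-memory slices
train_loop <- function(slices_tr, slices_va, params, config, tc, weights,
                       verbose = FALSE) {
  if (length(slices_tr) == 0) stop("empty training set", call. = FALSE)
  labs <- vapply(slices_tr, `[[`, numeric(1), "label")
  if (length(unique(labs)) < 2)
    warning("training set contains a single class; the weak-supervision ",
            "losses cannot localize anything", call. = FALSE)
  set.seed(tc$seed)
  lr <- tc$initial_lr
  state <- list()
  best <- Inf
  best_params <- params
  best_epoch <- 0L
  streak_lr <- 0L
  streak_stop <- 0L
  hist <- NULL
  n <- length(slices_tr)
  for (epoch in seq_len(tc$max_epochs)) {
    perm <- sample(n)
    comp <- c(fg = 0, bg = 0, con = 0, cls = 0, total = 0)
    for (start in seq(1, n, by = tc$batch_size)) {
      idx <- perm[start:min(start + tc$batch_size - 1L, n)]
      acc <- NULL
      for (i in idx) {
        sl <- slices_tr[[i]]
        out <- model_forward(sl$image, params, config, train = TRUE)
        lb <- loss_bundle(out, sl$label, weights)
        g <- model_backward(out, lb$dm_p, lb$dm_s, lb$dlogits, params,
                            config)
        acc <- add_grads(acc, g)
        comp <- comp + unlist(lb$bundle)
      }
      for (nm in names(acc)) acc[[nm]] <- acc[[nm]] / length(idx)
      upd <- rmsprop_update(params, acc, state, lr, tc$rho, tc$eps)
      params <- upd$params
      state <- upd$state
    }
    comp <- comp / n
    val <- eval_loss(slices_va, params, config, weights)
    hist <- rbind(hist, data.frame(epoch = epoch, loss_fg = comp["fg"],
                                   loss_bg = comp["bg"],
                                   loss_con = comp["con"],
                                   loss_cls = comp["cls"],
                                   train_loss = comp["total"],
                                   val_loss = val, lr = lr,
                                   row.names = NULL))
    if (val <= best - tc$improve_tol) {
      best <- val
      best_params <- params
      best_epoch <- epoch
      streak_lr <- 0L
      streak_stop <- 0L
    } else {
      streak_lr <- streak_lr + 1L
      streak_stop <- streak_stop + 1L
    }
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f  lr %.2e", epoch,
                      comp["total"], val, lr))
    if (streak_stop >= tc$early_stop_patience) break
    if (streak_lr >= tc$plateau_patience) {
      lr <- lr / tc$plateau_factor
      streak_lr <- 0L
    }
  }
  list(params = best_params, history = hist, best_epoch = best_epoch,
       best_val_loss = best, final_params = params)
}
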