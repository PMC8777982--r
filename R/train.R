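#' Training configuration
#'
#' Defaults follow the full-scale fundus training regime: Adam with initial
#' learning rate 1e-4 and epsilon 1e-6, 35 epochs, per-epoch shuffling and
#' global L2 gradient normalization (interpreted as clipping the global
#' gradient norm at `grad_norm`). Batch size 12 reproduces the published
#' bookkeeping (3840 augmented images / 12 = 320 iterations per epoch, x 35
#' epochs = 11,200 iterations). For short desk-scale runs on synthetic data
#' see [desk_training_config()].
#'
#' @param learning_rate Adam step size (> 0).
#' @param epochs number of passes over the training catalog (>= 1).
#' @param batch_size mini-batch size (>= 1).
#' @param epsilon Adam epsilon.
#' @param beta1,beta2 Adam moment decay rates.
#' @param grad_norm global L2 gradient-clipping threshold.
#' @param shuffle reshuffle the catalog each epoch.
#' @param weight_cap absent-class weight cap of the Dice loss.
#' @param seed seed governing shuffling (and, through [build_network()],
#'   any freshly initialized weights).
#' @return object of class `training_config`.
#' @export
training_config <- function(learning_rate = 1e-4,
                            epochs = 35L,
                            batch_size = 12L,
                            epsilon = 1e-6,
                            beta1 = 0.9,
                            beta2 = 0.999,
                            grad_norm = 1.0,
                            shuffle = TRUE,
                            weight_cap = 1e8,
                            seed = 1L) {
  stopifnot(learning_rate > 0, epochs >= 1, batch_size >= 1)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), epsilon = epsilon,
                 beta1 = beta1, beta2 = beta2, grad_norm = grad_norm,
                 shuffle = isTRUE(shuffle), weight_cap = weight_cap,
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Desk-scale training preset for synthetic data
#'
#' Five epochs over a small synthetic catalog is about 1% of the full-scale
#' iteration budget, so the preset raises the Adam step size to 1e-3;
#' everything else matches [training_config()].
#'
#' @param epochs,seed see [training_config()].
#' @return object of class `training_config`.
#' @export
desk_training_config <- function(epochs = 5L, seed = 1L) {
  training_config(learning_rate = 1e-3, epochs = epochs, seed = seed)
}

#' Train a segmentation model
#'
#' Runs `epochs * ceiling(N / batch_size)` Adam iterations on the
#' Generalized Dice Loss with per-epoch shuffling and global-L2 gradient
#' clipping. The loss and its gradient are computed in single precision by
#' the native network core; the run is fully reproducible for a given seed
#' on a single device.
#'
#' @param model a `segmentation_model` from [build_network()].
#' @param pairs list of [sample_pair()]s (the training catalog).
#' @param config a [training_config()].
#' @param checkpoint_path optional file path: the model (with history so
#'   far) is written there after every epoch, keeping only the latest.
#' @param verbose print per-epoch progress.
#' @return list with `model` (trained) and `history` (list with
#'   `iterations`: data.frame of per-iteration epoch/loss/pixel accuracy,
#'   and `epochs`: data.frame of per-epoch mean loss and training pixel
#'   accuracy). The history is also stored on the returned model.
#' @export
train <- function(model, pairs, config = training_config(),
                  checkpoint_path = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "segmentation_model"),
            inherits(config, "training_config"))
  n <- length(pairs)
  if (n == 0L) stop("training error: empty catalog", call. = FALSE)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(config$seed)

  params <- model$params
  mstate <- rapply(params, function(a) array(0, dim(a) %||% length(a)),
                   how = "replace")
  vstate <- mstate
  adam_t <- 0L
  n_batches <- ceiling(n / config$batch_size)
  hist_loss <- numeric(config$epochs * n_batches)
  hist_acc <- numeric(config$epochs * n_batches)
  hist_epoch <- integer(config$epochs * n_batches)
  it <- 0L

  for (ep in seq_len(config$epochs)) {
    ord <- if (config$shuffle) sample.int(n) else seq_len(n)
    for (bi in seq_len(n_batches)) {
      idx <- ord[((bi - 1L) * config$batch_size + 1L):
                   min(bi * config$batch_size, n)]
      res <- cpp_net_batch(params, model$plan,
                           lapply(pairs[idx], `[[`, "image"),
                           lapply(pairs[idx], `[[`, "mask"),
                           config$weight_cap)
      it <- it + 1L
      if (!is.finite(res$loss)) {
        stop("divergence error: non-finite loss at iteration ", it,
             call. = FALSE)
      }
      hist_loss[it] <- res$loss
      hist_acc[it] <- res$acc
      hist_epoch[it] <- ep

      # global L2 gradient clipping across every parameter tensor
      grads <- res$grads
      sq <- 0
      for (li in seq_along(grads)) {
        for (nm in names(grads[[li]])) {
          sq <- sq + sum(grads[[li]][[nm]]^2)
        }
      }
      scale <- if (sqrt(sq) > config$grad_norm) {
        config$grad_norm / sqrt(sq)
      } else {
        1
      }
      adam_t <- adam_t + 1L
      bc1 <- 1 - config$beta1^adam_t
      bc2 <- 1 - config$beta2^adam_t
      for (li in seq_along(grads)) {
        for (nm in names(grads[[li]])) {
          g <- grads[[li]][[nm]] * scale
          mstate[[li]][[nm]] <- config$beta1 * mstate[[li]][[nm]] +
            (1 - config$beta1) * g
          vstate[[li]][[nm]] <- config$beta2 * vstate[[li]][[nm]] +
            (1 - config$beta2) * g^2
          step <- config$learning_rate * (mstate[[li]][[nm]] / bc1) /
            (sqrt(vstate[[li]][[nm]] / bc2) + config$epsilon)
          params[[li]][[nm]] <- params[[li]][[nm]] - step
        }
      }
      # adopt updated BN running moments
      for (li in seq_along(res$bn)) {
        if (!is.null(res$bn[[li]])) {
          params[[li]]$rmean <- as.numeric(res$bn[[li]]$rmean)
          params[[li]]$rvar <- as.numeric(res$bn[[li]]$rvar)
        }
      }
    }
    if (verbose) {
      sel <- hist_epoch == ep
      message(sprintf("epoch %d/%d  loss %.4f  train acc %.4f", ep,
                      config$epochs, mean(hist_loss[sel]),
                      mean(hist_acc[sel])))
    }
    if (!is.null(checkpoint_path)) {
      ck <- model
      ck$params <- params
      ck$history <- list(
        iterations = data.frame(iteration = seq_len(it),
                                epoch = hist_epoch[seq_len(it)],
                                loss = hist_loss[seq_len(it)],
                                pixel_accuracy = hist_acc[seq_len(it)]),
        config = config
      )
      save_model(ck, checkpoint_path)  # keep-last policy
    }
  }

  model$params <- params
  model$history <- list(
    iterations = data.frame(iteration = seq_len(it), epoch = hist_epoch,
                            loss = hist_loss, pixel_accuracy = hist_acc),
    epochs = data.frame(
      epoch = seq_len(config$epochs),
      loss = vapply(seq_len(config$epochs),
                    function(e) mean(hist_loss[hist_epoch == e]), numeric(1)),
      pixel_accuracy = vapply(seq_len(config$epochs),
                              function(e) mean(hist_acc[hist_epoch == e]),
                              numeric(1))
    ),
    config = config
  )
  list(model = model, history = model$history)
}

#' Planned iteration count of a training run
#'
#' `epochs * ceiling(n_images / batch_size)`: 3840 images at batch 12 for
#' 35 epochs gives 11,200 iterations.
#'
#' @param n_images training catalog size.
#' @param config a [training_config()] (or anything with `epochs` and
#'   `batch_size`).
#' @return integer iteration count.
#' @export
planned_iterations <- function(n_images, config) {
  as.integer(config$epochs * ceiling(n_images / config$batch_size))
}

#' Evaluate a model on a test catalog
#'
#' Segments every pair and computes per-image accuracy, sensitivity,
#' specificity, AUC and Dice coefficient, plus a `mean` aggregate row
#' (mean over images).
#'
#' @param model a `segmentation_model`.
#' @param pairs list of [sample_pair()]s.
#' @param roi optional binary FOV mask applied to every image (or a list of
#'   per-image masks).
#' @param report_csv optional path: write the per-image report as CSV.
#' @param mask_dir optional directory: write predicted masks as 8-bit PNG.
#' @return data.frame with columns `id`, `accuracy`, `sensitivity`,
#'   `specificity`, `auc`, `dice`; the last row is the mean.
#' @export
evaluate <- function(model, pairs, roi = NULL, report_csv = NULL,
                     mask_dir = NULL) {
  if (length(pairs) == 0L) stop("evaluation error: empty catalog",
                                call. = FALSE)
  if (!is.null(mask_dir)) {
    dir.create(mask_dir, showWarnings = FALSE, recursive = TRUE)
  }
  rows <- lapply(seq_along(pairs), function(i) {
    pr <- pairs[[i]]
    res <- tryCatch(segment(model, pr$image), error = function(e) {
      stop("evaluation error for image '", pr$id, "': ",
           conditionMessage(e), call. = FALSE)
    })
    this_roi <- if (is.list(roi)) roi[[i]] else roi
    cc <- confusion(res$mask, pr$mask, roi = this_roi)
    if (!is.null(mask_dir)) {
      write_mask_png(res$mask, file.path(mask_dir, paste0(pr$id, "_pred.png")))
    }
    data.frame(
      id = pr$id,
      accuracy = accuracy(cc),
      sensitivity = sensitivity(cc),
      specificity = specificity(cc),
      auc = roc_auc(res$prob[, , 2], pr$mask, roi = this_roi),
      dice = 2 * cc$TP / (2 * cc$TP + cc$FP + cc$FN)
    )
  })
  rep <- do.call(rbind, rows)
  means <- data.frame(id = "mean", t(colMeans(rep[, -1])))
  names(means) <- names(rep)
  rep <- rbind(rep, means)
  if (!is.null(report_csv)) {
    utils::write.csv(rep, report_csv, row.names = FALSE)
  }
  rep
}
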