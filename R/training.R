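#' Training protocol configuration
#'
#' Defaults follow the reference protocol: batch size 8, initial learning
#' rate 0.001 with cosine annealing to 0, AdamW, at most 200 epochs, and
#' early stopping when the validation Dice has not improved by more than
#' `min_delta` for `patience` consecutive epochs.
#'
#' @param batch_size Images per optimization step (default 8).
#' @param lr0 Initial learning rate (default 0.001).
#' @param lr_min Final learning rate of the cosine schedule (default 0).
#' @param max_epochs Maximum epochs (default 200).
#' @param patience Consecutive non-improving epochs before stopping
#'   (default 20); must be below `max_epochs`.
#' @param min_delta Minimum absolute validation-Dice improvement that
#'   counts as progress (default 1e-4).
#' @param weight_decay Decoupled AdamW weight decay on convolution and
#'   ECA weights (default 1e-4); batch-norm parameters and biases are
#'   not decayed.
#' @param bce_w,dice_w Weights of the binary cross-entropy and soft-Dice
#'   terms of the composite loss (default 0.5 / 0.5).
#' @param deep_supervision Average the loss over all supervision heads
#'   (TRUE, default) or use only the deepest head.
#' @param seed Integer seed controlling shuffling (and any other
#'   randomness inside the loop).
#' @return An object of class `us_train_config`.
#' @export
train_config <- function(batch_size = 8, lr0 = 0.001, lr_min = 0,
                         max_epochs = 200, patience = 20, min_delta = 1e-4,
                         weight_decay = 1e-4, bce_w = 0.5, dice_w = 0.5,
                         deep_supervision = TRUE, seed = 1L) {
  stopifnot(batch_size >= 1, lr0 > 0, patience < max_epochs, max_epochs >= 1)
  structure(list(
    batch_size = as.integer(batch_size), lr0 = lr0, lr_min = lr_min,
    max_epochs = as.integer(max_epochs), patience = as.integer(patience),
    min_delta = min_delta, weight_decay = weight_decay,
    bce_w = bce_w, dice_w = dice_w,
    deep_supervision = isTRUE(deep_supervision), seed = as.integer(seed)
  ), class = "us_train_config")
}

#' Cosine-annealed learning rate
#'
#' `lr(e) = lr_min + (lr0 - lr_min) * (1 + cos(pi * e / max_epochs)) / 2`,
#' so training starts at `lr0` (epoch 0), passes `lr0 / 2` at the halfway
#' point, and ends at `lr_min`.
#'
#' @param epoch Zero-based epoch index, `0 <= epoch <= max_epochs`.
#' @param cfg A [train_config()] (or any list with `lr0`, `lr_min`,
#'   `max_epochs`).
#' @return The learning rate.
#' @export
cosine_lr <- function(epoch, cfg) {
  stopifnot(epoch >= 0, epoch <= cfg$max_epochs)
  cfg$lr_min + (cfg$lr0 - cfg$lr_min) *
    (1 + cos(pi * epoch / cfg$max_epochs)) / 2
}

#' Composite deep-supervision segmentation loss
#'
#' Per supervision head, `bce_w * BCE + dice_w * (1 - soft Dice)` (soft
#' Dice uses an additive smoothing constant and is computed per sample,
#' then averaged over the batch); the total is the mean over the heads
#' used (all heads under deep supervision, else the deepest only).
#'
#' @param outputs A probability array `(H, W, 1, N)` or a list of them
#'   (one per head), values in `(0, 1)`.
#' @param target Binary mask array broadcastable to each output.
#' @param cfg A [train_config()] supplying `bce_w`, `dice_w`,
#'   `deep_supervision`.
#' @return The scalar loss, with attribute `"components"` (named vector
#'   with the BCE and Dice terms of each head).
#' @export
composite_loss <- function(outputs, target, cfg = train_config()) {
  if (!is.list(outputs)) outputs <- list(outputs)
  if (!all(target %in% c(0, 1))) stop("target mask must be binary")
  use <- if (cfg$deep_supervision) seq_along(outputs) else length(outputs)
  comps <- c()
  total <- 0
  for (j in use) {
    p <- outputs[[j]]
    if (!identical(dim(p), dim(target))) {
      tgt <- array(target, dim(p))
    } else {
      tgt <- target
    }
    pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
    bce <- -mean(tgt * log(pc) + (1 - tgt) * log(1 - pc))
    d <- dim(p)
    m <- length(p) / d[4]
    pm <- matrix(p, m, d[4])
    tm <- matrix(tgt, m, d[4])
    sdice <- mean((2 * colSums(pm * tm) + 1) / (colSums(pm) + colSums(tm) + 1))
    total <- total + cfg$bce_w * bce + cfg$dice_w * (1 - sdice)
    comps <- c(comps, stats::setNames(c(bce, 1 - sdice),
                                      paste0(c("bce", "dice"), j)))
  }
  structure(total / length(use), components = comps)
}

#' Early-stopping bookkeeping on a validation-metric sequence
#'
#' Replays the early-stopping protocol over a sequence of per-epoch
#' validation metrics: an epoch counts as an improvement when it exceeds
#' the best seen so far by more than `min_delta`; training stops at the
#' first epoch whose run of consecutive non-improvements reaches
#' `patience`. [train_segmenter()] applies exactly this rule online.
#'
#' @param metric_seq Numeric vector of per-epoch validation metrics.
#' @param patience Consecutive non-improving epochs tolerated.
#' @param min_delta Minimum improvement that resets the counter.
#' @return List with `stopped_epoch`, `best_epoch`, `best`, and
#'   `stopped_by`.
#' @export
early_stopping_trace <- function(metric_seq, patience, min_delta = 1e-4) {
  best <- -Inf
  best_epoch <- 0L
  since <- 0L
  stopped <- length(metric_seq)
  stopped_by <- "max_epochs"
  for (e in seq_along(metric_seq)) {
    if (metric_seq[e] > best + min_delta) {
      best <- metric_seq[e]
      best_epoch <- e
      since <- 0L
    } else {
      since <- since + 1L
      if (since >= patience) {
        stopped <- e
        stopped_by <- "early_stopping"
        break
      }
    }
  }
  list(stopped_epoch = stopped, best_epoch = best_epoch, best = best,
       stopped_by = stopped_by)
}

#' Train a segmentation model
#'
#' Full training protocol: shuffled mini-batches, composite
#' deep-supervision loss, AdamW with cosine-annealed learning rate,
#' per-epoch validation Dice (deepest head, threshold 0.5), retention of
#' the best-validation-Dice parameters, and early stopping after
#' `patience` consecutive epochs without improvement. Fully deterministic
#' given the model/config seeds.
#'
#' @param model A `us_model` (modified in place; the returned model has
#'   the best-epoch parameters restored).
#' @param train_pairs,val_pairs Lists of sample pairs (image/mask/id).
#' @param cfg A [train_config()].
#' @param verbose Print one line per epoch.
#' @return An object of class `us_fit`: list with `model`, `history`
#'   (tibble: epoch, lr, train_loss, val_dice), `best_val_dice`,
#'   `best_epoch`, `stopped_epoch`, and `stopped_by`
#'   (`"early_stopping"` or `"max_epochs"`).
#' @export
train_segmenter <- function(model, train_pairs, val_pairs,
                            cfg = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "us_model"), length(train_pairs) > 0,
            length(val_pairs) > 0)
  tr <- pairs_to_arrays(train_pairs)
  n <- length(train_pairs)
  val_imgs <- pairs_to_arrays(val_pairs)$images
  val_masks <- lapply(val_pairs, function(p) p$mask)
  best <- -Inf
  best_epoch <- 0L
  best_snap <- snapshot_params(model$layers)
  since_improve <- 0L
  hist <- list()
  stopped_by <- "max_epochs"
  withr::with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$max_epochs)) {
      lr <- cosine_lr(epoch - 1, cfg)
      perm <- sample.int(n)
      losses <- c()
      for (bstart in seq(1, n, by = cfg$batch_size)) {
        bidx <- perm[bstart:min(bstart + cfg$batch_size - 1, n)]
        x <- tr$images[, , , bidx, drop = FALSE]
        y <- tr$masks[, , , bidx, drop = FALSE]
        run <- run_program(model, x, training = TRUE)
        L <- model$cfg$depth
        head_ids <- vapply(seq_len(L), function(j) {
          get(sprintf("head%d", j), envir = run$ids)
        }, integer(1))
        use <- if (cfg$deep_supervision) head_ids else head_ids[L]
        loss_ids <- vapply(use, function(h) {
          op_bce_dice(run$tape, h, y, cfg$bce_w, cfg$dice_w)
        }, integer(1))
        loss_id <- op_mean_scalars(run$tape, loss_ids)
        loss <- tp_val(run$tape, loss_id)
        if (!is.finite(loss)) {
          stop(sprintf(
            "training diverged: non-finite loss at epoch %d (lr %.2g)",
            epoch, lr))
        }
        tape_backward(run$tape, loss_id)
        adamw_step(model$layers, lr, weight_decay = cfg$weight_decay)
        losses <- c(losses, loss)
      }
      probs <- predict_probs(model, val_imgs)
      vdice <- mean(vapply(seq_along(val_masks), function(i) {
        suppressWarnings(dice((probs[, , i] > 0.5) * 1, val_masks[[i]]))
      }, numeric(1)))
      hist[[epoch]] <- tibble::tibble(
        epoch = epoch, lr = lr, train_loss = mean(losses), val_dice = vdice)
      if (verbose) {
        message(sprintf("epoch %3d | lr %.5f | loss %.4f | val Dice %.4f",
                        epoch, lr, mean(losses), vdice))
      }
      if (vdice > best + cfg$min_delta) {
        best <- vdice
        best_epoch <- epoch
        best_snap <- snapshot_params(model$layers)
        since_improve <- 0L
      } else {
        since_improve <- since_improve + 1L
        if (since_improve >= cfg$patience) {
          stopped_by <- "early_stopping"
          break
        }
      }
    }
  })
  restore_params(model$layers, best_snap)
  structure(list(
    model = model, history = dplyr::bind_rows(hist),
    best_val_dice = best, best_epoch = best_epoch,
    stopped_epoch = length(hist), stopped_by = stopped_by, cfg = cfg
  ), class = "us_fit")
}

#' @export
print.us_fit <- function(x, ...) {
  cat(sprintf(
    "<us_fit> %d epoch(s) (%s), best val Dice %.4f at epoch %d\n",
    x$stopped_epoch, x$stopped_by, x$best_val_dice, x$best_epoch))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-epoch training history
#' @param x A `us_fit`.
#' @param ... Unused.
#' @return Tibble with epoch, lr, train_loss, val_dice.
#' @export
tidy.us_fit <- function(x, ...) x$history

#' One-row training summary
#' @param x A `us_fit`.
#' @param ... Unused.
#' @export
glance.us_fit <- function(x, ...) {
  tibble::tibble(
    epochs = x$stopped_epoch, best_epoch = x$best_epoch,
    best_val_dice = x$best_val_dice, stopped_by = x$stopped_by,
    final_train_loss = utils::tail(x$history$train_loss, 1),
    parameters = count_parameters(x$model)
  )
}

#' Per-image evaluation table
#' @param x A `us_eval`.
#' @param ... Unused.
#' @export
tidy.us_eval <- function(x, ...) x$per_image

#' One-row evaluation summary (macro and pooled aggregates)
#' @param x A `us_eval`.
#' @param ... Unused.
#' @export
glance.us_eval <- function(x, ...) {
  out <- c(stats::setNames(as.list(x$macro), paste0("macro_", names(x$macro))),
           stats::setNames(as.list(x$pooled),
                           paste0("pooled_", names(x$pooled))),
           list(hausdorff_excluded = x$hausdorff_excluded))
  tibble::as_tibble(out)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot training history
#' @param object A `us_fit`.
#' @param ... Unused.
#' @return A ggplot of training loss and validation Dice per epoch.
#' @export
autoplot.us_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, c("train_loss", "val_dice"),
                            names_to = "series", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = "Training loss and validation Dice") +
    ggplot2::theme_minimal()
}

#' Plot a pooled ROC curve
#' @param object A `us_roc` from [roc_auc()].
#' @param ... Unused.
#' @export
autoplot.us_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("Pooled pixelwise ROC (AUC = %.3f)",
                                  object$auc)) +
    ggplot2::theme_minimal()
}

#' Plot a phantom sample
#' @param object A `us_phantom_sample`.
#' @param ... Unused.
#' @return A ggplot showing the rendered image with the lesion contour.
#' @export
autoplot.us_phantom_sample <- function(object, ...) {
  n <- nrow(object$image)
  # column-major order: row varies fastest, matching as.vector()
  df <- tidyr::expand_grid(col = seq_len(n), row = seq_len(n))
  df$intensity <- as.vector(object$image)
  bp <- boundary_points(object$mask)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::geom_point(data = tibble::tibble(col = bp[, 2], row = bp[, 1]),
                        colour = "red", size = 0.2) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(title = sprintf("Phantom #%d", object$index))
  }
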