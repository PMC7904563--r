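#' Train the junction segmentation network
#'
#' Minimises `1 - soft_dice` with Adam over shuffled epochs. Each sampled
#' pair is randomly cropped to `config$input_size_px` (training crops are
#' smaller than the stored images, as in the acquisition-scale recipe
#' where 1024-px fields are cropped to 256-px inputs). Every
#' `config$eval_interval` updates the mean held-out loss is evaluated, the
#' mean training loss over the interval recorded, and the parameters
#' snapshotted, producing the two loss-vs-updates curves used for
#' checkpoint selection. Training is fully seeded and aborts with a
#' diagnostic if the loss diverges to NaN.
#'
#' @param train_pairs,heldout_pairs Lists of `list(image, mask)` pairs
#'   with binary masks, e.g. from [augment_pair()].
#' @param config A [segmenter_config()].
#' @param verbose Print a line per evaluation.
#' @return List with `model` (final-update `tj_segmenter`) and `state`, a
#'   `train_state`: `updates`, `train_loss`, `heldout_loss`, `snapshots`,
#'   and `selected_update` from [select_checkpoint()].
#' @export
train_segmenter <- function(train_pairs, heldout_pairs,
                            config = segmenter_config(), verbose = FALSE) {
  stopifnot(length(train_pairs) > 0, length(heldout_pairs) > 0)
  for (p in train_pairs)
    if (any(p$mask != 0 & p$mask != 1)) stop("masks must be binary")
  model <- new_segmenter(config)
  n <- length(train_pairs)
  total <- if (!is.null(config$n_updates)) config$n_updates else
    config$n_epochs * ceiling(n / config$batch_size)
  set.seed(config$rng_seed + 1L)
  opt <- NULL
  order_pool <- integer()
  updates <- integer(); train_curve <- numeric(); heldout_curve <- numeric()
  snapshots <- list()
  interval_losses <- numeric()
  for (t in seq_len(total)) {
    if (length(order_pool) < config$batch_size)
      order_pool <- c(order_pool, sample.int(n))
    batch <- order_pool[seq_len(config$batch_size)]
    order_pool <- order_pool[-seq_len(config$batch_size)]
    gsum <- NULL
    bloss <- 0
    for (i in batch) {
      pr <- .crop_pair(train_pairs[[i]], config)
      fw <- .net_fwd(model$params, config, pr$image)
      lg <- .dice_loss_grad(fw$prob, pr$mask)
      bloss <- bloss + lg$loss
      g <- .net_bwd(model$params, config, fw$cache, lg$dprob)
      gsum <- if (is.null(gsum)) g else .grad_add(gsum, g)
    }
    bloss <- bloss / length(batch)
    if (!is.finite(bloss))
      stop("training diverged: loss is not finite at update ", t)
    gsum <- .grad_scale(gsum, 1 / length(batch))
    st <- .adam_step(model$params, gsum, opt, config$learning_rate,
                     config$weight_decay, t)
    model$params <- st$p
    opt <- st$s
    interval_losses <- c(interval_losses, bloss)
    if (t %% config$eval_interval == 0 || t == total) {
      hl <- evaluate_loss(model, heldout_pairs)
      updates <- c(updates, t)
      train_curve <- c(train_curve, mean(interval_losses))
      heldout_curve <- c(heldout_curve, hl)
      snapshots[[length(snapshots) + 1]] <- model$params
      interval_losses <- numeric()
      if (verbose)
        message(sprintf("update %d: train %.4f held-out %.4f",
                        t, utils::tail(train_curve, 1), hl))
    }
  }
  state <- structure(list(updates = updates, train_loss = train_curve,
                          heldout_loss = heldout_curve,
                          snapshots = snapshots),
                     class = "train_state")
  state$selected_update <- select_checkpoint(state)
  list(model = model, state = state)
}

# deterministic-size random crop to the configured input size (the crop
# position consumes RNG, which is seeded by the training loop)
.crop_pair <- function(pair, config) {
  cs <- config$input_size_px
  H <- nrow(pair$image); W <- ncol(pair$image)
  if (H == cs && W == cs) return(pair)
  if (H < cs || W < cs) stop("training pair smaller than input_size_px")
  r <- sample.int(H - cs + 1, 1); c <- sample.int(W - cs + 1, 1)
  list(image = pair$image[r:(r + cs - 1), c:(c + cs - 1)],
       mask = pair$mask[r:(r + cs - 1), c:(c + cs - 1)])
}

#' Mean soft-Dice loss of a model over a set of pairs
#' @param model A `tj_segmenter`.
#' @param pairs List of `list(image, mask)`.
#' @return Mean `1 - soft_dice`.
#' @export
evaluate_loss <- function(model, pairs) {
  mean(vapply(pairs, function(p) {
    prob <- predict_probability(model, p$image)
    1 - soft_dice(prob, p$mask)
  }, numeric(1)))
}

#' Select the training checkpoint from the held-out loss curve
#'
#' Returns the update index minimising the moving-average-smoothed
#' held-out loss (window `smooth_window` evaluation points, centred,
#' truncated at the ends); ties break to the earliest update. This is the
#' read-the-minimum-off-the-curve rule used to pick the final model before
#' overfitting sets in.
#'
#' @param state A `train_state`.
#' @param smooth_window Moving-average window in evaluation points.
#' @return The selected update index (an element of `state$updates`).
#' @export
select_checkpoint <- function(state, smooth_window = 5) {
  y <- state$heldout_loss
  stopifnot(length(y) > 0)
  n <- length(y)
  half <- (smooth_window - 1) %/% 2
  sm <- vapply(seq_len(n), function(i)
    mean(y[max(1, i - half):min(n, i + half)]), numeric(1))
  state$updates[which.min(sm)]
}

#' Restore the model parameters of a recorded checkpoint
#' @param model A `tj_segmenter` returned by [train_segmenter()].
#' @param state The matching `train_state`.
#' @param update Update index; defaults to `state$selected_update`.
#' @return The model with that checkpoint's parameters.
#' @export
restore_checkpoint <- function(model, state, update = state$selected_update) {
  i <- match(update, state$updates)
  if (is.na(i)) stop("no checkpoint recorded at update ", update)
  model$params <- state$snapshots[[i]]
  model
}

#' Save / load a trained segmenter (single-file archive, config embedded)
#' @param model A `tj_segmenter`.
#' @param path File path.
#' @export
save_segmenter <- function(model, path) saveRDS(model, path)

#' @rdname save_segmenter
#' @export
load_segmenter <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "tj_segmenter"))
  m
}

#' @export
print.train_state <- function(x, ...) {
  cat(sprintf(
    "<train_state> %d evaluations to update %d; selected update %d (held-out loss %.4f)\n",
    length(x$updates), max(x$updates), x$selected_update,
    x$heldout_loss[match(x$selected_update, x$updates)]))
  invisible(x)
}
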