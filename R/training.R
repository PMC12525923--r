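# Training regime: hybrid cross-entropy + soft-Dice loss, AdamW with
# per-epoch or plateau learning-rate decay, loss bookkeeping (raw and
# exponentially smoothed train/validation series) and per-epoch validation
# precision / MIoU.

#' Training configuration
#'
#' Defaults follow the full-scale regime: initial learning rate 6e-5, decay
#' factor 0.8, batch size 8, 200 epochs, AdamW. Two schedule modes exist:
#' `"epoch_decay"` multiplies the learning rate by the decay factor after
#' every epoch; `"plateau"` (default) multiplies only when the smoothed
#' validation loss has not improved for `plateau_patience` epochs.
#'
#' @param initial_lr initial learning rate.
#' @param lr_decay_factor multiplicative decay in (0, 1].
#' @param schedule_mode `"plateau"` or `"epoch_decay"`.
#' @param plateau_patience epochs without improvement before a plateau decay.
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param k_folds optional fold count for cross-validation mode.
#' @param loss_weights length-2 numeric `c(w_ce, w_dice)`, non-negative, not
#'   both zero.
#' @param class_weights optional per-class cross-entropy weights.
#' @param smoothing_alpha EMA coefficient in (0, 1] for the smoothed loss
#'   series.
#' @param weight_decay,beta1,beta2,adam_eps AdamW hyperparameters.
#' @param seed integer seed governing batch shuffling.
#' @return an object of class `train_config`.
#' @export
train_config <- function(initial_lr = 6e-5, lr_decay_factor = 0.8,
                         schedule_mode = c("plateau", "epoch_decay"),
                         plateau_patience = 5L, batch_size = 8L, epochs = 200L,
                         k_folds = NULL, loss_weights = c(ce = 1, dice = 1),
                         class_weights = NULL, smoothing_alpha = 0.1,
                         weight_decay = 0.01, beta1 = 0.9, beta2 = 0.999,
                         adam_eps = 1e-8, seed = 0L) {
  schedule_mode <- match.arg(schedule_mode)
  assert_that(initial_lr > 0, "initial_lr must be positive")
  assert_that(lr_decay_factor > 0 && lr_decay_factor <= 1,
              "lr_decay_factor must lie in (0, 1]")
  assert_that(batch_size >= 1L, "batch_size must be >= 1")
  assert_that(length(loss_weights) == 2L && all(loss_weights >= 0) &&
                sum(loss_weights) > 0,
              "loss_weights must be two non-negative values, not both zero")
  assert_that(smoothing_alpha > 0 && smoothing_alpha <= 1,
              "smoothing_alpha must lie in (0, 1]")
  structure(list(initial_lr = initial_lr, lr_decay_factor = lr_decay_factor,
                 schedule_mode = schedule_mode,
                 plateau_patience = as.integer(plateau_patience),
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 k_folds = if (is.null(k_folds)) NULL else as.integer(k_folds),
                 loss_weights = unname(loss_weights),
                 class_weights = class_weights,
                 smoothing_alpha = smoothing_alpha,
                 weight_decay = weight_decay, beta1 = beta1, beta2 = beta2,
                 adam_eps = adam_eps, seed = as.integer(seed)),
            class = "train_config")
}

#' Hybrid segmentation loss
#'
#' `w_ce * CE + w_dice * (1 - mean soft Dice)` where CE is (optionally
#' class-weighted) cross-entropy of the softmax over the class axis and soft
#' Dice is computed per class from the softmax probabilities and averaged.
#' The loss approaches zero exactly when the prediction is a perfect hard
#' assignment in the saturated-logit limit.
#'
#' @param logits H x W x K array of class scores.
#' @param mask H x W integer label matrix with labels in 0..K-1.
#' @param loss_weights length-2 `c(w_ce, w_dice)`.
#' @param class_weights optional length-K cross-entropy class weights.
#' @return scalar loss with attributes `ce` and `dice` holding the
#'   components.
#' @export
hybrid_loss <- function(logits, mask, loss_weights = c(1, 1), class_weights = NULL) {
  d <- dim(logits)
  assert_that(length(d) == 3L, "logits must be an H x W x K array")
  assert_that(identical(d[1:2], dim(mask)), "logits and mask shapes disagree")
  tape <- tape_new(8L)
  z <- tp_input(tape, matrix(logits, d[1] * d[2], d[3]))
  node <- tp_hybrid_loss_node(tape, z, as.integer(mask), loss_weights[1],
                              loss_weights[2], class_weights)
  v <- tp_val(tape, node)
  out <- v[1]
  attr(out, "ce") <- attr(v, "ce")
  attr(out, "dice") <- attr(v, "dice")
  out
}

#' Learning rate at a given epoch
#'
#' In `epoch_decay` mode the rate is `initial_lr * factor^epoch` (epoch 0 is
#' the first). In `plateau` mode the rate starts at `initial_lr` and is
#' multiplied by the factor each time the smoothed per-epoch validation loss
#' fails to improve for `plateau_patience` consecutive epochs; the smoothed
#' series is taken from `history` (epochs completed so far). Without history
#' the plateau rate is the initial rate.
#'
#' @param config a [train_config()].
#' @param epoch 0-based epoch index.
#' @param history optional `train_history` (or numeric vector of smoothed
#'   per-epoch validation losses for completed epochs).
#' @return the learning rate used during `epoch`.
#' @export
lr_at_epoch <- function(config, epoch, history = NULL) {
  stopifnot(inherits(config, "train_config"), epoch >= 0)
  if (config$schedule_mode == "epoch_decay") {
    return(config$initial_lr * config$lr_decay_factor^epoch)
  }
  sv <- if (inherits(history, "train_history")) history$epochs$smoothed_val_loss
        else history
  if (is.null(sv) || epoch == 0L) return(config$initial_lr)
  sv <- sv[seq_len(min(length(sv), epoch))]
  lr <- config$initial_lr
  best <- Inf; wait <- 0L
  for (v in sv) {
    if (is.finite(v) && v < best - 1e-12) {
      best <- v; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$plateau_patience) {
        lr <- lr * config$lr_decay_factor
        wait <- 0L
      }
    }
  }
  lr
}

#' Exponential moving average smoothing of a loss series
#'
#' `s_1 = x_1`, `s_t = alpha * x_t + (1 - alpha) * s_(t-1)`.
#'
#' @param raw non-empty numeric series.
#' @param alpha EMA coefficient in (0, 1].
#' @return smoothed series of the same length.
#' @export
smooth_losses <- function(raw, alpha) {
  assert_that(length(raw) >= 1L, "cannot smooth an empty series")
  assert_that(alpha > 0 && alpha <= 1, "alpha must lie in (0, 1]")
  out <- numeric(length(raw))
  out[1] <- raw[1]
  if (length(raw) > 1) {
    for (t in 2:length(raw)) out[t] <- alpha * raw[t] + (1 - alpha) * out[t - 1]
  }
  out
}

#' Balanced k-fold assignment
#'
#' Random disjoint folds covering 1..n with sizes differing by at most one.
#'
#' @param n number of samples.
#' @param k number of folds (2 <= k <= n).
#' @param seed integer seed.
#' @return integer vector of fold labels 1..k.
#' @export
kfold_assign <- function(n, k, seed = 0L) {
  assert_that(k >= 2L && k <= n, "need 2 <= k <= n")
  with_seed(seed, {
    folds <- rep(seq_len(k), length.out = n)
    sample(folds)
  })
}

# --- AdamW ------------------------------------------------------------------

adamw_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

# Decoupled weight decay applied to projection matrices only (names containing
# ".W"); layer-norm gains/offsets and biases are not decayed.
adamw_step <- function(params, grads, state, lr, cfg) {
  state$t <- state$t + 1L
  b1 <- cfg$beta1; b2 <- cfg$beta2
  bc1 <- 1 - b1^state$t; bc2 <- 1 - b2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    upd <- mhat / (sqrt(vhat) + cfg$adam_eps)
    if (cfg$weight_decay > 0 && grepl("\\.W", nm)) {
      upd <- upd + cfg$weight_decay * params[[nm]]
    }
    params[[nm]] <- params[[nm]] - lr * upd
  }
  list(params = params, state = state)
}

# --- training loop ----------------------------------------------------------

samples_dims <- function(samples) {
  d <- dim(samples[[1]]$mask)
  for (s in samples) {
    assert_that(identical(dim(s$mask), d), "all samples must share one image size")
  }
  d
}

# Batched forward to the loss node; returns list(tape, logits_id, loss_id).
forward_loss_batch <- function(model, ids_cache, samples, cfg, tcfg) {
  d <- dim(samples[[1]]$mask)
  B <- length(samples)
  tape <- tape_new(4096L)
  ids <- reg_params(tape, model)
  X <- do.call(rbind, lapply(samples, function(s) normalize_image(s$image)))
  pyr <- encoder_tape(tape, ids, tp_input(tape, X), d[1], d[2], cfg, B)
  pyr <- cfpt_tape(tape, ids, pyr, cfg, B)
  lg <- decoder_tape(tape, ids, pyr, cfg, d[1], d[2], B)
  labels <- unlist(lapply(samples, function(s) as.integer(s$mask)))
  loss <- tp_hybrid_loss_node(tape, lg, labels, tcfg$loss_weights[1],
                              tcfg$loss_weights[2], tcfg$class_weights)
  list(tape = tape, ids = ids, logits = lg, loss = loss, B = B, d = d)
}

# Forward-only evaluation of precision / MIoU over a sample list, with
# intersection/union counts aggregated across all pixels of the set.
evaluate_model <- function(model, samples, batch_size = 8L) {
  cfg <- model$config
  K <- cfg$num_classes
  inter <- uni <- numeric(K)
  correct <- 0; total <- 0
  i <- 1L
  while (i <= length(samples)) {
    chunk <- samples[i:min(i + batch_size - 1L, length(samples))]
    fw <- forward_loss_batch(model, NULL, chunk, cfg, train_config())
    LG <- tp_val(fw$tape, fw$logits)
    pred <- max.col(LG, ties.method = "first") - 1L
    gt <- unlist(lapply(chunk, function(s) as.integer(s$mask)))
    correct <- correct + sum(pred == gt)
    total <- total + length(gt)
    for (k in seq_len(K) - 1L) {
      p <- pred == k; g <- gt == k
      inter[k + 1L] <- inter[k + 1L] + sum(p & g)
      uni[k + 1L] <- uni[k + 1L] + sum(p | g)
    }
    i <- i + batch_size
  }
  valid <- uni > 0
  list(precision = correct / total,
       per_class_iou = ifelse(valid, inter / pmax(uni, 1), NA_real_),
       miou = mean((inter / pmax(uni, 1))[valid]))
}

#' Train a segmentation model
#'
#' Runs `epochs` passes of AdamW minibatch updates with the hybrid loss,
#' recording per-batch training loss, per-batch validation loss (one
#' validation sample per batch, cycled), their EMA-smoothed versions, and
#' per-epoch learning rate, pixel precision and MIoU on the full validation
#' set. The run is fully reproducible from the config seed. A non-finite
#' loss aborts the run, returning the last finite parameters.
#'
#' @param model a `seg_model`.
#' @param train_samples,val_samples lists of `stoma_sample` objects (equal
#'   image sizes, sides divisible by 32).
#' @param config a [train_config()].
#' @param verbose print one line per epoch.
#' @return list with `model` (trained) and `history` (a `train_history`:
#'   data.frames `batches` and `epochs`).
#' @export
train_model <- function(model, train_samples, val_samples, config = train_config(),
                        verbose = FALSE) {
  stopifnot(inherits(model, "seg_model"), inherits(config, "train_config"))
  assert_that(length(train_samples) >= 1L, "empty training partition")
  assert_that(length(val_samples) >= 1L, "empty validation partition")
  samples_dims(c(train_samples, val_samples))
  cfg <- model$config
  params <- model$params
  state <- adamw_init(params)

  n <- length(train_samples)
  bs <- min(config$batch_size, n)
  alpha <- config$smoothing_alpha
  batches <- list()
  epochs_rec <- list()
  sm_tr <- sm_va <- NULL
  lr <- config$initial_lr
  plateau_best <- Inf; plateau_wait <- 0L
  epoch_sm_val <- numeric(0)
  val_cursor <- 0L
  aborted <- FALSE

  for (epoch in seq_len(config$epochs) - 1L) {
    ord <- with_seed(derive_seed(config$seed, epoch), sample.int(n))
    epoch_val_losses <- numeric(0)
    nb <- ceiling(n / bs)
    for (bi in seq_len(nb)) {
      sel <- ord[((bi - 1L) * bs + 1L):min(bi * bs, n)]
      cur <- model; cur$params <- params
      fw <- forward_loss_batch(cur, NULL, train_samples[sel], cfg, config)
      lval <- tp_val(fw$tape, fw$loss)[1]
      if (!is.finite(lval)) {
        warning(sprintf("non-finite loss at epoch %d batch %d; aborting with last finite checkpoint",
                        epoch, bi), call. = FALSE)
        aborted <- TRUE
        break
      }
      gr <- tp_backward(fw$tape, fw$loss)
      grads <- list()
      for (nm in names(params)) grads[[nm]] <- gr[[pid(fw$ids, nm)]]
      st <- adamw_step(params, grads, state, lr, config)
      params <- st$params; state <- st$state

      val_cursor <- val_cursor %% length(val_samples) + 1L
      vcur <- model; vcur$params <- params
      vf <- forward_loss_batch(vcur, NULL, val_samples[val_cursor], cfg, config)
      vloss <- tp_val(vf$tape, vf$loss)[1]
      epoch_val_losses <- c(epoch_val_losses, vloss)

      sm_tr <- if (is.null(sm_tr)) lval else alpha * lval + (1 - alpha) * sm_tr
      sm_va <- if (is.null(sm_va)) vloss else alpha * vloss + (1 - alpha) * sm_va
      batches[[length(batches) + 1L]] <- data.frame(
        epoch = epoch, batch = bi, train_loss = lval, val_loss = vloss,
        smoothed_train_loss = sm_tr, smoothed_val_loss = sm_va, lr = lr)
    }
    if (aborted) break

    cur <- model; cur$params <- params
    ev <- evaluate_model(cur, val_samples, bs)
    epochs_rec[[length(epochs_rec) + 1L]] <- data.frame(
      epoch = epoch, lr = lr, precision = ev$precision, miou = ev$miou,
      mean_val_loss = mean(epoch_val_losses),
      smoothed_val_loss = NA_real_)
    # epoch-level smoothed validation loss drives the plateau schedule
    ev_loss <- mean(epoch_val_losses)
    epoch_sm_val <- c(epoch_sm_val,
                      if (length(epoch_sm_val) == 0) ev_loss
                      else alpha * ev_loss + (1 - alpha) * utils::tail(epoch_sm_val, 1))
    epochs_rec[[length(epochs_rec)]]$smoothed_val_loss <- utils::tail(epoch_sm_val, 1)
    if (verbose) {
      message(sprintf("epoch %3d  lr %.2e  loss %.4f  val %.4f  prec %.4f  miou %.4f",
                      epoch, lr, utils::tail(batches, 1)[[1]]$train_loss,
                      ev_loss, ev$precision, ev$miou))
    }
    # schedule update for the next epoch
    if (config$schedule_mode == "epoch_decay") {
      lr <- lr * config$lr_decay_factor
    } else {
      v <- utils::tail(epoch_sm_val, 1)
      if (is.finite(v) && v < plateau_best - 1e-12) {
        plateau_best <- v; plateau_wait <- 0L
      } else {
        plateau_wait <- plateau_wait + 1L
        if (plateau_wait >= config$plateau_patience) {
          lr <- lr * config$lr_decay_factor
          plateau_wait <- 0L
        }
      }
    }
  }

  model$params <- params
  history <- structure(list(batches = do.call(rbind, batches),
                            epochs = do.call(rbind, epochs_rec),
                            aborted = aborted, config = config),
                       class = "train_history")
  list(model = model, history = history)
}

#' k-fold cross-validation training
#'
#' Splits `samples` into k balanced folds; each fold in turn serves as the
#' validation set while the remaining folds train a model restarted from the
#' same initial weights.
#'
#' @param model a freshly built `seg_model` (per-fold runs restart from its
#'   weights).
#' @param samples list of samples.
#' @param config a [train_config()] with `k_folds` set (default 5).
#' @return list of per-fold [train_model()] results.
#' @export
cross_validate <- function(model, samples, config = train_config(k_folds = 5L)) {
  k <- config$k_folds %||% 5L
  folds <- kfold_assign(length(samples), k, config$seed)
  lapply(seq_len(k), function(f) {
    train_model(model, samples[folds != f], samples[folds == f], config)
  })
}

#' Write a training history to CSV
#'
#' @param history a `train_history`.
#' @param path batch-level CSV path; an `_epochs.csv` sibling stores the
#'   per-epoch records.
#' @return `path` invisibly.
#' @export
write_history_csv <- function(history, path) {
  stopifnot(inherits(history, "train_history"))
  utils::write.csv(history$batches, path, row.names = FALSE)
  utils::write.csv(history$epochs, sub("\\.csv$", "_epochs.csv", path),
                   row.names = FALSE)
  invisible(path)
}
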