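# Optimization loop: AdamW with per-batch linear warm-up and cosine
# annealing, best-validation checkpointing, and seeded evaluation.

#' Training configuration
#'
#' @param epochs Total epochs (default 100).
#' @param batch_size Minibatch size (default 32).
#' @param lr_start Warm-up starting learning rate (default 1e-6).
#' @param lr_peak Peak learning rate reached at the end of warm-up
#'   (default 0.01).
#' @param lr_floor Cosine-annealing floor (default 1e-6).
#' @param warmup_epochs Linear warm-up length in epochs (default 2).
#' @param weight_decay Decoupled AdamW weight decay on weight matrices
#'   (default 1e-4).
#' @param clip_norm Global gradient-norm clip (default 5; `Inf` disables).
#'   Keeps the aggressive peak learning rate stable on small step counts.
#' @param seed Seed controlling initialization and batch shuffling.
#' @param alpha,ndcg_temperature,sigma_init Loss parameters, see
#'   [loss_state()].
#' @return Object of class `train_config`.
#' @export
train_config <- function(epochs = 100L, batch_size = 32L,
                         lr_start = 1e-6, lr_peak = 0.01, lr_floor = 1e-6,
                         warmup_epochs = 2L, weight_decay = 1e-4,
                         clip_norm = 5.0, seed = 1L, alpha = 1.0,
                         ndcg_temperature = 1.0, sigma_init = 1.0) {
  stopifnot(epochs >= 1, batch_size >= 1, lr_start < lr_peak,
            warmup_epochs < epochs, lr_floor <= lr_peak, weight_decay >= 0,
            clip_norm > 0)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr_start = lr_start, lr_peak = lr_peak, lr_floor = lr_floor,
                 warmup_epochs = as.integer(warmup_epochs),
                 weight_decay = weight_decay, clip_norm = clip_norm,
                 seed = as.integer(seed),
                 alpha = alpha, ndcg_temperature = ndcg_temperature,
                 sigma_init = sigma_init),
            class = "train_config")
}

#' Learning-rate schedule
#'
#' Linear per-batch warm-up from `lr_start` at step 0 to `lr_peak` at the
#' last warm-up step (`warmup_epochs * steps_per_epoch` steps), followed by
#' cosine annealing from `lr_peak` down to `lr_floor` over the remaining
#' steps.
#'
#' @param global_step 0-based batch index.
#' @param steps_per_epoch Batches per epoch.
#' @param config A [train_config()].
#' @return Learning rate for this step.
#' @export
lr_schedule <- function(global_step, steps_per_epoch, config) {
  stopifnot(global_step >= 0, steps_per_epoch >= 1)
  W <- config$warmup_epochs * steps_per_epoch
  total <- config$epochs * steps_per_epoch
  if (global_step < W) {
    if (W == 1) return(config$lr_start)
    return(config$lr_start +
             (config$lr_peak - config$lr_start) * global_step / (W - 1))
  }
  Tt <- total - W
  if (Tt <= 0) return(config$lr_floor)
  u <- (global_step - W + 1) / Tt
  u <- min(u, 1)
  config$lr_floor + (config$lr_peak - config$lr_floor) * (1 + cos(pi * u)) / 2
}

#' Train a model on labelled graph data
#'
#' AdamW over minibatches with the warm-up/cosine schedule, the total loss
#' (balanced MSE plus amplified ranking loss), and the noise variance of the
#' balanced MSE learned jointly with the model. When validation items are
#' supplied the parameters with the best validation RMSE are the ones
#' returned. Fully reproducible under `config$seed`.
#'
#' @param train_items List of dataset items (`list(graphs, label)`), e.g.
#'   from [make_dataset()].
#' @param val_items Optional validation items.
#' @param config A [train_config()].
#' @param model Optional pre-built [affinity_model()]; by default one is
#'   initialized from `encoder_cfg` under `config$seed`.
#' @param encoder_cfg An [encoder_config()] used when `model` is `NULL`.
#' @param verbose Print per-epoch progress?
#' @return List with `model` (best checkpoint), `log` (per-epoch
#'   data.frame), `best_epoch`, and `sigma_noise` (learned noise sd).
#' @export
train_affinity <- function(train_items, val_items = NULL, config = train_config(),
                         model = NULL, encoder_cfg = encoder_config(),
                         verbose = FALSE) {
  stopifnot(inherits(config, "train_config"))
  if (length(train_items) == 0) stop("empty training dataset")
  labels <- vapply(train_items, function(it) it$label, 0)
  if (!all(is.finite(labels))) stop("non-finite training labels")
  if (is.null(model)) model <- affinity_model(encoder_cfg, seed = config$seed)
  ecfg <- model$config
  set.seed(config$seed)

  packs <- lapply(train_items, pack_item, config = ecfg)
  nf <- packs[[1]]$nf
  val_packs <- if (!is.null(val_items)) lapply(val_items, pack_item, config = ecfg)
  val_labels <- if (!is.null(val_items)) vapply(val_items, function(it) it$label, 0)

  n <- length(train_items)
  spe <- ceiling(n / config$batch_size)
  lstate <- loss_state(alpha = config$alpha,
                       ndcg_temperature = config$ndcg_temperature,
                       sigma_init = config$sigma_init)
  log_sigma2 <- lstate$log_sigma2
  astate <- adam_init(model$params)
  sig_state <- list(m = 0, v = 0)
  step <- 0L
  tstep <- 0L
  best_val <- Inf
  best_params <- model$params
  best_epoch <- NA_integer_
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_rmse = numeric(0), lr = numeric(0))
  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(n)
    epoch_loss <- 0
    for (bi in seq_len(spe)) {
      sel <- perm[((bi - 1) * config$batch_size + 1):min(bi * config$batch_size, n)]
      batch <- assemble_batch(packs[sel], ecfg)
      y <- labels[sel]
      res <- batch_train_step(model, batch, y, nf, log_sigma2, lstate)
      epoch_loss <- epoch_loss + res$value
      grads <- if (ecfg$shared_weights) res$grads[[1]]
               else stats::setNames(res$grads, names(batch))
      if (is.finite(config$clip_norm)) {
        gn <- sqrt(grad_sq_norm(grads) + res$dlog_sigma2^2)
        if (gn > config$clip_norm) {
          grads <- rapply(grads, function(g) g * (config$clip_norm / gn),
                          how = "replace")
          res$dlog_sigma2 <- res$dlog_sigma2 * (config$clip_norm / gn)
        }
      }
      lr <- lr_schedule(step, spe, config)
      step <- step + 1L
      tstep <- tstep + 1L
      r <- adam_step(model$params, grads, astate, lr, tstep,
                     weight_decay = config$weight_decay)
      model$params <- r$params
      astate <- r$state
      rs <- adam_step(log_sigma2, res$dlog_sigma2, sig_state, lr, tstep,
                      decay_this = FALSE)
      log_sigma2 <- min(max(rs$params, -8), 8) # keep the noise scale sane
      sig_state <- rs$state
    }
    epoch_loss <- epoch_loss / spe
    val_rmse <- NA_real_
    if (!is.null(val_items)) {
      vp <- predict_packed(model, val_packs, nf)
      val_rmse <- sqrt(mean((vp - val_labels)^2))
      if (val_rmse < best_val) {
        best_val <- val_rmse
        best_params <- model$params
        best_epoch <- epoch
      }
    }
    log <- rbind(log, data.frame(epoch = epoch, train_loss = epoch_loss,
                                 val_rmse = val_rmse,
                                 lr = lr_schedule(step - 1L, spe, config)))
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  val RMSE %s", epoch, epoch_loss,
                      ifelse(is.na(val_rmse), "-", sprintf("%.4f", val_rmse))))
  }
  if (!is.null(val_items)) model$params <- best_params
  list(model = model, log = log,
       best_epoch = if (is.na(best_epoch)) config$epochs else best_epoch,
       sigma_noise = sqrt(exp(log_sigma2)))
}

# forward-only predictions for a list of item packs, in chunks sized like a
# training minibatch so the engine's buffer pool is shared
predict_packed <- function(model, packs, nf, chunk = 32L) {
  n <- length(packs)
  preds <- numeric(n)
  for (start in seq(1, n, by = chunk)) {
    sel <- start:min(start + chunk - 1, n)
    batch <- assemble_batch(packs[sel], model$config)
    preds[sel] <- batch_predict(model, batch, length(sel), nf)$preds
  }
  preds
}

#' Predict affinities for a list of dataset items
#'
#' Batched forward pass of the model over items produced by
#' [make_dataset()] (or any list of `list(graphs = ...)`).
#'
#' @param model An [affinity_model()].
#' @param items List of dataset items.
#' @return Numeric vector of predicted affinities.
#' @export
predict_dataset <- function(model, items) {
  stopifnot(inherits(model, "affinity_model"))
  if (length(items) == 0) return(numeric(0))
  packs <- lapply(items, pack_item, config = model$config)
  predict_packed(model, packs, packs[[1]]$nf)
}

#' Evaluate predictions against labels
#'
#' @param model An [affinity_model()].
#' @param items Labelled dataset items.
#' @return Object of class `eval_report` with `rmse`, `pearson` (NA with
#'   `degenerate = TRUE` if the predictions are constant, never a silent 0),
#'   `n`, and the prediction/label vectors.
#' @export
evaluate_affinity <- function(model, items) {
  if (length(items) == 0) stop("empty evaluation dataset")
  y <- vapply(items, function(it) it$label, 0)
  p <- predict_dataset(model, items)
  rmse <- sqrt(mean((p - y)^2))
  degenerate <- stats::sd(p) == 0 || stats::sd(y) == 0
  pearson <- if (degenerate) NA_real_ else stats::cor(p, y)
  if (degenerate)
    warning("constant predictions or labels: Pearson correlation undefined",
            call. = FALSE)
  structure(list(rmse = rmse, pearson = pearson, degenerate = degenerate,
                 n = length(y), predictions = p, labels = y),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n=%d  RMSE=%.4f  Pearson=%s%s\n", x$n, x$rmse,
              ifelse(is.na(x$pearson), "NA", sprintf("%.4f", x$pearson)),
              if (x$degenerate) " (degenerate predictions)" else ""))
  invisible(x)
}

#' Multi-seed training harness
#'
#' Repeats train + evaluate over several seeds and reports per-run metrics
#' with their mean and standard deviation.
#'
#' @param train_items,val_items,test_items Dataset splits.
#' @param config Base [train_config()]; its seed is replaced per run.
#' @param encoder_cfg An [encoder_config()].
#' @param seeds Integer vector of seeds (default `1:5`).
#' @return List with `per_run` (data.frame of seed, rmse, pearson) and
#'   `summary` (mean and sd of each metric).
#' @export
run_seeds <- function(train_items, val_items, test_items,
                      config = train_config(), encoder_cfg = encoder_config(),
                      seeds = 1:5) {
  rows <- lapply(seeds, function(s) {
    cfg <- config
    cfg$seed <- as.integer(s)
    fit <- train_affinity(train_items, val_items, cfg, encoder_cfg = encoder_cfg)
    ev <- evaluate_affinity(fit$model, test_items)
    data.frame(seed = s, rmse = ev$rmse, pearson = ev$pearson)
  })
  per_run <- do.call(rbind, rows)
  list(per_run = per_run,
       summary = data.frame(
         metric = c("rmse", "pearson"),
         mean = c(mean(per_run$rmse), mean(per_run$pearson)),
         sd = c(stats::sd(per_run$rmse), stats::sd(per_run$pearson))))
}
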