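# Losses, the AdamW/cosine optimization loop, and the two-phase
# pre-train -> freeze -> transfer protocol.

#' Training configuration
#'
#' Reference-scale optimization settings are AdamW with initial learning
#' rate 3e-4, cosine annealing over 200 epochs, batch size 8 and weight
#' decay 1e-2; the desk-scale defaults used in the tests are 20 epochs and
#' batch size 4. `supervision_alpha` weights the attention-supervision term
#' in the total loss (0.3).
#'
#' @param epochs Training epochs (>= 1).
#' @param batch_size Cases per optimization step.
#' @param lr_init Initial learning rate (> 0).
#' @param weight_decay Decoupled weight-decay coefficient.
#' @param supervision_alpha Attention-supervision weight (>= 0).
#' @param freeze_encoder Whether the target-phase run expects a frozen
#'   encoder (the transfer protocol's default).
#' @param seed Seed for shuffling and any training randomness.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 20L, batch_size = 4L, lr_init = 3e-4,
                         weight_decay = 1e-2, supervision_alpha = 0.3,
                         freeze_encoder = TRUE, seed = 1L) {
  if (lr_init < 0) stop("lr_init must be >= 0", call. = FALSE)
  if (supervision_alpha < 0) stop("supervision_alpha must be >= 0", call. = FALSE)
  if (epochs < 1) stop("epochs must be >= 1", call. = FALSE)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr_init = lr_init, weight_decay = weight_decay,
                 supervision_alpha = supervision_alpha,
                 freeze_encoder = freeze_encoder, seed = as.integer(seed)),
            class = "train_config")
}

#' Soft Dice loss
#'
#' `1 - (2 sum(t p) + s) / (sum(t) + sum(p) + s)` with smoothing
#' `s = 1e-6`, so two empty masks give loss 0. Bounded in \[0, 1\];
#' 0 for perfect overlap of binary masks, approaching 1 for disjoint ones.
#'
#' @param truth Binary array.
#' @param pred Probability array in \[0, 1\], same shape.
#' @param smooth Smoothing constant.
#' @return Scalar loss.
#' @export
dice_loss <- function(truth, pred, smooth = 1e-6) {
  if (!all((dim(truth) %||% length(truth)) == (dim(pred) %||% length(pred))))
    stop("shape mismatch", call. = FALSE)
  if (any(pred < 0 | pred > 1)) stop("pred must lie in [0, 1]", call. = FALSE)
  1 - (2 * sum(truth * pred) + smooth) / (sum(truth) + sum(pred) + smooth)
}

#' Total training loss
#'
#' `dice + alpha * attention`, the weighted sum of the segmentation and
#' attention-supervision terms.
#'
#' @param dice Dice-loss value.
#' @param attention_loss Attention-supervision loss value.
#' @param alpha Nonnegative weight (default 0.3).
#' @return Scalar.
#' @export
total_loss <- function(dice, attention_loss = 0, alpha = 0.3) {
  if (alpha < 0) stop("alpha must be >= 0", call. = FALSE)
  dice + alpha * attention_loss
}

#' Cosine-annealed learning rate
#'
#' `lr_init * (1 + cos(pi * step / total_steps)) / 2`: starts at `lr_init`,
#' halves at midpoint, reaches 0 at the final step.
#'
#' @param step Current step in `[0, total_steps]`.
#' @param total_steps Total steps (> 0).
#' @param lr_init Initial learning rate.
#' @return Learning rate.
#' @export
cosine_lr <- function(step, total_steps, lr_init) {
  if (total_steps <= 0) stop("total_steps must be positive", call. = FALSE)
  if (any(step < 0 | step > total_steps)) stop("step out of range", call. = FALSE)
  lr_init * (1 + cos(pi * step / total_steps)) / 2
}

# --- optimizer ----------------------------------------------------------------

adamw_new <- function() {
  st <- new.env(parent = emptyenv())
  st$m <- list(); st$v <- list(); st$t <- 0L
  st
}

adamw_step <- function(st, params, grads, lr, weight_decay = 1e-2,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                       frozen = character(0)) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(grads)) {
    if (nm %in% frozen) next
    g <- grads[[nm]]
    m <- st$m[[nm]] %||% (g * 0)
    v <- st$v[[nm]] %||% (g * 0)
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    st$m[[nm]] <- m
    st$v[[nm]] <- v
    upd <- (m / bc1) / (sqrt(v / bc2) + eps)
    params[[nm]] <- params[[nm]] - lr * upd - lr * weight_decay * params[[nm]]
  }
  params
}

# --- shared training loop -----------------------------------------------------

case_mask2d <- function(case) if (is.matrix(case$mask)) case$mask else case$mask[, , 1]

# One gradient pass over a batch; returns list(loss, dice, grads).
batch_pass <- function(model, nc_batch, ven_batch, truth, masks, alpha,
                       supervise, frozen_encoder, fallback_stats = NULL,
                       encoder_cache = NULL) {
  tp <- tape_new()
  res <- wlau_forward_t(tp, model, nc_batch, ven_batch, masks = masks,
                        fallback_stats = fallback_stats, supervise = supervise,
                        frozen_encoder = frozen_encoder,
                        encoder_cache = encoder_cache)
  dice_id <- t_dice_loss(tp, res$prob, truth)
  loss_id <- dice_id
  if (supervise && !is.null(res$attn_loss)) {
    loss_id <- t_add(tp, dice_id, t_scale(tp, res$attn_loss, alpha))
  }
  grads <- tape_backward(tp, loss_id)
  list(loss = t_val(tp, loss_id), dice = t_val(tp, dice_id), grads = grads)
}

stack_truth <- function(cases) {
  n <- nrow(case_mask2d(cases[[1]]))
  out <- array(0, c(n, n, length(cases)))
  for (b in seq_along(cases)) out[, , b] <- case_mask2d(cases[[b]])
  out
}

bind4 <- function(arrs) {
  d <- dim(arrs[[1]])
  out <- array(0, c(d[1:3], length(arrs)))
  for (b in seq_along(arrs)) out[, , , b] <- arrs[[b]]
  out
}

# Generic epoch loop shared by both phases.
train_loop <- function(model, cases, tcfg, paired, supervise, frozen_encoder,
                       use_masks = TRUE, label = "train") {
  n <- length(cases)
  if (n == 0L) stop("empty training dataset", call. = FALSE)
  bs <- min(tcfg$batch_size, n)
  steps_per_epoch <- ceiling(n / bs)
  total_steps <- steps_per_epoch * tcfg$epochs
  opt <- adamw_new()
  frozen <- if (frozen_encoder) model$frozen else character(0)
  history <- data.frame()

  # inputs are fixed across epochs: preprocess/enhance every case once
  planes <- lapply(cases, function(cs) {
    ncb <- array(prepare_plane(model, cs, "noncontrast"),
                 c(dim(case_mask2d(cs)), 1L, 1L))
    tokb <- if (paired) array(prepare_plane(model, cs, "venous"),
                              dim(ncb)) else ncb
    list(nc = ncb, tok = tokb)
  })
  # frozen encoder: additionally cache its outputs per case
  cache <- NULL
  if (frozen_encoder) {
    cache <- lapply(planes, function(pl) {
      enc_nc <- encoder_forward(pl$nc, model$params, model$config)
      enc_tok <- if (paired) encoder_forward(pl$tok, model$params, model$config)
                 else enc_nc
      list(nc = enc_nc, tok = enc_tok)
    })
  }

  step <- 0L
  for (epoch in seq_len(tcfg$epochs)) {
    ord <- with_seed(derive_seed(tcfg$seed, 5000L + epoch), sample.int(n))
    epoch_loss <- 0; epoch_dice <- 0
    for (s0 in seq(1L, n, by = bs)) {
      idx <- ord[s0:min(s0 + bs - 1L, n)]
      batch_cases <- cases[idx]
      lr <- cosine_lr(step, total_steps, tcfg$lr_init)
      masks <- if (use_masks) lapply(batch_cases, case_mask2d)
      truth <- stack_truth(batch_cases)
      nc_batch <- bind4(lapply(planes[idx], function(x) x$nc))
      ven_batch <- if (paired) bind4(lapply(planes[idx], function(x) x$tok))
      if (!is.null(cache)) {
        cc <- cache[idx]
        enc_cache <- list(
          nc = list(final = bind4(lapply(cc, function(x) x$nc$final)),
                    skips = lapply(1:4, function(j)
                      bind4(lapply(cc, function(x) x$nc$skips[[j]])))),
          tok = list(final = bind4(lapply(cc, function(x) x$tok$final))))
        pass <- batch_pass(model, nc_batch, ven_batch, truth, masks,
                           tcfg$supervision_alpha, supervise,
                           frozen_encoder = TRUE, encoder_cache = enc_cache)
      } else {
        pass <- batch_pass(model, nc_batch, ven_batch, truth, masks,
                           tcfg$supervision_alpha, supervise,
                           frozen_encoder = FALSE)
      }
      model$params <- adamw_step(opt, model$params, pass$grads, lr,
                                 tcfg$weight_decay, frozen = frozen)
      epoch_loss <- epoch_loss + pass$loss
      epoch_dice <- epoch_dice + pass$dice
      step <- step + 1L
    }
    history <- rbind(history, data.frame(
      phase = label, epoch = epoch,
      loss = epoch_loss / steps_per_epoch,
      dice_loss = epoch_dice / steps_per_epoch,
      lr = lr))
  }
  list(model = model, history = history)
}

#' Pre-train on venous-phase data
#'
#' Phase 1 of the transfer protocol: the full model (encoder included) is
#' trained on venous-phase slices with the Dice loss, the venous plane
#' feeding both the token branch and the skip connections. The returned
#' checkpoint's encoder weights are what [transfer_and_freeze()] moves to
#' the target-phase model.
#'
#' @param cases Non-empty list of `phantom_case`s (training split).
#' @param model A `wlau_model`, or `NULL` to create one from `config`.
#' @param tcfg A [train_config()].
#' @param config,enhancement Used when `model` is `NULL`.
#' @param supervise Enable attention supervision already in this phase
#'   (off by default; it belongs to the target phase).
#' @return List with the trained `model` (the checkpoint) and the epoch
#'   `history` data frame.
#' @export
pretrain_venous <- function(cases, model = NULL, tcfg = train_config(),
                            config = model_config(), enhancement = NULL,
                            supervise = FALSE) {
  if (length(cases) == 0L) stop("empty dataset", call. = FALSE)
  if (is.null(model))
    model <- wlau_model(config, seed = tcfg$seed, enhancement = enhancement)
  # venous-only phase: the same plane plays both roles
  venous_cases <- lapply(cases, function(cs) {
    cs$noncontrast <- cs$venous
    cs
  })
  train_loop(model, venous_cases, tcfg, paired = FALSE,
             supervise = supervise, frozen_encoder = FALSE,
             label = "pretrain_venous")
}

#' Transfer and freeze encoder weights
#'
#' Copies the checkpoint's encoder parameters into the target model and
#' marks them non-trainable. The Gaussian attention, transformer and decoder
#' stay trainable and adapt to the non-contrast domain inside the stable
#' feature space the frozen encoder provides.
#'
#' @param checkpoint A trained `wlau_model` (from [pretrain_venous()]).
#' @param model Target `wlau_model`; defaults to the checkpoint itself (the
#'   usual protocol: same weights carried forward).
#' @return The target model with encoder weights copied and frozen.
#' @export
transfer_and_freeze <- function(checkpoint, model = NULL) {
  if (is.null(model)) model <- checkpoint
  enc_names <- encoder_param_names(model$config)
  for (nm in enc_names) {
    src <- checkpoint$params[[nm]]
    if (is.null(src) || !all((dim(src) %||% length(src)) ==
                             (dim(model$params[[nm]]) %||% length(model$params[[nm]]))))
      stop("architecture mismatch for ", nm, call. = FALSE)
    model$params[[nm]] <- src
  }
  model$frozen <- enc_names
  usage_bump("transfer")
  model
}

#' Train on non-contrast data with a frozen encoder
#'
#' Phase 2 of the transfer protocol: paired forward passes (venous tokens,
#' non-contrast skips and Gaussian statistics), optimizing the total loss
#' (Dice plus `supervision_alpha` times the attention-supervision term when
#' GPSA is enabled) over the trainable parameters only. Per-case Gaussian
#' statistics are accumulated and their population averages stored in the
#' model for annotation-free inference.
#'
#' @param cases Non-empty list of `phantom_case`s.
#' @param model A `wlau_model` with a frozen encoder (see
#'   [transfer_and_freeze()]).
#' @param tcfg A [train_config()].
#' @param allow_unfrozen Override the frozen-encoder requirement (ablation
#'   mode: trains everything on non-contrast data).
#' @return List with the trained `model` (population statistics attached)
#'   and the epoch `history`.
#' @export
train_noncontrast <- function(cases, model, tcfg = train_config(),
                              allow_unfrozen = FALSE) {
  if (length(cases) == 0L) stop("empty dataset", call. = FALSE)
  if (length(model$frozen) == 0L && !allow_unfrozen) {
    warning("encoder is not frozen; refusing to run the target phase ",
            "(set allow_unfrozen = TRUE for the no-transfer ablation)")
    stop("unfrozen encoder in the transfer phase", call. = FALSE)
  }
  frozen_encoder <- length(model$frozen) > 0L
  supervise <- model$gpsa && tcfg$supervision_alpha > 0
  res <- train_loop(model, cases, tcfg, paired = TRUE, supervise = supervise,
                    frozen_encoder = frozen_encoder, label = "train_noncontrast")
  model <- res$model
  if (model$gpsa || model$gate) {
    stats <- collect_case_stats(model, cases)
    if (length(stats)) model$population_stats <- population_stats(stats)
    model$per_case_stats <- stats
  }
  list(model = model, history = res$history)
}

# Per-case Gaussian statistics of the channel-mean non-contrast feature map.
collect_case_stats <- function(model, cases) {
  s <- model$config$grid_side
  out <- list()
  for (cs in cases) {
    ncb <- cases_to_batch(model, list(cs), "noncontrast")
    fin <- encoder_forward(ncb, model$params, model$config)$final
    I <- apply(fin[, , , 1, drop = FALSE], c(1, 2), mean)
    gm <- grid_mask_robust(case_mask2d(cs), s)
    if (!is.null(gm) && any(gm == 1)) out[[length(out) + 1L]] <- tumor_stats(I, gm)
  }
  out
}

#' Run one full experiment
#'
#' The end-to-end protocol behind the sweep/ablation harnesses: split the
#' cases, optionally pre-train on the venous phase and freeze/transfer the
#' encoder, train on non-contrast data with the requested module flags, and
#' evaluate on the held-out split.
#'
#' @param cases List of `phantom_case`s.
#' @param transfer,gpsa,weem Module switches (the ablation axes).
#' @param epochs Epochs per phase.
#' @param net_config A [model_config()] sized to the cases.
#' @param seed Master seed (weights, shuffling, split).
#' @param enhancement [enhancement_config()] used when `weem` is on.
#' @param split Train/test fractions, default `c(0.8, 0.2)`.
#' @param batch_size,lr_init Optimization settings.
#' @return List with the `report` ([evaluate_model()] on the test split),
#'   the trained `model`, the training `history` and `module_usage` counts.
#' @export
run_experiment <- function(cases, transfer = TRUE, gpsa = TRUE, weem = TRUE,
                           epochs = 4L, net_config = NULL, seed = 1L,
                           enhancement = enhancement_config(),
                           split = c(0.8, 0.2), batch_size = 4L,
                           lr_init = 3e-4) {
  if (is.null(net_config))
    net_config <- model_config(input_size = nrow(case_mask2d(cases[[1]])))
  usage_reset()
  n <- length(cases)
  n_test <- max(1L, floor(n * split[2]))
  perm <- with_seed(derive_seed(seed, 77L), sample.int(n))
  test_cases <- cases[perm[seq_len(n_test)]]
  train_cases <- cases[perm[(n_test + 1L):n]]
  tcfg <- train_config(epochs = epochs, batch_size = batch_size,
                       lr_init = lr_init, seed = seed)
  model <- wlau_model(net_config, seed = seed,
                      enhancement = if (weem) enhancement,
                      gpsa = gpsa)
  if (transfer) {
    pre <- pretrain_venous(train_cases, model, tcfg)
    model <- transfer_and_freeze(pre$model)
    ph2 <- train_noncontrast(train_cases, model, tcfg)
    history <- rbind(pre$history, ph2$history)
  } else {
    ph2 <- train_noncontrast(train_cases, model, tcfg, allow_unfrozen = TRUE)
    history <- ph2$history
  }
  model <- ph2$model
  report <- evaluate_model(model, test_cases, mode = "paired")
  list(report = report, model = model, history = history,
       module_usage = module_usage())
}

# --- checkpointing ------------------------------------------------------------

#' Save a model checkpoint
#'
#' Writes the weights and configuration as JSON (text, fully portable) plus
#' a sidecar with the population Gaussian statistics.
#'
#' @param model A `wlau_model`.
#' @param path Output file (`.json`).
#' @return Invisibly, `path`.
#' @export
save_checkpoint <- function(model, path) {
  obj <- list(
    version = "1",
    config = unclass(model$config),
    hu_window = model$hu_window,
    enhancement = if (!is.null(model$enhancement)) unclass(model$enhancement),
    gpsa = model$gpsa, gate = model$gate,
    frozen = model$frozen,
    params = lapply(model$params, function(p)
      list(dim = dim(p) %||% length(p), data = as.numeric(p))),
    population_stats = if (!is.null(model$population_stats))
      unclass(model$population_stats)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path File written by [save_checkpoint()].
#' @return A `wlau_model`.
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(model_config, obj$config[c(
    "input_size", "encoder_layers", "encoder_kernel", "encoder_stride",
    "base_channels", "token_dim", "transformer_layers", "attention_heads",
    "decoder_stages", "num_classes")])
  model <- wlau_model(cfg, seed = 1L,
                      enhancement = if (!is.null(obj$enhancement))
                        do.call(enhancement_config, obj$enhancement[
                          c("wavelet", "lambda1", "lambda2", "grid", "boundary_mode")]),
                      gpsa = isTRUE(obj$gpsa), gate = isTRUE(obj$gate),
                      hu_window = obj$hu_window)
  model$params <- lapply(obj$params, function(p) {
    v <- as.numeric(p$data)
    if (length(p$dim) > 1L) dim(v) <- p$dim
    v
  })
  model$frozen <- as.character(obj$frozen)
  if (!is.null(obj$population_stats))
    model$population_stats <- gaussian_stats(
      obj$population_stats$mu, obj$population_stats$sigma,
      obj$population_stats$epsilon, obj$population_stats$scales)
  model
}
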