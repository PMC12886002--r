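# Full-model assembly: paired-phase forward pass with optional wavelet
# enhancement, Gaussian attention bias, gating and attention supervision;
# the model container; mask prediction.

#' Create a segmentation model
#'
#' Bundles parameters with the preprocessing/enhancement/attention options
#' that define the pipeline variant. The three module switches mirror the
#' ablation design: `transfer` (pre-train/freeze/transfer protocol, recorded
#' after [transfer_and_freeze()]), `gpsa` (Gaussian attention bias) and
#' `weem` (wavelet enhancement, carried by `enhancement`).
#'
#' @param config A [model_config()].
#' @param seed Weight-initialization seed.
#' @param enhancement An [enhancement_config()] to enable wavelet
#'   enhancement, or `NULL` to disable it.
#' @param gpsa Enable the Gaussian attention bias path.
#' @param gate Additionally gate tokens multiplicatively by `1 + G`
#'   (off by default; the bias path is the primary integration).
#' @param hu_window HU window used to normalize inputs.
#' @return A `wlau_model`.
#' @export
wlau_model <- function(config = model_config(), seed = 1L, enhancement = NULL,
                       gpsa = FALSE, gate = FALSE, hu_window = c(-150, 250)) {
  structure(list(
    config = config,
    params = init_params(config, seed),
    enhancement = enhancement,
    gpsa = gpsa,
    gate = gate,
    hu_window = hu_window,
    frozen = character(0),
    population_stats = NULL
  ), class = "wlau_model")
}

#' @export
print.wlau_model <- function(x, ...) {
  cat("<wlau_model>", x$config$input_size, "px,",
      x$config$transformer_layers, "transformer layers,",
      format(n_parameters(x$params), big.mark = ","), "parameters\n")
  cat("  modules: weem =", !is.null(x$enhancement),
      "| gpsa =", x$gpsa,
      "| frozen encoder =", length(x$frozen) > 0, "\n")
  invisible(x)
}

# Preprocess one phase of a case into the model's input plane.
prepare_plane <- function(model, case, phase) {
  img <- hu_clip_normalize(case[[phase]]$data, model$hu_window)
  if (is.array(img) && length(dim(img)) == 3L) img <- img[, , 1]
  if (!is.null(model$enhancement)) img <- enhance(img, model$enhancement)
  img
}

cases_to_batch <- function(model, cases, phase) {
  planes <- lapply(cases, prepare_plane, model = model, phase = phase)
  n <- nrow(planes[[1]])
  out <- array(0, c(n, n, 1L, length(planes)))
  for (b in seq_along(planes)) out[, , 1L, b] <- planes[[b]]
  out
}

# Taped full forward. `masks` is a list of pixel masks (or NULLs) used for
# per-case Gaussian statistics and attention supervision; `fallback_stats`
# replaces per-case statistics when a mask is absent or empty.
# `frozen_encoder` computes the encoder untaped and feeds its outputs in as
# constants, so no gradient machinery is built for it.
wlau_forward_t <- function(tp, model, nc_batch, ven_batch = NULL,
                           masks = NULL, fallback_stats = NULL,
                           supervise = FALSE, frozen_encoder = FALSE,
                           encoder_cache = NULL) {
  cfg <- model$config
  params <- model$params
  B <- dim(nc_batch)[4]
  s <- cfg$grid_side
  paired <- !is.null(ven_batch)
  token_src <- if (paired) ven_batch else nc_batch

  nc_in <- t_leaf(tp, nc_batch)
  if (!is.null(encoder_cache)) {
    enc_nc <- list(final = t_leaf(tp, encoder_cache$nc$final),
                   skips = lapply(encoder_cache$nc$skips, function(v) t_leaf(tp, v)))
    enc_tok <- list(final = t_leaf(tp, encoder_cache$tok$final))
  } else if (frozen_encoder) {
    pe <- encoder_forward(nc_batch, params, cfg)
    enc_nc <- list(final = t_leaf(tp, pe$final),
                   skips = lapply(pe$skips, function(v) t_leaf(tp, v)))
    pt <- if (paired && !identical(token_src, nc_batch))
      encoder_forward(token_src, params, cfg) else pe
    enc_tok <- list(final = t_leaf(tp, pt$final))
  } else {
    enc_nc <- encoder_forward_t(tp, params, cfg, nc_in)
    enc_tok <- if (paired && !identical(token_src, nc_batch))
      encoder_forward_t(tp, params, cfg, t_leaf(tp, ven_batch))
    else enc_nc
  }

  # GPSA: per-sample Gaussian statistics on the channel-mean non-contrast
  # feature map; the weight map enters attention as a constant (the learnable
  # part is lambda_bias).
  biases <- vector("list", B)
  targets <- vector("list", B)
  case_stats <- vector("list", B)
  gates <- vector("list", B)
  if (model$gpsa || model$gate) {
    ncF <- t_val(tp, enc_nc$final)
    lam_id <- t_leaf(tp, params$lambda_bias, "lambda_bias")
    for (b in seq_len(B)) {
      I <- apply(ncF[, , , b, drop = FALSE], c(1, 2), mean)
      msk <- if (!is.null(masks)) masks[[b]]
      grid_mask <- if (!is.null(msk)) grid_mask_robust(msk, s) else NULL
      st <- if (!is.null(grid_mask) && any(grid_mask == 1))
        tumor_stats(I, grid_mask)
      else if (!is.null(fallback_stats)) fallback_stats
      else stop("GPSA needs a nonempty mask or population statistics",
                call. = FALSE)
      case_stats[[b]] <- st
      G <- multiscale_gaussian(I, st)
      bb <- build_bias(G, params$lambda_bias)
      if (model$gpsa) biases[[b]] <- bb
      if (model$gate) gates[[b]] <- 1 + bb$g
      if (supervise && !is.null(msk))
        targets[[b]] <- attention_supervision_target(msk, c(s, s))
    }
  } else lam_id <- NULL

  proj_W <- t_leaf(tp, params$proj_W, "proj_W")
  proj_b <- t_leaf(tp, params$proj_b, "proj_b")
  posemb <- t_leaf(tp, params$posemb, "posemb")

  out_tokens <- vector("list", B)
  attn_losses <- integer(0)
  for (b in seq_len(B)) {
    tok <- t_map_to_tokens(tp, enc_tok$final, b)
    tok <- t_linear(tp, tok, proj_W, proj_b)
    tok <- t_add(tp, tok, posemb)
    if (!is.null(gates[[b]])) tok <- t_rowscale_const(tp, tok, gates[[b]])
    tf <- transformer_forward_t(tp, params, cfg, tok, bias = biases[[b]],
                                lambda_id = lam_id)
    out_tokens[[b]] <- tf$out
    if (supervise && !is.null(targets[[b]]))
      attn_losses <- c(attn_losses, t_attn_bce(tp, tf$last_A, targets[[b]]))
  }
  map_id <- t_stack_tokens_to_map(tp, out_tokens, s, s)
  skip_ids <- c(rev(enc_nc$skips)[2:4], nc_in)
  logits <- decoder_forward_t(tp, params, cfg, map_id, skip_ids)
  prob <- t_softmax2_prob(tp, logits)

  attn_loss <- if (length(attn_losses)) {
    acc <- attn_losses[[1]]
    if (length(attn_losses) > 1)
      for (i in 2:length(attn_losses)) acc <- t_add(tp, acc, attn_losses[[i]])
    t_scale(tp, acc, 1 / length(attn_losses))
  }
  list(logits = logits, prob = prob, attn_loss = attn_loss,
       case_stats = case_stats)
}

#' Full network forward pass
#'
#' Runs the complete pipeline on preprocessed input planes: encoders,
#' tokenization, (optionally biased) transformer, decoder, segmentation
#' head. In `"paired"` mode the venous plane feeds the transformer tokens
#' while the non-contrast plane supplies the skip connections and the
#' Gaussian statistics; in `"single"` mode the non-contrast plane plays both
#' roles.
#'
#' @param model A `wlau_model`.
#' @param nc_batch Non-contrast input, matrix or `(H, W, 1, B)` array,
#'   already windowed to \[0, 1\] (and enhanced, if the model enhances).
#' @param ven_batch Venous input for `"paired"` mode, `NULL` for
#'   `"single"`.
#' @param masks Optional list of `B` pixel masks for mask-guided attention.
#' @param stats Fallback [gaussian_stats()] when masks are absent.
#' @param mode `"paired"` or `"single"`.
#' @return List with `logits` `(H, W, 2, B)` and `prob` `(H, W, B)`.
#' @export
wlau_forward <- function(model, nc_batch, ven_batch = NULL, masks = NULL,
                         stats = NULL, mode = c("paired", "single")) {
  mode <- match.arg(mode)
  if (mode == "paired" && is.null(ven_batch))
    stop("paired mode requires a venous input; use mode = 'single' otherwise",
         call. = FALSE)
  if (mode == "single") ven_batch <- NULL
  tp <- tape_new()
  res <- wlau_forward_t(tp, model, as_batch(nc_batch),
                        if (!is.null(ven_batch)) as_batch(ven_batch),
                        masks = masks, fallback_stats = stats,
                        frozen_encoder = TRUE)
  list(logits = t_val(tp, res$logits), prob = t_val(tp, res$prob))
}

#' Predict a segmentation mask for a phantom case
#'
#' Preprocesses the case with the model's HU window (and wavelet
#' enhancement, if enabled), runs the forward pass and thresholds the
#' class probabilities by argmax. With GPSA enabled the Gaussian statistics
#' come from the stored population statistics (`stats_mode = "population"`,
#' the annotation-free inference path) or from the case's own mask
#' (`stats_mode = "mask"`, the training-time path).
#'
#' @param model A `wlau_model`.
#' @param case A `phantom_case`.
#' @param mode `"paired"` (uses the venous phase for tokens) or `"single"`.
#' @param stats_mode `"auto"` (population if stored, else mask), or force
#'   `"population"` / `"mask"`.
#' @return Binary mask matrix.
#' @export
predict_mask <- function(model, case, mode = c("paired", "single"),
                         stats_mode = c("auto", "population", "mask")) {
  mode <- match.arg(mode)
  stats_mode <- match.arg(stats_mode)
  nc <- cases_to_batch(model, list(case), "noncontrast")
  ven <- if (mode == "paired") cases_to_batch(model, list(case), "venous")
  masks <- NULL; stats <- NULL
  if (model$gpsa || model$gate) {
    use_pop <- switch(stats_mode,
                      population = TRUE,
                      mask = FALSE,
                      auto = !is.null(model$population_stats))
    if (use_pop) {
      if (is.null(model$population_stats))
        stop("no population statistics stored in the model", call. = FALSE)
      stats <- model$population_stats
    } else {
      masks <- list(if (is.matrix(case$mask)) case$mask else case$mask[, , 1])
    }
  }
  out <- wlau_forward(model, nc, ven, masks = masks, stats = stats, mode = mode)
  (out$prob[, , 1] > 0.5) + 0
}
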