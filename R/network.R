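# The segmentation network: dual-branch 4-stage CNN encoder (stride-2 3x3
# convolutions), linear token projection with learned positional embeddings,
# a pre-norm transformer encoder whose attention logits carry the Gaussian
# rank-1 bias, and a 4-stage bilinear-upsampling decoder with skip
# connections from the non-contrast branch, ending in a 1x1 segmentation
# head. Sized by `model_config` so desk-scale instances train on one CPU.

#' Network configuration
#'
#' The reference-scale configuration is 512 x 512 inputs, 12 transformer
#' layers and 8 heads; the desk-scale default used throughout the tests is
#' 64 x 64 with 2 layers and 2 heads. The encoder halves the side four
#' times, so the feature grid is `input_size / 16` (512 -> 32, 64 -> 4) and
#' the token count its square.
#'
#' @param input_size Input side in pixels; must be divisible by
#'   `2^encoder_layers`.
#' @param encoder_layers Number of stride-2 encoder stages (4).
#' @param encoder_kernel,encoder_stride Convolution kernel size (3) and
#'   stride (2).
#' @param base_channels Channel width of the first stage; stages use
#'   `base_channels * c(1, 2, 4, 8)`.
#' @param token_dim Transformer width; must be divisible by
#'   `attention_heads`.
#' @param transformer_layers,attention_heads Transformer depth and heads
#'   (reference scale 12 and 8).
#' @param decoder_stages Number of x2 upsampling stages (4).
#' @param num_classes Output classes (2: background, tumor).
#' @return A `model_config` list; derived fields `grid_side` and `n_tokens`.
#' @export
model_config <- function(input_size = 64L, encoder_layers = 4L,
                         encoder_kernel = 3L, encoder_stride = 2L,
                         base_channels = 8L, token_dim = 32L,
                         transformer_layers = 2L, attention_heads = 2L,
                         decoder_stages = 4L, num_classes = 2L) {
  if (input_size %% (encoder_stride^encoder_layers) != 0L)
    stop("input_size must be divisible by ", encoder_stride^encoder_layers,
         call. = FALSE)
  if (token_dim %% attention_heads != 0L)
    stop("token_dim must be divisible by attention_heads", call. = FALSE)
  grid_side <- input_size %/% (encoder_stride^encoder_layers)
  structure(list(
    input_size = as.integer(input_size), encoder_layers = as.integer(encoder_layers),
    encoder_kernel = as.integer(encoder_kernel), encoder_stride = as.integer(encoder_stride),
    base_channels = as.integer(base_channels), token_dim = as.integer(token_dim),
    transformer_layers = as.integer(transformer_layers),
    attention_heads = as.integer(attention_heads),
    decoder_stages = as.integer(decoder_stages), num_classes = as.integer(num_classes),
    grid_side = as.integer(grid_side), n_tokens = as.integer(grid_side^2)
  ), class = "model_config")
}

#' Reference-scale network configuration
#'
#' The full-size configuration: 512 x 512 inputs, 64 base channels, 768-wide
#' tokens, 12 transformer layers with 8 heads. Provided for completeness;
#' training it is a GPU-scale undertaking.
#'
#' @return A `model_config`.
#' @export
model_config_full <- function() {
  model_config(input_size = 512L, base_channels = 64L, token_dim = 768L,
               transformer_layers = 12L, attention_heads = 8L)
}

encoder_channels <- function(cfg) cfg$base_channels * c(1L, 2L, 4L, 8L)

# Decoder conv output channels per stage (after skip concatenation).
decoder_channels <- function(cfg) {
  ch <- encoder_channels(cfg)
  c(ch[3], ch[2], ch[1], ch[1])
}

rnorm_mat <- function(n1, n2, sd) matrix(stats::rnorm(n1 * n2, 0, sd), n1, n2)

#' Initialize network parameters
#'
#' He-normal initialization for convolutions, Xavier for linear maps, zero
#' biases, N(0, 0.02) positional embeddings; the Gaussian-bias scale
#' `lambda_bias` starts at 0.5.
#'
#' @param cfg A [model_config()].
#' @param seed Integer seed (weights are a deterministic function of it).
#' @return Named list of parameter arrays.
#' @export
init_params <- function(cfg, seed = 1L) {
  with_seed(seed, {
    p <- list()
    ch <- encoder_channels(cfg)
    k <- cfg$encoder_kernel
    cin <- 1L
    for (i in seq_len(cfg$encoder_layers)) {
      K <- k * k * cin
      p[[paste0("enc", i, "_W")]] <- rnorm_mat(ch[i], K, sqrt(2 / K))
      p[[paste0("enc", i, "_b")]] <- numeric(ch[i])
      cin <- ch[i]
    }
    D <- cfg$token_dim
    p$proj_W <- rnorm_mat(ch[cfg$encoder_layers], D, sqrt(1 / ch[cfg$encoder_layers]))
    p$proj_b <- numeric(D)
    p$posemb <- rnorm_mat(cfg$n_tokens, D, 0.02)
    for (l in seq_len(cfg$transformer_layers)) {
      pre <- paste0("tf", l, "_")
      p[[paste0(pre, "ln1_g")]] <- rep(1, D)
      p[[paste0(pre, "ln1_b")]] <- numeric(D)
      p[[paste0(pre, "ln2_g")]] <- rep(1, D)
      p[[paste0(pre, "ln2_b")]] <- numeric(D)
      for (h in seq_len(cfg$attention_heads)) {
        dh <- D %/% cfg$attention_heads
        sdq <- sqrt(1 / D)
        p[[paste0(pre, "h", h, "_Wq")]] <- rnorm_mat(D, dh, sdq)
        p[[paste0(pre, "h", h, "_Wk")]] <- rnorm_mat(D, dh, sdq)
        p[[paste0(pre, "h", h, "_Wv")]] <- rnorm_mat(D, dh, sdq)
      }
      p[[paste0(pre, "Wo")]] <- rnorm_mat(D, D, sqrt(1 / D))
      p[[paste0(pre, "bo")]] <- numeric(D)
      p[[paste0(pre, "ffn_W1")]] <- rnorm_mat(D, 4L * D, sqrt(1 / D))
      p[[paste0(pre, "ffn_b1")]] <- numeric(4L * D)
      p[[paste0(pre, "ffn_W2")]] <- rnorm_mat(4L * D, D, sqrt(1 / (4 * D)))
      p[[paste0(pre, "ffn_b2")]] <- numeric(D)
    }
    p$tf_lnf_g <- rep(1, D)
    p$tf_lnf_b <- numeric(D)
    dch <- decoder_channels(cfg)
    skip_ch <- c(ch[3], ch[2], ch[1], 1L)  # stage-3, -2, -1 maps, then input
    cin_dec <- D
    for (j in seq_len(cfg$decoder_stages)) {
      K <- 9L * (cin_dec + skip_ch[j])
      p[[paste0("dec", j, "_W")]] <- rnorm_mat(dch[j], K, sqrt(2 / K))
      p[[paste0("dec", j, "_b")]] <- numeric(dch[j])
      cin_dec <- dch[j]
    }
    p$head_W <- rnorm_mat(cfg$num_classes, cin_dec, sqrt(2 / cin_dec))
    p$head_b <- numeric(cfg$num_classes)
    p$lambda_bias <- 0.5
    p
  })
}

encoder_param_names <- function(cfg) {
  as.vector(vapply(seq_len(cfg$encoder_layers),
                   function(i) paste0("enc", i, c("_W", "_b")), character(2)))
}

#' Count model parameters
#'
#' @param params Named parameter list from [init_params()].
#' @return Total number of scalar parameters.
#' @export
n_parameters <- function(params) sum(vapply(params, length, numeric(1)))

# --- forward pieces -----------------------------------------------------------

# Taped encoder: image batch (H, W, 1, B) -> list(final map id, skip ids).
encoder_forward_t <- function(tp, params, cfg, x_id, prefix = "enc") {
  skips <- integer(0)
  cur <- x_id
  for (i in seq_len(cfg$encoder_layers)) {
    w <- t_leaf(tp, params[[paste0(prefix, i, "_W")]], paste0(prefix, i, "_W"))
    b <- t_leaf(tp, params[[paste0(prefix, i, "_b")]], paste0(prefix, i, "_b"))
    cur <- t_conv2d(tp, cur, w, b, stride = cfg$encoder_stride,
                    pad = (cfg$encoder_kernel - 1L) %/% 2L, act = "relu")
    skips <- c(skips, cur)
  }
  list(final = cur, skips = skips)
}

#' Encoder forward pass
#'
#' Runs the 4-stage stride-2 CNN encoder on an image batch and returns the
#' final feature map together with the per-stage maps used as skip
#' connections.
#'
#' @param image Matrix (one image) or array `(H, W, 1, B)`.
#' @param params,cfg Parameters and configuration.
#' @return List with `final` `(H/16, W/16, 8*base, B)` and `skips` (list of
#'   four arrays, halving resolution each stage).
#' @export
encoder_forward <- function(image, params, cfg = model_config()) {
  x <- as_batch(image)
  if (dim(x)[1] %% (cfg$encoder_stride^cfg$encoder_layers) != 0L)
    stop("input side must be divisible by ", cfg$encoder_stride^cfg$encoder_layers,
         call. = FALSE)
  tp <- tape_new()
  res <- encoder_forward_t(tp, params, cfg, t_leaf(tp, x))
  list(final = t_val(tp, res$final),
       skips = lapply(res$skips, t_val, tp = tp))
}

as_batch <- function(image) {
  if (is.matrix(image)) array(image, c(dim(image), 1L, 1L))
  else if (length(dim(image)) == 4L) image
  else stop("expected a matrix or (H, W, C, B) array", call. = FALSE)
}

#' Tokenize a feature map
#'
#' Row-major flattening of the spatial grid followed by the linear
#' projection into transformer width, plus learned positional embeddings.
#'
#' @param feature_map `(s, s, C)` array or `(s, s, C, 1)`.
#' @param params,cfg Parameters and configuration.
#' @return `(n_tokens, token_dim)` matrix.
#' @export
tokenize <- function(feature_map, params, cfg = model_config()) {
  if (length(dim(feature_map)) == 3L)
    feature_map <- array(feature_map, c(dim(feature_map), 1L))
  tp <- tape_new()
  x <- t_leaf(tp, feature_map)
  tok <- t_map_to_tokens(tp, x, 1L)
  pw <- t_leaf(tp, params$proj_W); pb <- t_leaf(tp, params$proj_b)
  t_val(tp, t_linear(tp, tok, pw, pb)) + params$posemb
}

# Taped transformer: tokens id (N x D) -> tokens id. `bias` is an
# attention_bias or NULL; lambda_id the learnable scalar node (or NULL).
# Returns list(out, last_A) where last_A is the head-mean logit node of the
# final layer (for attention supervision).
transformer_forward_t <- function(tp, params, cfg, tok_id, bias = NULL,
                                  lambda_id = NULL) {
  D <- cfg$token_dim
  H <- cfg$attention_heads
  cur <- tok_id
  last_A <- NULL
  for (l in seq_len(cfg$transformer_layers)) {
    pre <- paste0("tf", l, "_")
    ln1 <- t_layernorm(tp, cur,
                       t_leaf(tp, params[[paste0(pre, "ln1_g")]], paste0(pre, "ln1_g")),
                       t_leaf(tp, params[[paste0(pre, "ln1_b")]], paste0(pre, "ln1_b")))
    heads <- vector("list", H)
    A_heads <- vector("list", H)
    for (h in seq_len(H)) {
      hw <- function(nm) t_leaf(tp, params[[paste0(pre, "h", h, "_", nm)]],
                                paste0(pre, "h", h, "_", nm))
      q <- t_matmul(tp, ln1, hw("Wq"))
      k <- t_matmul(tp, ln1, hw("Wk"))
      v <- t_matmul(tp, ln1, hw("Wv"))
      A <- t_attn_logits(tp, q, k,
                         lambda = if (!is.null(bias)) lambda_id,
                         B = if (!is.null(bias)) bias$B)
      A_heads[[h]] <- A
      P <- t_softmax_rows(tp, A)
      heads[[h]] <- t_matmul(tp, P, v)
    }
    if (l == cfg$transformer_layers) {
      acc <- A_heads[[1]]
      if (H > 1) for (h in 2:H) acc <- t_add(tp, acc, A_heads[[h]])
      last_A <- t_scale(tp, acc, 1 / H)
    }
    mha <- t_cbind(tp, heads)
    mha <- t_linear(tp, mha,
                    t_leaf(tp, params[[paste0(pre, "Wo")]], paste0(pre, "Wo")),
                    t_leaf(tp, params[[paste0(pre, "bo")]], paste0(pre, "bo")))
    cur <- t_add(tp, cur, mha)
    ln2 <- t_layernorm(tp, cur,
                       t_leaf(tp, params[[paste0(pre, "ln2_g")]], paste0(pre, "ln2_g")),
                       t_leaf(tp, params[[paste0(pre, "ln2_b")]], paste0(pre, "ln2_b")))
    ffn <- t_linear(tp, ln2,
                    t_leaf(tp, params[[paste0(pre, "ffn_W1")]], paste0(pre, "ffn_W1")),
                    t_leaf(tp, params[[paste0(pre, "ffn_b1")]], paste0(pre, "ffn_b1")))
    ffn <- t_relu(tp, ffn)
    ffn <- t_linear(tp, ffn,
                    t_leaf(tp, params[[paste0(pre, "ffn_W2")]], paste0(pre, "ffn_W2")),
                    t_leaf(tp, params[[paste0(pre, "ffn_b2")]], paste0(pre, "ffn_b2")))
    cur <- t_add(tp, cur, ffn)
  }
  cur <- t_layernorm(tp, cur, t_leaf(tp, params$tf_lnf_g, "tf_lnf_g"),
                     t_leaf(tp, params$tf_lnf_b, "tf_lnf_b"))
  list(out = cur, last_A = last_A)
}

#' Transformer forward pass
#'
#' Pre-norm transformer blocks whose attention logits carry the Gaussian
#' rank-1 bias term when one is supplied.
#'
#' @param tokens `(N, token_dim)` matrix.
#' @param params,cfg Parameters and configuration.
#' @param bias Optional [build_bias()] result with `N` matching.
#' @return `(N, token_dim)` matrix.
#' @export
transformer_forward <- function(tokens, params, cfg = model_config(), bias = NULL) {
  if (!is.null(bias) && bias$N != nrow(tokens))
    stop("bias dimension ", bias$N, " != token count ", nrow(tokens), call. = FALSE)
  tp <- tape_new()
  tok <- t_leaf(tp, tokens)
  lam <- if (!is.null(bias)) t_leaf(tp, bias$lambda_bias, "lambda_bias")
  t_val(tp, transformer_forward_t(tp, params, cfg, tok, bias, lam)$out)
}

t_cbind <- function(tp, ids) {
  vals <- lapply(ids, t_val, tp = tp)
  widths <- vapply(vals, ncol, numeric(1))
  out <- do.call(cbind, vals)
  tape_push(tp, out, as.integer(ids), function(g) {
    at <- 0L
    lapply(seq_along(ids), function(i) {
      sl <- g[, at + seq_len(widths[i]), drop = FALSE]
      at <<- at + widths[i]
      sl
    })
  })
}

# Taped decoder: feature-map id (s, s, D, B) + skip ids (list, finest last
# resolution order stage3, stage2, stage1, input) -> logits id (H, W, 2, B).
decoder_forward_t <- function(tp, params, cfg, map_id, skip_ids) {
  if (length(skip_ids) != cfg$decoder_stages)
    stop("need ", cfg$decoder_stages, " skip connections, got ",
         length(skip_ids), call. = FALSE)
  cur <- map_id
  for (j in seq_len(cfg$decoder_stages)) {
    cur <- t_upsample2x(tp, cur)
    skip_dim <- dim(t_val(tp, skip_ids[[j]]))
    cur_dim <- dim(t_val(tp, cur))
    if (!all(cur_dim[c(1, 2, 4)] == skip_dim[c(1, 2, 4)]))
      stop("skip connection ", j, " shape mismatch: decoder ",
           paste(cur_dim[1:2], collapse = "x"), " vs skip ",
           paste(skip_dim[1:2], collapse = "x"), call. = FALSE)
    cur <- t_concat_c(tp, c(cur, skip_ids[[j]]))
    w <- t_leaf(tp, params[[paste0("dec", j, "_W")]], paste0("dec", j, "_W"))
    b <- t_leaf(tp, params[[paste0("dec", j, "_b")]], paste0("dec", j, "_b"))
    cur <- t_conv2d(tp, cur, w, b, stride = 1L, pad = 1L, act = "relu")
  }
  hw <- t_leaf(tp, params$head_W, "head_W")
  hb <- t_leaf(tp, params$head_b, "head_b")
  t_conv2d(tp, cur, hw, hb, stride = 1L, pad = 0L)
}

#' Decoder forward pass
#'
#' Four x2 bilinear upsampling stages, each concatenating the matching skip
#' feature map and applying a 3x3 stride-1 ReLU convolution, followed by the
#' 1x1 segmentation head.
#'
#' @param feature_map `(s, s, token_dim, B)` array (transformer output
#'   reshaped onto the grid).
#' @param skips List of four skip arrays, coarsest first (encoder stages 3,
#'   2, 1, then the network input).
#' @param params,cfg Parameters and configuration.
#' @return Logits array `(input_size, input_size, num_classes, B)`.
#' @export
decoder_forward <- function(feature_map, skips, params, cfg = model_config()) {
  tp <- tape_new()
  map_id <- t_leaf(tp, feature_map)
  skip_ids <- lapply(skips, function(s) t_leaf(tp, s))
  t_val(tp, decoder_forward_t(tp, params, cfg, map_id, skip_ids))
}
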