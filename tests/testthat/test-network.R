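# Network: shape contracts, encoder/tokenizer/transformer/decoder behaviour,
# full-forward properties.

test_that("stage shapes are a pure function of the configuration", {
  for (side in c(32L, 64L, 128L)) {
    cfg <- model_config(input_size = side)
    p <- init_params(cfg, seed = 1)
    x <- array(stats::rnorm(side * side), c(side, side, 1L, 1L))
    enc <- encoder_forward(x, p, cfg)
    expect_identical(dim(enc$final),
                     c(side %/% 16L, side %/% 16L, 8L * cfg$base_channels, 1L))
    expect_length(enc$skips, 4L)
    for (i in 1:4)
      expect_equal(dim(enc$skips[[i]])[1], side / 2^i)
    m <- wlau_model(cfg, seed = 1)
    out <- wlau_forward(m, x, x, mode = "paired")
    expect_identical(dim(out$logits), c(side, side, 2L, 1L))
    expect_identical(dim(out$prob), c(side, side, 1L))
  }
  expect_error(model_config(input_size = 50), "divisible")
})

test_that("the reference-scale encoder maps 512 inputs to a 32 x 32 grid", {
  cfg <- model_config(input_size = 512L, base_channels = 2L, token_dim = 8L)
  p <- init_params(cfg, seed = 1)
  x <- array(stats::rnorm(512 * 512), c(512L, 512L, 1L, 1L))
  enc <- encoder_forward(x, p, cfg)
  expect_identical(dim(enc$final)[1:2], c(32L, 32L))
  expect_identical(model_config_full()$grid_side, 32L)
  expect_identical(model_config_full()$n_tokens, 1024L)
})

test_that("zero input with zero biases yields zero features at every stage", {
  cfg <- model_config(input_size = 32)
  p <- init_params(cfg, seed = 2)
  x <- array(0, c(32, 32, 1, 1))
  enc <- encoder_forward(x, p, cfg)
  for (s in enc$skips) expect_equal(max(abs(s)), 0)
})

test_that("tokenize flattens the grid row-major and projects to token_dim", {
  cfg <- model_config(input_size = 64)  # grid 4 -> 16 tokens
  p <- init_params(cfg, seed = 3)
  fm <- array(stats::rnorm(4 * 4 * 64), c(4, 4, 64))
  tok <- tokenize(fm, p, cfg)
  expect_identical(dim(tok), c(16L, 32L))
  # constant map with identity-block projection gives constant tokens
  fm_const <- array(1, c(4, 4, 64))
  tok_const <- tokenize(fm_const, p, cfg)
  expect_lt(max(abs(sweep(tok_const - p$posemb, 2,
                          colSums(p$proj_W) + p$proj_b))), 1e-10)
})

test_that("the transformer matches an independent plain forward when unbiased", {
  cfg <- model_config(input_size = 64, token_dim = 8L, transformer_layers = 2L,
                      attention_heads = 2L)
  p <- init_params(cfg, seed = 4)
  set.seed(4)
  tok <- matrix(rnorm(16 * 8), 16, 8)

  layernorm_ref <- function(X, g, b) {
    mu <- rowMeans(X); v <- rowMeans((X - mu)^2)
    sweep(sweep((X - mu) / sqrt(v + 1e-5), 2, g, `*`), 2, b, `+`)
  }
  ref <- tok
  for (l in 1:2) {
    pre <- paste0("tf", l, "_")
    ln1 <- layernorm_ref(ref, p[[paste0(pre, "ln1_g")]], p[[paste0(pre, "ln1_b")]])
    heads <- lapply(1:2, function(h) {
      Q <- ln1 %*% p[[paste0(pre, "h", h, "_Wq")]]
      K <- ln1 %*% p[[paste0(pre, "h", h, "_Wk")]]
      V <- ln1 %*% p[[paste0(pre, "h", h, "_Wv")]]
      oracle_attention(Q, K, V)
    })
    mha <- sweep(do.call(cbind, heads) %*% p[[paste0(pre, "Wo")]], 2,
                 p[[paste0(pre, "bo")]], `+`)
    ref <- ref + mha
    ln2 <- layernorm_ref(ref, p[[paste0(pre, "ln2_g")]], p[[paste0(pre, "ln2_b")]])
    h1 <- pmax(sweep(ln2 %*% p[[paste0(pre, "ffn_W1")]], 2,
                     p[[paste0(pre, "ffn_b1")]], `+`), 0)
    ref <- ref + sweep(h1 %*% p[[paste0(pre, "ffn_W2")]], 2,
                       p[[paste0(pre, "ffn_b2")]], `+`)
  }
  ref <- layernorm_ref(ref, p$tf_lnf_g, p$tf_lnf_b)

  bias0 <- build_bias(runif(16, 0.2, 1), lambda_bias = 0)
  out <- transformer_forward(tok, p, cfg, bias = bias0)
  expect_equal(out, ref, tolerance = 1e-5)
  out_nobias <- transformer_forward(tok, p, cfg, bias = NULL)
  expect_equal(out_nobias, ref, tolerance = 1e-5)
  expect_identical(dim(out), dim(tok))
  expect_error(transformer_forward(tok[1:4, ], p, cfg, bias = bias0),
               "token count")
})

test_that("increasing lambda_bias concentrates attention on high-weight tokens", {
  cfg <- model_config(input_size = 64, token_dim = 8L, transformer_layers = 1L,
                      attention_heads = 1L)
  p <- init_params(cfg, seed = 5)
  set.seed(5)
  tok <- matrix(rnorm(16 * 8), 16, 8)
  g <- rep(0.05, 16); g[c(6, 7, 10, 11)] <- 1   # tumor-concentrated weights
  mass <- vapply(c(0.5, 1, 2, 4), function(lam) {
    ln <- {
      mu <- rowMeans(tok); v <- rowMeans((tok - mu)^2)
      sweep(sweep((tok - mu) / sqrt(v + 1e-5), 2, p$tf1_ln1_g, `*`), 2,
            p$tf1_ln1_b, `+`)
    }
    Q <- ln %*% p$tf1_h1_Wq; K <- ln %*% p$tf1_h1_Wk; V <- ln %*% p$tf1_h1_Wv
    res <- biased_attention(Q, K, V, build_bias(g, lambda_bias = lam),
                            return_logits = TRUE)
    mean(res$P[, g == 1])
  }, numeric(1))
  expect_true(all(diff(mass) > 0))
})

test_that("decoder shapes double per stage and the head emits class logits", {
  cfg <- model_config(input_size = 64)
  p <- init_params(cfg, seed = 6)
  x <- array(stats::rnorm(64 * 64), c(64, 64, 1, 1))
  enc <- encoder_forward(x, p, cfg)
  fm <- array(stats::rnorm(4 * 4 * 32), c(4, 4, 32, 1))
  skips <- c(rev(enc$skips)[2:4], list(x))
  out <- decoder_forward(fm, skips, p, cfg)
  expect_identical(dim(out), c(64L, 64L, 2L, 1L))
  bad <- skips; bad[[2]] <- bad[[3]]
  expect_error(decoder_forward(fm, bad, p, cfg), "mismatch")
  expect_error(decoder_forward(fm, skips[1:3], p, cfg), "skip")
})

test_that("the full forward is deterministic and phase-symmetric when inputs match", {
  cfg <- model_config(input_size = 32)
  m <- wlau_model(cfg, seed = 7)
  x <- array(stats::rnorm(32 * 32), c(32, 32, 1, 1))
  y <- array(stats::rnorm(32 * 32), c(32, 32, 1, 1))
  o1 <- wlau_forward(m, x, y, mode = "paired")
  o2 <- wlau_forward(m, x, y, mode = "paired")
  expect_identical(o1$logits, o2$logits)
  single <- wlau_forward(m, x, mode = "single")
  same <- wlau_forward(m, x, x, mode = "paired")
  expect_equal(single$logits, same$logits, tolerance = 1e-12)
  expect_error(wlau_forward(m, x, NULL, mode = "paired"), "venous")
})

test_that("with bias and gate off the forward reduces to the plain hybrid network", {
  cfg <- model_config(input_size = 32)
  cs <- small_cases(1, seed = 8)[[1]]
  plain <- wlau_model(cfg, seed = 8, gpsa = FALSE, gate = FALSE)
  biased <- wlau_model(cfg, seed = 8, gpsa = TRUE)
  nc <- hu_clip_normalize(cs$noncontrast$data)
  ve <- hu_clip_normalize(cs$venous$data)
  po <- wlau_forward(plain, nc, ve, mode = "paired")
  bo <- wlau_forward(biased, nc, ve, masks = list(cs$mask), mode = "paired")
  expect_false(isTRUE(all.equal(po$logits, bo$logits)))
  # lambda_bias = 0 with the gate off collapses the biased path onto the plain one
  biased0 <- biased
  biased0$params$lambda_bias <- 0
  bo0 <- wlau_forward(biased0, nc, ve, masks = list(cs$mask), mode = "paired")
  expect_equal(bo0$logits, po$logits, tolerance = 1e-10)
})

test_that("parameter counts are finite and independent of input content", {
  cfg <- model_config(input_size = 32)
  p <- init_params(cfg, seed = 9)
  expect_true(is.finite(n_parameters(p)))
  expect_identical(n_parameters(p), n_parameters(init_params(cfg, seed = 77)))
  expect_gt(n_parameters(p), 1000)
})
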