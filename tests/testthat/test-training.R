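# Training: losses, schedule, the two-phase transfer protocol, freezing,
# checkpoints.

test_that("soft Dice loss matches its hand-computed cases", {
  t2 <- c(1, 1, 0, 0); p_perf <- c(1, 1, 0, 0)
  expect_equal(dice_loss(t2, p_perf), 0, tolerance = 1e-6)
  expect_equal(dice_loss(c(1, 1, 0, 0), c(0, 0, 1, 1)), 1, tolerance = 1e-6)
  # |T| = |P| = 2 with overlap 1: 1 - 2/4
  expect_equal(dice_loss(c(1, 1, 0, 0), c(0, 1, 1, 0)), 0.5, tolerance = 1e-6)
  expect_equal(dice_loss(numeric(4), numeric(4)), 0, tolerance = 1e-9)
  expect_error(dice_loss(c(1, 0), c(0.5, 1.2)), "0, 1")
  expect_error(dice_loss(c(1, 0), c(0.5)), "shape")
})

test_that("Dice loss is bounded in [0, 1] on random mask/probability pairs", {
  set.seed(1)
  for (i in 1:1000) {
    n <- sample(4:32, 1)
    truth <- as.numeric(runif(n) < 0.4)
    pred <- runif(n)
    l <- dice_loss(truth, pred)
    expect_true(l >= 0 && l <= 1)
  }
})

test_that("the total loss is dice + alpha * attention", {
  expect_equal(total_loss(0.5, 1.0, 0.3), 0.8)
  expect_equal(total_loss(0.42, 99, 0), 0.42)
  expect_equal(total_loss(0, 0, 0.3), 0)
  expect_gte(total_loss(0.3, 0.2, 0.5), 0.3)  # alpha >= 0 never reduces it
  expect_error(total_loss(1, 1, -0.1), "alpha")
})

test_that("cosine annealing hits its anchor points", {
  expect_equal(cosine_lr(0, 100, 3e-4), 3e-4)
  expect_equal(cosine_lr(100, 100, 3e-4), 0)
  expect_equal(cosine_lr(50, 100, 3e-4), 1.5e-4)
  lrs <- cosine_lr(0:100, 100, 3e-4)
  expect_true(all(diff(lrs) < 0))
  expect_error(cosine_lr(0, 0, 1e-3), "positive")
  expect_error(cosine_lr(5, 4, 1e-3), "range")
})

test_that("training configuration validates its ranges", {
  expect_error(train_config(epochs = 0), "epochs")
  expect_error(train_config(supervision_alpha = -1), "alpha")
  cfg <- train_config()
  expect_equal(cfg$lr_init, 3e-4)
  expect_equal(cfg$weight_decay, 1e-2)
  expect_equal(cfg$supervision_alpha, 0.3)
})

test_that("venous pretraining reduces the Dice loss on the phantom set", {
  cases <- small_cases(12, seed = 50)
  cfg <- model_config(input_size = 32)
  res <- pretrain_venous(cases, tcfg = train_config(epochs = 5, seed = 1),
                         config = cfg)
  h <- res$history$dice_loss
  expect_lt(mean(tail(h, 2)), mean(head(h, 2)))
})

test_that("training is deterministic given a seed, and a zero lr is a null update", {
  cases <- small_cases(6, seed = 60)
  cfg <- model_config(input_size = 32)
  r1 <- pretrain_venous(cases, tcfg = train_config(epochs = 2, seed = 3), config = cfg)
  r2 <- pretrain_venous(cases, tcfg = train_config(epochs = 2, seed = 3), config = cfg)
  expect_identical(r1$history$loss, r2$history$loss)
  expect_identical(r1$model$params, r2$model$params)
  m0 <- wlau_model(cfg, seed = 3)
  r0 <- pretrain_venous(cases, model = m0,
                        tcfg = train_config(epochs = 2, lr_init = 0, seed = 3))
  expect_identical(r0$model$params[names(m0$params)], m0$params)
})

test_that("transfer copies encoder weights bit-exactly and freezing holds", {
  cases <- small_cases(8, seed = 70)
  cfg <- model_config(input_size = 32)
  pre <- pretrain_venous(cases, tcfg = train_config(epochs = 2, seed = 5),
                         config = cfg)
  enc_names <- wlaunet:::encoder_param_names(cfg)
  fresh <- wlau_model(cfg, seed = 99, gpsa = TRUE)
  m <- transfer_and_freeze(pre$model, fresh)
  for (nm in enc_names) expect_identical(m$params[[nm]], pre$model$params[[nm]])
  expect_identical(m$frozen, enc_names)
  ph2 <- train_noncontrast(cases, m, train_config(epochs = 3, seed = 5))
  for (nm in enc_names)
    expect_identical(ph2$model$params[[nm]], pre$model$params[[nm]])
  # everything else did move
  expect_false(identical(ph2$model$params$head_W, m$params$head_W))
  # trainable bookkeeping
  total <- n_parameters(m$params)
  frozen_n <- sum(vapply(m$params[enc_names], length, numeric(1)))
  trainable <- n_parameters(m$params[setdiff(names(m$params), enc_names)])
  expect_identical(trainable, total - frozen_n)
})

test_that("architecture mismatch and unfrozen phase-2 runs are refused", {
  cfg32 <- model_config(input_size = 32)
  cfg64 <- model_config(input_size = 64, base_channels = 4L, token_dim = 16L)
  a <- wlau_model(cfg32, seed = 1)
  b <- wlau_model(cfg64, seed = 1)
  expect_error(transfer_and_freeze(a, b), "mismatch")
  cases <- small_cases(4, seed = 80)
  m <- wlau_model(cfg32, seed = 1)
  expect_error(suppressWarnings(
    train_noncontrast(cases, m, train_config(epochs = 1))), "unfrozen")
  r <- train_noncontrast(cases, m, train_config(epochs = 1), allow_unfrozen = TRUE)
  expect_s3_class(r$model, "wlau_model")
})

test_that("the stats sidecar is the plain mean of the per-case statistics", {
  cases <- small_cases(8, seed = 90)
  cfg <- model_config(input_size = 32)
  pre <- pretrain_venous(cases, tcfg = train_config(epochs = 1, seed = 2),
                         config = cfg,
                         enhancement = NULL)
  m <- transfer_and_freeze(pre$model)
  m$gpsa <- TRUE
  ph2 <- train_noncontrast(cases, m, train_config(epochs = 1, seed = 2))
  stats <- ph2$model$per_case_stats
  expect_gt(length(stats), 0)
  expect_equal(ph2$model$population_stats$mu,
               mean(vapply(stats, `[[`, numeric(1), "mu")))
  expect_equal(ph2$model$population_stats$sigma,
               mean(vapply(stats, `[[`, numeric(1), "sigma")))
})

test_that("attention supervision changes the optimization trajectory", {
  cases <- small_cases(6, seed = 100)
  cfg <- model_config(input_size = 32)
  pre <- pretrain_venous(cases, tcfg = train_config(epochs = 1, seed = 4),
                         config = cfg)
  m <- transfer_and_freeze(pre$model)
  m$gpsa <- TRUE
  rA <- train_noncontrast(cases, m, train_config(epochs = 2, seed = 4,
                                                 supervision_alpha = 0.3))
  rB <- train_noncontrast(cases, m, train_config(epochs = 2, seed = 4,
                                                 supervision_alpha = 0))
  expect_false(identical(rA$model$params$tf1_h1_Wq, rB$model$params$tf1_h1_Wq))
})

test_that("checkpoints round-trip through JSON including population statistics", {
  cases <- small_cases(6, seed = 110)
  cfg <- model_config(input_size = 32)
  res <- run_experiment(cases, transfer = TRUE, gpsa = TRUE, weem = TRUE,
                        epochs = 1, net_config = cfg, seed = 6)
  path <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(res$model, path)
  back <- load_checkpoint(path)
  expect_equal(back$params, res$model$params, tolerance = 1e-12)
  expect_identical(back$frozen, res$model$frozen)
  expect_equal(back$population_stats$mu, res$model$population_stats$mu)
  cs <- cases[[1]]
  expect_equal(predict_mask(back, cs), predict_mask(res$model, cs),
               tolerance = 0)
})
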