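# Wavelet edge-enhancement: transform correctness, amplification contracts,
# energy bookkeeping, sweep harness.

test_that("details of a constant image vanish and subbands share one shape", {
  s <- dwt2(matrix(3.7, 32, 32), "sym4")
  expect_lt(max(abs(s$LH)), 1e-10)
  expect_lt(max(abs(s$HL)), 1e-10)
  expect_lt(max(abs(s$HH)), 1e-10)
  expect_true(all(vapply(s[c("LH", "HL", "HH")],
                         function(b) identical(dim(b), dim(s$LL)), logical(1))))
})

test_that("subbands match the brute-force 2D convolution oracle", {
  set.seed(7)
  x <- matrix(rnorm(16 * 16), 16, 16)
  f <- wlaunet:::wavelet_filter("sym4")
  s <- dwt2(x, "sym4", "periodization")
  expect_equal(s$LL, oracle_dwt2_per(x, f$dec_lo, f$dec_lo), tolerance = 1e-12)
  expect_equal(s$LH, oracle_dwt2_per(x, f$dec_lo, f$dec_hi), tolerance = 1e-12)
  expect_equal(s$HL, oracle_dwt2_per(x, f$dec_hi, f$dec_lo), tolerance = 1e-12)
  expect_equal(s$HH, oracle_dwt2_per(x, f$dec_hi, f$dec_hi), tolerance = 1e-12)
  # and for an impulse specifically
  imp <- matrix(0, 16, 16); imp[5, 9] <- 1
  si <- dwt2(imp, "sym4", "periodization")
  expect_equal(si$HH, oracle_dwt2_per(imp, f$dec_hi, f$dec_hi), tolerance = 1e-12)
})

test_that("perfect reconstruction holds for every family in both boundary modes", {
  set.seed(1)
  x <- matrix(rnorm(64 * 64), 64, 64)
  for (w in supported_wavelets()) {
    for (mode in c("periodization", "symmetric")) {
      expect_lt(max(abs(idwt2(dwt2(x, w, mode)) - x)), 1e-8,
                label = paste("PR", w, mode))
    }
  }
})

test_that("idwt2 is linear", {
  set.seed(2)
  x1 <- matrix(rnorm(32 * 32), 32, 32)
  x2 <- matrix(rnorm(32 * 32), 32, 32)
  s1 <- dwt2(x1); s2 <- dwt2(x2)
  comb <- s1
  for (b in c("LL", "LH", "HL", "HH")) comb[[b]] <- 2 * s1[[b]] - 0.5 * s2[[b]]
  expect_equal(idwt2(comb), 2 * idwt2(s1) - 0.5 * idwt2(s2), tolerance = 1e-8)
  zero <- s1
  for (b in c("LL", "LH", "HL", "HH")) zero[[b]] <- s1[[b]] * 0
  expect_equal(idwt2(zero), matrix(0, 32, 32), tolerance = 1e-12)
})

test_that("amplify_subbands scales only the directional detail bands", {
  set.seed(3)
  s <- dwt2(matrix(rnorm(32 * 32), 32, 32))
  a1 <- amplify_subbands(s, 1, 1)
  expect_identical(a1[c("LL", "LH", "HL", "HH")], s[c("LL", "LH", "HL", "HH")])
  a2 <- amplify_subbands(s, 2, 2)
  expect_identical(a2$LH, 2 * s$LH)   # amplitude doubled at the operating point
  expect_identical(a2$HL, 2 * s$HL)
  expect_identical(a2$LL, s$LL)
  expect_identical(a2$HH, s$HH)
  expect_error(amplify_subbands(s, -1, 2), "positive")
})

test_that("enhance is the identity at lambda = 1 and exact on zero-detail images", {
  set.seed(4)
  x <- matrix(rnorm(32 * 32), 32, 32)
  expect_equal(enhance(x, enhancement_config(lambda1 = 1, lambda2 = 1)), x,
               tolerance = 1e-8)
  const <- matrix(5, 32, 32)
  expect_equal(enhance(const, enhancement_config(lambda1 = 1.7, lambda2 = 1.4)),
               const, tolerance = 1e-8)
})

test_that("the energy added by enhancement follows the Parseval identity", {
  set.seed(5)
  x <- matrix(rnorm(64 * 64), 64, 64)
  for (lams in list(c(2, 2), c(1.3, 2.2), c(1.5, 1.0))) {
    cfg <- enhancement_config("sym4", lams[1], lams[2])
    s <- dwt2(x, "sym4")
    lhs <- sum((enhance(x, cfg) - x)^2)
    rhs <- (lams[1] - 1)^2 * sum(s$LH^2) + (lams[2] - 1)^2 * sum(s$HL^2)
    expect_equal(lhs, rhs, tolerance = 1e-6)
  }
  # re-decomposing after lambda = 2 enhancement finds ~4x detail energy
  s0 <- dwt2(x, "sym4")
  s2 <- dwt2(enhance(x, enhancement_config("sym4", 2, 2)), "sym4")
  expect_equal(sum(s2$LH^2) / sum(s0$LH^2), 4, tolerance = 1e-6)
  expect_equal(sum(s2$HL^2) / sum(s0$HL^2), 4, tolerance = 1e-6)
})

test_that("enhance commutes with a global intensity shift", {
  set.seed(6)
  x <- matrix(rnorm(32 * 32), 32, 32)
  cfg <- enhancement_config()
  expect_equal(enhance(x + 7, cfg), enhance(x, cfg) + 7, tolerance = 1e-8)
})

test_that("unknown wavelets and invalid grids are rejected informatively", {
  expect_error(dwt2(matrix(0, 16, 16), "haar9"), "supported families")
  expect_error(enhancement_config(grid = numeric(0)), "grid")
  expect_error(enhancement_config(grid = c(2, 1)), "increasing")
  expect_error(dwt2(matrix(0, 4, 4), "sym10"), "filter length")
  expect_error(dwt2(matrix(0, 15, 15), "sym4", "periodization"), "even")
})

test_that("the default sweep grid covers [1.3, 2.2] in steps of 0.1", {
  g <- enhancement_config()$grid
  expect_length(g, 10)
  expect_equal(g[1], 1.3)
  expect_equal(g[length(g)], 2.2)
  expect_true(all(abs(diff(g) - 0.1) < 1e-12))
})

test_that("the proxy sweep ranks amplification above identity on clean phantoms", {
  cases <- small_cases(3, noise_sd_hu = 0, seed = 40)
  tab <- weem_sweep(cases, wavelets = "sym4", grid = c(1.0, 2.0),
                    scorer = "proxy", diagonal_only = TRUE)
  expect_named(tab, c("wavelet", "lambda1", "lambda2", "score"))
  expect_equal(nrow(tab), 2)
  expect_true(all(diff(tab$score) <= 0))  # sorted descending
  s20 <- tab$score[tab$lambda1 == 2.0]
  s10 <- tab$score[tab$lambda1 == 1.0]
  expect_gte(s20, s10)
  # degenerate sweep: one wavelet, one factor
  one <- weem_sweep(cases, "sym4", grid = 2.0, scorer = "proxy")
  expect_equal(nrow(one), 1)
  expect_error(weem_sweep(cases, "sym4", grid = numeric(0)), "empty")
})
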