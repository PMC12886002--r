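# Gaussian position-sensitive attention: statistics, weight maps, rank-1
# bias, biased attention, supervision, population statistics.

test_that("tumor statistics follow the definition, with the 1e-5 stabilizer", {
  fm <- matrix(c(1, 3, 10, 10), 2, 2)
  mask <- matrix(c(1, 1, 0, 0), 2, 2)
  st <- tumor_stats(fm, mask)
  expect_equal(st$mu, 2)
  expect_equal(st$sigma, sqrt(1 + 1e-5))
  const <- tumor_stats(matrix(7, 3, 3), matrix(1, 3, 3))
  expect_equal(const$mu, 7)
  expect_equal(const$sigma, sqrt(1e-5))
  expect_error(tumor_stats(fm, matrix(0, 2, 2)), "population")
  expect_error(tumor_stats(fm, matrix(0, 3, 3)), "aligned")
})

test_that("gaussian_map hits its closed forms", {
  st <- gaussian_stats(mu = 0.5, sigma = 0.2)
  fm <- matrix(0.5, 4, 4)
  expect_equal(gaussian_map(fm, st, 1), matrix(1, 4, 4))
  # deviation exactly sigma, sigma^2 >> epsilon
  dev <- matrix(0.5 + 0.2, 4, 4)
  expect_equal(gaussian_map(dev, st, 1)[1, 1],
               exp(-0.2^2 / (2 * 0.2^2 + 1e-5)), tolerance = 1e-12)
  expect_equal(gaussian_map(dev, st, 1)[1, 1], exp(-1 / 2), tolerance = 1e-4)
  # widening the scale drives weights to 1
  expect_gt(gaussian_map(dev, st, 100)[1, 1], 0.9999)
  expect_error(gaussian_map(fm, st, 0), "positive")
})

test_that("the multiscale map averages the three scales and stays in (0, 1]", {
  st <- gaussian_stats(mu = 0, sigma = 0.3)
  dev <- matrix(0.3, 2, 2)   # deviation = sigma
  target <- (exp(-2) + exp(-1 / 2) + exp(-1 / 8)) / 3
  expect_equal(multiscale_gaussian(dev, st)[1, 1], target, tolerance = 1e-4)
  expect_equal(multiscale_gaussian(matrix(0, 2, 2), st), matrix(1, 2, 2),
               tolerance = 1e-6)
  set.seed(1)
  fm <- matrix(rnorm(64), 8, 8)
  G <- multiscale_gaussian(fm, st)
  per_scale <- lapply(c(0.5, 1, 2), function(k) gaussian_map(fm, st, k))
  expect_true(all(G <= pmax(per_scale[[1]], per_scale[[2]], per_scale[[3]]) + 1e-12))
  expect_true(all(G >= pmin(per_scale[[1]], per_scale[[2]], per_scale[[3]]) - 1e-12))
  expect_true(all(G > 0 & G <= 1))
})

test_that("gaussian maps depend only on the standardized deviation", {
  set.seed(2)
  fm <- matrix(rnorm(64, 5, 2), 8, 8)
  st <- gaussian_stats(mu = 5, sigma = 2)
  sc <- gaussian_stats(mu = 5 * 3 - 1, sigma = 2 * 3)
  # affine transform of features with matching stats (epsilon breaks exact
  # equality only at the 1e-6 level for these sigmas)
  expect_equal(multiscale_gaussian(fm, st),
               multiscale_gaussian(3 * fm - 1, sc), tolerance = 1e-4)
})

test_that("build_bias produces the rank-1 symmetric outer product", {
  b1 <- build_bias(matrix(1, 2, 2))
  expect_equal(b1$B, matrix(1, 4, 4))
  b2 <- build_bias(c(1, 0.5))
  expect_equal(b2$B, matrix(c(1, 0.5, 0.5, 0.25), 2, 2))
  set.seed(3)
  G <- matrix(runif(16, 0.1, 1), 4, 4)
  bb <- build_bias(G)
  expect_equal(bb$B, t(bb$B))
  ev <- eigen(bb$B, symmetric = TRUE)$values
  expect_equal(ev[1], sum(bb$g^2), tolerance = 1e-10)
  expect_lt(max(abs(ev[-1])), 1e-10)
  expect_equal(bb$lambda_bias, 0.5)
  # row-major flattening: cell (1, 2) is the second entry
  G2 <- matrix(c(0.1, 0.3, 0.2, 0.4), 2, 2)  # column-major storage
  expect_equal(build_bias(G2)$g, c(0.1, 0.2, 0.3, 0.4))
  expect_error(build_bias(matrix(c(1, NA, 1, 1), 2, 2)), "finite")
})

test_that("bias construction is permutation-equivariant", {
  set.seed(4)
  g <- runif(6, 0.2, 1)
  p <- sample(6)
  B <- build_bias(g)$B
  Bp <- build_bias(g[p])$B
  expect_equal(Bp, B[p, p])
})

test_that("biased attention with lambda 0 equals the brute-force oracle", {
  set.seed(5)
  for (N in c(4, 6, 8)) {
    Q <- matrix(rnorm(N * 3), N, 3)
    K <- matrix(rnorm(N * 3), N, 3)
    V <- matrix(rnorm(N * 2), N, 2)
    bias <- build_bias(runif(N, 0.2, 1), lambda_bias = 0)
    expect_equal(biased_attention(Q, K, V, bias), oracle_attention(Q, K, V),
                 tolerance = 1e-6)
    expect_equal(biased_attention(Q, K, V, NULL), oracle_attention(Q, K, V),
                 tolerance = 1e-6)
  }
})

test_that("the 2-token hand computation matches", {
  Q <- matrix(c(1, 0), 2, 1)
  K <- matrix(c(1, 0), 2, 1)
  V <- diag(2)
  bias <- build_bias(c(1, 1), lambda_bias = 0.5)
  res <- biased_attention(Q, K, V, bias, return_logits = TRUE)
  expect_equal(res$A, matrix(c(1.5, 0.5, 0.5, 0.5), 2, 2))
  expect_equal(res$P[1, ], c(exp(1.5), exp(0.5)) / (exp(1.5) + exp(0.5)),
               tolerance = 1e-6)
  expect_equal(unname(rowSums(res$P)), c(1, 1), tolerance = 1e-6)
})

test_that("a uniform weight vector leaves attention unchanged for any lambda", {
  set.seed(6)
  N <- 5
  Q <- matrix(rnorm(N * 4), N, 4); K <- matrix(rnorm(N * 4), N, 4)
  V <- matrix(rnorm(N * 3), N, 3)
  plain <- biased_attention(Q, K, V, NULL)
  for (lam in c(0.5, 3, -2)) {
    bias <- build_bias(rep(0.7, N), lambda_bias = lam)
    expect_equal(biased_attention(Q, K, V, bias), plain, tolerance = 1e-10)
  }
})

test_that("attention output rows are convex combinations of V", {
  set.seed(7)
  N <- 6
  Q <- matrix(rnorm(N * 2), N, 2); K <- matrix(rnorm(N * 2), N, 2)
  V <- diag(N)  # one-hot values: outputs are the attention rows themselves
  bias <- build_bias(runif(N, 0.1, 1))
  out <- biased_attention(Q, K, V, bias)
  expect_equal(unname(rowSums(out)), rep(1, N), tolerance = 1e-6)
  expect_true(all(out > 0))
  expect_error(biased_attention(Q, K[1:3, ], V), "token counts")
  expect_error(biased_attention(Q, matrix(0, N, 3), V), "dimensions differ")
})

test_that("supervision targets downsample by area fraction at threshold 0.5", {
  expect_equal(attention_supervision_target(matrix(1, 4, 4), c(2, 2)),
               rep(1, 4))
  expect_equal(attention_supervision_target(matrix(0, 4, 4), c(2, 2)),
               rep(0, 4))
  m <- matrix(0, 4, 4); m[1:2, 1:2] <- 1   # one full corner cell
  expect_equal(attention_supervision_target(m, c(2, 2)), c(1, 0, 0, 0))
  expect_error(attention_supervision_target(matrix(0, 2, 2), c(4, 4)), "larger")
})

test_that("the supervision loss matches hand BCE for uniform attention", {
  N <- 4
  A <- matrix(0, N, N)             # uniform rows after softmax
  target <- c(1, 1, 0, 0)
  p <- 1 / N
  hand <- mean(c(rep(-log(p), 2), rep(-log(1 - p), 2)))
  expect_equal(attention_supervision_loss(A, target), hand, tolerance = 1e-10)
  expect_gte(attention_supervision_loss(A, target), 0)
})

test_that("the supervision loss rewards concentration and is permutation-equivariant", {
  N <- 6
  target <- c(1, 1, 0, 0, 0, 0)
  losses <- vapply(c(0, 1, 2, 4, 8), function(s) {
    A <- matrix(0, N, N)
    A[, target == 1] <- s            # increasingly tumor-focused attention
    attention_supervision_loss(A, target)
  }, numeric(1))
  expect_true(all(diff(losses) < 0))
  set.seed(8)
  A <- matrix(rnorm(N * N), N, N)
  p <- sample(N)
  expect_equal(attention_supervision_loss(A[p, p], target[p]),
               attention_supervision_loss(A, target), tolerance = 1e-12)
  expect_error(attention_supervision_loss(A, target[1:3]), "token count")
})

test_that("population statistics are plain averages", {
  s1 <- gaussian_stats(1, 1)
  s2 <- gaussian_stats(3, 2)
  s3 <- gaussian_stats(2, 3)
  expect_equal(population_stats(list(s1))$mu, 1)
  expect_equal(population_stats(list(s1, s2))$mu, 2)
  expect_equal(population_stats(list(s1, s2, s3))$sigma, 2)
  expect_error(population_stats(list()), "empty")
})
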