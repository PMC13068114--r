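# Balanced MSE, approximate NDCG, amplified ranking loss, and gradients.

test_that("balanced_mse matches a term-by-term brute-force evaluation", {
  set.seed(4)
  p <- rnorm(8, 6, 2)
  y <- rnorm(8, 6, 2)
  s <- 1.3
  oracle <- 0
  for (i in 1:8) {
    num <- exp(-(p[i] - y[i])^2 / (2 * s^2))
    den <- sum(exp(-(p[i] - y)^2 / (2 * s^2)))
    oracle <- oracle - log(num / den) / 8
  }
  expect_equal(balanced_mse(p, y, s), oracle, tolerance = 1e-10)
})

test_that("balanced_mse degenerate and limiting behaviour", {
  expect_equal(balanced_mse(3.7, 9.9, 1), 0) # B = 1: single-label softmax
  # small sigma: the correct label dominates each softmax
  expect_lt(balanced_mse(c(1, 2), c(1, 2), 1e-3), 1e-10)
  expect_error(balanced_mse(1, 1, 0), "positive")
  # invariance to batch permutation
  set.seed(5)
  p <- rnorm(6); y <- rnorm(6)
  perm <- sample(6)
  expect_equal(balanced_mse(p, y, 0.8), balanced_mse(p[perm], y[perm], 0.8))
})

test_that("approx_ndcg approaches exact NDCG over all 4-item permutations", {
  set.seed(6)
  rel <- c(0.5, 1.5, 2.5, 3.5)
  scores <- rnorm(4, sd = 3)
  perms <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 4), ]
  for (k in seq_len(nrow(perms))) {
    s <- scores[as.integer(perms[k, ])]
    expect_equal(approx_ndcg(s, rel, temperature = 1e-4), exact_ndcg(s, rel),
                 tolerance = 1e-6)
  }
  # perfect ordering scores 1; reversed ordering scores strictly less
  expect_equal(approx_ndcg(sort(rel), rel, 1e-4), 1, tolerance = 1e-9)
  expect_lt(approx_ndcg(rev(sort(rel)), rel, 1e-4),
            approx_ndcg(sort(rel), rel, 1e-4))
  # all-equal relevances: any order is ideal
  expect_equal(approx_ndcg(rnorm(5), rep(2, 5)), 1)
})

test_that("rank_loss closed-form values and shape", {
  expect_equal(rank_loss(1, alpha = 3), 0)
  expect_equal(rank_loss(0.37, alpha = 0), 0)
  expect_equal(rank_loss(0.5, alpha = 2), exp(1) - 2, tolerance = 1e-12)
  # non-negative, increasing in (1 - ndcg), convex
  nd <- seq(0, 1, by = 0.05)
  vals <- sapply(nd, rank_loss, alpha = 1.5)
  expect_true(all(vals >= 0))
  expect_true(all(diff(vals) <= 1e-12))
  expect_true(all(diff(diff(vals)) >= -1e-12))
  expect_error(rank_loss(1.2, 1), "ndcg")
})

test_that("total_loss is the sum of its parts", {
  set.seed(8)
  p <- rnorm(10, 6, 1.5); y <- rnorm(10, 6, 1.5)
  st <- loss_state(alpha = 1.3, ndcg_temperature = 0.7, sigma_init = 1.1)
  oracle <- balanced_mse(p, y, 1.1) +
    rank_loss(min(approx_ndcg(p, y, 0.7), 1), 1.3)
  expect_equal(total_loss(p, y, st), oracle, tolerance = 1e-10)
  # batch of one: rank term skipped
  expect_equal(total_loss(4.2, 5.0, st), balanced_mse(4.2, 5.0, 1.1))
  # perfect predictions, tight sigma, perfect low-temperature ranking:
  # both terms vanish
  st0 <- loss_state(sigma_init = 1e-3, ndcg_temperature = 1e-4)
  expect_lt(total_loss(c(1, 2, 3), c(1, 2, 3), st0), 1e-10)
})

test_that("analytic loss gradients agree with finite differences", {
  set.seed(9)
  p <- rnorm(7, 6, 2); y <- rnorm(7, 6, 2)
  st <- loss_state(alpha = 1.2, ndcg_temperature = 0.9, sigma_init = 1.4)
  tg <- potentialbind:::.total_grad(p, y, st)
  eps <- 1e-6
  for (i in seq_along(p)) {
    p1 <- p; p1[i] <- p1[i] + eps
    p2 <- p; p2[i] <- p2[i] - eps
    num <- (total_loss(p1, y, st) - total_loss(p2, y, st)) / (2 * eps)
    expect_equal(tg$dpred[i], num, tolerance = 1e-4)
  }
  # gradient wrt the log noise variance
  stp <- st; stp$log_sigma2 <- st$log_sigma2 + eps
  stm <- st; stm$log_sigma2 <- st$log_sigma2 - eps
  g2 <- function(s) potentialbind:::.bme_grad(p, y, s$log_sigma2)$value
  expect_equal(tg$dlog_sigma2, (g2(stp) - g2(stm)) / (2 * eps),
               tolerance = 1e-4)
})

test_that("the compiled loss matches the R loss on engine predictions", {
  spec <- tiny_spec(n = 5)
  items <- make_dataset(spec)
  m <- tiny_model()
  packs <- lapply(items, potentialbind:::pack_item, config = m$config)
  b <- potentialbind:::assemble_batch(packs, m$config)
  y <- vapply(items, function(it) it$label, 0)
  st <- loss_state(alpha = 1.1, ndcg_temperature = 0.8)
  res <- potentialbind:::batch_train_step(m, b, y, packs[[1]]$nf,
                                          st$log_sigma2, st)
  st$log_sigma2 <- st$log_sigma2 # unchanged
  expect_equal(res$value, total_loss(res$preds, y, st), tolerance = 1e-10)
})
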