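# Compiled engine vs the reference R path, and its analytic gradients.

test_that("batched compiled predictions equal the reference implementation", {
  spec <- tiny_spec(n = 4)
  items <- make_dataset(spec)
  for (cfg in list(tiny_config(),
                   tiny_config(symmetry = "e3"),
                   tiny_config(symmetry = "none"),
                   tiny_config(difference_head = FALSE))) {
    m <- affinity_model(cfg, seed = 3)
    ref <- vapply(items, function(it)
      predict_affinity(m, it$graphs$complex, it$graphs$protein,
                       it$graphs$ligand)$affinity, 0)
    expect_equal(predict_dataset(m, items), ref, tolerance = 1e-10)
  }
})

test_that("the unshared (three-network) engine matches its reference", {
  spec <- tiny_spec(n = 3)
  items <- make_dataset(spec)
  m <- affinity_model(tiny_config(shared_weights = FALSE), seed = 9)
  ref <- vapply(items, function(it)
    predict_affinity(m, it$graphs$complex, it$graphs$protein,
                     it$graphs$ligand)$affinity, 0)
  expect_equal(predict_dataset(m, items), ref, tolerance = 1e-10)
  # the three parameter sets genuinely differ
  expect_false(isTRUE(all.equal(m$params$protein$emb, m$params$ligand$emb)))
})

test_that("fused-step gradients match finite differences", {
  spec <- tiny_spec(n = 4)
  items <- make_dataset(spec)
  cfg <- encoder_config(hidden_dim = 6L, n_rbf = 4L, n_layers = 2L,
                        precision = "double")
  m <- affinity_model(cfg, seed = 3)
  packs <- lapply(items, potentialbind:::pack_item, config = cfg)
  b <- potentialbind:::assemble_batch(packs, cfg)
  y <- vapply(items, function(it) it$label, 0)
  st <- loss_state(alpha = 1.0, ndcg_temperature = 1.0)
  res <- potentialbind:::batch_train_step(m, b, y, packs[[1]]$nf, 0.2, st)
  gr <- res$grads[[1]]
  lossfun <- function(params) {
    m2 <- m
    m2$params <- params
    potentialbind:::batch_train_step(m2, b, y, packs[[1]]$nf, 0.2, st)$value
  }
  eps <- 1e-6
  set.seed(21)
  for (pn in c("emb", "We1", "be2", "F1e_1", "F1i_2", "F1j_1", "bf1_2",
               "F2_1", "U1_2", "bu1_1", "U2_1", "O1", "O2")) {
    p <- m$params[[pn]]
    for (k in sample(length(p), min(3, length(p)))) {
      p1 <- m$params; p1[[pn]][k] <- p1[[pn]][k] + eps
      p2 <- m$params; p2[[pn]][k] <- p2[[pn]][k] - eps
      num <- (lossfun(p1) - lossfun(p2)) / (2 * eps)
      expect_equal(as.numeric(gr[[pn]])[k], num, tolerance = 1e-4,
                   label = paste("grad", pn, "entry", k))
    }
  }
  # noise-variance gradient
  num <- (potentialbind:::batch_train_step(m, b, y, packs[[1]]$nf, 0.2 + eps, st)$value -
          potentialbind:::batch_train_step(m, b, y, packs[[1]]$nf, 0.2 - eps, st)$value) /
    (2 * eps)
  expect_equal(res$dlog_sigma2, num, tolerance = 1e-4)
})

test_that("single-precision kernels agree with double to float tolerance", {
  spec <- tiny_spec(n = 4)
  items <- make_dataset(spec)
  md <- affinity_model(encoder_config(precision = "double"), seed = 5)
  ms <- md
  ms$config$precision <- "single"
  pd <- predict_dataset(md, items)
  ps <- predict_dataset(ms, items)
  expect_equal(ps, pd, tolerance = 1e-4)
  # training-step loss and gradients track the double path
  packs <- lapply(items, potentialbind:::pack_item, config = md$config)
  b <- potentialbind:::assemble_batch(packs, md$config)
  y <- vapply(items, function(it) it$label, 0)
  st <- loss_state()
  rd <- potentialbind:::batch_train_step(md, b, y, packs[[1]]$nf, 0, st)
  rs <- potentialbind:::batch_train_step(ms, b, y, packs[[1]]$nf, 0, st)
  expect_equal(rs$value, rd$value, tolerance = 1e-3)
  gd <- unlist(rd$grads[[1]])
  gs <- unlist(rs$grads[[1]])
  expect_lt(sqrt(sum((gd - gs)^2)) / (sqrt(sum(gd^2)) + 1e-12), 1e-3)
})

test_that("segment bookkeeping assigns each graph its sign and frame share", {
  spec <- tiny_spec(n = 2)
  items <- make_dataset(spec)
  cfg <- tiny_config()
  packs <- lapply(items, potentialbind:::pack_item, config = cfg)
  b <- potentialbind:::assemble_batch(packs, cfg)
  pk <- b$all
  # 2 items x 3 roles x 4 frames segments, signs -1 (complex) and +1 (others)
  expect_equal(pk$nseg, 24L)
  expect_equal(sum(pk$seg_sign == -1), 8L)
  expect_equal(sort(unique(pk$seg_item)), c(1L, 2L))
  # every node belongs to a segment, every edge endpoint is a valid node
  expect_true(all(pk$seg >= 1 & pk$seg <= pk$nseg))
  expect_true(all(c(pk$src, pk$dst) >= 1 & c(pk$src, pk$dst) <= pk$n))
})
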