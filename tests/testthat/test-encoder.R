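# Atom/edge embeddings and message passing.

test_that("node embeddings are a shared lookup table", {
  m <- tiny_model()
  h <- embed_nodes(c(6L, 6L, 8L), m)
  expect_equal(dim(h), c(3L, 8L))
  expect_equal(h[1, ], h[2, ])
  expect_false(isTRUE(all.equal(h[1, ], h[3, ])))
  # permuting atoms permutes rows
  z <- c(6L, 7L, 8L, 16L)
  perm <- c(3L, 1L, 4L, 2L)
  expect_equal(embed_nodes(z[perm], m), embed_nodes(z, m)[perm, ])
  expect_error(embed_nodes(0L, m), "range")
  expect_error(embed_nodes(999L, m), "range")
  # the default table covers every element up to uranium and beyond
  md <- affinity_model(encoder_config(), seed = 1)
  expect_equal(ncol(embed_nodes(92L, md)), 128L)
})

test_that("RBF centers span (0, cutoff] and edge embeddings are deterministic", {
  B <- rbf_expand(c(0.5, 5.0), n_rbf = 16, cutoff = 5.0)
  expect_equal(dim(B), c(2L, 16L))
  # an edge at the cutoff activates the last basis most strongly
  expect_equal(which.max(B[2, ]), 16L)
  expect_equal(max(B[2, ]), 1)

  m <- tiny_model()
  d <- c(2.0, 2.0, 3.5)
  r <- rbind(c(2, 0, 0), c(0, 2, 0), c(0, 0, 3.5))
  e <- embed_edges(d, r, m)
  expect_equal(dim(e), c(3L, 8L))
  expect_false(isTRUE(all.equal(e[1, ], e[2, ]))) # direction matters
  expect_equal(embed_edges(d, r, m), e) # deterministic
  # scaling r leaves the unit-normalized direction (and embedding) unchanged
  expect_equal(embed_edges(d, r * 3, m), e)
  expect_error(embed_edges(c(0, 1), matrix(0, 2, 3), m), "positive")
})

test_that("message passing is residual, local, and permutation-equivariant", {
  m <- tiny_model()
  set.seed(11)
  n <- 20
  X <- matrix(runif(n * 3, 0, 8), n, 3)
  ed <- radius_edges(X, 5.0)
  z <- sample(c(6L, 7L, 8L, 16L), n, replace = TRUE)
  h <- embed_nodes(z, m)
  e <- embed_edges(ed$d, ed$r, m)
  h1 <- message_layer(h, e, ed, m, layer = 1L)
  expect_equal(dim(h1), dim(h))

  # isolated node: update is MLP(0), identical for all isolated nodes
  h_iso <- message_layer(h, matrix(0, 0, 8), list(i = integer(0), j = integer(0)),
                         m, layer = 1L)
  mlp0 <- h_iso - h
  expect_equal(mlp0[1, ], mlp0[2, ]) # same constant added everywhere

  # zeroed update MLP: residual path gives the identity
  m0 <- m
  m0$params$U2_1 <- m0$params$U2_1 * 0
  m0$params$bu2_1 <- m0$params$bu2_1 * 0
  expect_equal(message_layer(h, e, ed, m0, layer = 1L), h)

  # permutation equivariance of the full encoder
  g <- potentialbind:::molecular_graph(z, X, ed, "complex")
  out <- encode(g, m)
  perm <- sample(n)
  Xp <- X[perm, ]
  edp <- radius_edges(Xp, 5.0)
  gp <- potentialbind:::molecular_graph(z[perm], Xp, edp, "complex")
  outp <- encode(gp, m)
  expect_equal(outp, out[perm, ], tolerance = 1e-10)
})

test_that("encode depends on coordinates only through edge geometry", {
  m <- tiny_model()
  spec <- tiny_spec()
  g <- generate_complex(spec, 1)
  g <- build_graphs(g)$complex
  out <- encode(g, m)
  # translation leaves distances and directions unchanged even without frames
  g2 <- g
  g2$X <- g$X + rep(c(10, -5, 3), each = nrow(g$X))
  expect_equal(encode(g2, m), out, tolerance = 1e-12)
  # single-atom graph: four residual increments on the embedding
  g1 <- potentialbind:::molecular_graph(
    6L, matrix(0, 1, 3), list(i = integer(0), j = integer(0), d = numeric(0),
                              r = matrix(0, 0, 3)), "ligand")
  h1 <- encode(g1, m)
  expect_equal(dim(h1), c(1L, 8L))
  h_manual <- embed_nodes(6L, m)
  for (l in 1:2)
    h_manual <- message_layer(h_manual, matrix(0, 0, 8),
                              list(i = integer(0), j = integer(0)), m, layer = l)
  expect_equal(h1, h_manual)
})
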