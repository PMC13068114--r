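# Synthetic complex generator and the additive oracle potential.

test_that("generation is deterministic and satisfies placement constraints", {
  spec <- tiny_spec()
  s1 <- generate_complex(spec, 3)
  s2 <- generate_complex(spec, 3)
  expect_identical(s1, s2) # bitwise-identical coordinates per (seed, index)
  expect_false(identical(generate_complex(spec, 4), s1))

  for (idx in 1:5) {
    st <- generate_complex(spec, idx)
    P <- as.matrix(st$atoms[!st$atoms$is_ligand, c("x", "y", "z")])
    L <- as.matrix(st$atoms[st$atoms$is_ligand, c("x", "y", "z")])
    dmin <- min(sqrt(outer(rowSums(P^2), rowSums(L^2), "+") - 2 * P %*% t(L)))
    expect_gte(dmin, spec$clash_distance - 1e-9)
    expect_lte(dmin, spec$interface_distance + 1e-9)
    # below the residue cap: cropping is a no-op
    expect_equal(crop_pocket(st), st)
  }
})

test_that("oracle labels match a brute-force pair sum and are additive", {
  spec <- tiny_spec()
  st <- generate_complex(spec, 2)
  at <- st$atoms
  # independent double loop with the explicit pair formula
  g_pair <- function(d, e1, e2) {
    eps <- sqrt(spec$well_depths[e1] * spec$well_depths[e2])
    raw <- function(x) eps * ((spec$r0 / x)^12 - 2 * (spec$r0 / x)^6)
    if (d <= spec$interaction_range) raw(d) - raw(spec$interaction_range) else 0
  }
  total <- 0
  prot <- which(!at$is_ligand)
  lig <- which(at$is_ligand)
  for (i in prot) for (j in lig) {
    d <- sqrt((at$x[i] - at$x[j])^2 + (at$y[i] - at$y[j])^2 +
                (at$z[i] - at$z[j])^2)
    total <- total + g_pair(d, at$element[i], at$element[j])
  }
  total <- as.numeric(total)
  label <- oracle_affinity(st, spec, noise = FALSE)
  expect_equal(label, spec$label_center + spec$label_scale * (-total),
               tolerance = 1e-10)
  # per-atom split reproduces the total exactly (oracle additivity)
  expect_equal(sum(oracle_atom_energies(st, spec)), total, tolerance = 1e-10)
})

test_that("a far-away ligand has no interaction energy", {
  spec <- tiny_spec()
  st <- generate_complex(spec, 1)
  at <- st$atoms
  at$x[at$is_ligand] <- at$x[at$is_ligand] + 100
  far <- molecular_structure(at)
  expect_equal(oracle_affinity(far, spec, noise = FALSE), spec$label_center)
  expect_equal(oracle_atom_energies(far, spec), rep(0, nrow(at)))
})

test_that("the oracle potential is achiral", {
  # the oracle depends on pair distances only, so a mirrored complex must
  # carry exactly the same label
  spec <- tiny_spec()
  st <- generate_complex(spec, 4)
  at <- st$atoms
  at$x <- -at$x
  expect_equal(oracle_affinity(molecular_structure(at), spec, noise = FALSE),
               oracle_affinity(st, spec, noise = FALSE), tolerance = 1e-12)
})

test_that("label noise is unbiased around the deterministic label", {
  spec <- tiny_spec()
  st <- generate_complex(spec, 1)
  det <- oracle_affinity(st, spec, noise = FALSE)
  set.seed(31)
  draws <- replicate(400, oracle_affinity(st, spec, noise = TRUE))
  se <- spec$noise_sd / sqrt(length(draws))
  expect_lt(abs(mean(draws) - det), 3 * se)
  expect_equal(sd(draws), spec$noise_sd, tolerance = 0.25)
})

test_that("make_dataset splits by index and labels vary", {
  spec <- synthetic_spec(n_complexes = 12, seed = 3)
  ds <- make_dataset(spec, split = c(8, 2, 2))
  expect_length(ds$train, 8L)
  expect_length(ds$val, 2L)
  expect_length(ds$test, 2L)
  y <- vapply(c(ds$train, ds$val, ds$test), function(it) it$label, 0)
  expect_gt(sd(y), 0)
  # items carry the three graphs with consistent node counts
  it <- ds$train[[1]]
  expect_equal(length(it$graphs$complex$z),
               length(it$graphs$protein$z) + length(it$graphs$ligand$z))
  # deterministic rebuild
  ds2 <- make_dataset(spec, split = c(8, 2, 2))
  expect_equal(vapply(ds2$train, function(it) it$label, 0),
               vapply(ds$train, function(it) it$label, 0))
})

test_that("written PDB + SDF files round-trip through parse_complex", {
  spec <- tiny_spec()
  st <- generate_complex(spec, 6)
  dir <- tempfile("synth")
  paths <- write_complex_files(st, dir, "c6")
  st2 <- parse_complex(paths["protein"], paths["ligand"])
  expect_equal(st2$n_protein_atoms, st$n_protein_atoms)
  expect_equal(st2$n_ligand_atoms, st$n_ligand_atoms)
  expect_equal(st2$atoms$atomic_number, st$atoms$atomic_number)
  # PDB fixed-point coordinates: 3 decimals
  expect_equal(as.matrix(st2$atoms[, c("x", "y", "z")]),
               as.matrix(st$atoms[, c("x", "y", "z")]), tolerance = 1e-3,
               ignore_attr = TRUE)
})
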