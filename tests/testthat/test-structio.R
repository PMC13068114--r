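# Structure parsing, pocket cropping, and radius-graph construction.

test_that("parse_complex counts heavy atoms and strips hydrogens and waters", {
  pdb <- write_test_pdb(tempfile(fileext = ".pdb"))
  sdf <- write_test_sdf(tempfile(fileext = ".sdf"))
  st <- parse_complex(pdb, sdf)
  expect_s3_class(st, "molecular_structure")
  expect_equal(st$n_protein_atoms, 6L)
  expect_equal(st$n_ligand_atoms, 1L)

  # adding hydrogens must not change the parsed structure
  pdb_h <- write_test_pdb(tempfile(fileext = ".pdb"), with_h = TRUE)
  st_h <- parse_complex(pdb_h, sdf)
  expect_equal(st_h$atoms, st$atoms)

  # waters are removed; oracle count from a raw record scan
  pdb_w <- write_test_pdb(tempfile(fileext = ".pdb"), with_water = TRUE)
  raw <- readLines(pdb_w)
  n_nonwater <- sum(grepl("^(ATOM|HETATM)", raw) & !grepl("HOH", raw))
  st_w <- parse_complex(pdb_w, sdf)
  expect_equal(st_w$n_protein_atoms, n_nonwater)
  expect_false(any(st_w$atoms$residue_name == "HOH"))
})

test_that("parse_complex reads MOL2 ligands and validates inputs", {
  pdb <- write_test_pdb(tempfile(fileext = ".pdb"))
  mol2 <- tempfile(fileext = ".mol2")
  writeLines(c(
    "@<TRIPOS>MOLECULE", "lig", " 3 2 0 0 0", "SMALL", "USER_CHARGES",
    "@<TRIPOS>ATOM",
    "  1 C1  1.000  2.000  3.000 C.3  1 LIG 0.0",
    "  2 H1  1.500  2.500  3.000 H    1 LIG 0.0",
    "  3 O1  2.000  3.100  3.200 O.2  1 LIG 0.0",
    "@<TRIPOS>BOND", "  1 1 2 1", "  2 1 3 1"), mol2)
  st <- parse_complex(pdb, mol2)
  expect_equal(st$n_ligand_atoms, 2L) # hydrogen stripped
  expect_setequal(st$atoms$element[st$atoms$is_ligand], c("C", "O"))

  expect_error(parse_complex("nonexistent.pdb", mol2), "not found")
  # ligand with only hydrogens is rejected
  sdf_h <- write_test_sdf(tempfile(fileext = ".sdf"), elements = "H")
  expect_error(parse_complex(pdb, sdf_h), "no heavy atoms")
})

test_that("crop_pocket keeps the residues nearest the ligand", {
  spec <- synthetic_spec(n_complexes = 1, protein_residues = c(80L, 80L),
                         seed = 42)
  st <- generate_complex(spec, 1)
  cropped <- crop_pocket(st, max_residues = 50L)
  kept <- unique(cropped$atoms$residue_index[!cropped$atoms$is_ligand])
  expect_length(kept, 50L)
  expect_equal(cropped$n_ligand_atoms, st$n_ligand_atoms)

  # brute-force oracle: per-residue min distance over all atom pairs
  at <- st$atoms
  lig <- at[at$is_ligand, ]
  res_ids <- unique(at$residue_index[!at$is_ligand])
  dmin <- sapply(res_ids, function(r) {
    ra <- at[at$residue_index == r & !at$is_ligand, ]
    m <- Inf
    for (i in seq_len(nrow(ra))) for (j in seq_len(nrow(lig)))
      m <- min(m, sqrt((ra$x[i] - lig$x[j])^2 + (ra$y[i] - lig$y[j])^2 +
                         (ra$z[i] - lig$z[j])^2))
    m
  })
  oracle <- res_ids[order(dmin, res_ids)][1:50]
  expect_setequal(kept, oracle)

  # below the cap everything is retained
  spec30 <- synthetic_spec(n_complexes = 1, protein_residues = c(30L, 30L),
                           seed = 42)
  st30 <- generate_complex(spec30, 1)
  expect_equal(crop_pocket(st30, 50L), st30)

  # crop monotonicity: enlarging the cap never drops a retained residue
  k20 <- unique(crop_pocket(st, 20L)$atoms$residue_index)
  k35 <- unique(crop_pocket(st, 35L)$atoms$residue_index)
  expect_true(all(k20 %in% k35))

  st_nolig <- molecular_structure(st$atoms[!st$atoms$is_ligand, ])
  expect_error(crop_pocket(st_nolig), "ligand")
})

test_that("radius_edges matches an exhaustive pairwise oracle", {
  # boundary cases
  X2 <- rbind(c(0, 0, 0), c(5.1, 0, 0))
  expect_length(radius_edges(X2, 5.0)$i, 0L)
  X2b <- rbind(c(0, 0, 0), c(4, 0, 0))
  e2 <- radius_edges(X2b, 5.0)
  expect_equal(sort(paste(e2$i, e2$j)), c("1 2", "2 1"))
  expect_equal(e2$d, c(4, 4))
  expect_length(radius_edges(matrix(0, 1, 3), 5.0)$i, 0L)

  # random 50-atom cloud vs O(n^2) double loop
  set.seed(3)
  X <- matrix(runif(150, 0, 12), 50, 3)
  e <- radius_edges(X, 5.0)
  oracle <- character(0)
  for (i in 1:50) for (j in 1:50) {
    if (i == j) next
    d <- sqrt(sum((X[j, ] - X[i, ])^2))
    if (d <= 5.0) oracle <- c(oracle, paste(i, j))
  }
  expect_setequal(paste(e$i, e$j), oracle)
  # edge symmetry and stored-distance correctness
  expect_setequal(paste(e$i, e$j), paste(e$j, e$i))
  recomputed <- sqrt(rowSums((X[e$j, ] - X[e$i, ])^2))
  expect_lt(max(abs(e$d - recomputed)), 1e-6)
  expect_equal(e$r, X[e$j, ] - X[e$i, ], ignore_attr = TRUE)
})

test_that("the three graphs partition edges by molecule", {
  spec <- tiny_spec()
  st <- generate_complex(spec, 2)
  g <- build_graphs(st, cutoff = 5.0)
  np <- st$n_protein_atoms
  # protein graph edges = complex edges with both endpoints in the protein
  ec <- paste(g$complex$i, g$complex$j)
  both_prot <- g$complex$i <= np & g$complex$j <= np
  expect_setequal(paste(g$protein$i, g$protein$j), ec[both_prot])
  both_lig <- g$complex$i > np & g$complex$j > np
  expect_setequal(paste(g$ligand$i + np, g$ligand$j + np), ec[both_lig])
  # coordinates identical across graphs (unbound = bound pose)
  expect_equal(g$complex$X[seq_len(np), ], g$protein$X)
  expect_equal(g$complex$X[-seq_len(np), ], g$ligand$X)

  # a cross-molecule contact appears only in the complex graph
  at <- data.frame(atomic_number = c(6L, 8L),
                   x = c(0, 4.9), y = 0, z = 0,
                   residue_index = c(1L, -1L), chain_id = c("A", "L"),
                   is_ligand = c(FALSE, TRUE))
  g2 <- build_graphs(molecular_structure(at), cutoff = 5.0)
  expect_length(g2$complex$i, 2L)
  expect_length(g2$protein$i, 0L)
  expect_length(g2$ligand$i, 0L) # single-atom ligand: one node, no self-edge
  expect_length(g2$ligand$z, 1L)
})
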