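# Shared fixtures: tiny structure files written on the fly, small models,
# and independent oracles used across the test files.

pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          element, type = "ATOM", occ = 1.0, b = 0.0,
                          alt = " ") {
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, name, alt, resname, chain, resno, x, y, z, occ, b,
          element)
}

# two-residue, six-heavy-atom protein; optionally with hydrogens and waters
write_test_pdb <- function(path, with_h = FALSE, with_water = FALSE) {
  lines <- c(
    pdb_atom_line(1, "N", "ALA", "A", 1, 0.0, 0.0, 0.0, "N"),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 1.5, 0.0, 0.0, "C"),
    pdb_atom_line(3, "C", "ALA", "A", 1, 2.2, 1.3, 0.0, "C"),
    pdb_atom_line(4, "N", "GLY", "A", 2, 3.5, 1.3, 0.3, "N"),
    pdb_atom_line(5, "CA", "GLY", "A", 2, 4.4, 2.4, 0.2, "C"),
    pdb_atom_line(6, "O", "GLY", "A", 2, 5.6, 2.2, 0.1, "O"))
  if (with_h) {
    lines <- c(lines,
               pdb_atom_line(7, "H1", "ALA", "A", 1, 0.2, 0.9, 0.1, "H"),
               pdb_atom_line(8, "H2", "ALA", "A", 1, -0.8, 0.1, 0.2, "H"),
               pdb_atom_line(9, "H3", "GLY", "A", 2, 3.6, 0.4, 0.5, "H"),
               pdb_atom_line(10, "H4", "GLY", "A", 2, 4.2, 3.1, 0.9, "H"))
  }
  if (with_water) {
    lines <- c(lines,
               pdb_atom_line(11, "O", "HOH", "W", 101, 8.0, 8.0, 8.0, "O",
                             type = "HETATM"),
               pdb_atom_line(12, "O", "HOH", "W", 102, 9.5, 8.5, 8.0, "O",
                             type = "HETATM"))
  }
  writeLines(c(lines, "END"), path)
  path
}

write_test_sdf <- function(path, xyz = matrix(c(2.0, 3.0, 1.0), 1, 3),
                           elements = "C") {
  n <- nrow(xyz)
  writeLines(c(
    "test ligand", "  fixture", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, 0L),
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            xyz[, 1], xyz[, 2], xyz[, 3], elements),
    "M  END", "$$$$"), path)
  path
}

# small encoder configuration: fast but structurally identical to default;
# double precision so reference-path comparisons are exact
tiny_config <- function(..., precision = "double") {
  encoder_config(hidden_dim = 8L, n_rbf = 4L, n_layers = 2L,
                 precision = precision, ...)
}

tiny_model <- function(seed = 1L, ...) affinity_model(tiny_config(...), seed = seed)

# small synthetic spec for quick dataset construction
tiny_spec <- function(n = 6L, seed = 5L, ...) {
  synthetic_spec(n_complexes = n, seed = seed, ...)
}

random_rotation_fix <- function() potentialbind:::random_rotation()

# rigidly move every graph of one item's structure/graphs
move_graphs <- function(graphs, R, v) {
  for (role in names(graphs)) {
    g <- graphs[[role]]
    g$X <- g$X %*% t(R) + rep(v, each = nrow(g$X))
    g$r <- g$r %*% t(R)
    graphs[[role]] <- g
  }
  graphs
}

# exact NDCG oracle: sort-based, gain 2^rel - 1, discount 1/log2(1 + rank)
exact_ndcg <- function(scores, rel) {
  if (min(rel) < 0) rel <- rel - min(rel)
  gain <- 2^rel - 1
  ord <- order(scores, decreasing = TRUE)
  dcg <- sum(gain[ord] / log2(1 + seq_along(scores)))
  idcg <- sum(sort(gain, decreasing = TRUE) / log2(1 + seq_along(scores)))
  if (idcg == 0) return(1)
  dcg / idcg
}
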