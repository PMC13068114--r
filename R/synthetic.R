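# Synthetic protein-ligand complexes with an additive pairwise oracle
# potential. Labels have exactly the sum-of-atomic-contributions structure
# the model assumes, so parameter recovery is testable without any downloads.

#' Specification for the synthetic complex generator
#'
#' The generator emulates the aspects of real complexes the model consumes:
#' an atomic point cloud with element types, a protein/ligand partition, an
#' interface with cross-molecule contacts inside the edge cutoff, and labels
#' produced by a known additive pairwise potential on a pK-like scale.
#'
#' @param n_complexes Number of complexes.
#' @param protein_residues Length-2 range of residues per protein.
#' @param atoms_per_residue Length-2 range of heavy atoms per residue.
#' @param ligand_atoms Length-2 range of ligand heavy atoms.
#' @param elements Element alphabet for atom sampling.
#' @param element_probs Sampling weights (default mimics organic composition).
#' @param interface_distance Maximum allowed minimum protein-ligand heavy-atom
#'   distance, Angstrom; must not exceed the edge cutoff so cross edges exist.
#' @param clash_distance Minimum allowed cross-molecule distance, Angstrom.
#' @param interaction_range Cutoff of the oracle pairwise potential, Angstrom.
#' @param r0 Equilibrium distance of the oracle potential, Angstrom.
#' @param well_depths Named per-element well depths; pair depths combine as
#'   the geometric mean.
#' @param noise_sd Gaussian label noise, pK units.
#' @param label_center,label_scale Affine map from (negated) oracle energy to
#'   the pK-like label scale.
#' @param seed Base seed; each complex is deterministic given (seed, index).
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_complexes = 500L,
                           protein_residues = c(5L, 8L),
                           atoms_per_residue = c(3L, 4L),
                           ligand_atoms = c(4L, 6L),
                           elements = c("C", "N", "O", "S"),
                           element_probs = c(0.6, 0.17, 0.17, 0.06),
                           interface_distance = 4.0,
                           clash_distance = 3.0,
                           interaction_range = 5.0,
                           r0 = 3.6,
                           well_depths = c(C = 1.0, N = 1.3, O = 1.6, S = 2.0),
                           noise_sd = 0.3,
                           label_center = 4.0,
                           label_scale = 0.9,
                           seed = 1L) {
  stopifnot(n_complexes >= 1, length(protein_residues) == 2,
            length(atoms_per_residue) == 2, length(ligand_atoms) == 2,
            interface_distance > clash_distance, noise_sd >= 0,
            all(elements %in% names(well_depths)),
            length(element_probs) == length(elements))
  structure(list(n_complexes = as.integer(n_complexes),
                 protein_residues = as.integer(protein_residues),
                 atoms_per_residue = as.integer(atoms_per_residue),
                 ligand_atoms = as.integer(ligand_atoms),
                 elements = elements,
                 element_probs = element_probs / sum(element_probs),
                 interface_distance = interface_distance,
                 clash_distance = clash_distance,
                 interaction_range = interaction_range,
                 r0 = r0, well_depths = well_depths,
                 noise_sd = noise_sd,
                 label_center = label_center, label_scale = label_scale,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate one synthetic complex
#'
#' The protein is a random self-avoiding chain of residue clusters (centers
#' ~4.5-5.5 Angstrom apart, atoms scattered around each center); the ligand
#' is a compact atom cluster placed off a randomly chosen surface residue so
#' that the minimum protein-ligand distance lies in
#' `[clash_distance, interface_distance]`. Deterministic per `(seed, index)`.
#'
#' @param spec A [synthetic_spec()].
#' @param index Complex index (1-based), part of the RNG stream key.
#' @return A [molecular_structure()].
#' @export
generate_complex <- function(spec, index) {
  stopifnot(inherits(spec, "synthetic_spec"), index >= 1)
  with_seed(spec$seed * 100003 + index, .generate_complex_impl(spec))
}

# draw one integer uniformly from [lo, hi] (robust to lo == hi, where
# sample(lo:hi, 1) would sample from 1:lo instead)
sample_range <- function(range) {
  range[1] + sample.int(range[2] - range[1] + 1L, 1L) - 1L
}

.generate_complex_impl <- function(spec) {
  n_res <- sample_range(spec$protein_residues)
  centers <- matrix(0, n_res, 3)
  for (r in seq_len(n_res)[-1]) {
    placed <- FALSE
    for (try in 1:50) {
      dir <- stats::rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      cand <- centers[r - 1, ] + dir * stats::runif(1, 4.5, 5.5)
      if (min(sqrt(rowSums((centers[seq_len(r - 1), , drop = FALSE] -
                              rep(cand, each = r - 1))^2))) >= 3.8) {
        centers[r, ] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("protein chain placement failed after bounded retries")
  }
  atoms <- list()
  for (r in seq_len(n_res)) {
    k <- sample_range(spec$atoms_per_residue)
    ele <- sample(spec$elements, k, replace = TRUE, prob = spec$element_probs)
    xyz <- rep(centers[r, ], each = k) + matrix(stats::rnorm(3 * k, sd = 1.0), k, 3)
    atoms[[r]] <- data.frame(
      atomic_number = element_to_z(ele), x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      residue_index = r, chain_id = "A", is_ligand = FALSE, element = ele,
      atom_name = paste0(ele, seq_len(k)), residue_name = "RES",
      stringsAsFactors = FALSE)
  }
  prot <- do.call(rbind, atoms)
  prot_xyz <- as.matrix(prot[, c("x", "y", "z")])
  pcen <- colMeans(prot_xyz)

  nl <- sample_range(spec$ligand_atoms)
  for (try in 1:60) {
    anchor <- prot_xyz[sample(nrow(prot_xyz), 1), ]
    outward <- anchor - pcen + stats::rnorm(3, sd = 0.5)
    nrm <- sqrt(sum(outward^2))
    if (nrm < 1e-8) next
    outward <- outward / nrm
    lcen <- anchor + outward * stats::runif(1, 3.8, 4.8)
    lig_xyz <- rep(lcen, each = nl) + matrix(stats::rnorm(3 * nl, sd = 1.0), nl, 3)
    d2 <- outer(rowSums(prot_xyz^2), rowSums(lig_xyz^2), "+") -
      2 * prot_xyz %*% t(lig_xyz)
    dmin <- sqrt(max(min(d2), 0))
    if (dmin >= spec$clash_distance && dmin <= spec$interface_distance) {
      ele <- sample(spec$elements, nl, replace = TRUE, prob = spec$element_probs)
      lig <- data.frame(
        atomic_number = element_to_z(ele),
        x = lig_xyz[, 1], y = lig_xyz[, 2], z = lig_xyz[, 3],
        residue_index = -1L, chain_id = "L", is_ligand = TRUE, element = ele,
        atom_name = paste0(ele, seq_len(nl)), residue_name = "LIG",
        stringsAsFactors = FALSE)
      return(molecular_structure(rbind(prot, lig)))
    }
  }
  stop("ligand placement failed after bounded retries")
}

# oracle pairwise term: truncated + shifted Lennard-Jones-like well
oracle_pair_energy <- function(d, eps, spec) {
  raw <- function(x) eps * ((spec$r0 / x)^12 - 2 * (spec$r0 / x)^6)
  ifelse(d <= spec$interaction_range, raw(d) - raw(spec$interaction_range), 0)
}

#' Oracle binding affinity of a synthetic structure
#'
#' The deterministic part of the label is an affine map of the negated sum of
#' a smooth pairwise well `g(d; elements)` over all cross-molecule heavy-atom
#' pairs within the interaction range -- exactly additive over atoms, so the
#' model class can represent it. Gaussian noise with `spec$noise_sd` is added
#' from the caller's RNG stream when `noise = TRUE`.
#'
#' @param structure A [molecular_structure()].
#' @param spec A [synthetic_spec()].
#' @param noise Add label noise? (default `TRUE`; `FALSE` gives the
#'   deterministic label).
#' @return Scalar label on the pK-like scale.
#' @export
oracle_affinity <- function(structure, spec, noise = TRUE) {
  stopifnot(inherits(structure, "molecular_structure"),
            inherits(spec, "synthetic_spec"))
  per_atom <- oracle_atom_energies(structure, spec)
  raw <- sum(per_atom)
  label <- spec$label_center + spec$label_scale * (-raw)
  if (noise && spec$noise_sd > 0) label <- label + stats::rnorm(1, sd = spec$noise_sd)
  label
}

#' Per-atom oracle interaction energies
#'
#' Splits the oracle cross-molecule pair energies evenly onto the two atoms of
#' each pair, giving the ground-truth analogue of the model's per-atom
#' contributions (their sum is the raw oracle energy).
#'
#' @inheritParams oracle_affinity
#' @return Numeric vector, one value per atom in structure order.
#' @export
oracle_atom_energies <- function(structure, spec) {
  at <- structure$atoms
  np <- structure$n_protein_atoms
  out <- numeric(nrow(at))
  if (np == 0 || structure$n_ligand_atoms == 0) return(out)
  P <- as.matrix(at[!at$is_ligand, c("x", "y", "z")])
  L <- as.matrix(at[at$is_ligand, c("x", "y", "z")])
  D <- sqrt(pmax(outer(rowSums(P^2), rowSums(L^2), "+") - 2 * P %*% t(L), 0))
  eps_p <- spec$well_depths[at$element[!at$is_ligand]]
  eps_l <- spec$well_depths[at$element[at$is_ligand]]
  E <- outer(sqrt(eps_p), sqrt(eps_l)) # geometric-mean combining rule
  G <- oracle_pair_energy(D, E, spec)
  out[seq_len(np)] <- rowSums(G) / 2
  out[np + seq_len(ncol(G))] <- colSums(G) / 2
  out
}

#' Build a labelled synthetic dataset
#'
#' End to end: generate each complex, crop the pocket, build the three radius
#' graphs, and attach the oracle label (noise drawn under a seed disjoint
#' from the geometry stream). Optionally splits into train/validation/test by
#' index.
#'
#' @param spec A [synthetic_spec()].
#' @param cutoff Radius-edge cutoff passed to [build_graphs()].
#' @param split Optional integer vector `c(train, val, test)` summing to at
#'   most `spec$n_complexes`.
#' @return If `split` is `NULL`, a list of items, each
#'   `list(graphs, label, structure, index)`; otherwise a list with elements
#'   `train`, `val`, `test` of such items.
#' @export
make_dataset <- function(spec, cutoff = 5.0, split = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  items <- vector("list", spec$n_complexes)
  for (idx in seq_len(spec$n_complexes)) {
    st <- generate_complex(spec, idx)
    st <- crop_pocket(st)
    label <- with_seed(spec$seed * 100003 + idx + 500000000,
                       oracle_affinity(st, spec, noise = TRUE))
    items[[idx]] <- list(graphs = build_graphs(st, cutoff = cutoff),
                         label = label, structure = st, index = idx)
  }
  if (is.null(split)) return(items)
  stopifnot(length(split) == 3, sum(split) <= spec$n_complexes)
  list(train = items[seq_len(split[1])],
       val = items[split[1] + seq_len(split[2])],
       test = items[split[1] + split[2] + seq_len(split[3])])
}

#' Write a synthetic complex as PDB + SDF files
#'
#' Exports the protein atoms as a PDB file and the ligand as an SDF file so
#' the file-parsing path can be exercised on generated data.
#'
#' @param structure A [molecular_structure()].
#' @param dir Output directory (created if needed).
#' @param name Base file name.
#' @return Invisibly, the two file paths (`protein`, `ligand`).
#' @export
write_complex_files <- function(structure, dir, name = "complex") {
  stopifnot(inherits(structure, "molecular_structure"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  at <- structure$atoms
  prot <- at[!at$is_ligand, , drop = FALSE]
  lig <- at[at$is_ligand, , drop = FALSE]
  pdb_path <- file.path(dir, paste0(name, ".pdb"))
  sdf_path <- file.path(dir, paste0(name, ".sdf"))
  bio3d::write.pdb(file = pdb_path,
                   xyz = as.numeric(t(as.matrix(prot[, c("x", "y", "z")]))),
                   resno = prot$residue_index,
                   chain = prot$chain_id,
                   resid = prot$residue_name,
                   eleno = seq_len(nrow(prot)),
                   elety = make.unique(prot$atom_name, sep = ""),
                   elesy = prot$element,
                   o = rep(1, nrow(prot)), b = rep(0, nrow(prot)))
  nl <- nrow(lig)
  bonds <- if (nl >= 2) # chain bonds keep the file valid for standard readers
    sprintf("%3d%3d  1  0", seq_len(nl - 1), 2:nl) else character(0)
  writeLines(c(
    name, "  potentialbind synthetic", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", nl, length(bonds)),
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            lig$x, lig$y, lig$z, lig$element),
    bonds, "M  END", "$$$$"), sdf_path)
  invisible(c(protein = pdb_path, ligand = sdf_path))
}
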