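# Structure input: parsing protein/ligand files, pocket cropping, and the
# three atomic radius graphs (complex, protein, ligand).

#' Construct a molecular structure
#'
#' A `molecular_structure` is an ordered table of heavy atoms with a
#' protein/ligand partition. Protein atoms always come first, in file order,
#' followed by ligand atoms; this node-order contract is relied upon by
#' [build_graphs()] and [predict_affinity()].
#'
#' @param atoms data.frame with columns `atomic_number` (integer, >= 1, no
#'   hydrogens), `x`, `y`, `z` (finite, Angstrom), `residue_index` (integer;
#'   ligand atoms carry the sentinel `-1L`), `chain_id` (character),
#'   `is_ligand` (logical). Optional: `element`, `atom_name`, `residue_name`.
#' @return Object of class `molecular_structure`: the atom table plus
#'   `n_protein_atoms` / `n_ligand_atoms` counts.
#' @export
molecular_structure <- function(atoms) {
  stopifnot(is.data.frame(atoms))
  req <- c("atomic_number", "x", "y", "z", "residue_index", "chain_id", "is_ligand")
  miss <- setdiff(req, names(atoms))
  if (length(miss) > 0)
    stop("atoms table missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(atoms) > 0) {
    if (any(atoms$atomic_number < 1)) stop("atomic numbers must be >= 1")
    if (any(atoms$atomic_number == 1))
      stop("hydrogens must be removed before constructing a molecular_structure")
    if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
      stop("atom coordinates must be finite")
  }
  # enforce the node-order contract: protein block first, then ligand block
  atoms <- rbind(atoms[!atoms$is_ligand, , drop = FALSE],
                 atoms[atoms$is_ligand, , drop = FALSE])
  rownames(atoms) <- NULL
  structure(
    list(atoms = atoms,
         n_protein_atoms = sum(!atoms$is_ligand),
         n_ligand_atoms = sum(atoms$is_ligand)),
    class = "molecular_structure")
}

#' @export
print.molecular_structure <- function(x, ...) {
  cat(sprintf("<molecular_structure> %d protein atoms (%d residues), %d ligand atoms\n",
              x$n_protein_atoms,
              length(unique(x$atoms$residue_index[!x$atoms$is_ligand])),
              x$n_ligand_atoms))
  invisible(x)
}

# coordinates of a structure as an n x 3 matrix
struct_coords <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

.WATER_RESNAMES <- c("HOH", "WAT", "DOD", "H2O", "SOL", "TIP", "TIP3", "TIP4")

#' Parse a protein-ligand complex from structure files
#'
#' Reads a protein PDB file and a ligand SDF or MOL2 file, strips hydrogens
#' and water molecules, resolves alternate-location records to the
#' highest-occupancy conformer, and assembles a [molecular_structure()] with
#' protein atoms first. Metal ions and cofactors present as HETATM records are
#' retained as single-atom residues on the protein side.
#'
#' @param protein_file Path to a PDB file.
#' @param ligand_file Path to an SDF (`.sdf`) or MOL2 (`.mol2`) file.
#' @return A [molecular_structure()].
#' @export
parse_complex <- function(protein_file, ligand_file) {
  if (!file.exists(protein_file)) stop("protein file not found: ", protein_file)
  if (!file.exists(ligand_file)) stop("ligand file not found: ", ligand_file)

  pdb <- tryCatch(bio3d::read.pdb(protein_file, verbose = FALSE),
                  error = function(e) stop("failed to parse PDB file '", protein_file,
                                           "': ", conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  # drop waters
  at <- at[!(toupper(at$resid) %in% .WATER_RESNAMES), , drop = FALSE]
  if (nrow(at) == 0) stop("no non-water atoms in ", protein_file)
  # resolve element symbols; bio3d fills 'elesy' from columns 77-78 or the name
  ele <- toupper(trimws(at$elesy))
  fallback <- is.na(ele) | ele == ""
  if (any(fallback)) ele[fallback] <- toupper(substr(trimws(at$elety[fallback]), 1, 1))
  # drop hydrogens/deuterium
  keep <- !(ele %in% c("H", "D"))
  at <- at[keep, , drop = FALSE]
  ele <- ele[keep]
  # alternate locations: keep the highest-occupancy conformer per atom site
  occ <- at$o
  occ[is.na(occ)] <- 1
  site <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  ord <- order(site, -occ)
  at <- at[ord, , drop = FALSE]
  ele <- ele[ord]
  dup <- duplicated(site[ord])
  at <- at[!dup, , drop = FALSE]
  ele <- ele[!dup]
  # restore file order
  ord2 <- order(at$eleno)
  at <- at[ord2, , drop = FALSE]
  ele <- ele[ord2]

  reskey <- paste(at$chain, at$resno, at$insert, sep = "|")
  prot <- data.frame(
    atomic_number = element_to_z(ele, context = protein_file),
    x = at$x, y = at$y, z = at$z,
    residue_index = match(reskey, unique(reskey)),
    chain_id = ifelse(is.na(at$chain), "A", at$chain),
    is_ligand = FALSE,
    element = ele,
    atom_name = trimws(at$elety),
    residue_name = trimws(at$resid),
    stringsAsFactors = FALSE)

  lig <- parse_ligand(ligand_file)
  if (nrow(lig) == 0)
    stop("ligand has no heavy atoms: ", ligand_file)

  molecular_structure(rbind(prot, lig))
}

# parse an SDF or MOL2 ligand file into the atom-table format (heavy atoms only)
parse_ligand <- function(ligand_file) {
  ext <- tolower(tools::file_ext(ligand_file))
  if (ext == "sdf") {
    lines <- readLines(ligand_file, warn = FALSE)
    if (length(lines) < 5) stop("truncated SDF file: ", ligand_file)
    natoms <- suppressWarnings(as.integer(substr(lines[4], 1, 3)))
    nbonds <- suppressWarnings(as.integer(substr(lines[4], 4, 6)))
    if (is.na(natoms) || natoms < 1)
      stop("cannot read the counts line of SDF file '", ligand_file,
           "' (line 4: '", lines[4], "')")
    if (!is.na(nbonds) && nbonds >= 1) {
      sdfs <- tryCatch(suppressWarnings(ChemmineR::read.SDFset(ligand_file)),
                       error = function(e) stop("failed to parse SDF file '",
                                                ligand_file, "': ",
                                                conditionMessage(e), call. = FALSE))
      if (length(sdfs) < 1) stop("no molecules in SDF file: ", ligand_file)
      ab <- ChemmineR::atomblock(sdfs[[1]])
      if (is.null(ab) || nrow(ab) == 0)
        stop("empty ligand in SDF file: ", ligand_file)
      ele <- toupper(sub("_.*$", "", rownames(ab)))
      xyz <- ab[, 1:3, drop = FALSE]
    } else {
      # bond-free SDF (e.g. single-atom or ion ligands): ChemmineR rejects
      # these, so read the fixed-width V2000 atom block directly
      rows <- lines[4 + seq_len(natoms)]
      xyz <- cbind(as.numeric(substr(rows, 1, 10)),
                   as.numeric(substr(rows, 11, 20)),
                   as.numeric(substr(rows, 21, 30)))
      if (anyNA(xyz))
        stop("malformed atom block in SDF file: ", ligand_file)
      ele <- toupper(trimws(substr(rows, 32, 34)))
    }
  } else if (ext == "mol2") {
    m <- tryCatch(bio3d::read.mol2(ligand_file),
                  error = function(e) stop("failed to parse MOL2 file '", ligand_file,
                                           "': ", conditionMessage(e), call. = FALSE))
    a <- m$atom
    if (is.null(a) || nrow(a) == 0) stop("empty ligand in MOL2 file: ", ligand_file)
    ele <- toupper(sub("\\..*$", "", a$elety))
    xyz <- cbind(a$x, a$y, a$z)
  } else {
    stop("unsupported ligand format '", ext, "' (expected .sdf or .mol2)")
  }
  keep <- !(ele %in% c("H", "D"))
  ele <- ele[keep]
  xyz <- xyz[keep, , drop = FALSE]
  if (length(ele) == 0) return(data.frame())
  data.frame(
    atomic_number = element_to_z(ele, context = ligand_file),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    residue_index = -1L,
    chain_id = "L",
    is_ligand = TRUE,
    element = ele,
    atom_name = paste0(ele, seq_along(ele)),
    residue_name = "LIG",
    stringsAsFactors = FALSE)
}

#' Crop a structure to the binding pocket
#'
#' Retains all ligand atoms plus the heavy atoms of the protein residues
#' closest to the ligand, where residue-ligand distance is the minimum over
#' all (residue heavy atom, ligand heavy atom) pairs. At most `max_residues`
#' residues are kept (all of them if the protein is smaller); ties at the
#' cutoff rank are broken by ascending residue index for determinism.
#'
#' @param structure A [molecular_structure()] with at least one ligand atom.
#' @param max_residues Residue cap for the pocket (default 50).
#' @return The cropped [molecular_structure()].
#' @export
crop_pocket <- function(structure, max_residues = 50L) {
  stopifnot(inherits(structure, "molecular_structure"))
  if (structure$n_ligand_atoms < 1)
    stop("crop_pocket requires at least one ligand atom")
  at <- structure$atoms
  lig_xyz <- as.matrix(at[at$is_ligand, c("x", "y", "z"), drop = FALSE])
  prot <- at[!at$is_ligand, , drop = FALSE]
  if (nrow(prot) == 0) return(structure)
  res_ids <- unique(prot$residue_index)
  if (length(res_ids) <= max_residues) return(structure)
  prot_xyz <- as.matrix(prot[, c("x", "y", "z")])
  # squared distances protein-atoms x ligand-atoms, then min per residue
  d2 <- outer(rowSums(prot_xyz^2), rowSums(lig_xyz^2), "+") -
    2 * prot_xyz %*% t(lig_xyz)
  atom_min <- sqrt(pmax(apply(d2, 1, min), 0))
  res_min <- tapply(atom_min, prot$residue_index, min)
  res_tab <- data.frame(residue_index = as.integer(names(res_min)),
                        dist = as.numeric(res_min))
  res_tab <- res_tab[order(res_tab$dist, res_tab$residue_index), ]
  keep_res <- res_tab$residue_index[seq_len(max_residues)]
  keep <- at$is_ligand | (at$residue_index %in% keep_res)
  molecular_structure(at[keep, , drop = FALSE])
}

#' Radius edges over a point cloud
#'
#' Directed edges `(i, j)` for every ordered pair of distinct atoms within
#' `cutoff` Angstrom. Edge `(i, j)` carries the message from `j` into the
#' neighbourhood of `i`; its relative vector is `r_ij = X[j,] - X[i,]`.
#'
#' @param X n x 3 coordinate matrix.
#' @param cutoff Distance cutoff in Angstrom (> 0).
#' @return List with integer vectors `i`, `j`, numeric `d`, and an
#'   `n_edges` x 3 matrix `r` of relative vectors.
#' @export
radius_edges <- function(X, cutoff) {
  X <- as.matrix(X)
  stopifnot(ncol(X) == 3, nrow(X) >= 1, cutoff > 0)
  n <- nrow(X)
  if (n == 1) {
    return(list(i = integer(0), j = integer(0), d = numeric(0),
                r = matrix(0, 0, 3)))
  }
  D <- as.matrix(stats::dist(X))
  hit <- which(D <= cutoff & upper.tri(D), arr.ind = TRUE)
  # symmetrize: both directions of each unordered pair
  i <- c(hit[, 1], hit[, 2])
  j <- c(hit[, 2], hit[, 1])
  ord <- order(i, j)
  i <- i[ord]; j <- j[ord]
  list(i = as.integer(i), j = as.integer(j),
       d = D[cbind(i, j)],
       r = X[j, , drop = FALSE] - X[i, , drop = FALSE])
}

# internal graph constructor with invariant checks
molecular_graph <- function(z, X, edges, role) {
  stopifnot(role %in% c("complex", "protein", "ligand"))
  g <- structure(
    list(z = as.integer(z), X = as.matrix(X),
         i = edges$i, j = edges$j, d = edges$d, r = edges$r,
         role = role),
    class = "molecular_graph")
  g
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf("<molecular_graph:%s> %d atoms, %d directed edges\n",
              x$role, length(x$z), length(x$i)))
  invisible(x)
}

#' Build the complex, protein, and ligand radius graphs
#'
#' All three graphs share the bound-pose coordinates: the unbound protein and
#' ligand are represented by the same conformation with the partner removed,
#' so their edge sets are exactly the homo-molecular subsets of the complex
#' graph's edges.
#'
#' @param structure A pocket-cropped [molecular_structure()].
#' @param cutoff Radius-edge cutoff in Angstrom (default 5.0).
#' @return Named list of three `molecular_graph` objects: `complex`,
#'   `protein`, `ligand`. Node order in the complex graph is protein atoms
#'   first, then ligand atoms, matching the structure.
#' @export
build_graphs <- function(structure, cutoff = 5.0) {
  stopifnot(inherits(structure, "molecular_structure"))
  at <- structure$atoms
  X <- struct_coords(structure)
  z <- at$atomic_number
  np <- structure$n_protein_atoms
  idx_p <- seq_len(np)
  idx_l <- setdiff(seq_len(nrow(at)), idx_p)
  list(
    complex = molecular_graph(z, X, radius_edges(X, cutoff), "complex"),
    protein = molecular_graph(z[idx_p], X[idx_p, , drop = FALSE],
                              radius_edges(X[idx_p, , drop = FALSE], cutoff),
                              "protein"),
    ligand = molecular_graph(z[idx_l], X[idx_l, , drop = FALSE],
                             radius_edges(X[idx_l, , drop = FALSE], cutoff),
                             "ligand"))
}
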