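# Prediction head: per-atom energies and the unbound-minus-bound affinity.

#' Per-atom energies from node states
#'
#' A pointwise two-layer MLP maps each atom's representation to a scalar
#' energy contribution.
#'
#' @param h n x `hidden_dim` node states from [encode()].
#' @param model An [affinity_model()].
#' @param role Graph role for unshared encoders.
#' @return Numeric vector of length n.
#' @export
atom_energies <- function(h, model, role = "complex") {
  p <- param_set(model, role)
  if (!all(is.finite(h))) stop("non-finite node states")
  drop(add_bias(swish(add_bias(h %*% p$O1, p$bo1)) %*% p$O2, p$bo2))
}

#' Predict binding affinity with per-atom contributions
#'
#' For each frame of each graph the encoder and energy head produce per-atom
#' energies; the frame affinity is the unbound-minus-bound difference
#' `(E_protein + E_ligand) - E_complex`, and the reported affinity is the
#' frame average. Per-atom contributions are the frame-averaged unbound
#' energy minus bound energy of each atom (complex-graph ordering), so the
#' scalar affinity always equals their sum. With
#' `difference_head = FALSE` in the model config (framework-off ablation),
#' the affinity is the frame-averaged complex-graph energy sum and the
#' contributions are the bound energies themselves.
#'
#' @param model An [affinity_model()].
#' @param complex_g,protein_g,ligand_g The three graphs from [build_graphs()]
#'   for one structure (consistent node ordering: protein atoms first).
#' @return Object of class `affinity_prediction` with fields `affinity`
#'   (scalar, pK units), `per_frame_affinities`, `atom_contributions`
#'   (length n, complex ordering), and the frame-averaged per-atom energies
#'   of each graph (`energies_complex`, `energies_protein`,
#'   `energies_ligand`).
#' @export
predict_affinity <- function(model, complex_g, protein_g, ligand_g) {
  stopifnot(inherits(model, "affinity_model"))
  np <- length(protein_g$z)
  nl <- length(ligand_g$z)
  n <- length(complex_g$z)
  if (n != np + nl)
    stop("node-count mismatch: complex graph has ", n,
         " atoms but protein + ligand have ", np + nl)
  if (!identical(complex_g$z, c(protein_g$z, ligand_g$z)))
    stop("node-order mismatch: complex graph must list protein atoms first, then ligand")
  sym <- model$config$symmetry
  fs <- list(complex = compute_frames(complex_g$X, sym),
             protein = compute_frames(protein_g$X, sym),
             ligand = compute_frames(ligand_g$X, sym))
  nf <- length(fs$complex$frames)
  graphs <- list(complex = complex_g, protein = protein_g, ligand = ligand_g)
  roles <- if (model$config$difference_head) c("complex", "protein", "ligand")
           else "complex"
  energies <- list()
  for (role in roles) {
    g <- graphs[[role]]
    per_frame <- matrix(0, length(g$z), nf)
    for (k in seq_len(nf)) {
      h <- encode(g, model, frame = fs[[role]]$frames[[k]])
      per_frame[, k] <- atom_energies(h, model, role = role)
    }
    energies[[role]] <- per_frame
  }
  if (model$config$difference_head) {
    unbound <- rbind(energies$protein, energies$ligand) # complex node order
    per_frame_aff <- colSums(unbound) - colSums(energies$complex)
    contrib <- rowMeans(unbound - energies$complex)
    e_p <- rowMeans(energies$protein)
    e_l <- rowMeans(energies$ligand)
  } else {
    per_frame_aff <- colSums(energies$complex)
    contrib <- rowMeans(energies$complex)
    e_p <- contrib[seq_len(np)]
    e_l <- if (nl > 0) contrib[np + seq_len(nl)] else numeric(0)
  }
  structure(
    list(affinity = frame_average(per_frame_aff),
         per_frame_affinities = as.numeric(per_frame_aff),
         atom_contributions = as.numeric(contrib),
         energies_complex = rowMeans(energies$complex),
         energies_protein = as.numeric(e_p),
         energies_ligand = as.numeric(e_l),
         n_protein_atoms = np, n_ligand_atoms = nl),
    class = "affinity_prediction")
}

#' @export
print.affinity_prediction <- function(x, ...) {
  cat(sprintf("<affinity_prediction> affinity = %.4f pK over %d frames (%d atoms)\n",
              x$affinity, length(x$per_frame_affinities),
              length(x$atom_contributions)))
  invisible(x)
}
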