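# Atomic encoder: element embedding, RBF/direction edge embedding, and the
# residual message-passing layers with an enhanced convolution filter. One
# shared encoder processes the complex, protein and ligand graphs.

#' Encoder configuration
#'
#' @param hidden_dim Width of node/edge representations (default 128).
#' @param n_layers Number of message-passing layers (default 4).
#' @param n_rbf Number of Gaussian radial basis functions for distances
#'   (default 32; centers uniform on `[0, cutoff]`, width = center spacing).
#' @param cutoff Radius-edge cutoff in Angstrom (default 5.0); also the upper
#'   end of the RBF grid.
#' @param max_z Largest atomic number in the embedding table (default 100).
#' @param shared_weights If `TRUE` (default) one parameter set serves all
#'   three graphs; `FALSE` gives complex/protein/ligand their own encoders.
#' @param symmetry Frame group: `"se3"` (default), `"e3"`, or `"none"`.
#' @param difference_head If `TRUE` (default) the affinity is the unbound
#'   minus bound energy difference; `FALSE` regresses from the complex-graph
#'   energy sum alone (framework-off ablation).
#' @param precision Element type of the compiled compute kernels: `"single"`
#'   (default; the standard for this model class -- parameters and optimizer
#'   state remain double precision) or `"double"` (exact agreement with the
#'   reference R path, used by the verification tests).
#' @return Object of class `encoder_config`.
#' @export
encoder_config <- function(hidden_dim = 128L, n_layers = 4L, n_rbf = 32L,
                           cutoff = 5.0, max_z = 100L, shared_weights = TRUE,
                           symmetry = c("se3", "e3", "none"),
                           difference_head = TRUE,
                           precision = c("single", "double")) {
  symmetry <- match.arg(symmetry)
  precision <- match.arg(precision)
  stopifnot(hidden_dim >= 1, n_layers >= 1, n_rbf >= 2, cutoff > 0, max_z >= 92)
  structure(list(hidden_dim = as.integer(hidden_dim),
                 n_layers = as.integer(n_layers),
                 n_rbf = as.integer(n_rbf),
                 cutoff = cutoff, max_z = as.integer(max_z),
                 shared_weights = isTRUE(shared_weights),
                 symmetry = symmetry,
                 difference_head = isTRUE(difference_head),
                 precision = precision),
            class = "encoder_config")
}

# one full parameter set (embedding + edge MLP + layers + output head)
init_param_set <- function(config) {
  H <- config$hidden_dim
  nin <- config$n_rbf + 3L
  lin <- function(fi, fo) matrix(stats::rnorm(fi * fo, sd = sqrt(2 / fi)), fi, fo)
  p <- list(
    emb = matrix(stats::rnorm(config$max_z * H, sd = 1 / sqrt(H)), config$max_z, H),
    We1 = lin(nin, H), be1 = numeric(H),
    We2 = lin(H, H), be2 = numeric(H),
    O1 = lin(H, H), bo1 = numeric(H),
    O2 = lin(H, 1), bo2 = numeric(1))
  for (l in seq_len(config$n_layers)) {
    p[[paste0("F1e_", l)]] <- lin(H, H)
    p[[paste0("F1i_", l)]] <- lin(H, H)
    p[[paste0("F1j_", l)]] <- lin(H, H)
    p[[paste0("bf1_", l)]] <- numeric(H)
    p[[paste0("F2_", l)]] <- lin(H, H)
    p[[paste0("bf2_", l)]] <- numeric(H)
    p[[paste0("U1_", l)]] <- lin(H, H)
    p[[paste0("bu1_", l)]] <- numeric(H)
    p[[paste0("U2_", l)]] <- lin(H, H)
    p[[paste0("bu2_", l)]] <- numeric(H)
  }
  p
}

#' Initialize a model
#'
#' Draws all encoder and head parameters under a fixed seed. With
#' `shared_weights = FALSE` three independent parameter sets are created,
#' keyed by graph role.
#'
#' @param config An [encoder_config()].
#' @param seed Integer seed for the parameter draw.
#' @return Object of class `affinity_model`: `config` plus `params` (one
#'   parameter set, or a list of three when unshared).
#' @export
affinity_model <- function(config = encoder_config(), seed = 1L) {
  stopifnot(inherits(config, "encoder_config"))
  with_seed(seed, {
    params <- if (config$shared_weights) init_param_set(config)
              else list(complex = init_param_set(config),
                        protein = init_param_set(config),
                        ligand = init_param_set(config))
    structure(list(config = config, params = params, seed = as.integer(seed),
                   version = as.character(utils::packageVersion("potentialbind"))),
              class = "affinity_model")
  })
}

#' @export
print.affinity_model <- function(x, ...) {
  cfg <- x$config
  np <- function(p) sum(vapply(p, length, 1L))
  n <- if (cfg$shared_weights) np(x$params) else sum(vapply(x$params, np, 1L))
  cat(sprintf(
    "<affinity_model> hidden=%d layers=%d rbf=%d cutoff=%.1fA %s %s head, %s params: %s\n",
    cfg$hidden_dim, cfg$n_layers, cfg$n_rbf, cfg$cutoff, toupper(cfg$symmetry),
    if (cfg$difference_head) "difference" else "complex-only",
    if (cfg$shared_weights) "shared" else "per-role", format(n, big.mark = ",")))
  invisible(x)
}

# parameter set serving a given graph role
param_set <- function(model, role) {
  if (model$config$shared_weights) model$params else model$params[[role]]
}

#' Gaussian radial basis expansion of distances
#'
#' Centers are uniform on `[0, cutoff]` and the Gaussian width equals the
#' center spacing, so an edge at `d = cutoff` activates the last basis most
#' strongly.
#'
#' @param d Numeric vector of distances.
#' @param n_rbf Number of basis functions.
#' @param cutoff Upper end of the center grid.
#' @return `length(d)` x `n_rbf` matrix of basis activations.
#' @export
rbf_expand <- function(d, n_rbf, cutoff) {
  centers <- seq(0, cutoff, length.out = n_rbf)
  w <- centers[2] - centers[1]
  exp(-(outer(d, centers, "-"))^2 / (2 * w^2))
}

#' Embed atomic numbers
#'
#' Lookup-table embedding: every atom of the same element gets the same
#' initial `hidden_dim`-dimensional representation.
#'
#' @param z Integer vector of atomic numbers.
#' @param model An [affinity_model()] (its shared or complex-role table is used).
#' @return `length(z)` x `hidden_dim` matrix.
#' @export
embed_nodes <- function(z, model) {
  p <- param_set(model, "complex")
  if (any(z < 1) || any(z > nrow(p$emb)))
    stop("atomic number out of embedding-table range [1, ", nrow(p$emb), "]")
  p$emb[z, , drop = FALSE]
}

#' Embed edges from distances and relative vectors
#'
#' Concatenates the Gaussian RBF expansion of each distance with the
#' unit-normalized relative vector and maps the result through a one-hidden-
#' layer MLP with swish activations to a `hidden_dim`-dimensional edge
#' feature.
#'
#' @param d Edge distances (> 0).
#' @param r n_edges x 3 relative vectors (non-zero).
#' @param model An [affinity_model()].
#' @param role Graph role whose parameter set to use (matters only for
#'   unshared encoders).
#' @return n_edges x `hidden_dim` matrix of edge features.
#' @export
embed_edges <- function(d, r, model, role = "complex") {
  r <- as.matrix(r)
  if (length(d) == 0) return(matrix(0, 0, model$config$hidden_dim))
  if (any(d <= 0)) stop("edge distances must be positive")
  nrm <- sqrt(rowSums(r^2))
  if (any(nrm == 0)) stop("zero-length relative vector on an edge")
  p <- param_set(model, role)
  x <- cbind(rbf_expand(d, model$config$n_rbf, model$config$cutoff), r / nrm)
  swish(add_bias(swish(add_bias(x %*% p$We1, p$be1)) %*% p$We2, p$be2))
}

#' One message-passing layer
#'
#' For each directed edge `(i, j)` a filter
#' `f_ij = swish(MLP(e_ij || h_i || h_j))` gates the neighbour state, and the
#' node update is residual:
#' `h_i <- h_i + MLP(sum_j h_j * f_ij)`. Only node states change; edge
#' features are left untouched.
#'
#' @param h n x `hidden_dim` node states.
#' @param e n_edges x `hidden_dim` edge features.
#' @param edges List with integer vectors `i` (receiver) and `j` (sender).
#' @param model An [affinity_model()].
#' @param layer Layer index (selects the layer's parameters).
#' @param role Graph role for unshared encoders.
#' @return Updated n x `hidden_dim` node states.
#' @export
message_layer <- function(h, e, edges, model, layer = 1L, role = "complex") {
  p <- param_set(model, role)
  l <- layer
  n <- nrow(h)
  m <- matrix(0, n, ncol(h))
  if (length(edges$i) > 0) {
    pre1 <- add_bias(e %*% p[[paste0("F1e_", l)]] +
                       (h %*% p[[paste0("F1i_", l)]])[edges$i, , drop = FALSE] +
                       (h %*% p[[paste0("F1j_", l)]])[edges$j, , drop = FALSE],
                     p[[paste0("bf1_", l)]])
    f <- swish(add_bias(swish(pre1) %*% p[[paste0("F2_", l)]], p[[paste0("bf2_", l)]]))
    m <- scatter_sum(h[edges$j, , drop = FALSE] * f, edges$i, n)
  }
  h + add_bias(swish(add_bias(m %*% p[[paste0("U1_", l)]], p[[paste0("bu1_", l)]])) %*%
                 p[[paste0("U2_", l)]], p[[paste0("bu2_", l)]])
}

#' Encode a molecular graph into per-atom representations
#'
#' Embeds atomic numbers, embeds edges once (directions taken in the given
#' frame, so coordinates enter only through distances and unit relative
#' vectors), and applies the configured number of message-passing layers.
#'
#' @param graph A `molecular_graph` from [build_graphs()].
#' @param model An [affinity_model()].
#' @param frame Optional single frame `list(R, t)`; when supplied, edge
#'   directions are rotated into that frame. `NULL` uses raw directions.
#' @return n x `hidden_dim` matrix of final atom states.
#' @export
encode <- function(graph, model, frame = NULL) {
  stopifnot(inherits(graph, "molecular_graph"))
  role <- graph$role
  h <- if (model$config$shared_weights) embed_nodes(graph$z, model) else {
    p <- param_set(model, role)
    if (any(graph$z < 1) || any(graph$z > nrow(p$emb)))
      stop("atomic number out of embedding-table range")
    p$emb[graph$z, , drop = FALSE]
  }
  r <- graph$r
  if (!is.null(frame)) r <- r %*% frame$R
  e <- embed_edges(graph$d, r, model, role = role)
  edges <- list(i = graph$i, j = graph$j)
  for (l in seq_len(model$config$n_layers))
    h <- message_layer(h, e, edges, model, layer = l, role = role)
  h
}
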