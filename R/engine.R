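# Internal training engine glue. Graphs are packed once into disjoint unions
# over (complex x role x frame) with fixed edge inputs (RBF expansion and
# frame-projected unit directions), so a minibatch is a cheap concatenation
# and the compiled kernels in src/engine.cpp do all heavy numerical work.

# Precompute everything about one dataset item that does not depend on the
# model parameters.
pack_item <- function(item, config) {
  roles <- if (config$difference_head) c("complex", "protein", "ligand") else "complex"
  graphs <- item$graphs
  packs <- list()
  for (role in roles) {
    g <- graphs[[role]]
    fr <- compute_frames(g$X, config$symmetry)
    nf <- length(fr$frames)
    n <- length(g$z); ne <- length(g$i)
    rbf <- rbf_expand(g$d, config$n_rbf, config$cutoff)
    runit <- if (ne > 0) g$r / sqrt(rowSums(g$r^2)) else matrix(0, 0, 3)
    xe <- matrix(0, ne * nf, config$n_rbf + 3L)
    src <- integer(ne * nf); dst <- integer(ne * nf)
    for (f in seq_len(nf)) {
      rows <- (f - 1L) * ne + seq_len(ne)
      if (ne > 0) {
        xe[rows, ] <- cbind(rbf, runit %*% fr$frames[[f]]$R)
        src[rows] <- g$j + (f - 1L) * n
        dst[rows] <- g$i + (f - 1L) * n
      }
    }
    packs[[role]] <- list(z = rep(g$z, nf), src = src, dst = dst, xe = xe,
                          n = n * nf, ne = ne * nf,
                          seg = rep(seq_len(nf), each = n), nseg = nf)
  }
  list(roles = packs, nf = packs[[1]]$nseg, label = item$label)
}

# Concatenate item packs into one disjoint batch per parameter set. With a
# shared encoder all roles go into a single pack; unshared encoders get one
# pack per role.
assemble_batch <- function(item_packs, config) {
  roles <- if (config$difference_head) c("complex", "protein", "ligand") else "complex"
  sign_of <- if (config$difference_head)
    c(complex = -1, protein = 1, ligand = 1) else c(complex = 1)
  groups <- if (config$shared_weights) list(all = roles) else
    stats::setNames(as.list(roles), roles)
  out <- list()
  for (gname in names(groups)) {
    grp <- groups[[gname]]
    zs <- list(); srcs <- list(); dsts <- list(); xes <- list()
    segs <- list(); seg_item <- list(); seg_sign <- list()
    noff <- 0L; soff <- 0L
    for (b in seq_along(item_packs)) {
      for (role in grp) {
        p <- item_packs[[b]]$roles[[role]]
        k <- length(zs) + 1L
        zs[[k]] <- p$z
        srcs[[k]] <- p$src + noff
        dsts[[k]] <- p$dst + noff
        xes[[k]] <- p$xe
        segs[[k]] <- p$seg + soff
        seg_item[[k]] <- rep(b, p$nseg)
        seg_sign[[k]] <- rep(sign_of[[role]], p$nseg)
        noff <- noff + p$n
        soff <- soff + p$nseg
      }
    }
    out[[gname]] <- list(z = unlist(zs, use.names = FALSE),
                         src = unlist(srcs, use.names = FALSE),
                         dst = unlist(dsts, use.names = FALSE),
                         xe = do.call(rbind, xes),
                         seg = unlist(segs, use.names = FALSE),
                         seg_item = unlist(seg_item, use.names = FALSE),
                         seg_sign = unlist(seg_sign, use.names = FALSE),
                         nseg = soff, n = noff)
  }
  out
}

# parameter sets in the order of the batch's packs
param_sets_for <- function(model, batch) {
  if (model$config$shared_weights) list(model$params)
  else unname(model$params[names(batch)])
}

# forward-only predictions for an assembled batch
batch_predict <- function(model, batch, n_items, nf) {
  list(preds = .eng_predict(param_sets_for(model, batch), unname(batch),
                            n_items, nf, model$config$n_layers,
                            identical(model$config$precision, "single")))
}

# fused forward + loss + backward; grads come back parallel to the batch's
# packs (length 1 for a shared encoder, else one per role)
batch_train_step <- function(model, batch, y, nf, log_sigma2, lstate) {
  .eng_train_step(param_sets_for(model, batch), unname(batch),
                  length(y), nf, model$config$n_layers,
                  y, log_sigma2, lstate$alpha, lstate$ndcg_temperature,
                  identical(model$config$precision, "single"))
}

# squared Euclidean norm of a (possibly nested) gradient list
grad_sq_norm <- function(grads) {
  if (is.list(grads)) return(sum(vapply(grads, grad_sq_norm, 0)))
  sum(grads^2)
}

# ---- AdamW over (possibly nested) lists of numeric arrays ----

adam_init <- function(params) {
  if (is.list(params)) return(lapply(params, adam_init))
  list(m = params * 0, v = params * 0)
}

# returns list(params, state); weight decay applies to weight matrices only
adam_step <- function(params, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0, decay_this = NA) {
  if (is.list(params) && !identical(names(state), c("m", "v"))) {
    for (k in names(params)) {
      dec <- if (is.na(decay_this)) is.matrix(params[[k]]) && k != "emb" else decay_this
      r <- adam_step(params[[k]], grads[[k]], state[[k]], lr, t, beta1, beta2,
                     eps, weight_decay, if (is.list(params[[k]])) NA else dec)
      params[[k]] <- r$params
      state[[k]] <- r$state
    }
    return(list(params = params, state = state))
  }
  if (!is.matrix(params)) grads <- as.numeric(grads)
  state$m <- beta1 * state$m + (1 - beta1) * grads
  state$v <- beta2 * state$v + (1 - beta2) * grads^2
  mhat <- state$m / (1 - beta1^t)
  vhat <- state$v / (1 - beta2^t)
  upd <- mhat / (sqrt(vhat) + eps)
  if (isTRUE(decay_this) && weight_decay > 0) upd <- upd + weight_decay * params
  list(params = params - lr * upd, state = state)
}
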