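# Training losses: Balanced MSE for skewed affinity labels, a smooth
# approximate-NDCG ranking term with exponential amplification, and their sum.

#' Loss-state container
#'
#' @param alpha Amplification of the ranking loss (>= 0, default 1).
#' @param ndcg_temperature Temperature of the sigmoid rank approximation, in
#'   label units (default 1; smaller is closer to the exact NDCG).
#' @param sigma_init Initial noise standard deviation of the balanced MSE
#'   (default 1). Internally the noise variance is stored as `log(sigma^2)`
#'   and exponentiated, keeping it positive while it is learned jointly with
#'   the model.
#' @return Object of class `loss_state` with fields `alpha`,
#'   `ndcg_temperature`, `log_sigma2`.
#' @export
loss_state <- function(alpha = 1.0, ndcg_temperature = 1.0, sigma_init = 1.0) {
  stopifnot(alpha >= 0, ndcg_temperature > 0, sigma_init > 0)
  structure(list(alpha = alpha, ndcg_temperature = ndcg_temperature,
                 log_sigma2 = 2 * log(sigma_init)),
            class = "loss_state")
}

#' Balanced mean-squared-error loss
#'
#' Negative log-likelihood of each label under a Gaussian centered at the
#' prediction, renormalized over the training label distribution; the
#' normalizing integral is estimated with the batch labels as the empirical
#' training distribution, giving a per-item log-softmax
#' `-log[ exp(-(p_i - y_i)^2 / 2 sigma^2) / sum_k exp(-(p_i - y_k)^2 / 2 sigma^2) ]`,
#' averaged over the batch. Unlike plain MSE, rare labels are not swamped by
#' the dense center of the label distribution.
#'
#' @param y_pred,y_true Numeric vectors of equal length (batch).
#' @param sigma_noise Noise standard deviation (> 0).
#' @return Scalar loss (0 for a batch of size 1).
#' @export
balanced_mse <- function(y_pred, y_true, sigma_noise = 1.0) {
  stopifnot(length(y_pred) == length(y_true), length(y_pred) >= 1)
  if (sigma_noise <= 0) stop("sigma_noise must be positive")
  .bme_grad(y_pred, y_true, 2 * log(sigma_noise))$value
}

# value + gradients wrt predictions and log(sigma^2)
.bme_grad <- function(p, y, log_sigma2) {
  B <- length(p)
  s2 <- exp(log_sigma2)
  A <- -(outer(p, y, "-"))^2 / (2 * s2) # A[i, k]
  mx <- apply(A, 1, max)
  lse <- mx + log(rowSums(exp(A - mx)))
  value <- mean(lse - diag(A))
  P <- exp(A - lse) # row softmax
  W <- P - diag(B) # dloss_i / dA[i, k], up to 1/B
  dA_dp <- -(outer(p, y, "-")) / s2
  dpred <- rowSums(W * dA_dp) / B
  dlog <- sum(W * (-A)) / B
  list(value = value, dpred = dpred, dlog_sigma2 = dlog)
}

#' Smooth approximate NDCG
#'
#' Normalized discounted cumulative gain with sigmoid-approximated ranks:
#' the rank of item `i` is `1 + sum_{j != i} sigmoid((s_j - s_i) / tau)`,
#' gains are `2^rel - 1` (relevances min-shifted to be non-negative), and
#' discounts `1 / log2(1 + rank)`. As `tau -> 0` this approaches the exact
#' NDCG of the score ordering. If all relevances are equal, any order is
#' ideal and 1 is returned.
#'
#' @param scores Predicted scores (length >= 2).
#' @param relevances Ground-truth labels.
#' @param temperature Sigmoid temperature `tau` (> 0).
#' @return Scalar in (0, 1] (up to smoothing error).
#' @export
approx_ndcg <- function(scores, relevances, temperature = 1.0) {
  stopifnot(length(scores) == length(relevances), length(scores) >= 2,
            temperature > 0)
  .ndcg_grad(scores, relevances, temperature)$value
}

# value + gradient wrt scores
.ndcg_grad <- function(s, rel, tau) {
  n <- length(s)
  # all-equal relevances: any ordering is ideal
  if (max(rel) == min(rel)) return(list(value = 1, dscores = numeric(n)))
  if (min(rel) < 0) rel <- rel - min(rel)
  gain <- 2^rel - 1
  idcg <- sum(sort(gain, decreasing = TRUE) / log2(1 + seq_len(n)))
  if (idcg == 0) return(list(value = 1, dscores = numeric(n)))
  Dif <- outer(s, s, "-") / tau # Dif[i, j] = (s_i - s_j)/tau
  Sg <- sigmoid(-Dif) # sigmoid((s_j - s_i)/tau)
  diag(Sg) <- 0
  ranks <- 1 + rowSums(Sg)
  dcg_terms <- gain / log2(1 + ranks)
  value <- sum(dcg_terms) / idcg
  # d value / d rank_i
  dv_drank <- -gain * log(2) / ((1 + ranks) * (log(1 + ranks))^2) / idcg
  Sgp <- Sg * (1 - Sg) / tau # derivative of sigmoid((s_j - s_i)/tau)
  # rank_i depends on s_i (negatively) and each s_j (positively)
  dscores <- -dv_drank * rowSums(Sgp) + colSums(dv_drank * Sgp)
  list(value = value, dscores = dscores)
}

#' Exponentially amplified ranking loss
#'
#' `exp(alpha * (1 - ndcg)) - 1 - alpha * (1 - ndcg)`: zero iff the ranking
#' is perfect (or `alpha = 0`), non-negative, convex, and increasingly steep
#' as the ranking quality drops.
#'
#' @param ndcg NDCG value in `[0, 1]`.
#' @param alpha Amplification (>= 0).
#' @return Scalar loss.
#' @export
rank_loss <- function(ndcg, alpha = 1.0) {
  stopifnot(alpha >= 0)
  if (ndcg < -1e-8 || ndcg > 1 + 1e-8) stop("ndcg must lie in [0, 1]")
  u <- alpha * (1 - min(max(ndcg, 0), 1))
  exp(u) - 1 - u
}

#' Total training loss
#'
#' Sum of the balanced MSE and the amplified ranking loss on the batch. For a
#' batch of size 1 the ranking term is undefined and contributes 0.
#'
#' @param y_pred,y_true Numeric vectors of equal length.
#' @param state A [loss_state()].
#' @return Scalar loss.
#' @export
total_loss <- function(y_pred, y_true, state = loss_state()) {
  stopifnot(inherits(state, "loss_state"))
  .total_grad(y_pred, y_true, state)$value
}

# value + gradients of the total loss wrt predictions and log(sigma^2)
.total_grad <- function(p, y, state) {
  bme <- .bme_grad(p, y, state$log_sigma2)
  if (length(p) >= 2 && state$alpha > 0) {
    nd <- .ndcg_grad(p, y, state$ndcg_temperature)
    u <- state$alpha * (1 - min(max(nd$value, 0), 1))
    rloss <- exp(u) - 1 - u
    drank_dndcg <- state$alpha * (1 - exp(u))
    list(value = bme$value + rloss,
         dpred = bme$dpred + drank_dndcg * nd$dscores,
         dlog_sigma2 = bme$dlog_sigma2)
  } else {
    list(value = bme$value, dpred = bme$dpred, dlog_sigma2 = bme$dlog_sigma2)
  }
}
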