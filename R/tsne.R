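# t-SNE for visualising the sketched feature space. The embedding is
# computed with exact pairwise affinities and gradients (no tree
# approximation), which is the appropriate regime for sketch-sized inputs;
# the `theta` argument is accepted for interface compatibility and the
# exact computation corresponds to its theta -> 0 limit.

# per-point Gaussian bandwidths by bisection on perplexity
tsne_input_p <- function(D2, perplexity) {
  n <- nrow(D2)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; betamin <- -Inf; betamax <- Inf
    Di <- D2[i, -i]
    for (iter in 1:50) {
      Pi <- exp(-Di * beta)
      sumP <- sum(Pi)
      if (sumP == 0) { Pi <- rep(1 / length(Di), length(Di)); sumP <- 1 }
      H <- log(sumP) + beta * sum(Di * Pi) / sumP
      if (abs(H - logU) < 1e-5) break
      if (H > logU) {
        betamin <- beta
        beta <- if (is.finite(betamax)) (beta + betamax) / 2 else beta * 2
      } else {
        betamax <- beta
        beta <- if (is.finite(betamin)) (beta + betamin) / 2 else beta / 2
      }
    }
    P[i, -i] <- Pi / sum(Pi)
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

#' t-SNE embedding of (sketched) records
#'
#' Embeds the standardised feature subset in two dimensions with t-SNE,
#' initialised from the first two principal components. Deterministic under
#' a fixed seed.
#'
#' @param records Track table rows to embed (typically the geometric
#'   sketch).
#' @param feature_subset Feature columns.
#' @param perplexity Gaussian perplexity (default 50); must be < n / 3.
#' @param n_iter Gradient-descent iterations (default 2000).
#' @param theta Approximation parameter retained for interface parity; the
#'   gradient is computed exactly.
#' @param seed RNG seed.
#' @return Tibble with columns `tsne1`, `tsne2`, one row per record.
#' @export
embed_tsne <- function(records, feature_subset, perplexity = 50,
                       n_iter = 2000, theta = 0.5, seed = 1L) {
  X <- feature_matrix(records, feature_subset)
  if (anyNA(X)) stop("records with missing features cannot be embedded")
  n <- nrow(X)
  if (perplexity >= n / 3) {
    stop("perplexity (", perplexity, ") must be smaller than n/3 = ", n / 3)
  }
  set.seed(seed)
  D2 <- as.matrix(dist(X))^2
  P <- tsne_input_p(D2, perplexity)

  pc <- prcomp(X, center = TRUE, scale. = FALSE)$x
  Y <- cbind(pc[, 1], if (ncol(pc) >= 2) pc[, 2] else 0)
  Y <- Y / sd(Y[, 1]) * 1e-4            # standard small-scale PCA init
  Y <- Y + matrix(rnorm(2 * n, sd = 1e-6), n, 2)

  exaggeration <- 12; stop_lying <- 250
  eta <- 200; momentum <- 0.5
  gains <- matrix(1, n, 2); inc <- matrix(0, n, 2)
  Pe <- P * exaggeration
  for (it in seq_len(n_iter)) {
    if (it == stop_lying + 1) Pe <- P
    if (it == 251) momentum <- 0.8
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    gains <- ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    inc <- momentum * inc - eta * gains * grad
    Y <- Y + inc
    Y <- sweep(Y, 2, colMeans(Y))
  }
  tibble::tibble(tsne1 = Y[, 1], tsne2 = Y[, 2])
}
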