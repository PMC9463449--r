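# Independent oracles used to validate the statistical and sequence
# machinery. These are deliberately written as plain step-by-step formula
# evaluations, separate from the package's implementations.

# direct-formula CMH chi-square (no continuity correction)
oracle_cmh <- function(tab) {
  top <- 0
  bottom <- 0
  for (k in seq_len(dim(tab)[3])) {
    m <- tab[, , k] * 1.0
    n1 <- sum(m[1, ]); n2 <- sum(m[2, ])
    m1 <- sum(m[, 1]); m2 <- sum(m[, 2]); tt <- sum(m)
    top <- top + (m[1, 1] - n1 * m1 / tt)
    bottom <- bottom + n1 * n2 * m1 * m2 / (tt^2 * (tt - 1))
  }
  stat <- top^2 / bottom
  list(statistic = stat, p = pchisq(stat, 1, lower.tail = FALSE))
}

# Breslow-Day via the closed-form quadratic for the expected cell
oracle_bd <- function(tab, tarone = FALSE) {
  K <- dim(tab)[3]
  num <- 0; den <- 0
  for (k in seq_len(K)) {
    m <- tab[, , k] * 1.0
    tt <- sum(m)
    num <- num + m[1, 1] * m[2, 2] / tt
    den <- den + m[1, 2] * m[2, 1] / tt
  }
  or <- num / den
  stat <- 0; dsum <- 0; vsum <- 0
  for (k in seq_len(K)) {
    m <- tab[, , k] * 1.0
    r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); tt <- sum(m)
    if (abs(or - 1) < 1e-12) {
      a_exp <- r1 * c1 / tt
    } else {
      A <- or - 1
      B <- -(or * (r1 + c1) + (tt - r1 - c1))
      C <- or * r1 * c1
      roots <- c((-B + sqrt(B^2 - 4 * A * C)) / (2 * A),
                 (-B - sqrt(B^2 - 4 * A * C)) / (2 * A))
      feas <- roots[roots > max(0, r1 + c1 - tt) & roots < min(r1, c1)]
      a_exp <- feas[1]
    }
    v <- 1 / (1 / a_exp + 1 / (r1 - a_exp) + 1 / (c1 - a_exp) +
                1 / (tt - r1 - c1 + a_exp))
    stat <- stat + (m[1, 1] - a_exp)^2 / v
    dsum <- dsum + (m[1, 1] - a_exp)
    vsum <- vsum + v
  }
  if (tarone) stat <- stat - dsum^2 / vsum
  list(statistic = stat, p = pchisq(stat, K - 1, lower.tail = FALSE))
}

# Woolf with Haldane-Anscombe correction, step by step
oracle_woolf <- function(tab) {
  K <- dim(tab)[3]
  lor <- numeric(K); w <- numeric(K)
  for (k in seq_len(K)) {
    m <- tab[, , k] + 0.5
    lor[k] <- log((m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1]))
    w[k] <- 1 / (1 / m[1, 1] + 1 / m[1, 2] + 1 / m[2, 1] + 1 / m[2, 2])
  }
  mean_lor <- sum(w * lor) / sum(w)
  stat <- sum(w * (lor - mean_lor)^2)
  list(statistic = stat, p = pchisq(stat, K - 1, lower.tail = FALSE))
}

# random stratified table with strictly positive margins
rand_strat_table <- function(K, max_cell = 50) {
  arr <- array(0L, c(2, 2, K))
  for (k in seq_len(K)) {
    repeat {
      m <- matrix(sample.int(max_cell, 4, replace = TRUE), 2, 2)
      if (all(rowSums(m) > 0) && all(colSums(m) > 0)) break
    }
    arr[, , k] <- m
  }
  arr
}

# textbook dynamic-programming edit distance over token vectors
oracle_edit_distance <- function(a, b) {
  na <- length(a); nb <- length(b)
  D <- matrix(0L, na + 1, nb + 1)
  D[, 1] <- 0:na
  D[1, ] <- 0:nb
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      D[i + 1, j + 1] <- min(D[i, j + 1] + 1L, D[i + 1, j] + 1L,
                             D[i, j] + (a[i] != b[j]))
    }
  }
  D[na + 1, nb + 1]
}

# records with d pre-standardised features set directly from a matrix
make_feature_records <- function(X) {
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  out <- tibble::as_tibble(as.data.frame(X))
  for (cn in colnames(X)) out[[paste0(cn, "_z")]] <- out[[cn]]
  out
}

feat_names <- function(d) paste0("f", seq_len(d))

# hand-built pt_sequences object from a state matrix
make_seqs <- function(M, levels = sort(unique(as.vector(M[!is.na(M)])))) {
  keys <- tibble::tibble(experiment_id = "e", well = "w", position = "1",
                         track_id = seq_len(nrow(M)))
  rownames(M) <- paste("e", "w", "1", keys$track_id, sep = "\r")
  structure(list(states = M, keys = keys, state_levels = levels),
            class = "pt_sequences")
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
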