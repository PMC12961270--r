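# independent brute-force oracles used across tests; deliberately naive,
# never shared code paths with the package

# pearson from the direct sum formula
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# spearman = pearson on mid-ranks
oracle_spearman <- function(x, y) oracle_pearson(rank(x), rank(y))

# kendall tau-b by O(n^2) pair counting with tie correction
oracle_kendall <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
      if (s > 0) conc <- conc + 1
      if (s < 0) disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  tx <- sum(sapply(table(x), function(t) t * (t - 1) / 2))
  ty <- sum(sapply(table(y), function(t) t * (t - 1) / 2))
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

# TOM by explicit triple loop over the definition
oracle_tom <- function(A) {
  n <- nrow(A)
  out <- diag(n)
  k <- sapply(seq_len(n), function(i) sum(A[i, -i]))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      shared <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) shared <- shared + A[i, u] * A[u, j]
      }
      out[i, j] <- (shared + A[i, j]) / (min(k[i], k[j]) + 1 - A[i, j])
    }
  }
  dimnames(out) <- dimnames(A)
  out
}

# step-up/step-down adjustment formulas written out longhand
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}
oracle_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, cummax((m - seq_len(m) + 1) * p[o]))
  out <- numeric(m)
  out[o] <- adj
  out
}
oracle_bonferroni <- function(p) pmin(1, length(p) * p)

# adjusted Rand index straight from the contingency-table formula
oracle_ari <- function(a, b) {
  ct <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(ct))
  ai <- sum(comb2(rowSums(ct)))
  bj <- sum(comb2(colSums(ct)))
  e <- ai * bj / comb2(length(a))
  (sij - e) / ((ai + bj) / 2 - e)
}

# random valid correlation matrix (from random data, so PSD by construction)
random_cor_matrix <- function(n_feat, n_obs = n_feat + 5) {
  stats::cor(matrix(stats::rnorm(n_obs * n_feat), n_obs, n_feat))
}

# all permutations of 1..n (tiny n only) and the raw Kendall S statistic,
# for exact-null enumeration
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in combinat_perms(n - 1)) {
    for (k in 0:(n - 1)) out[[length(out) + 1]] <- append(p, n, after = k)
  }
  out
}

kendall_s <- function(x, y) {
  s <- 0
  n <- length(x)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) s <- s + sign(x[j] - x[i]) * sign(y[j] - y[i])
  }
  s
}
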