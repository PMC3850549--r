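# Independent brute-force oracle for the partition statistics: literal
# double loops over examples and pairs, no shared code with the package
# internals.
oracle_partition <- function(L, omega, W = NULL) {
  n <- nrow(L)
  m <- colMeans(L)
  ssd <- 0
  for (i in seq_len(n)) ssd <- ssd + sum(omega * (L[i, ] - m)^2)
  w_sum <- 0
  wd_sum <- 0
  if (!is.null(W) && n > 0) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        w_sum <- w_sum + W[i, j]
        wd_sum <- wd_sum + W[i, j] * sum(omega * (L[i, ] - L[j, ])^2)
      }
    }
  }
  list(n = n, ssd = ssd, w_sum = w_sum, wd_sum = wd_sum,
       var = if (n >= 1) ssd / n else NA_real_,
       ay = if (n < 2 || w_sum <= 0 || ssd <= 0) 0.5 else
         min(1, max(0, 1 - ((n - 1) * wd_sum) / (4 * w_sum * ssd))))
}

# random symmetric 0/1-or-weighted adjacency with zero diagonal
random_adjacency <- function(n, p = 0.3, weighted = FALSE) {
  W <- matrix(0, n, n)
  up <- which(upper.tri(W))
  on <- up[stats::runif(length(up)) < p]
  W[on] <- if (weighted) stats::runif(length(on), 0.5, 3) else 1
  W + t(W)
}

random_labels <- function(n, K) {
  matrix(stats::rbinom(n * K, 1, 0.5), n, K)
}

# small three-class hierarchy used across tests
toy_hierarchy <- function(w0 = 0.75) parse_hierarchy(c("A", "B", "B/B1"), w0)

# tiny separable dataset: one attribute perfectly separates A-only from
# B/B1-labelled examples
toy_dataset <- function(n_per = 6L) {
  h <- toy_hierarchy()
  L <- rbind(matrix(rep(close_labels(h, "A"), n_per), n_per, byrow = TRUE),
             matrix(rep(close_labels(h, "B1"), n_per), n_per, byrow = TRUE))
  X <- data.frame(x1 = c(seq_len(n_per), seq_len(n_per) + 100),
                  x2 = rep(1, 2 * n_per))
  hmc_dataset(X, L, h)
}
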