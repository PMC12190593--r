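# independent oracles shared by the unit and acceptance suites

# exhaustive graph-metric oracle: triple loop over nodes, no linear algebra
brute_metrics <- function(adj) {
  n <- nrow(adj)
  degree <- integer(n); clustering <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] == 1)
    degree[i] <- length(nb)
    if (length(nb) >= 2) {
      e <- 0
      for (a in seq_along(nb)) {
        for (b in seq_along(nb)) {
          if (a < b && adj[nb[a], nb[b]] == 1) e <- e + 1
        }
      }
      clustering[i] <- 2 * e / (degree[i] * (degree[i] - 1))
    }
  }
  list(degree = degree, clustering = clustering)
}

random_cm <- function(n, seed) {
  set.seed(seed)
  r <- matrix(runif(n * n, -1, 1), n)
  r <- (r + t(r)) / 2; diag(r) <- 1
  structure(list(r = r, channels = sprintf("N%d", seq_len(n)),
                 band = "test"), class = "corr_matrix")
}

# full enumeration of all 2^n sign patterns of the observed absolute
# differences: the model-free reference for the signed-rank p-value
enum_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- signs %*% r
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}
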