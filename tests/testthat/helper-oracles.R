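# Independent brute-force oracles for the four nodal metrics, plus graph
# fixtures. These deliberately share no code with the package: triple loops,
# dense eigendecomposition, and stub-level weighted correlation.

random_graph <- function(n, density = 0.5, wmax = 5) {
  W <- matrix(0, n, n)
  ut <- which(upper.tri(W))
  present <- stats::runif(length(ut)) < density
  W[ut[present]] <- stats::runif(sum(present), 0.01, wmax)
  W + t(W)
}

# guarantees at least one edge and non-constant endpoint strengths over the
# edge stubs (a lone-edge component makes LA legitimately undefined)
random_graph_nondeg <- function(n, density = 0.5) {
  repeat {
    W <- random_graph(n, density)
    s <- rowSums(W)
    stubs <- which(W > 0, arr.ind = TRUE)
    if (nrow(stubs) > 0 && stats::sd(s[stubs[, 2]]) > 1e-6) return(W)
  }
}

oracle_cc <- function(W) {
  n <- nrow(W)
  Wh <- W / max(W)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(W[i, ] > 0)
    if (k < 2) next
    acc <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j < h && j != i && h != i) {
        acc <- acc + (Wh[i, j] * Wh[i, h] * Wh[j, h])^(1 / 3)
      }
    }
    cc[i] <- 2 * acc / (k * (k - 1))
  }
  cc
}

oracle_ec <- function(W) {
  e <- eigen(W, symmetric = TRUE)
  v <- e$vectors[, which.max(e$values)]
  v <- v * sign(sum(v))
  abs(v) / sqrt(sum(v^2))
}

# LA oracle: evaluate the edge-decomposition formula stub by stub, and the
# global coefficient as a weighted Pearson correlation over directed stubs
oracle_la <- function(W) {
  n <- nrow(W)
  s <- rowSums(W)
  stubs <- which(W > 0, arr.ind = TRUE)  # ordered pairs
  w <- W[stubs]
  S <- sum(w)
  mu <- sum(w * s[stubs[, 2]]) / S
  sigma2 <- sum(w * (s[stubs[, 2]] - mu)^2) / S
  la <- numeric(n)
  for (k in seq_len(nrow(stubs))) {
    i <- stubs[k, 1]; j <- stubs[k, 2]
    la[i] <- la[i] + w[k] * (s[i] - mu) * (s[j] - mu) / (sigma2 * S)
  }
  la
}

oracle_global_assortativity <- function(W) {
  stubs <- which(W > 0, arr.ind = TRUE)
  w <- W[stubs]
  s <- rowSums(W)
  x <- s[stubs[, 1]]; y <- s[stubs[, 2]]
  mx <- sum(w * x) / sum(w); my <- sum(w * y) / sum(w)
  sum(w * (x - mx) * (y - my)) /
    sqrt(sum(w * (x - mx)^2) * sum(w * (y - my)^2))
}

oracle_pc <- function(W, partition) {
  n <- nrow(W)
  pc <- numeric(n)
  for (i in seq_len(n)) {
    s <- sum(W[i, ])
    if (s == 0) next
    acc <- 0
    for (m in unique(partition)) {
      acc <- acc + (sum(W[i, partition == m]) / s)^2
    }
    pc[i] <- 1 - acc
  }
  pc
}

# independently coded Benjamini-Hochberg step-up adjustment
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# small whole-brain matrix fixture with the WM nodes populated
tiny_wholebrain <- function(seed = 1, density = 0.4) {
  withr::with_seed(seed, {
    W <- matrix(0, 379, 379)
    ut <- which(upper.tri(W))
    present <- stats::runif(length(ut)) < density
    W[ut[present]] <- stats::rgamma(sum(present), 2, 1)
    W <- W + t(W)
    W
  })
}

unit_volume_table <- function() {
  tibble::tibble(wholebrain_index = 0:378, volume = rep(1, 379))
}

test_hierarchy <- function() attach_wholebrain_indices(wm_hierarchy())

# minimal covariate table for model tests
balanced_covariates <- function(n_per_group = 70, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    subject_id = sprintf("s%03d", seq_len(2 * n_per_group)),
    group = rep(c("ALL", "HC"), each = n_per_group),
    age = stats::runif(2 * n_per_group, 6.2, 20.3),
    sex = rep(rep(c("M", "F"), length.out = n_per_group), 2)))
}
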