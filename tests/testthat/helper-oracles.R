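# Brute-force oracles, independent of the package's graph code, plus
# small graph constructors used across test files.

# Floyd-Warshall all-pairs shortest paths on a 0/1 adjacency matrix.
fw_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  d[a == 1] <- 1
  diag(d) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# Exhaustive triangle enumeration clustering.
clustering_oracle <- function(a) {
  n <- nrow(a)
  vapply(seq_len(n), function(i) {
    nb <- which(a[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    tri <- 0
    for (u in seq_along(nb))
      for (v in seq_len(u - 1))
        if (a[nb[u], nb[v]] == 1) tri <- tri + 1
    tri / (k * (k - 1) / 2)
  }, numeric(1))
}

lp_oracle <- function(a) {
  d <- fw_distances(a)
  off <- d[row(d) != col(d)]
  mean(off[is.finite(off)])
}

global_eff_oracle <- function(a) {
  d <- fw_distances(a)
  inv <- 1 / d
  diag(inv) <- 0
  mean(inv[row(inv) != col(inv)])
}

nodal_eff_oracle <- function(a) {
  d <- fw_distances(a)
  inv <- 1 / d
  diag(inv) <- 0
  rowSums(inv) / (nrow(a) - 1)
}

# Explicit neighbor-subgraph construction for local efficiency.
local_eff_oracle <- function(a) {
  n <- nrow(a)
  vals <- vapply(seq_len(n), function(i) {
    nb <- which(a[i, ] == 1)
    if (length(nb) < 2) return(0)
    global_eff_oracle(a[nb, nb, drop = FALSE])
  }, numeric(1))
  mean(vals)
}

# Erdos-Renyi adjacency with at least one edge.
random_adj <- function(n, p, seed) {
  set.seed(seed)
  repeat {
    a <- matrix(0L, n, n)
    up <- upper.tri(a)
    a[up] <- as.integer(runif(sum(up)) < p)
    a <- a + t(a)
    if (sum(a) >= 2) return(a)
  }
}

# Ring lattice: n nodes, each joined to its k nearest neighbors (k even).
ring_lattice <- function(n, k) {
  a <- matrix(0L, n, n)
  for (i in seq_len(n))
    for (s in seq_len(k / 2)) {
      j <- ((i - 1 + s) %% n) + 1
      a[i, j] <- a[j, i] <- 1L
    }
  a
}

path_graph <- function(n) {
  a <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) a[i, i + 1] <- a[i + 1, i] <- 1L
  a
}

complete_graph <- function(n) {
  a <- matrix(1L, n, n)
  diag(a) <- 0L
  a
}

star_graph <- function(leaves) {
  a <- matrix(0L, leaves + 1, leaves + 1)
  a[1, -1] <- a[-1, 1] <- 1L
  a
}

# Wrap an adjacency matrix as a binary_network-shaped object.
make_net <- function(a, cost = NA_real_) {
  storage.mode(a) <- "integer"
  structure(list(adjacency = a, cost = cost,
                 n_edges = as.integer(sum(a) / 2),
                 subject_id = "test", n_tied = 0L),
            class = "binary_network")
}

# Watts-Strogatz rewired ring (for small-world regime checks).
watts_strogatz <- function(n, k, p, seed) {
  set.seed(seed)
  a <- ring_lattice(n, k)
  up <- which(upper.tri(a) & a == 1)
  for (idx in up) {
    if (runif(1) < p) {
      i <- ((idx - 1) %% n) + 1
      j <- ((idx - 1) %/% n) + 1
      cand <- which(a[i, ] == 0)
      cand <- setdiff(cand, i)
      if (length(cand) > 0) {
        new_j <- sample(cand, 1)
        a[i, j] <- a[j, i] <- 0L
        a[i, new_j] <- a[new_j, i] <- 1L
      }
    }
  }
  a
}
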