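# Small-graph constructors and a region-table helper used across tests.

make_regions <- function(n) {
  data.frame(id = seq_len(n),
             name = sprintf("region_%03d", seq_len(n)),
             hemisphere = ifelse(seq_len(n) %% 2 == 1, "L", "R"),
             stringsAsFactors = FALSE)
}

conn <- function(m, mode = "binary") {
  m <- as.matrix(m)
  connectome(m, make_regions(nrow(m)), mode = mode)
}

complete_graph <- function(n, w = 1) {
  m <- matrix(w, n, n)
  diag(m) <- 0
  m
}

path_graph <- function(n, w = 1) {
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1)) m[i, i + 1] <- m[i + 1, i] <- w
  m
}

star_graph <- function(n_leaves, w = 1) {
  n <- n_leaves + 1
  m <- matrix(0, n, n)
  m[1, 2:n] <- m[2:n, 1] <- w
  m
}

ring_lattice <- function(n, k) {
  m <- matrix(0, n, n)
  for (i in seq_len(n)) for (d in seq_len(k / 2)) {
    j <- ((i - 1 + d) %% n) + 1
    m[i, j] <- m[j, i] <- 1
  }
  m
}

# Erdos-Renyi adjacency, optionally with uniform random weights.
er_matrix <- function(n, p, weighted = FALSE, seed = 1) {
  set.seed(seed)
  m <- matrix(0, n, n)
  ut <- upper.tri(m)
  on <- stats::runif(sum(ut)) < p
  vals <- if (weighted) stats::runif(sum(ut), 0.2, 1.5) else 1
  m[ut] <- on * vals
  m + t(m)
}

# A connected random weighted/binary connectome (adds a spanning path if
# the ER draw is disconnected) for oracle-equivalence runs.
rand_conn <- function(n, p = 0.4, mode = "binary", seed = 1) {
  m <- er_matrix(n, p, weighted = mode == "weighted", seed = seed)
  conn(m, mode)
}
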