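# Independent brute-force oracles. These deliberately use different
# algorithms from the package (Floyd-Warshall instead of Dijkstra,
# triple loops instead of matrix products, exhaustive simple-path
# enumeration instead of Brandes accumulation).

# Per-link length matrix for a connectome, mirroring the 1/w convention.
oracle_lengths <- function(c) {
  w <- c$matrix
  len <- matrix(Inf, nrow(w), ncol(w))
  len[w > 0] <- if (c$mode == "binary") 1 else 1 / w[w > 0]
  len
}

# All-pairs shortest paths by Floyd-Warshall.
oracle_apsp <- function(len) {
  d <- len
  diag(d) <- 0
  n <- nrow(d)
  for (k in seq_len(n)) {
    d <- pmin(d, outer(d[, k], d[k, ], "+"))
  }
  d
}

oracle_cpl <- function(c) {
  d <- oracle_apsp(oracle_lengths(c))
  off <- d[row(d) != col(d)]
  mean(off[is.finite(off)])
}

oracle_efficiency <- function(d) {
  n <- nrow(d)
  if (n < 2) return(0)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && is.finite(d[i, j])) tot <- tot + 1 / d[i, j]
  }
  tot / (n * (n - 1))
}

oracle_global_efficiency <- function(c) {
  oracle_efficiency(oracle_apsp(oracle_lengths(c)))
}

oracle_local_efficiency <- function(c) {
  a <- c$matrix > 0
  len <- oracle_lengths(c)
  n <- nrow(a)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ])
    if (length(nb) < 2) next
    out[i] <- oracle_efficiency(oracle_apsp(len[nb, nb, drop = FALSE]))
  }
  out
}

# Clustering by explicit neighbour-pair loops.
oracle_clustering <- function(c) {
  w <- c$matrix
  a <- w > 0
  n <- nrow(w)
  hat <- if (c$mode == "binary") a * 1 else w / max(w)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ])
    k <- length(nb)
    if (k < 2) next
    tot <- 0
    for (j in nb) for (h in nb) {
      if (j != h && a[j, h])
        tot <- tot + (hat[i, j] * hat[i, h] * hat[j, h])^(1 / 3)
    }
    out[i] <- tot / (k * (k - 1))
  }
  out
}

# Betweenness by exhaustive enumeration of simple paths (with pruning at
# the running best length), counting interior nodes of all shortest paths;
# ordered-pair convention (each unordered pair contributes twice).
oracle_betweenness <- function(c) {
  len <- oracle_lengths(c)
  n <- nrow(len)
  adj <- lapply(seq_len(n), function(i) which(is.finite(len[i, ])))
  bc <- numeric(n)
  tol <- 1e-9
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    best <- Inf
    paths <- list()
    rec <- function(node, visited, d, path) {
      if (d > best + tol) return()
      if (node == t) {
        if (d < best - tol) {
          best <<- d
          paths <<- list(path)
        } else {
          paths[[length(paths) + 1L]] <<- path
        }
        return()
      }
      for (v in adj[[node]]) {
        if (!visited[v]) {
          visited[v] <- TRUE
          rec(v, visited, d + len[node, v], c(path, v))
          visited[v] <- FALSE
        }
      }
    }
    visited <- rep(FALSE, n)
    visited[s] <- TRUE
    rec(s, visited, 0, s)
    if (length(paths) == 0) next
    sigma <- length(paths)
    interior <- unlist(lapply(paths, function(p) p[-c(1, length(p))]))
    if (length(interior) > 0) {
      cnt <- table(interior)
      idx <- as.integer(names(cnt))
      bc[idx] <- bc[idx] + 2 * as.numeric(cnt) / sigma
    }
  }
  bc
}
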