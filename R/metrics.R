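#' @name graph_metrics
#' @title Graph-theoretical network measures
#'
#' @description
#' Node-level and network-level measures for binary and weighted
#' connectomes, following the conventions of the structural-connectome
#' literature:
#'
#' * weighted shortest paths use per-link lengths `l = 1/w`, so strong
#'   connections are short;
#' * weighted clustering is the Onnela geometric-mean form with weights
#'   normalized by the network-wide maximum;
#' * betweenness centrality is reported unnormalized over ordered node
#'   pairs (each unordered pair counted twice);
#' * pairs with no connecting path are excluded from the characteristic
#'   path length (their count is reported) and contribute zero efficiency.
NULL

# Per-link length matrix: 1 for binary links, 1/w for weighted; Inf where
# there is no link.
.length_matrix <- function(c) {
  w <- c$matrix
  .assert(all(w >= 0), "negative weights are not allowed")
  len <- matrix(Inf, nrow(w), ncol(w))
  pos <- w > 0
  len[pos] <- if (c$mode == "binary") 1 else 1 / w[pos]
  dimnames(len) <- dimnames(w)
  len
}

#' Node degree
#'
#' Number of links of each node of a binary connectome.
#'
#' @param c a binary [connectome].
#' @return Named integer vector, one entry per node.
#' @export
degree <- function(c) {
  .assert(inherits(c, "connectome"), "c must be a connectome")
  .assert(c$mode == "binary", "degree is defined for binary connectomes; use strength() for weighted ones")
  k <- as.integer(rowSums(c$matrix > 0))
  names(k) <- rownames(c$matrix)
  k
}

#' Node strength
#'
#' Sum of the weights of the links of each node of a weighted connectome.
#'
#' @param c a weighted [connectome].
#' @return Named numeric vector, one entry per node.
#' @export
strength <- function(c) {
  .assert(inherits(c, "connectome"), "c must be a connectome")
  .assert(c$mode == "weighted", "strength is defined for weighted connectomes; use degree() for binary ones")
  rowSums(c$matrix)
}

#' Clustering coefficient
#'
#' Binary: fraction of a node's neighbour pairs that are themselves linked,
#' `C_i = 2 t_i / (k_i (k_i - 1))` with `t_i` the number of triangles at i.
#' Weighted: Onnela's geometric-mean form,
#' `C_i = (2 / (k_i (k_i - 1))) * sum over neighbour pairs of
#' (w_ij w_ih w_jh)^(1/3)` with weights normalized by the network maximum.
#' Nodes with fewer than two neighbours have `C_i = 0`.
#'
#' @param c a [connectome].
#' @return Named numeric vector of per-node coefficients.
#' @export
clustering <- function(c) {
  .assert(inherits(c, "connectome"), "c must be a connectome")
  a <- (c$matrix > 0) * 1
  k <- rowSums(a)
  if (c$mode == "binary") {
    t2 <- diag(a %*% a %*% a)          # 2 * triangles at each node
  } else {
    mx <- max(c$matrix)
    if (mx == 0) {
      t2 <- numeric(nrow(a))
    } else {
      w3 <- (c$matrix / mx)^(1 / 3)
      t2 <- diag(w3 %*% w3 %*% w3)
    }
  }
  ci <- ifelse(k >= 2, t2 / (k * (k - 1)), 0)
  names(ci) <- rownames(c$matrix)
  ci
}

# All-sources Dijkstra on a length matrix (Inf = no link). Handles unit
# lengths (binary BFS distances) as a special case of the same relaxation.
.apsp <- function(len) {
  n <- nrow(len)
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    done <- logical(n)
    repeat {
      cand <- which(!done & is.finite(dist))
      if (length(cand) == 0) break
      u <- cand[which.min(dist[cand])]
      done[u] <- TRUE
      nd <- dist[u] + len[u, ]
      upd <- !done & nd < dist
      dist[upd] <- nd[upd]
    }
    d[s, ] <- dist
  }
  diag(d) <- 0
  dimnames(d) <- dimnames(len)
  d
}

#' All-pairs shortest path lengths
#'
#' Binary connectomes give hop counts; weighted connectomes give minimal
#' sums of per-link lengths `l = 1/w` (Dijkstra). Unreachable pairs are
#' `Inf`; the diagonal is 0.
#'
#' @param c a [connectome].
#' @return Numeric matrix of path lengths.
#' @export
shortest_path_lengths <- function(c) {
  .assert(inherits(c, "connectome"), "c must be a connectome")
  .apsp(.length_matrix(c))
}

#' Characteristic path length
#'
#' Mean shortest path length over ordered node pairs with a finite path.
#' The number of unreachable ordered pairs is attached as attribute
#' `"n_infinite"`. With no finite pair the result is `NA` with a warning.
#'
#' @param c a [connectome].
#' @return Scalar L with attribute `n_infinite`.
#' @export
characteristic_path_length <- function(c) {
  d <- shortest_path_lengths(c)
  off <- d[row(d) != col(d)]
  fin <- is.finite(off)
  if (!any(fin)) {
    warning("no finite node pairs; characteristic path length undefined")
    out <- NA_real_
  } else {
    out <- mean(off[fin])
  }
  attr(out, "n_infinite") <- sum(!fin)
  out
}

#' Global efficiency
#'
#' Mean of the inverse shortest path lengths over ordered node pairs, with
#' `1/Inf = 0` for unreachable pairs. A single-node network has efficiency 0
#' by convention.
#'
#' @param c a [connectome].
#' @return Scalar efficiency.
#' @export
global_efficiency <- function(c) {
  d <- shortest_path_lengths(c)
  .efficiency_from_d(d)
}

.efficiency_from_d <- function(d) {
  n <- nrow(d)
  if (n < 2) return(0)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0   # also zeroes the diagonal (1/0 = Inf)
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Local efficiency
#'
#' For each node, the global efficiency of the subnetwork induced by its
#' neighbours (the node itself excluded); 0 for nodes with fewer than two
#' neighbours. The weighted subgraph keeps the original weights.
#'
#' @param c a [connectome].
#' @return Named numeric vector of per-node efficiencies.
#' @export
local_efficiency <- function(c) {
  .assert(inherits(c, "connectome"), "c must be a connectome")
  len <- .length_matrix(c)
  a <- c$matrix > 0
  n <- nrow(a)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ])
    if (length(nb) < 2) next
    out[i] <- .efficiency_from_d(.apsp(len[nb, nb, drop = FALSE]))
  }
  names(out) <- rownames(c$matrix)
  out
}

#' Betweenness centrality
#'
#' Brandes' accumulation of pair dependencies:
#' `BC(i) = sum over ordered pairs (s, t), s != i != t, of
#' sigma_st(i) / sigma_st`, where `sigma_st` counts shortest paths and
#' `sigma_st(i)` those through i. Endpoints are excluded and values are
#' unnormalized raw counts over ordered pairs (each unordered pair counted
#' twice). Weighted connectomes use per-link lengths `1/w`.
#'
#' @param c a [connectome].
#' @return Named numeric vector of per-node centralities.
#' @export
betweenness <- function(c) {
  .assert(inherits(c, "connectome"), "c must be a connectome")
  len <- .length_matrix(c)
  n <- nrow(len)
  bc <- numeric(n)
  adj <- lapply(seq_len(n), function(i) which(is.finite(len[i, ])))
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    sigma <- numeric(n); sigma[s] <- 1
    pred <- vector("list", n)
    done <- logical(n)
    order_settled <- integer(n); settled <- 0L
    repeat {
      cand <- which(!done & is.finite(dist))
      if (length(cand) == 0) break
      u <- cand[which.min(dist[cand])]
      done[u] <- TRUE
      settled <- settled + 1L
      order_settled[settled] <- u
      for (v in adj[[u]]) {
        if (done[v]) next
        nd <- dist[u] + len[u, v]
        tol <- 1e-12 * (1 + abs(nd))
        if (nd < dist[v] - tol) {
          dist[v] <- nd
          sigma[v] <- sigma[u]
          pred[[v]] <- u
        } else if (abs(nd - dist[v]) <= tol) {
          sigma[v] <- sigma[v] + sigma[u]
          pred[[v]] <- c(pred[[v]], u)
        }
      }
    }
    delta <- numeric(n)
    for (wi in rev(seq_len(settled))) {
      w <- order_settled[wi]
      for (u in pred[[w]]) {
        delta[u] <- delta[u] + sigma[u] / sigma[w] * (1 + delta[w])
      }
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  names(bc) <- rownames(c$matrix)
  bc
}

#' Identify hubs
#'
#' Hubs are nodes whose value (strength or betweenness centrality) exceeds
#' the mean by more than two sample standard deviations (strict inequality,
#' n - 1 denominator).
#'
#' @param values named per-node numeric vector; names are region ids.
#' @return Character vector of hub region ids (possibly empty).
#' @export
identify_hubs <- function(values) {
  .assert(is.numeric(values) && length(values) >= 2,
          "values must be numeric with at least 2 nodes")
  thr <- mean(values) + 2 * stats::sd(values)
  ids <- names(values)
  if (is.null(ids)) ids <- as.character(seq_along(values))
  structure(ids[values > thr], threshold = thr)
}

#' Per-node metric table
#'
#' Convenience wrapper computing degree (binary) or strength (weighted),
#' clustering, local efficiency and betweenness centrality for every node.
#'
#' @param c a [connectome].
#' @return data.frame with one row per node.
#' @export
node_metrics <- function(c) {
  .assert(inherits(c, "connectome"), "c must be a connectome")
  size <- if (c$mode == "binary") degree(c) else strength(c)
  data.frame(
    region_id = c$regions$id,
    name = c$regions$name,
    size = as.numeric(size),
    clustering = as.numeric(clustering(c)),
    local_efficiency = as.numeric(local_efficiency(c)),
    betweenness = as.numeric(betweenness(c)),
    row.names = NULL
  )
}

#' Network-level metric record
#'
#' Mean degree or strength, mean clustering coefficient, characteristic
#' path length (with unreachable-pair count) and global efficiency.
#'
#' @param c a [connectome].
#' @return Named list of global measures.
#' @export
global_metrics <- function(c) {
  .assert(inherits(c, "connectome"), "c must be a connectome")
  size <- if (c$mode == "binary") mean(degree(c)) else mean(strength(c))
  L <- characteristic_path_length(c)
  list(
    mode = c$mode,
    mean_size = size,
    clustering = mean(clustering(c)),
    path_length = as.numeric(L),
    n_unreachable_pairs = attr(L, "n_infinite"),
    global_efficiency = global_efficiency(c)
  )
}
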