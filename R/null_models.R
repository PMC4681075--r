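#' @name null_models
#' @title Degree- and strength-preserving null models
#'
#' @description
#' Randomized reference networks for normalizing clustering and path
#' length. Binary networks are rewired with Maslov-Sneppen double-edge
#' swaps, which preserve every node's degree exactly. Weighted networks are
#' rewired the same way with weights travelling on the swapped links, after
#' which the weight multiset is reassigned across the randomized topology
#' by greedy residual-strength matching, preserving the weight multiset
#' exactly and the node strength distribution approximately.
NULL

.edge_list <- function(m) {
  ut <- which(upper.tri(m) & m > 0, arr.ind = TRUE)
  list(a = ut[, 1], b = ut[, 2], w = m[ut])
}

# Double-edge swaps on an edge list; returns the rewired edge list.
# Attempted swaps = rewires_per_link * edge count; failed attempts count
# toward the budget so runtime is bounded and deterministic.
.double_edge_swap <- function(edges, n, rewires_per_link) {
  a <- edges$a; b <- edges$b; w <- edges$w
  m <- length(a)
  adj <- matrix(FALSE, n, n)
  adj[cbind(a, b)] <- TRUE
  adj[cbind(b, a)] <- TRUE
  attempts <- round(rewires_per_link * m)
  for (t in seq_len(attempts)) {
    e <- sample.int(m, 2L)
    p <- a[e[1]]; q <- b[e[1]]
    r <- a[e[2]]; s <- b[e[2]]
    if (stats::runif(1) < 0.5) { tmp <- r; r <- s; s <- tmp }
    # propose (p-q, r-s) -> (p-s, r-q)
    if (length(unique(c(p, q, r, s))) < 4L) next
    if (adj[p, s] || adj[r, q]) next
    adj[p, q] <- adj[q, p] <- FALSE
    adj[r, s] <- adj[s, r] <- FALSE
    adj[p, s] <- adj[s, p] <- TRUE
    adj[r, q] <- adj[q, r] <- TRUE
    b[e[1]] <- s
    a[e[2]] <- r
    b[e[2]] <- q
  }
  list(a = a, b = b, w = w)
}

.edges_to_matrix <- function(edges, n, dn) {
  m <- matrix(0, n, n, dimnames = dn)
  m[cbind(edges$a, edges$b)] <- edges$w
  m[cbind(edges$b, edges$a)] <- edges$w
  m
}

#' Degree-preserving rewiring of a binary connectome
#'
#' Maslov-Sneppen double-edge swaps: two links (a-b, c-d) with four distinct
#' nodes are replaced by (a-d, c-b) unless that would create a duplicate
#' link. The degree sequence is preserved exactly and the graph stays
#' simple.
#'
#' @param c a binary [connectome] with at least 2 links.
#' @param rewires_per_link attempted swaps per link (default 10).
#' @param seed RNG seed for the swap sequence.
#' @return A rewired binary [connectome].
#' @export
rewire_binary <- function(c, rewires_per_link = 10, seed = 1) {
  .assert(inherits(c, "connectome"), "c must be a connectome")
  .assert(c$mode == "binary", "rewire_binary needs a binary connectome")
  edges <- .edge_list(c$matrix)
  if (length(edges$a) < 2) {
    warning("fewer than 2 links; returning the input unchanged")
    return(c)
  }
  out <- with_seed(seed, .double_edge_swap(edges, n_nodes(c), rewires_per_link))
  connectome(.edges_to_matrix(out, n_nodes(c), dimnames(c$matrix)),
             c$regions, mode = "binary", provenance = c$provenance)
}

# Reassign the weight multiset over a fixed topology by greedy residual-
# strength matching: weights in descending order each go to the free edge
# whose endpoints have the largest product of residual target strengths.
.match_weights_to_strength <- function(edges, target_strength) {
  ord <- order(edges$w, decreasing = TRUE)
  ws <- edges$w[ord]
  a <- edges$a; b <- edges$b
  m <- length(a)
  res <- target_strength
  free <- seq_len(m)
  new_w <- numeric(m)
  for (k in seq_len(m)) {
    sc <- res[a[free]] * res[b[free]]
    pick <- free[which.max(sc)]
    new_w[pick] <- ws[k]
    res[a[pick]] <- res[a[pick]] - ws[k]
    res[b[pick]] <- res[b[pick]] - ws[k]
    free <- free[free != pick]
  }
  list(a = a, b = b, w = new_w)
}

#' Degree-preserving rewiring of a weighted connectome
#'
#' Topology is randomized by double-edge swaps with weights carried on the
#' swapped links; the weight multiset is then reassigned across the
#' randomized topology by rank-matching node strength, so the weight
#' multiset is preserved exactly and the strength distribution
#' approximately. The degree sequence is preserved exactly.
#'
#' @param c a weighted [connectome].
#' @inheritParams rewire_binary
#' @return A rewired weighted [connectome].
#' @export
rewire_weighted <- function(c, rewires_per_link = 10, seed = 1) {
  .assert(inherits(c, "connectome"), "c must be a connectome")
  .assert(c$mode == "weighted", "rewire_weighted needs a weighted connectome")
  edges <- .edge_list(c$matrix)
  if (length(edges$a) < 2) {
    warning("fewer than 2 links; returning the input unchanged")
    return(c)
  }
  target <- rowSums(c$matrix)
  out <- with_seed(seed, {
    swapped <- .double_edge_swap(edges, n_nodes(c), rewires_per_link)
    .match_weights_to_strength(swapped, target)
  })
  connectome(.edges_to_matrix(out, n_nodes(c), dimnames(c$matrix)),
             c$regions, mode = "weighted", provenance = c$provenance)
}

#' Rewire a connectome (mode dispatch)
#'
#' @param c a [connectome].
#' @inheritParams rewire_binary
#' @return A rewired [connectome] of the same mode.
#' @export
rewire <- function(c, rewires_per_link = 10, seed = 1) {
  if (c$mode == "binary") rewire_binary(c, rewires_per_link, seed)
  else rewire_weighted(c, rewires_per_link, seed)
}

#' Normalized clustering coefficient and path length
#'
#' gamma = C(network) / mean C over an ensemble of degree- (and strength-)
#' preserving null networks; lambda = L(network) / mean L over the same
#' ensemble. Per-null values are returned for audit.
#'
#' @param c a [connectome].
#' @param n_nulls number of null networks (>= 1; default 100).
#' @param rewires_per_link attempted swaps per link per null (default 10).
#' @param seed base seed; null r uses a seed derived from `seed` and `r`.
#' @return List with `gamma`, `lambda`, and `ensemble` (data.frame with one
#'   row per null: index, seed, clustering, path_length).
#' @export
normalized_metrics <- function(c, n_nulls = 100, rewires_per_link = 10,
                               seed = 1) {
  .assert(inherits(c, "connectome"), "c must be a connectome")
  .assert(n_nulls >= 1, "n_nulls must be >= 1")
  c_obs <- mean(clustering(c))
  l_obs <- as.numeric(characteristic_path_length(c))
  seeds <- vapply(seq_len(n_nulls), function(r) .child_seed(seed, r), integer(1))
  cr <- numeric(n_nulls)
  lr <- numeric(n_nulls)
  for (r in seq_len(n_nulls)) {
    null <- rewire(c, rewires_per_link, seed = seeds[r])
    cr[r] <- mean(clustering(null))
    lr[r] <- as.numeric(characteristic_path_length(null))
  }
  mc <- mean(cr)
  ml <- mean(lr)
  gamma <- if (mc == 0) { warning("mean null clustering is 0; gamma undefined"); NA_real_ } else c_obs / mc
  lambda <- if (is.na(ml) || ml == 0) { warning("mean null path length is 0 or undefined; lambda undefined"); NA_real_ } else l_obs / ml
  list(
    gamma = gamma, lambda = lambda,
    clustering = c_obs, path_length = l_obs,
    ensemble = data.frame(null_index = seq_len(n_nulls), seed = seeds,
                          clustering = cr, path_length = lr),
    settings = list(n_nulls = n_nulls, rewires_per_link = rewires_per_link,
                    seed = seed)
  )
}
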