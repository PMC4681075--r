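test_that("degree and strength follow their definitions on closed forms", {
  k3 <- conn(complete_graph(3))
  expect_equal(unname(degree(k3)), c(2L, 2L, 2L))
  empty <- conn(matrix(0, 4, 4))
  expect_equal(unname(degree(empty)), rep(0L, 4))

  two <- conn(path_graph(2, w = 0.025), mode = "weighted")
  expect_equal(unname(strength(two)), c(0.025, 0.025))
  k3w <- conn(complete_graph(3, w = 0.3), mode = "weighted")
  expect_equal(unname(strength(k3w)), rep(0.6, 3))

  # handshake identity on random graphs
  for (s in 1:5) {
    g <- rand_conn(15, 0.3, seed = s)
    expect_equal(sum(degree(g)), 2 * sum(g$matrix[upper.tri(g$matrix)] > 0))
  }

  # mode guards
  expect_error(degree(k3w), "binary")
  expect_error(strength(k3), "weighted")
})

test_that("clustering matches closed forms and unit-weight reduction", {
  expect_equal(unname(clustering(conn(complete_graph(3)))), rep(1, 3))
  expect_equal(unname(clustering(conn(path_graph(3)))), rep(0, 3))
  # all-unit-weight network reproduces the binary coefficients exactly
  m <- er_matrix(10, 0.4, seed = 3)
  expect_equal(clustering(conn(m, "weighted")), clustering(conn(m, "binary")))
})

test_that("shortest path lengths follow the 1/w length convention", {
  p3 <- conn(path_graph(3))
  d <- shortest_path_lengths(p3)
  expect_equal(d[1, 3], 2)
  two <- conn(path_graph(2, w = 0.025), mode = "weighted")
  expect_equal(shortest_path_lengths(two)[1, 2], 40)
  # unreachable pairs are Inf
  m <- matrix(0, 3, 3); m[1, 2] <- m[2, 1] <- 1
  expect_equal(shortest_path_lengths(conn(m))[1, 3], Inf)
})

test_that("characteristic path length averages finite ordered pairs", {
  expect_equal(as.numeric(characteristic_path_length(conn(complete_graph(3)))), 1)
  expect_equal(as.numeric(characteristic_path_length(conn(path_graph(3)))), 4 / 3)
  # disconnected pairs are excluded and counted
  m <- matrix(0, 4, 4)
  m[1, 2] <- m[2, 1] <- m[3, 4] <- m[4, 3] <- 1
  L <- characteristic_path_length(conn(m))
  expect_equal(as.numeric(L), 1)
  expect_equal(attr(L, "n_infinite"), 8)
  # fully disconnected network: undefined, not a crash
  expect_warning(L0 <- characteristic_path_length(conn(matrix(0, 3, 3))),
                 "undefined")
  expect_true(is.na(L0))
})

test_that("global efficiency matches hand enumeration", {
  expect_equal(global_efficiency(conn(complete_graph(3))), 1)
  m <- matrix(0, 4, 4)
  m[1, 2] <- m[2, 1] <- m[3, 4] <- m[4, 3] <- 1
  expect_equal(global_efficiency(conn(m)), 1 / 3)
  expect_true(global_efficiency(conn(er_matrix(12, 0.5, seed = 2))) <= 1)
})

test_that("local efficiency equals neighbourhood-subgraph efficiency", {
  expect_equal(unname(local_efficiency(conn(complete_graph(4)))), rep(1, 4))
  expect_equal(unname(local_efficiency(conn(star_graph(4)))), rep(0, 5))
})

test_that("betweenness uses the ordered-pair, endpoint-excluded convention", {
  p3 <- conn(path_graph(3))
  expect_equal(unname(betweenness(p3)), c(0, 2, 0))
  s5 <- conn(star_graph(4))
  expect_equal(unname(betweenness(s5))[1], 4 * 3)  # (n-1)(n-2) ordered
  expect_equal(unname(betweenness(s5))[-1], rep(0, 4))
})

test_that("all measures agree with independent brute-force oracles", {
  for (s in 1:12) {
    mode <- if (s %% 2 == 0) "weighted" else "binary"
    g <- rand_conn(5 + (s %% 4) * 2, 0.45, mode = mode, seed = 100 + s)
    expect_equal(shortest_path_lengths(g),
                 oracle_apsp(oracle_lengths(g)),
                 ignore_attr = TRUE, tolerance = 1e-12)
    expect_equal(unname(clustering(g)), oracle_clustering(g),
                 tolerance = 1e-12)
    expect_equal(global_efficiency(g), oracle_global_efficiency(g),
                 tolerance = 1e-12)
    expect_equal(unname(local_efficiency(g)), oracle_local_efficiency(g),
                 tolerance = 1e-12)
    expect_equal(unname(betweenness(g)), oracle_betweenness(g),
                 tolerance = 1e-9)
  }
})

test_that("measures agree with igraph on random graphs (external cross-check)", {
  for (s in 1:6) {
    mode <- if (s %% 2 == 0) "weighted" else "binary"
    g <- rand_conn(12, 0.35, mode = mode, seed = 200 + s)
    ig <- igraph::graph_from_adjacency_matrix(
      (g$matrix > 0) * 1, mode = "undirected")
    # igraph graph with 1/w edge lengths for the weighted comparisons
    lenm <- matrix(0, nrow(g$matrix), ncol(g$matrix))
    pos <- g$matrix > 0
    lenm[pos] <- 1 / g$matrix[pos]
    igw <- igraph::graph_from_adjacency_matrix(lenm, mode = "undirected",
                                               weighted = TRUE)
    expect_equal(unname(shortest_path_lengths(g)),
                 unname(igraph::distances(if (mode == "binary") ig else igw)),
                 tolerance = 1e-10)
    # igraph betweenness counts unordered pairs; ours counts ordered
    expect_equal(unname(betweenness(g)),
                 2 * unname(igraph::betweenness(
                   if (mode == "binary") ig else igw)),
                 tolerance = 1e-9)
    if (mode == "binary") {
      tr <- igraph::transitivity(ig, type = "local", isolates = "zero")
      expect_equal(unname(clustering(g)), unname(tr), tolerance = 1e-12)
    }
  }
})

test_that("metrics are invariant under node relabeling", {
  g <- rand_conn(10, 0.4, mode = "weighted", seed = 7)
  set.seed(8)
  perm <- sample(10)
  gp <- connectome(g$matrix[perm, perm], make_regions(10), mode = "weighted")
  expect_equal(unname(strength(gp)), unname(strength(g))[perm])
  expect_equal(unname(clustering(gp)), unname(clustering(g))[perm])
  expect_equal(unname(betweenness(gp)), unname(betweenness(g))[perm],
               tolerance = 1e-9)
  expect_equal(global_efficiency(gp), global_efficiency(g))
})

test_that("hub detection applies the strict mean + 2 SD rule", {
  expect_length(identify_hubs(c(a = 1, b = 1, c = 1)), 0)
  v <- c(rep(0, 9), 100)
  names(v) <- sprintf("n%02d", 1:10)
  # mean 10, sd 31.62 -> threshold 73.2: only the large node qualifies
  hubs <- identify_hubs(v)
  expect_equal(as.character(hubs), "n10")
  expect_equal(attr(hubs, "threshold"), 10 + 2 * sd(v))
})
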