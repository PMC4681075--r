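# Streamline -> connectome construction.

tiny_parcellation <- function() {
  # 4x2x2 grid of 10 mm voxels; x-slab i is region i (4 voxels each)
  labels <- array(0L, dim = c(4, 2, 2))
  for (i in 1:4) labels[i, , ] <- i
  parcellation(labels, c(10, 10, 10), make_regions(4))
}

test_that("streamline length sums Euclidean segments", {
  expect_equal(streamline_length(rbind(c(0, 0, 0), c(3, 4, 0))), 5)
  expect_equal(streamline_length(rbind(c(0, 0, 0), c(10, 0, 0),
                                       c(10, 10, 0))), 20)
  # independent re-summation on a random polyline
  set.seed(1)
  pts <- matrix(rnorm(150), ncol = 3)
  brute <- sum(vapply(seq_len(49), function(i) {
    sqrt(sum((pts[i + 1, ] - pts[i, ])^2))
  }, numeric(1)))
  expect_equal(streamline_length(pts), brute)
  expect_error(streamline_length(rbind(c(0, 0, 0), c(NA, 0, 0))),
               "finite")
})

test_that("length filtering keeps the boundary and records removals", {
  mk <- function(len) rbind(c(0, 0, 0), c(len, 0, 0))
  s <- streamline_set(list(mk(49.9), mk(50), mk(120)))
  f <- filter_streamlines(s, 50)
  expect_length(f$streamlines, 2)
  expect_equal(f$provenance$n_removed_short, 1)
  expect_length(filter_streamlines(s, 0)$streamlines, 3)
  expect_length(filter_streamlines(s, Inf)$streamlines, 0)
})

test_that("endpoints map through half-open voxel intervals", {
  p <- tiny_parcellation()
  # voxel centres
  expect_equal(assign_endpoints(rbind(c(5, 5, 5), c(25, 5, 5)), p),
               c(1L, 3L))
  # out of grid -> NA
  expect_equal(assign_endpoints(rbind(c(-5, 5, 5), c(5, 5, 5)), p),
               c(NA_integer_, 1L))
  # exactly on the boundary between voxel 1 and 2 along x: belongs to
  # voxel 2 (half-open [lo, hi))
  expect_equal(assign_endpoints(rbind(c(10, 5, 5), c(5, 5, 5)), p),
               c(2L, 1L))
  # background maps to NA
  labels <- array(0L, dim = c(2, 1, 1))
  labels[1, 1, 1] <- 1L
  pb <- parcellation(labels, c(1, 1, 1),
                     data.frame(id = 1, name = "only", hemisphere = "L"))
  expect_equal(assign_endpoints(rbind(c(1.5, 0.5, 0.5), c(0.5, 0.5, 0.5)), pb),
               c(NA_integer_, 1L))
})

test_that("connection counting discards loops and unassigned endpoints", {
  p <- tiny_parcellation()
  seg <- function(a, b) rbind(a, b)
  s <- streamline_set(list(
    seg(c(5, 5, 5), c(25, 5, 5)),    # 1-3
    seg(c(5, 15, 5), c(25, 15, 5)),  # 1-3
    seg(c(25, 5, 15), c(5, 5, 15)),  # 3-1 (reversed orientation)
    seg(c(5, 5, 5), c(5, 15, 15)),   # 1-1 self loop: discarded
    seg(c(5, 5, 5), c(500, 5, 5))    # out of grid: discarded
  ))
  f <- count_connections(s, p)
  expect_equal(f[1, 3], 3)
  expect_equal(f[3, 1], 3)
  expect_equal(sum(f), 6)
  expect_equal(attr(f, "discarded"), c(unassigned = 1L, self_loop = 1L))
  # empty set
  f0 <- count_connections(streamline_set(list()), p)
  expect_equal(sum(f0), 0)
})

test_that("binary and density-weighted construction follow their formulas", {
  regions <- make_regions(2)
  regions$volume_mm3 <- c(100, 300)
  f <- matrix(c(0, 5, 5, 0), 2, 2)
  cw <- build_density_weighted(f, regions)
  expect_equal(cw$matrix[1, 2], 5 / 200)  # F / mean(V_i, V_j)
  cb <- build_binary(f, regions)
  expect_equal(cb$matrix[1, 2], 1)
  # equal volumes reduce to F / V
  regions$volume_mm3 <- c(250, 250)
  expect_equal(build_density_weighted(f, regions)$matrix[1, 2], 5 / 250)
  # F = 0 -> W = 0; threshold at >= 1 streamline
  f0 <- matrix(0, 2, 2)
  expect_equal(sum(build_binary(f0, regions)$matrix), 0)
  f1 <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(build_binary(f1, regions)$matrix[1, 2], 1)
  # zero volume is rejected
  regions$volume_mm3 <- c(0, 250)
  expect_error(build_density_weighted(f, regions), "positive")
})

test_that("binary network equals the support of the weighted network", {
  p <- make_parcellation(c(10, 6, 6), 10, c(2, 2, 2), seed = 5)
  set.seed(6)
  f <- matrix(0L, 10, 10)
  ut <- upper.tri(f)
  f[ut] <- rpois(sum(ut), 0.8)
  f <- f + t(f)
  cb <- build_binary(f, p$regions)
  cw <- build_density_weighted(f, p$regions)
  expect_equal(cb$matrix, (cw$matrix > 0) * 1)
  expect_equal(binarize(cw)$matrix, cb$matrix)
})

test_that("connection counting is permutation-equivariant", {
  p <- tiny_parcellation()
  seg <- function(a, b) rbind(a, b)
  s <- streamline_set(list(seg(c(5, 5, 5), c(25, 5, 5)),
                           seg(c(15, 5, 5), c(35, 5, 5))))
  f <- count_connections(s, p)
  # relabel regions: swap ids 1 and 3 in both grid and table
  labels2 <- p$labels
  labels2[p$labels == 1L] <- 3L
  labels2[p$labels == 3L] <- 1L
  p2 <- parcellation(labels2, p$voxel_size_mm, make_regions(4))
  f2 <- count_connections(s, p2)
  perm <- c(3, 2, 1, 4)
  expect_equal(unname(f2), unname(f[perm, perm]), ignore_attr = TRUE)
})

test_that("hemisphere subnetworks partition the link count", {
  g <- rand_conn(12, 0.5, mode = "weighted", seed = 11)
  left <- hemisphere_subnetwork(g, "L")
  right <- hemisphere_subnetwork(g, "R")
  expect_equal(nrow(left$matrix), 6)
  expect_equal(left$regions$hemisphere, rep("L", 6))
  links <- function(m) sum(m[upper.tri(m)] > 0)
  il <- g$regions$hemisphere == "L"
  inter <- sum(g$matrix[il, !il] > 0)
  expect_equal(links(left$matrix) + links(right$matrix) + inter,
               links(g$matrix))
  expect_error(hemisphere_subnetwork(g, "X"), "side")
})

test_that("a 90-node connectome splits into two 45-node hemispheres", {
  p <- make_parcellation(c(20, 20, 20), 90, c(2, 2, 2), seed = 2)
  f <- matrix(0L, 90, 90)
  f[1, 2] <- f[2, 1] <- 1L
  cb <- build_binary(f, p$regions)
  expect_equal(n_nodes(cb), 90)
  expect_equal(n_nodes(hemisphere_subnetwork(cb, "L")), 45)
  expect_equal(n_nodes(hemisphere_subnetwork(cb, "R")), 45)
})

test_that("constructed matrices are symmetric, non-negative, zero-diagonal", {
  p <- make_parcellation(c(10, 6, 6), 10, c(2, 2, 2), seed = 9)
  set.seed(10)
  f <- matrix(0L, 10, 10)
  ut <- upper.tri(f)
  f[ut] <- rpois(sum(ut), 1)
  f <- f + t(f)
  s <- make_streamlines(p, f, 50, seed = 3)
  fc <- count_connections(filter_streamlines(s, 50), p)
  expect_equal(unname(fc), unname(t(fc)))
  expect_true(all(diag(fc) == 0))
  expect_true(all(fc >= 0))
})
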