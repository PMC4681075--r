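# Two-sample tests, Bonferroni, laterality, and the cohort comparison.

test_that("pooled t test matches the reference implementation", {
  set.seed(1)
  for (i in 1:10) {
    a <- rnorm(5 + i, mean = 0.2)
    b <- rnorm(8, sd = 1.4)
    res <- two_sample_t(a, b)
    ref <- t.test(a, b, var.equal = TRUE)
    expect_equal(res$t, unname(ref$statistic), tolerance = 1e-8)
    expect_equal(res$df, unname(ref$parameter))
    expect_equal(res$p, ref$p.value, tolerance = 1e-8)
  }
  # the worked example
  res <- two_sample_t(c(2.1, 2.5, 2.3, 2.7), c(1.1, 1.4, 1.2))
  ref <- t.test(c(2.1, 2.5, 2.3, 2.7), c(1.1, 1.4, 1.2), var.equal = TRUE)
  expect_equal(res$t, unname(ref$statistic), tolerance = 1e-8)
  expect_equal(res$p, ref$p.value, tolerance = 1e-8)
})

test_that("welch variant matches t.test(var.equal = FALSE)", {
  set.seed(2)
  a <- rnorm(10); b <- rnorm(14, sd = 3)
  res <- two_sample_t(a, b, var_equal = FALSE)
  ref <- t.test(a, b)
  expect_equal(res$t, unname(ref$statistic), tolerance = 1e-8)
  expect_equal(res$df, unname(ref$parameter), tolerance = 1e-8)
  expect_equal(res$p, ref$p.value, tolerance = 1e-8)
})

test_that("t test edge cases follow the documented conventions", {
  x <- c(1, 2, 3)
  res <- two_sample_t(x, x)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  # sign convention: first group below second -> negative t
  expect_lt(two_sample_t(x, x + 10)$t, 0)
  # zero variance, equal means -> t = 0, p = 1
  res <- two_sample_t(c(2, 2), c(2, 2, 2))
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  # zero variance, unequal means -> undefined-value signal
  expect_warning(res <- two_sample_t(c(1, 1), c(2, 2)), "zero variance")
  expect_true(is.na(res$t))
})

test_that("Bonferroni threshold over 90 nodes reproduces the printed value", {
  expect_equal(signif(bonferroni_threshold(0.05, 90), 2), 0.00056)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 5), 0.01)
  expect_error(bonferroni_threshold(1.2, 5), "alpha")
})

test_that("laterality index follows (L - R) / (L + R)", {
  expect_equal(laterality_index(1, 1), 0)
  expect_equal(laterality_index(2, 1), 1 / 3)
  expect_equal(laterality_index(0, 1), -1)
  expect_warning(li <- laterality_index(0, 0), "undefined")
  expect_true(is.na(li))
  set.seed(3)
  l <- runif(20); r <- runif(20)
  expect_true(all(abs(laterality_index(l, r)) <= 1))
})

small_cfg <- function(...) {
  compare_config(global_measures = c("size", "global_efficiency"),
                 nodal_measures = c("size", "betweenness"),
                 n_nulls = 2, rewires_per_link = 3, ...)
}

test_that("identical groups produce no significant differences", {
  co <- make_cohort(cohort_spec(n_group_a = 3, n_group_b = 3, n_nodes = 16,
                                seed = 2,
                                effect = null_effect_spec(edge_noise_cv = 0)))
  cmp <- suppressWarnings(compare_cohort(co, small_cfg()))
  expect_true(all(!cmp$global$significant))
  expect_true(all(!cmp$nodal$significant))
})

test_that("comparison output mirrors the global-table schema", {
  co <- make_cohort(cohort_spec(n_group_a = 4, n_group_b = 4, n_nodes = 16,
                                seed = 3))
  cmp <- compare_cohort(co, compare_config(modes = "binary", n_nulls = 2,
                                           rewires_per_link = 3,
                                           include_laterality = FALSE))
  expect_setequal(cmp$global$measure,
                  c("degree", "normalized_clustering",
                    "normalized_path_length", "global_efficiency"))
  expect_true(all(c("mean_a", "sd_a", "mean_b", "sd_b", "t", "df", "p",
                    "significant") %in% names(cmp$global)))
  expect_true(all(cmp$global$df == 6))
  expect_true(all(cmp$nodal$p_threshold == 0.05 / 16))
})

test_that("comparison is invariant to subject order within groups", {
  co <- make_cohort(cohort_spec(n_group_a = 4, n_group_b = 4, n_nodes = 14,
                                seed = 5))
  cmp1 <- compare_cohort(co, small_cfg(include_laterality = FALSE))
  co2 <- co
  perm <- c(3, 1, 4, 2, 6, 8, 5, 7)  # shuffles within each group
  co2$manifest <- co2$manifest[perm, ]
  cmp2 <- compare_cohort(co2, small_cfg(include_laterality = FALSE))
  expect_equal(cmp1$global, cmp2$global)
  expect_equal(cmp1$nodal, cmp2$nodal)
})

test_that("swapping group labels negates t and fixes p", {
  co <- make_cohort(cohort_spec(n_group_a = 4, n_group_b = 4, n_nodes = 14,
                                seed = 7))
  cmp1 <- compare_cohort(co, small_cfg(include_laterality = FALSE))
  co2 <- co
  co2$manifest <- co2$manifest[c(5:8, 1:4), ]  # control listed first
  cmp2 <- compare_cohort(co2, small_cfg(include_laterality = FALSE))
  expect_equal(cmp2$global$t, -cmp1$global$t)
  expect_equal(cmp2$global$p, cmp1$global$p)
  expect_equal(cmp2$nodal$t, -cmp1$nodal$t)
})

test_that("planted effects are recovered with the correct sign", {
  co <- make_cohort(cohort_spec(n_group_a = 10, n_group_b = 10, n_nodes = 30,
                                seed = 11))
  cmp <- compare_cohort(co, compare_config(
    modes = "weighted", global_measures = "size", nodal_measures = "size",
    include_hubs = FALSE, include_laterality = FALSE))
  g <- cmp$global[cmp$global$measure == "strength", ]
  expect_lt(g$mean_a, g$mean_b)
  weak <- cmp$nodal[cmp$nodal$region_id == 4, ]
  expect_lt(weak$t, 0)
  expect_true(weak$significant)
})

test_that("hub tables and laterality records have the documented shape", {
  co <- make_cohort(cohort_spec(n_group_a = 5, n_group_b = 5, n_nodes = 20,
                                seed = 13))
  cmp <- compare_cohort(co, small_cfg(include_laterality = TRUE))
  if (!is.null(cmp$hubs)) {
    expect_true(all(c("mode", "measure", "group", "region_id", "value",
                      "threshold") %in% names(cmp$hubs)))
    expect_true(all(cmp$hubs$value > cmp$hubs$threshold))
    expect_true(all(cmp$hubs$measure %in% c("betweenness", "strength")))
  }
  expect_false(is.null(cmp$laterality))
  expect_true(all(c("mode", "measure", "t", "df", "p") %in%
                    names(cmp$laterality)))
  # per-mode laterality covers the computed global measures
  expect_setequal(unique(cmp$laterality$measure),
                  c("degree", "strength", "global_efficiency"))
})

test_that("cohorts with mismatched region tables are rejected", {
  co <- make_cohort(cohort_spec(n_group_a = 2, n_group_b = 2, n_nodes = 10,
                                seed = 17))
  co$connectomes[[1]]$regions$name[1] <- "other"
  expect_error(compare_cohort(co, small_cfg()), "share one region table")
})
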