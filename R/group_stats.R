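#' Two-sample t test
#'
#' Pooled-variance (Student) two-sample t test with two-sided p value;
#' `t = (mean(a) - mean(b)) / se`, so t is negative when group a lies below
#' group b. A Welch variant is available. With zero pooled variance the
#' test returns `t = 0, p = 1` when the means are equal and `NA` (with a
#' warning) otherwise.
#'
#' @param a,b numeric vectors of length >= 2 with finite values.
#' @param var_equal pooled variance (TRUE, default) or Welch (FALSE).
#' @return List with `t`, `df`, `p`.
#' @export
two_sample_t <- function(a, b, var_equal = TRUE) {
  .assert(is.numeric(a) && is.numeric(b), "a and b must be numeric")
  .assert(length(a) >= 2 && length(b) >= 2,
          "both groups need at least 2 observations")
  .assert(all(is.finite(a)) && all(is.finite(b)), "values must be finite")
  res <- .t_many(matrix(a, ncol = 1), matrix(b, ncol = 1), var_equal)
  list(t = res$t, df = res$df, p = res$p)
}

# Vectorized column-wise two-sample t tests; returns one row per column.
.t_many <- function(ma, mb, var_equal = TRUE) {
  na <- nrow(ma); nb <- nrow(mb)
  mean_a <- colMeans(ma); mean_b <- colMeans(mb)
  va <- apply(ma, 2, stats::var)
  vb <- apply(mb, 2, stats::var)
  dm <- mean_a - mean_b
  if (var_equal) {
    df <- rep(na + nb - 2, length(dm))
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    df[se == 0] <- na + nb - 2
  }
  t <- ifelse(se > 0, dm / se, ifelse(dm == 0, 0, NA_real_))
  if (anyNA(t))
    warning("zero variance with unequal means: t undefined for some tests")
  p <- ifelse(is.na(t), NA_real_,
              ifelse(se > 0, 2 * stats::pt(-abs(dm / ifelse(se > 0, se, 1)), df), 1))
  data.frame(mean_a = mean_a, sd_a = sqrt(va), mean_b = mean_b,
             sd_b = sqrt(vb), t = t, df = df, p = p, row.names = NULL)
}

#' Bonferroni-corrected significance threshold
#'
#' `alpha / m`; nodal significance is declared when `p < alpha / m`
#' (strict). With alpha 0.05 over 90 nodes the threshold is 0.00056 to two
#' significant figures.
#'
#' @param alpha family-wise error rate, in (0, 1).
#' @param m number of comparisons (>= 1).
#' @return The corrected per-test threshold.
#' @export
bonferroni_threshold <- function(alpha, m) {
  .assert(is.numeric(alpha) && length(alpha) == 1 && alpha > 0 && alpha < 1,
          "alpha must be in (0, 1)")
  .assert(is.numeric(m) && length(m) == 1 && m >= 1 && m == round(m),
          "m must be a positive integer")
  alpha / m
}

#' Laterality index
#'
#' `(left - right) / (left + right)`: positive values mean the left
#' hemisphere dominates. Undefined (NA, with a warning) when
#' `left + right = 0`.
#'
#' @param left,right hemispheric measure values.
#' @return The laterality index, in `[-1, 1]` for non-negative inputs.
#' @export
laterality_index <- function(left, right) {
  s <- left + right
  if (any(s == 0)) warning("left + right = 0: laterality index undefined")
  ifelse(s == 0, NA_real_, (left - right) / s)
}

#' Configuration for [compare_cohort()]
#'
#' @param alpha nominal significance level (global tests are uncorrected;
#'   nodal tests use `alpha / n_nodes`, Bonferroni over nodes).
#' @param modes which network modes to analyze.
#' @param global_measures subset of `"size"` (mean degree/strength),
#'   `"normalized"` (gamma and lambda), `"global_efficiency"`.
#' @param nodal_measures subset of `"size"`, `"clustering"`,
#'   `"local_efficiency"`, `"betweenness"`.
#' @param include_hubs compute group hub tables (binary: group-mean
#'   betweenness; weighted: group-mean strength).
#' @param include_laterality compute per-subject laterality indices of the
#'   global measures on hemispheric subnetworks and compare them.
#' @param n_nulls,rewires_per_link null-ensemble settings for the
#'   normalized measures.
#' @param seed base seed for all stochastic stages (null ensembles).
#' @param t_variant `"pooled"` (Student, default) or `"welch"`.
#' @return A config list.
#' @export
compare_config <- function(alpha = 0.05,
                           modes = c("binary", "weighted"),
                           global_measures = c("size", "normalized",
                                               "global_efficiency"),
                           nodal_measures = c("size", "clustering",
                                              "local_efficiency",
                                              "betweenness"),
                           include_hubs = TRUE,
                           include_laterality = TRUE,
                           n_nulls = 100, rewires_per_link = 10,
                           seed = 1, t_variant = c("pooled", "welch")) {
  t_variant <- match.arg(t_variant)
  modes <- match.arg(modes, several.ok = TRUE)
  global_measures <- match.arg(global_measures, several.ok = TRUE)
  nodal_measures <- match.arg(nodal_measures, several.ok = TRUE)
  list(alpha = alpha, modes = modes, global_measures = global_measures,
       nodal_measures = nodal_measures, include_hubs = include_hubs,
       include_laterality = include_laterality, n_nulls = n_nulls,
       rewires_per_link = rewires_per_link, seed = seed,
       t_variant = t_variant)
}

.size_name <- function(mode) if (mode == "binary") "degree" else "strength"

# Global measures of one network as a named vector.
.subject_global <- function(conn, config, seed) {
  out <- c()
  if ("size" %in% config$global_measures) {
    v <- if (conn$mode == "binary") mean(degree(conn)) else mean(strength(conn))
    out[.size_name(conn$mode)] <- v
  }
  if ("normalized" %in% config$global_measures) {
    nm <- normalized_metrics(conn, n_nulls = config$n_nulls,
                             rewires_per_link = config$rewires_per_link,
                             seed = seed)
    out["normalized_clustering"] <- nm$gamma
    out["normalized_path_length"] <- nm$lambda
  }
  if ("global_efficiency" %in% config$global_measures)
    out["global_efficiency"] <- global_efficiency(conn)
  out
}

.subject_nodal <- function(conn, config) {
  out <- list()
  if ("size" %in% config$nodal_measures)
    out[[.size_name(conn$mode)]] <-
      if (conn$mode == "binary") as.numeric(degree(conn)) else strength(conn)
  if ("clustering" %in% config$nodal_measures)
    out[["clustering"]] <- clustering(conn)
  if ("local_efficiency" %in% config$nodal_measures)
    out[["local_efficiency"]] <- local_efficiency(conn)
  if ("betweenness" %in% config$nodal_measures)
    out[["betweenness"]] <- betweenness(conn)
  out
}

#' Two-group comparison of a connectome cohort
#'
#' Runs the full group-level analysis for each requested mode:
#'
#' * global measures (mean degree/strength, normalized clustering gamma,
#'   normalized path length lambda, global efficiency) per subject,
#'   compared with two-sample t tests at `alpha` (uncorrected);
#' * nodal measures (degree/strength, clustering, local efficiency,
#'   betweenness) per subject and node, compared per node with Bonferroni
#'   correction over the number of nodes (`p < alpha / N`);
#' * hub tables per group from group-mean betweenness (binary) and
#'   group-mean strength (weighted), hubs being nodes above mean + 2 SD;
#' * laterality: the global measures on left and right hemispheric
#'   subnetworks give a per-subject laterality index
#'   `(left - right) / (left + right)` per measure, compared across groups.
#'
#' Group A is the first group label appearing in the cohort manifest;
#' positive t means A above B.
#'
#' @param cohort a cohort (see [make_cohort()] / [read_cohort()]): a
#'   manifest (`subject_id`, `group`) plus one weighted [connectome] per
#'   subject on a shared region table.
#' @param config a [compare_config()].
#' @return An object of class `cohort_comparison`: data.frames `global`,
#'   `nodal`, `hubs`, `laterality`, and a `provenance` list.
#' @export
compare_cohort <- function(cohort, config = compare_config()) {
  .assert(inherits(cohort, "cohort"), "cohort must be a cohort object")
  groups <- unique(cohort$manifest$group)
  .assert(length(groups) == 2, "cohort must contain exactly 2 groups")
  ids_a <- cohort$manifest$subject_id[cohort$manifest$group == groups[1]]
  ids_b <- cohort$manifest$subject_id[cohort$manifest$group == groups[2]]
  .assert(length(ids_a) >= 2 && length(ids_b) >= 2,
          "each group needs at least 2 subjects")
  ref_regions <- cohort$connectomes[[1]]$regions
  for (cn in cohort$connectomes)
    .assert(identical(cn$regions[c("id", "name", "hemisphere")],
                      ref_regions[c("id", "name", "hemisphere")]),
            "all connectomes must share one region table")
  n_reg <- nrow(ref_regions)
  all_ids <- c(ids_a, ids_b)
  grp <- rep(c("A", "B"), c(length(ids_a), length(ids_b)))
  # per-subject seed keys from sorted ids: stable under subject reordering
  # and group-label swaps
  skey <- match(all_ids, sort(cohort$manifest$subject_id))

  has_both_hemi <- all(c("L", "R") %in% ref_regions$hemisphere)
  do_lat <- config$include_laterality && has_both_hemi

  global_rows <- list(); nodal_rows <- list(); hub_rows <- list()
  lat_rows <- list()
  for (mode in config$modes) {
    conns <- lapply(all_ids, function(id) {
      cw <- cohort$connectomes[[id]]
      .assert(!is.null(cw), "subject '%s' missing from cohort connectomes", id)
      if (mode == "binary" && cw$mode != "binary") binarize(cw)
      else if (mode == "weighted") {
        .assert(cw$mode == "weighted",
                "weighted analysis requested but connectomes are binary")
        cw
      } else cw
    })
    mode_k <- match(mode, c("binary", "weighted"))

    # --- global level -------------------------------------------------
    gvals <- lapply(seq_along(conns), function(i) {
      .subject_global(conns[[i]], config,
                      seed = .child_seed(config$seed, 1000L * mode_k + skey[i]))
    })
    gmat <- do.call(rbind, gvals)
    if (!is.null(gmat) && ncol(gmat) > 0) {
      tt <- .t_many(gmat[grp == "A", , drop = FALSE],
                    gmat[grp == "B", , drop = FALSE],
                    config$t_variant == "pooled")
      global_rows[[mode]] <- cbind(
        data.frame(mode = mode, measure = colnames(gmat)), tt,
        data.frame(significant = !is.na(tt$p) & tt$p < config$alpha))
    }

    # --- nodal level --------------------------------------------------
    nvals <- lapply(conns, .subject_nodal, config = config)
    p_thr <- bonferroni_threshold(config$alpha, n_reg)
    for (meas in names(nvals[[1]])) {
      nmat <- do.call(rbind, lapply(nvals, function(x) as.numeric(x[[meas]])))
      tt <- .t_many(nmat[grp == "A", , drop = FALSE],
                    nmat[grp == "B", , drop = FALSE],
                    config$t_variant == "pooled")
      nodal_rows[[paste(mode, meas)]] <- cbind(
        data.frame(mode = mode, measure = meas,
                   region_id = ref_regions$id, region_name = ref_regions$name),
        tt,
        data.frame(p_threshold = p_thr,
                   significant = !is.na(tt$p) & tt$p < p_thr))
      if (config$include_hubs) {
        hub_meas <- if (mode == "binary") "betweenness" else "strength"
        if (meas == hub_meas) {
          for (g in c("A", "B")) {
            gm <- colMeans(nmat[grp == g, , drop = FALSE])
            names(gm) <- ref_regions$id
            hubs <- identify_hubs(gm)
            if (length(hubs) > 0) {
              hi <- match(as.numeric(hubs), ref_regions$id)
              hub_rows[[paste(mode, g)]] <- data.frame(
                mode = mode, measure = hub_meas,
                group = ifelse(g == "A", groups[1], groups[2]),
                region_id = ref_regions$id[hi],
                region_name = ref_regions$name[hi],
                value = gm[hi], threshold = attr(hubs, "threshold"),
                row.names = NULL)
            }
          }
        }
      }
    }

    # --- laterality ---------------------------------------------------
    if (do_lat) {
      lvals <- lapply(seq_along(conns), function(i) {
        li <- .subject_global(hemisphere_subnetwork(conns[[i]], "L"), config,
                              seed = .child_seed(config$seed,
                                                 100000L + 1000L * mode_k + skey[i]))
        ri <- .subject_global(hemisphere_subnetwork(conns[[i]], "R"), config,
                              seed = .child_seed(config$seed,
                                                 200000L + 1000L * mode_k + skey[i]))
        laterality_index(li, ri)
      })
      lmat <- do.call(rbind, lvals)
      if (!is.null(lmat) && ncol(lmat) > 0) {
        tt <- .t_many(lmat[grp == "A", , drop = FALSE],
                      lmat[grp == "B", , drop = FALSE],
                      config$t_variant == "pooled")
        lat_rows[[mode]] <- cbind(
          data.frame(mode = mode, measure = colnames(lmat)), tt,
          data.frame(significant = !is.na(tt$p) & tt$p < config$alpha))
      }
    }
  }

  bind <- function(rows) {
    if (length(rows) == 0) return(NULL)
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  }
  res <- list(
    global = bind(global_rows),
    nodal = bind(nodal_rows),
    hubs = bind(hub_rows),
    laterality = bind(lat_rows),
    provenance = list(
      groups = as.character(groups),
      n_a = length(ids_a), n_b = length(ids_b), n_nodes = n_reg,
      config = config,
      version = as.character(utils::packageVersion("tractnet"))
    )
  )
  class(res) <- "cohort_comparison"
  res
}

#' @export
print.cohort_comparison <- function(x, ...) {
  pv <- x$provenance
  cat(sprintf("cohort comparison: %s (n=%d) vs %s (n=%d), %d nodes\n",
              pv$groups[1], pv$n_a, pv$groups[2], pv$n_b, pv$n_nodes))
  if (!is.null(x$global)) {
    cat("global tests (uncorrected):\n")
    print(x$global[, c("mode", "measure", "mean_a", "mean_b", "p",
                       "significant")], digits = 3)
  }
  if (!is.null(x$nodal)) {
    sig <- x$nodal[x$nodal$significant, , drop = FALSE]
    cat(sprintf("nodal tests: %d of %d significant after Bonferroni (p < %.2g)\n",
                nrow(sig), nrow(x$nodal), x$nodal$p_threshold[1]))
    if (nrow(sig) > 0)
      print(sig[, c("mode", "measure", "region_name", "mean_a", "mean_b", "p")],
            digits = 3)
  }
  invisible(x)
}
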