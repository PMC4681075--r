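#' @name synthetic_data
#' @title Synthetic parcellations, streamline sets and cohorts
#'
#' @description
#' Generators that emulate the statistical structure the pipeline assumes —
#' a 90-region cerebrum parcellation with left/right hemisphere labels,
#' streamline sets whose endpoint pairs induce a prescribed connectivity
#' matrix, and two-group cohorts of weighted connectomes with planted
#' effects (global weight attenuation, one node with boosted betweenness
#' via path rerouting, one node with attenuated strength) — so every
#' downstream stage is testable with known ground truth. Nothing about the
#' diffusion signal or real anatomy is simulated.
NULL

#' Planted-effect specification for synthetic cohorts
#'
#' @param global_weight_factor multiplicative factor applied to all
#'   patient-group edge weights (> 0; 1 = no effect). Default 0.9, a 10 %
#'   global attenuation.
#' @param target_hub_node node id whose patient-group betweenness is
#'   boosted by rerouting paths through it.
#' @param target_weak_node node id whose patient-group incident weights are
#'   attenuated.
#' @param weak_node_factor multiplicative attenuation of the weak node's
#'   incident weights (0-1; default 0.8).
#' @param edge_noise_cv coefficient of variation of the per-subject
#'   lognormal edge-weight noise (default 0.4).
#' @param density expected fraction of possible links present (0-1;
#'   default 0.22, matching mean binary degrees near 20 of 89 possible).
#' @param hub_reroute_fraction fraction of a patient subject's edges
#'   rerouted through the target hub node (default 0.1).
#' @return An `effect_spec` list.
#' @export
effect_spec <- function(global_weight_factor = 0.9,
                        target_hub_node = 2,
                        target_weak_node = 4,
                        weak_node_factor = 0.8,
                        edge_noise_cv = 0.4,
                        density = 0.22,
                        hub_reroute_fraction = 0.1) {
  .assert(global_weight_factor > 0, "global_weight_factor must be > 0")
  .assert(weak_node_factor > 0, "weak_node_factor must be > 0")
  .assert(edge_noise_cv >= 0, "edge_noise_cv must be >= 0")
  .assert(density > 0 && density <= 1, "density must be in (0, 1]")
  .assert(hub_reroute_fraction >= 0 && hub_reroute_fraction < 1,
          "hub_reroute_fraction must be in [0, 1)")
  structure(list(global_weight_factor = global_weight_factor,
                 target_hub_node = target_hub_node,
                 target_weak_node = target_weak_node,
                 weak_node_factor = weak_node_factor,
                 edge_noise_cv = edge_noise_cv,
                 density = density,
                 hub_reroute_fraction = hub_reroute_fraction),
            class = "effect_spec")
}

#' Null (no-effect) variant of [effect_spec()]
#' @param ... overrides passed to [effect_spec()].
#' @return An `effect_spec` with all factors 1 and no rerouting.
#' @export
null_effect_spec <- function(...) {
  effect_spec(global_weight_factor = 1, weak_node_factor = 1,
              hub_reroute_fraction = 0, ...)
}

#' Cohort specification for [make_cohort()]
#'
#' Defaults mirror the study design: 14 patient-like and 19 control-like
#' subjects on 90-node networks.
#'
#' @param n_group_a,n_group_b subject counts (>= 2 each).
#' @param n_nodes node count (>= 4).
#' @param seed base RNG seed; all generator randomness derives from it.
#' @param effect an [effect_spec()].
#' @param mean_strength target mean node strength of the control-like group
#'   (default 7.3e-5, the order of density-weighted strengths).
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_group_a = 14, n_group_b = 19, n_nodes = 90,
                        seed = 42, effect = effect_spec(),
                        mean_strength = 7.3e-5) {
  .assert(n_group_a >= 2 && n_group_b >= 2,
          "both groups need at least 2 subjects")
  .assert(n_nodes >= 4, "n_nodes must be >= 4")
  .assert(inherits(effect, "effect_spec"), "effect must be an effect_spec")
  .assert(effect$target_hub_node %in% seq_len(n_nodes) &&
            effect$target_weak_node %in% seq_len(n_nodes),
          "effect target nodes must be valid node ids (1..n_nodes)")
  .assert(mean_strength > 0, "mean_strength must be > 0")
  structure(list(n_group_a = n_group_a, n_group_b = n_group_b,
                 n_nodes = n_nodes, seed = seed, effect = effect,
                 mean_strength = mean_strength),
            class = "cohort_spec")
}

# AAL-style region table: odd ids left, even ids right.
.synthetic_regions <- function(n_nodes) {
  id <- seq_len(n_nodes)
  data.frame(id = id,
             name = sprintf("region_%03d", id),
             hemisphere = ifelse(id %% 2 == 1, "L", "R"),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic parcellation
#'
#' Partitions a voxel grid into `n_regions` regions (no background): the
#' grid is split into left and right halves along x, half the regions are
#' seeded in each half at random voxels, and every voxel joins the nearest
#' seed of its own half (Voronoi growth), so each region is spatially
#' coherent and every region receives at least one voxel. Odd region ids
#' are left-hemisphere, even ids right.
#'
#' @param grid_shape integer(3), voxel grid dimensions.
#' @param n_regions even region count (default 90).
#' @param voxel_size_mm numeric(3) voxel edge lengths in mm.
#' @param seed RNG seed.
#' @return A [parcellation].
#' @export
make_parcellation <- function(grid_shape = c(20, 20, 20), n_regions = 90,
                              voxel_size_mm = c(2, 2, 2), seed = 1) {
  .assert(length(grid_shape) == 3 && all(grid_shape >= 1) &&
            all(grid_shape == round(grid_shape)),
          "grid_shape must be 3 positive integers")
  .assert(n_regions >= 2 && n_regions %% 2 == 0,
          "n_regions must be even (half per hemisphere)")
  half <- n_regions / 2L
  nx <- grid_shape[1]
  .assert(nx >= 2, "grid must have at least 2 voxels along x for two hemispheres")
  x_split <- floor(nx / 2)
  cap_l <- x_split * grid_shape[2] * grid_shape[3]
  cap_r <- (nx - x_split) * grid_shape[2] * grid_shape[3]
  .assert(cap_l >= half && cap_r >= half,
          "grid too small: each hemisphere half needs >= %d voxels (have %d L, %d R)",
          half, cap_l, cap_r)
  labels <- array(0L, dim = grid_shape)
  coords <- as.matrix(expand.grid(i = seq_len(grid_shape[1]),
                                  j = seq_len(grid_shape[2]),
                                  k = seq_len(grid_shape[3])))
  mm <- sweep(coords - 0.5, 2, voxel_size_mm, "*")
  side <- ifelse(coords[, 1] <= x_split, "L", "R")
  regions <- .synthetic_regions(n_regions)
  with_seed(seed, {
    for (s in c("L", "R")) {
      vox <- which(side == s)
      ids <- regions$id[regions$hemisphere == s]
      seeds <- sample(vox, half)
      d2 <- matrix(0, length(vox), half)
      for (r in seq_len(half)) {
        d2[, r] <- rowSums(sweep(mm[vox, , drop = FALSE], 2,
                                 mm[seeds[r], ], "-")^2)
      }
      lab <- ids[max.col(-d2, ties.method = "first")]
      labels[coords[vox, , drop = FALSE]] <- lab
    }
  })
  parcellation(labels, voxel_size_mm, regions)
}

#' Generate streamlines that induce a target connectivity matrix
#'
#' For every region pair (i, j) with `target_counts[i, j] = F`, generates
#' exactly F streamlines whose endpoints sit at the centres of voxels
#' labelled i and j; when the straight endpoint-to-endpoint distance falls
#' below `min_length_mm`, a perpendicular midpoint detour lengthens the
#' polyline past the threshold (interior points may leave the grid).
#' Counting connections of the result therefore reproduces `target_counts`
#' exactly, even after length filtering.
#'
#' @param parcellation a [parcellation].
#' @param target_counts symmetric integer matrix, zero diagonal, in region
#'   table order.
#' @param min_length_mm minimum streamline length to guarantee (default 50).
#' @param seed RNG seed (endpoint voxel choice).
#' @return A [streamline_set].
#' @export
make_streamlines <- function(parcellation, target_counts, min_length_mm = 50,
                             seed = 1) {
  .assert(inherits(parcellation, "parcellation"),
          "parcellation must be a parcellation")
  f <- as.matrix(target_counts)
  .check_symmetric(f, "target_counts")
  .assert(all(f >= 0) && all(f == round(f)),
          "target_counts must be non-negative integers")
  ids <- parcellation$regions$id
  .assert(nrow(f) == length(ids), "target_counts dimension mismatch")
  dims <- dim(parcellation$labels)
  vox_by_region <- lapply(ids, function(id) {
    which(parcellation$labels == id, arr.ind = TRUE)
  })
  vs <- parcellation$voxel_size_mm
  needed <- which(rowSums(f) > 0)
  for (i in needed)
    .assert(nrow(vox_by_region[[i]]) > 0,
            "region %s has no voxels; cannot place streamline endpoints", ids[i])
  lines <- list()
  with_seed(seed, {
    for (i in seq_along(ids)) {
      for (j in seq_along(ids)) {
        if (j <= i || f[i, j] == 0) next
        vi <- vox_by_region[[i]]
        vj <- vox_by_region[[j]]
        for (k in seq_len(f[i, j])) {
          a_idx <- vi[sample.int(nrow(vi), 1), ]
          b_idx <- vj[sample.int(nrow(vj), 1), ]
          a <- (a_idx - 0.5) * vs
          b <- (b_idx - 0.5) * vs
          d <- sqrt(sum((b - a)^2))
          if (d >= min_length_mm) {
            lines[[length(lines) + 1L]] <- rbind(a, b)
          } else {
            target <- max(min_length_mm * 1.05, d * 1.01)
            h <- sqrt((target / 2)^2 - (d / 2)^2)
            u <- (b - a) / d
            ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
            v <- c(u[2] * ref[3] - u[3] * ref[2],
                   u[3] * ref[1] - u[1] * ref[3],
                   u[1] * ref[2] - u[2] * ref[1])
            v <- v / sqrt(sum(v^2))
            mid <- (a + b) / 2 + h * v
            lines[[length(lines) + 1L]] <- rbind(a, mid, b)
          }
        }
      }
    }
  })
  streamline_set(lines, provenance = list(
    generator = "make_streamlines", seed = seed,
    min_length_mm = min_length_mm))
}

#' Generate a two-group cohort of weighted connectomes
#'
#' The control-like base topology is a distance-dependent random geometric
#' graph: node centroids are placed uniformly in a unit cube, pair scores
#' decay exponentially with centroid distance (scale 0.3) times a lognormal
#' heterogeneity term, and each subject keeps the top `density` fraction of
#' pairs by noisy score, giving spatially biased networks with degree
#' heterogeneity. Edge weights are the scores scaled so control-group mean
#' node strength sits near `mean_strength`, multiplied per subject by
#' lognormal noise with coefficient of variation `edge_noise_cv`.
#'
#' Patient-group (group A) subjects additionally receive, per the effect
#' spec: a global multiplicative weight attenuation; attenuation of the
#' weak node's incident weights (applied before the density threshold, so
#' its degree may drop too); and hub boosting, where a fraction of edges
#' not incident to the target node are rerouted through it (edge a-b
#' becomes a-h plus h-b, each carrying half the weight, so the subject's
#' total weight is unchanged), raising its betweenness.
#'
#' @param spec a [cohort_spec()].
#' @return An object of class `cohort`: `manifest` (subject_id, group),
#'   `connectomes` (named list of weighted [connectome]s), `regions`, the
#'   `spec`, and provenance with every subject's derived seed.
#' @export
make_cohort <- function(spec = cohort_spec()) {
  .assert(inherits(spec, "cohort_spec"), "spec must be a cohort_spec")
  n <- spec$n_nodes
  eff <- spec$effect
  regions <- .synthetic_regions(n)
  n_pairs <- n * (n - 1) / 2
  n_edges <- max(1L, round(eff$density * n_pairs))
  ut <- upper.tri(matrix(0, n, n))

  base <- with_seed(spec$seed, {
    centroids <- matrix(stats::runif(n * 3), n, 3)
    d <- as.matrix(stats::dist(centroids))
    z <- matrix(0, n, n)
    z[ut] <- stats::rnorm(n_pairs)
    z <- z + t(z)
    score <- exp(-d / 0.3) * exp(0.5 * z)
    diag(score) <- 0
    list(score = score)
  })
  # scale so that, over the base top-density edges, mean node strength
  # matches the control target
  sel <- order(base$score[ut], decreasing = TRUE)[seq_len(n_edges)]
  wbar_target <- spec$mean_strength * n / (2 * n_edges)
  w_full <- base$score * (wbar_target / mean(base$score[ut][sel]))

  sdlog <- sqrt(log(1 + eff$edge_noise_cv^2))
  subj_ids <- c(sprintf("patient_%02d", seq_len(spec$n_group_a)),
                sprintf("control_%02d", seq_len(spec$n_group_b)))
  groups <- rep(c("patient", "control"),
                c(spec$n_group_a, spec$n_group_b))
  seeds <- vapply(seq_along(subj_ids),
                  function(i) .child_seed(spec$seed, 10000L + i), integer(1))

  connectomes <- vector("list", length(subj_ids))
  names(connectomes) <- subj_ids
  for (i in seq_along(subj_ids)) {
    is_patient <- groups[i] == "patient"
    w <- with_seed(seeds[i], {
      wi <- w_full
      if (sdlog > 0) {
        noise <- matrix(1, n, n)
        noise[ut] <- stats::rlnorm(n_pairs, meanlog = -sdlog^2 / 2,
                                   sdlog = sdlog)
        noise[t(ut)] <- t(noise)[t(ut)]
        wi <- w_full * noise
      }
      if (is_patient) {
        wi <- wi * eff$global_weight_factor
        tw <- eff$target_weak_node
        wi[tw, ] <- wi[tw, ] * eff$weak_node_factor
        wi[, tw] <- wi[, tw] * eff$weak_node_factor
        wi[tw, tw] <- 0
      }
      # density threshold: keep the top n_edges pairs by weight
      vals <- wi[ut]
      keep <- order(vals, decreasing = TRUE)[seq_len(n_edges)]
      m <- matrix(0, n, n)
      idx <- which(ut)
      m[idx[keep]] <- vals[keep]
      m <- m + t(m)
      if (is_patient && eff$hub_reroute_fraction > 0) {
        h <- eff$target_hub_node
        el <- which(upper.tri(m) & m > 0, arr.ind = TRUE)
        off_h <- which(el[, 1] != h & el[, 2] != h)
        n_re <- floor(eff$hub_reroute_fraction * length(off_h))
        if (n_re > 0) {
          pick <- sample(off_h, n_re)
          for (e in pick) {
            a <- el[e, 1]; b <- el[e, 2]
            wab <- m[a, b]
            m[a, b] <- m[b, a] <- 0
            m[a, h] <- m[h, a] <- m[a, h] + wab / 2
            m[h, b] <- m[b, h] <- m[h, b] + wab / 2
          }
        }
      }
      m
    })
    connectomes[[i]] <- connectome(
      w, regions, mode = "weighted",
      provenance = list(subject_id = subj_ids[i], group = groups[i],
                        seed = seeds[i]))
  }
  structure(list(
    manifest = data.frame(subject_id = subj_ids, group = groups,
                          stringsAsFactors = FALSE),
    connectomes = connectomes,
    regions = regions,
    spec = spec,
    provenance = list(base_seed = spec$seed, subject_seeds = seeds,
                      n_edges = n_edges,
                      generator = "make_cohort",
                      version = as.character(utils::packageVersion("tractnet")))
  ), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  tab <- table(x$manifest$group)
  cat(sprintf("cohort: %d subjects (%s), %d nodes\n",
              nrow(x$manifest),
              paste(sprintf("%s n=%d", names(tab), tab), collapse = ", "),
              nrow(x$regions)))
  invisible(x)
}

#' Write a cohort to a directory
#'
#' One connectome CSV (plus sidecars) per subject, a `manifest.tsv`
#' (subject_id, group, file) and a `cohort.json` provenance file.
#'
#' @param cohort a cohort.
#' @param dir output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_cohort <- function(cohort, dir) {
  .assert(inherits(cohort, "cohort"), "cohort must be a cohort")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("%s.csv", cohort$manifest$subject_id)
  for (i in seq_len(nrow(cohort$manifest))) {
    write_connectome(cohort$connectomes[[cohort$manifest$subject_id[i]]],
                     file.path(dir, files[i]))
  }
  man <- cbind(cohort$manifest, file = files)
  .write_atomic(file.path(dir, "manifest.tsv"), function(tmp) {
    utils::write.table(man, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  })
  .write_atomic(file.path(dir, "cohort.json"), function(tmp) {
    jsonlite::write_json(cohort$provenance, tmp, auto_unbox = TRUE,
                         digits = NA, null = "null")
  })
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir the cohort directory.
#' @return A cohort object.
#' @export
read_cohort <- function(dir) {
  man_path <- file.path(dir, "manifest.tsv")
  .assert(file.exists(man_path), "no manifest.tsv in '%s'", dir)
  man <- utils::read.delim(man_path, stringsAsFactors = FALSE)
  .assert(all(c("subject_id", "group", "file") %in% names(man)),
          "manifest must have subject_id, group, file columns")
  connectomes <- lapply(seq_len(nrow(man)), function(i) {
    read_connectome(file.path(dir, man$file[i]))
  })
  names(connectomes) <- man$subject_id
  prov_path <- file.path(dir, "cohort.json")
  prov <- if (file.exists(prov_path))
    jsonlite::read_json(prov_path, simplifyVector = TRUE) else list()
  structure(list(
    manifest = man[, c("subject_id", "group")],
    connectomes = connectomes,
    regions = connectomes[[1]]$regions,
    spec = NULL,
    provenance = prov
  ), class = "cohort")
}
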