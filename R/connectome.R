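#' Connectome objects
#'
#' A connectome is one subject's brain network: a region table (the nodes)
#' and a symmetric, non-negative adjacency matrix with zero diagonal. Mode
#' `"binary"` restricts entries to {0, 1}; mode `"weighted"` carries
#' density-weights (fiber count divided by the mean volume of the two
#' regions) or any other non-negative weights. The fiber-count matrix the
#' network was built from may be attached.
#'
#' @param matrix symmetric non-negative numeric matrix, zero diagonal.
#' @param regions region table (`id`, `name`, `hemisphere`, optionally
#'   `volume_mm3`), one row per matrix row, in matrix order.
#' @param mode `"binary"` or `"weighted"`.
#' @param fiber_counts optional symmetric integer matrix of streamline counts.
#' @param provenance named list of metadata.
#' @return An object of class `connectome`.
#' @export
connectome <- function(matrix, regions, mode = c("weighted", "binary"),
                       fiber_counts = NULL, provenance = list()) {
  mode <- match.arg(mode)
  m <- as.matrix(matrix)
  storage.mode(m) <- "double"
  .check_symmetric(m, "connectome matrix")
  .assert(all(m >= 0), "connectome matrix must be non-negative")
  .assert(is.data.frame(regions) &&
            all(c("id", "name", "hemisphere") %in% names(regions)),
          "regions must have columns id, name, hemisphere")
  .assert(nrow(regions) == nrow(m),
          "region table (%d rows) does not match matrix (%d rows)",
          nrow(regions), nrow(m))
  .assert(!anyDuplicated(regions$id), "duplicate region ids")
  if (mode == "binary")
    .assert(all(m %in% c(0, 1)), "binary connectome entries must be 0 or 1")
  if (!is.null(fiber_counts)) {
    fiber_counts <- as.matrix(fiber_counts)
    .check_symmetric(fiber_counts, "fiber_counts")
    .assert(all(fiber_counts >= 0) && all(fiber_counts == round(fiber_counts)),
            "fiber_counts must be non-negative integers")
    .assert(nrow(fiber_counts) == nrow(m), "fiber_counts dimension mismatch")
  }
  dimnames(m) <- list(regions$id, regions$id)
  structure(
    list(matrix = m, regions = regions, mode = mode,
         fiber_counts = fiber_counts, provenance = provenance),
    class = "connectome"
  )
}

#' @export
print.connectome <- function(x, ...) {
  n <- nrow(x$matrix)
  e <- sum(x$matrix[upper.tri(x$matrix)] > 0)
  cat(sprintf("connectome (%s): %d nodes, %d links, density %.3f\n",
              x$mode, n, e, if (n > 1) e / (n * (n - 1) / 2) else 0))
  invisible(x)
}

#' Number of nodes of a connectome
#' @param c a [connectome].
#' @return Integer node count.
#' @export
n_nodes <- function(c) {
  .assert(inherits(c, "connectome"), "c must be a connectome")
  nrow(c$matrix)
}

#' Build the binary (unweighted) network from fiber counts
#'
#' A link is present between two nodes if there is at least one streamline
#' between them.
#'
#' @param f symmetric integer fiber-count matrix (zero diagonal), in region
#'   table order.
#' @param regions region table.
#' @return A binary [connectome] with `f` attached as fiber counts.
#' @export
build_binary <- function(f, regions) {
  f <- as.matrix(f)
  .check_symmetric(f, "fiber-count matrix")
  .assert(all(f >= 0) && all(f == round(f)),
          "fiber counts must be non-negative integers")
  connectome((f >= 1) * 1, regions, mode = "binary", fiber_counts = f)
}

#' Build the density-weighted network from fiber counts
#'
#' Link weight between regions i and j is the streamline count divided by
#' the mean volume of the two regions:
#' `W[i, j] = F[i, j] / ((V_i + V_j) / 2)`.
#'
#' @inheritParams build_binary
#' @return A weighted [connectome].
#' @export
build_density_weighted <- function(f, regions) {
  f <- as.matrix(f)
  .check_symmetric(f, "fiber-count matrix")
  .assert(all(f >= 0) && all(f == round(f)),
          "fiber counts must be non-negative integers")
  .assert("volume_mm3" %in% names(regions),
          "region table has no volume_mm3 column")
  v <- regions$volume_mm3
  .assert(all(is.finite(v)) && all(v > 0),
          "all region volumes must be positive to form density weights")
  mean_vol <- outer(v, v, "+") / 2
  w <- f / mean_vol
  diag(w) <- 0
  connectome(w, regions, mode = "weighted", fiber_counts = f)
}

#' Binary support of a connectome
#'
#' Returns the binary network with a link wherever the input has a positive
#' entry. On binary input this is the identity.
#'
#' @param c a [connectome].
#' @return A binary [connectome] on the same nodes.
#' @export
binarize <- function(c) {
  .assert(inherits(c, "connectome"), "c must be a connectome")
  connectome((c$matrix > 0) * 1, c$regions, mode = "binary",
             fiber_counts = c$fiber_counts, provenance = c$provenance)
}

#' Hemispheric subnetwork
#'
#' Induced subnetwork on the nodes of one hemisphere; inter-hemispheric
#' links are dropped and the region table restricted accordingly.
#'
#' @param c a [connectome].
#' @param side `"L"` or `"R"`.
#' @return A [connectome] on the selected hemisphere's nodes.
#' @export
hemisphere_subnetwork <- function(c, side) {
  .assert(inherits(c, "connectome"), "c must be a connectome")
  .assert(is.character(side) && length(side) == 1L && side %in% c("L", "R"),
          "side must be 'L' or 'R'")
  idx <- which(c$regions$hemisphere == side)
  .assert(length(idx) > 0, "no regions in hemisphere '%s'", side)
  fc <- if (!is.null(c$fiber_counts)) c$fiber_counts[idx, idx, drop = FALSE]
  connectome(c$matrix[idx, idx, drop = FALSE],
             c$regions[idx, , drop = FALSE],
             mode = c$mode, fiber_counts = fc, provenance = c$provenance)
}

#' Write a connectome to CSV (plus metadata sidecar)
#'
#' Writes the adjacency matrix as CSV with a region-id header row and column,
#' in full double precision (scientific notation) so the round trip is
#' lossless; mode and the region table go to a `.meta.json` sidecar and fiber
#' counts, when present, to a `_fibers.csv` companion. All writes are atomic.
#'
#' @param c a [connectome].
#' @param path output CSV path for the adjacency matrix.
#' @return Invisibly, the paths written.
#' @export
write_connectome <- function(c, path) {
  .assert(inherits(c, "connectome"), "c must be a connectome")
  stem <- tools::file_path_sans_ext(path)
  write_matrix <- function(m, file, fmt) {
    ids <- rownames(m)
    lines <- c(paste(c("region_id", ids), collapse = ","),
               vapply(seq_len(nrow(m)), function(i) {
                 paste(c(ids[i], fmt(m[i, ])), collapse = ",")
               }, character(1)))
    .write_atomic(file, function(tmp) writeLines(lines, tmp))
  }
  write_matrix(c$matrix, path, .fmt_num)
  paths <- path
  if (!is.null(c$fiber_counts)) {
    fc <- c$fiber_counts
    dimnames(fc) <- dimnames(c$matrix)
    fp <- paste0(stem, "_fibers.csv")
    write_matrix(fc, fp, function(x) sprintf("%d", as.integer(x)))
    paths <- c(paths, fp)
  }
  meta <- list(mode = c$mode, regions = c$regions, provenance = c$provenance,
               has_fiber_counts = !is.null(c$fiber_counts))
  mp <- paste0(stem, ".meta.json")
  .write_atomic(mp, function(tmp) {
    jsonlite::write_json(meta, tmp, auto_unbox = TRUE, digits = NA, null = "null")
  })
  invisible(c(paths, mp))
}

.read_matrix_csv <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  ids <- raw[[1]]
  m <- as.matrix(raw[, -1, drop = FALSE])
  m <- matrix(as.numeric(m), nrow(m), ncol(m))
  .assert(!anyNA(m), "non-numeric entries in matrix file '%s'", path)
  dimnames(m) <- list(ids, colnames(raw)[-1])
  .assert(identical(rownames(m), colnames(m)),
          "row and column region ids disagree in '%s'", path)
  m
}

#' Read a connectome written by [write_connectome()]
#'
#' @param path the adjacency CSV path.
#' @return A [connectome]. Asymmetric or negative matrices are rejected.
#' @export
read_connectome <- function(path) {
  .assert(file.exists(path), "no such file: %s", path)
  stem <- tools::file_path_sans_ext(path)
  m <- .read_matrix_csv(path)
  .assert(all(m >= 0), "negative entry in connectome matrix '%s'", path)
  .check_symmetric(m, sprintf("matrix in '%s'", path))
  mp <- paste0(stem, ".meta.json")
  .assert(file.exists(mp), "missing metadata sidecar: %s", mp)
  meta <- jsonlite::read_json(mp, simplifyVector = TRUE)
  regions <- as.data.frame(meta$regions)
  fc <- NULL
  if (isTRUE(meta$has_fiber_counts)) {
    fc <- .read_matrix_csv(paste0(stem, "_fibers.csv"))
  }
  prov <- if (is.null(meta$provenance)) list() else as.list(meta$provenance)
  connectome(m, regions, mode = meta$mode, fiber_counts = fc,
             provenance = prov)
}
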