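#' Streamline sets
#'
#' A streamline set is a list of polylines (n x 3 matrices of world-space
#' coordinates in mm, one row per point, at least two points each) plus
#' free-form provenance metadata (source file, tracking parameters, discard
#' counts from filtering).
#'
#' @param streamlines list of numeric matrices with 3 columns.
#' @param provenance named list of metadata.
#' @return An object of class `streamline_set`.
#' @export
streamline_set <- function(streamlines, provenance = list()) {
  .assert(is.list(streamlines), "streamlines must be a list of matrices")
  streamlines <- lapply(streamlines, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    .assert(ncol(m) == 3L, "each streamline must have 3 coordinate columns")
    .assert(nrow(m) >= 2L, "each streamline must have at least 2 points")
    .assert(all(is.finite(m)), "streamline coordinates must be finite")
    dimnames(m) <- NULL
    m
  })
  structure(list(streamlines = streamlines, provenance = provenance),
            class = "streamline_set")
}

#' @export
print.streamline_set <- function(x, ...) {
  n <- length(x$streamlines)
  cat(sprintf("streamline_set: %d streamlines\n", n))
  if (n > 0) {
    len <- vapply(x$streamlines, streamline_length, numeric(1))
    cat(sprintf("  length range %.1f - %.1f mm (median %.1f)\n",
                min(len), max(len), stats::median(len)))
  }
  invisible(x)
}

#' @export
length.streamline_set <- function(x) length(x$streamlines)

#' Arc length of a polyline
#'
#' Sum of Euclidean segment lengths along an ordered point sequence.
#'
#' @param polyline numeric matrix, one 3D point per row (>= 2 rows).
#' @return Length in mm.
#' @export
streamline_length <- function(polyline) {
  m <- as.matrix(polyline)
  .assert(ncol(m) == 3L && nrow(m) >= 2L,
          "polyline must be an n x 3 matrix with n >= 2")
  .assert(all(is.finite(m)), "polyline has non-finite coordinates")
  seg <- diff(m)
  sum(sqrt(rowSums(seg^2)))
}

#' Length-filter a streamline set
#'
#' Retains streamlines whose arc length is at least `min_length_mm`
#' (boundary inclusive). The study default is 50 mm. The number of removed
#' streamlines is recorded in the provenance.
#'
#' @param s a [streamline_set].
#' @param min_length_mm minimum arc length in mm (>= 0).
#' @return The filtered [streamline_set].
#' @export
filter_streamlines <- function(s, min_length_mm = 50) {
  .assert(inherits(s, "streamline_set"), "s must be a streamline_set")
  .assert(is.numeric(min_length_mm) && length(min_length_mm) == 1L &&
            !is.na(min_length_mm) && min_length_mm >= 0,
          "min_length_mm must be a single number >= 0")
  len <- vapply(s$streamlines, streamline_length, numeric(1))
  keep <- len >= min_length_mm
  prov <- s$provenance
  prov$min_length_mm <- min_length_mm
  prov$n_removed_short <- sum(!keep)
  streamline_set(s$streamlines[keep], prov)
}

# World-space point -> region label. Voxel (i,j,k) (0-based) covers the
# half-open box [i*vs, (i+1)*vs) along each axis; points outside the grid or
# in background (label 0) map to NA.
.point_labels <- function(points, parcellation) {
  vs <- parcellation$voxel_size_mm
  dims <- dim(parcellation$labels)
  idx <- floor(sweep(points, 2, vs, "/"))
  inside <- idx[, 1] >= 0 & idx[, 1] < dims[1] &
    idx[, 2] >= 0 & idx[, 2] < dims[2] &
    idx[, 3] >= 0 & idx[, 3] < dims[3]
  lab <- rep(NA_integer_, nrow(points))
  if (any(inside)) {
    flat <- 1 + idx[inside, 1] + dims[1] * (idx[inside, 2] + dims[2] * idx[inside, 3])
    lab[inside] <- parcellation$labels[flat]
  }
  lab[!is.na(lab) & lab == 0] <- NA_integer_
  lab
}

#' Map a streamline's terminal points to region ids
#'
#' Each endpoint is assigned the label of the voxel containing it (world to
#' voxel by flooring the coordinate divided by the voxel size; half-open voxel
#' intervals). Background and out-of-grid endpoints give `NA`.
#'
#' @param polyline numeric n x 3 matrix.
#' @param parcellation a [parcellation].
#' @return Integer vector of length 2 (first endpoint, last endpoint), `NA`
#'   where unassigned.
#' @export
assign_endpoints <- function(polyline, parcellation) {
  m <- as.matrix(polyline)
  .assert(ncol(m) == 3L && nrow(m) >= 2L,
          "polyline must be an n x 3 matrix with n >= 2")
  .assert(all(is.finite(m)), "polyline has non-finite coordinates")
  .assert(inherits(parcellation, "parcellation"),
          "parcellation must be a parcellation")
  ends <- m[c(1L, nrow(m)), , drop = FALSE]
  .point_labels(ends, parcellation)
}

#' Count streamlines connecting each region pair
#'
#' Builds the fiber-count matrix F: `F[i, j]` is the number of streamlines
#' with one endpoint in region i and the other in region j (i != j).
#' Streamlines with an unassigned endpoint, or with both endpoints in the
#' same region, are discarded; discard counts are attached as the
#' `"discarded"` attribute.
#'
#' @param s a [streamline_set], already length-filtered.
#' @param p a [parcellation].
#' @return Symmetric integer matrix with zero diagonal; rows/columns ordered
#'   and named as in `p$regions$id`.
#' @export
count_connections <- function(s, p) {
  .assert(inherits(s, "streamline_set"), "s must be a streamline_set")
  .assert(inherits(p, "parcellation"), "p must be a parcellation")
  ids <- p$regions$id
  n <- length(ids)
  f <- matrix(0L, n, n, dimnames = list(ids, ids))
  ns <- length(s$streamlines)
  discarded <- c(unassigned = 0L, self_loop = 0L)
  if (ns > 0) {
    first <- t(vapply(s$streamlines, function(m) m[1L, ], numeric(3)))
    last <- t(vapply(s$streamlines, function(m) m[nrow(m), ], numeric(3)))
    la <- .point_labels(first, p)
    lb <- .point_labels(last, p)
    bad <- is.na(la) | is.na(lb)
    loop <- !bad & la == lb
    discarded <- c(unassigned = sum(bad), self_loop = sum(loop))
    keep <- !bad & !loop
    if (any(keep)) {
      ia <- match(la[keep], ids)
      ib <- match(lb[keep], ids)
      .assert(!anyNA(ia) && !anyNA(ib),
              "endpoint label not present in the region table")
      for (k in seq_along(ia)) {
        f[ia[k], ib[k]] <- f[ia[k], ib[k]] + 1L
        f[ib[k], ia[k]] <- f[ib[k], ia[k]] + 1L
      }
    }
  }
  attr(f, "discarded") <- discarded
  f
}
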