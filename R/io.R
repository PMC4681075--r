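#' @name streamline_io
#' @title Streamline file formats
#'
#' @description
#' Three interchange formats for streamline sets:
#'
#' * `text` — a documented plain-text fallback: one streamline per block,
#'   one `x y z` line per point (mm, world space), blank-line separated;
#' * `tck` — the MRtrix track format (Float32LE, NaN-triplet streamline
#'   separators, Inf-triplet end marker); coordinates are world mm;
#' * `trk` — the TrackVis format, version 2; points are stored in voxel-mm
#'   and mapped through the header's `vox_to_ras` affine when it is valid,
#'   otherwise taken as world mm.
#'
#' Readers return coordinates in mm world space and keep format metadata in
#' the provenance; writers are atomic.
NULL

.detect_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tck", "trk", "txt")) {
    if (ext == "txt") "text" else ext
  } else "text"
}

#' Read a streamline file
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"text"`, `"tck"` or `"trk"`.
#' @return A [streamline_set] with coordinates in mm world space.
#' @export
read_streamlines <- function(path, format = c("auto", "text", "tck", "trk")) {
  format <- match.arg(format)
  .assert(file.exists(path), "no such file: %s", path)
  if (format == "auto") format <- .detect_format(path)
  switch(format,
         text = .read_streamlines_text(path),
         tck = .read_streamlines_tck(path),
         trk = .read_streamlines_trk(path))
}

#' Write a streamline file
#'
#' @param s a [streamline_set].
#' @param path output file.
#' @param format `"auto"` (by extension), `"text"`, `"tck"` or `"trk"`.
#' @param voxel_size_mm voxel size recorded in the TRK header (ignored by
#'   the other formats).
#' @return Invisibly, `path`.
#' @export
write_streamlines <- function(s, path,
                              format = c("auto", "text", "tck", "trk"),
                              voxel_size_mm = c(1, 1, 1)) {
  format <- match.arg(format)
  .assert(inherits(s, "streamline_set"), "s must be a streamline_set")
  if (format == "auto") format <- .detect_format(path)
  switch(format,
         text = .write_streamlines_text(s, path),
         tck = .write_streamlines_tck(s, path),
         trk = .write_streamlines_trk(s, path, voxel_size_mm))
  invisible(path)
}

# ---- plain text ------------------------------------------------------

.write_streamlines_text <- function(s, path) {
  .write_atomic(path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    for (m in s$streamlines) {
      writeLines(apply(m, 1, function(p) paste(.fmt_num(p), collapse = " ")),
                 con)
      writeLines("", con)
    }
  })
}

.read_streamlines_text <- function(path) {
  lines <- readLines(path)
  blank <- !nzchar(trimws(lines))
  grp <- cumsum(c(TRUE, blank[-length(blank)]))
  keep <- !blank
  blocks <- split(lines[keep], grp[keep])
  lines_no <- split(seq_along(lines)[keep], grp[keep])
  streamlines <- lapply(seq_along(blocks), function(bi) {
    b <- blocks[[bi]]
    vals <- strsplit(trimws(b), "[[:space:]]+")
    bad <- which(lengths(vals) != 3)
    .assert(length(bad) == 0, "parse error in '%s' line %d: expected 'x y z'",
            path, if (length(bad)) lines_no[[bi]][bad[1]] else 0L)
    m <- matrix(as.numeric(unlist(vals)), ncol = 3, byrow = TRUE)
    .assert(!anyNA(m), "non-numeric coordinate in '%s' (block %d)", path, bi)
    m
  })
  streamline_set(streamlines,
                 provenance = list(source = path, format = "text"))
}

# ---- TCK (MRtrix) ----------------------------------------------------

.write_streamlines_tck <- function(s, path) {
  n <- length(s$streamlines)
  make_header <- function(offset) {
    paste0("mrtrix tracks\ndatatype: Float32LE\ncount: ", n,
           "\nfile: . ", offset, "\nEND\n")
  }
  offset <- nchar(make_header(0), type = "bytes")
  while (nchar(make_header(offset), type = "bytes") != offset)
    offset <- nchar(make_header(offset), type = "bytes")
  .write_atomic(path, function(tmp) {
    con <- file(tmp, "wb")
    on.exit(close(con))
    writeChar(make_header(offset), con, eos = NULL)
    for (m in s$streamlines) {
      writeBin(as.numeric(t(m)), con, size = 4, endian = "little")
      writeBin(rep(NaN, 3), con, size = 4, endian = "little")
    }
    writeBin(rep(Inf, 3), con, size = 4, endian = "little")
  })
}

.read_streamlines_tck <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  # header is ASCII up to and including the "END\n" line
  end_pat <- charToRaw("\nEND\n")
  hdr_end <- NA
  for (i in seq_len(min(length(raw) - 4L, 4096L))) {
    if (identical(raw[i:(i + 4L)], end_pat)) { hdr_end <- i + 4L; break }
  }
  .assert(!is.na(hdr_end), "malformed TCK header in '%s': no END line found within the first 4096 bytes", path)
  hdr <- strsplit(rawToChar(raw[1:hdr_end]), "\n")[[1]]
  .assert(grepl("^mrtrix tracks", hdr[1]),
          "not a TCK file: '%s' (byte 0)", path)
  get_field <- function(key) {
    ln <- grep(paste0("^", key, ": "), hdr, value = TRUE)
    if (length(ln) == 0) NA_character_ else sub(paste0("^", key, ": "), "", ln[1])
  }
  dt <- get_field("datatype")
  .assert(identical(dt, "Float32LE"),
          "unsupported TCK datatype '%s' in '%s'", dt, path)
  file_field <- get_field("file")
  .assert(!is.na(file_field) && grepl("^\\. [0-9]+$", file_field),
          "malformed TCK 'file' field in '%s'", path)
  offset <- as.integer(sub("^\\. ", "", file_field))
  .assert(offset <= length(raw), "TCK data offset %d beyond end of '%s'",
          offset, path)
  body <- raw[(offset + 1L):length(raw)]
  .assert(length(body) %% 12L == 0L,
          "truncated TCK body in '%s' (byte offset %d)", path,
          offset + length(body))
  pts <- readBin(body, "numeric", n = length(body) / 4L, size = 4,
                 endian = "little")
  pts <- matrix(pts, ncol = 3, byrow = TRUE)
  is_nan <- rowSums(is.na(pts)) > 0
  is_inf <- rowSums(is.infinite(pts)) > 0
  stop_at <- which(is_inf)[1]
  .assert(!is.na(stop_at), "TCK file '%s' has no end-of-file marker", path)
  pts <- pts[seq_len(stop_at - 1L), , drop = FALSE]
  is_nan <- is_nan[seq_len(stop_at - 1L)]
  grp <- cumsum(c(TRUE, is_nan[-length(is_nan)]))
  streamlines <- split.data.frame(pts[!is_nan, , drop = FALSE], grp[!is_nan])
  streamline_set(lapply(streamlines, as.matrix),
                 provenance = list(source = path, format = "tck",
                                   count = get_field("count")))
}

# ---- TRK (TrackVis) --------------------------------------------------

.write_streamlines_trk <- function(s, path, voxel_size_mm) {
  .write_atomic(path, function(tmp) {
    con <- file(tmp, "wb")
    on.exit(close(con))
    wchar <- function(x, nbytes) {
      r <- raw(nbytes)
      b <- charToRaw(x)
      r[seq_along(b)] <- b
      writeBin(r, con)
    }
    wchar("TRACK", 6)
    writeBin(as.integer(c(0, 0, 0)), con, size = 2, endian = "little")  # dim
    writeBin(as.numeric(voxel_size_mm), con, size = 4, endian = "little")
    writeBin(as.numeric(c(0, 0, 0)), con, size = 4, endian = "little")  # origin
    writeBin(0L, con, size = 2, endian = "little")  # n_scalars
    writeBin(raw(200), con)
    writeBin(0L, con, size = 2, endian = "little")  # n_properties
    writeBin(raw(200), con)
    affine <- diag(c(voxel_size_mm, 1))  # vox -> world: voxelmm equals mm
    writeBin(as.numeric(t(affine)), con, size = 4, endian = "little")
    writeBin(raw(444), con)
    wchar("RAS", 4)   # voxel_order
    wchar("RAS", 4)   # pad2
    writeBin(as.numeric(c(1, 0, 0, 0, 1, 0)), con, size = 4,
             endian = "little")
    writeBin(raw(2), con)  # pad1
    writeBin(raw(6), con)  # invert/swap flags
    writeBin(length(s$streamlines), con, size = 4, endian = "little")
    writeBin(2L, con, size = 4, endian = "little")   # version
    writeBin(1000L, con, size = 4, endian = "little")  # hdr_size
    for (m in s$streamlines) {
      writeBin(nrow(m), con, size = 4, endian = "little")
      # world mm -> voxel -> voxelmm
      vox <- sweep(m, 2, voxel_size_mm, "/")
      voxmm <- sweep(vox, 2, voxel_size_mm, "*")
      writeBin(as.numeric(t(voxmm)), con, size = 4, endian = "little")
    }
  })
}

.read_streamlines_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6)
  .assert(identical(rawToChar(magic[1:5]), "TRACK"),
          "not a TRK file: '%s' (byte 0)", path)
  invisible(readBin(con, "integer", 3, size = 2, endian = "little"))  # dim
  voxel_size <- readBin(con, "numeric", 3, size = 4, endian = "little")
  invisible(readBin(con, "numeric", 3, size = 4, endian = "little"))  # origin
  n_scalars <- readBin(con, "integer", 1, size = 2, endian = "little")
  invisible(readBin(con, "raw", 200))
  n_properties <- readBin(con, "integer", 1, size = 2, endian = "little")
  invisible(readBin(con, "raw", 200))
  affine <- matrix(readBin(con, "numeric", 16, size = 4, endian = "little"),
                   4, 4, byrow = TRUE)
  invisible(readBin(con, "raw", 444))
  voxel_order <- rawToChar(readBin(con, "raw", 4)[1:3])
  invisible(readBin(con, "raw", 4))
  invisible(readBin(con, "numeric", 6, size = 4, endian = "little"))
  invisible(readBin(con, "raw", 2))
  invisible(readBin(con, "raw", 6))
  n_count <- readBin(con, "integer", 1, size = 4, endian = "little")
  version <- readBin(con, "integer", 1, size = 4, endian = "little")
  hdr_size <- readBin(con, "integer", 1, size = 4, endian = "little")
  .assert(hdr_size == 1000L,
          "malformed TRK header in '%s': hdr_size %d at byte 996", path,
          hdr_size)
  affine_valid <- version >= 2 && affine[4, 4] != 0
  if (any(voxel_size <= 0)) voxel_size <- c(1, 1, 1)
  streamlines <- list()
  offset <- 1000
  repeat {
    np <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(np) == 0) break
    .assert(np > 0, "corrupt TRK track header at byte %d in '%s'",
            offset, path)
    vals <- readBin(con, "numeric", np * (3 + n_scalars), size = 4,
                    endian = "little")
    .assert(length(vals) == np * (3 + n_scalars),
            "truncated TRK file '%s' at byte %d", path, offset)
    if (n_properties > 0)
      invisible(readBin(con, "numeric", n_properties, size = 4,
                        endian = "little"))
    m <- matrix(vals, ncol = 3 + n_scalars, byrow = TRUE)[, 1:3, drop = FALSE]
    if (affine_valid) {
      vox <- sweep(m, 2, voxel_size, "/")
      m <- t(affine %*% rbind(t(vox), 1))[, 1:3, drop = FALSE]
    }
    streamlines[[length(streamlines) + 1L]] <- m
    offset <- offset + 4 + 4 * (np * (3 + n_scalars) + n_properties)
  }
  if (n_count > 0)
    .assert(length(streamlines) == n_count,
            "TRK file '%s' declares %d tracks but contains %d", path,
            n_count, length(streamlines))
  streamline_set(streamlines,
                 provenance = list(source = path, format = "trk",
                                   voxel_order = voxel_order,
                                   version = version))
}

# ---- config + manifest ----------------------------------------------

#' Write / read a cohort specification as a YAML config
#'
#' Schema: top-level keys `n_group_a`, `n_group_b`, `n_nodes`, `seed`,
#' `mean_strength`, and an `effect` mapping with the [effect_spec()]
#' fields.
#'
#' @param spec a [cohort_spec()].
#' @param path YAML file path.
#' @return `write_cohort_spec` invisibly returns `path`;
#'   `read_cohort_spec` returns a `cohort_spec`.
#' @export
write_cohort_spec <- function(spec, path) {
  .assert(inherits(spec, "cohort_spec"), "spec must be a cohort_spec")
  x <- unclass(spec)
  x$effect <- unclass(x$effect)
  .write_atomic(path, function(tmp) yaml::write_yaml(x, tmp))
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  .assert(file.exists(path), "no such file: %s", path)
  x <- yaml::read_yaml(path)
  cohort_spec(n_group_a = x$n_group_a, n_group_b = x$n_group_b,
              n_nodes = x$n_nodes, seed = x$seed,
              effect = do.call(effect_spec, x$effect),
              mean_strength = x$mean_strength)
}

#' Run manifest
#'
#' A reproducibility record for a pipeline run: configuration snapshot,
#' input file digests, seeds and the package version.
#'
#' @param config named list describing the run configuration.
#' @param inputs character vector of input file paths (digested with MD5).
#' @param seeds named list of seeds used by stochastic stages.
#' @return A manifest list.
#' @export
run_manifest <- function(config = list(), inputs = character(),
                         seeds = list()) {
  digests <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  list(config = config, input_digests = digests, seeds = seeds,
       version = as.character(utils::packageVersion("tractnet")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' Write a manifest (or any list) as JSON, atomically
#'
#' @param x a list.
#' @param path output JSON path.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(x, path) {
  .write_atomic(path, function(tmp) {
    jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  })
  invisible(path)
}
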