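# Internal helpers shared across the package.

.assert <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  .assert(is.numeric(seed) && length(seed) == 1L && is.finite(seed),
          "seed must be a single finite number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed that stays inside 32-bit integer range.
.child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k) %% 2147483587)
}

.check_square <- function(m, what = "matrix") {
  .assert(is.matrix(m) && nrow(m) == ncol(m), "%s must be square", what)
  .assert(all(is.finite(m)), "%s must have finite entries", what)
}

.check_symmetric <- function(m, what = "matrix") {
  .check_square(m, what)
  .assert(max(abs(m - t(m))) == 0, "%s must be symmetric", what)
  .assert(all(diag(m) == 0), "%s must have a zero diagonal", what)
}

# Atomic file write: write to a temp path in the same directory, then rename.
.write_atomic <- function(path, writer) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp))
  writer(tmp)
  ok <- file.rename(tmp, path)
  .assert(ok, "could not move temporary file onto '%s'", path)
  invisible(path)
}

# Full-precision numeric formatting so matrix round trips are lossless.
.fmt_num <- function(x) sprintf("%.17g", x)
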