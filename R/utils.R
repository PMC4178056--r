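# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. All stochastic operations in the package route through this.
with_rng_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# 32-bit FNV-1a over serialized R objects; used to stamp output files with
# the configuration that produced them (provenance, not cryptography).
config_hash <- function(x) {
  bytes <- serialize(x, connection = NULL, version = 2L)
  h <- 2166136261
  for (b in as.integer(bytes)) {
    h <- bitwXor(as.integer(h %% 2^31), b)  # keep within integer range
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

norm_symbols <- function(x) toupper(trimws(as.character(x)))

assert_file <- function(path) {
  if (!is.character(path) || length(path) != 1L)
    stop("`path` must be a single file path", call. = FALSE)
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  invisible(path)
}
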