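# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so library code never disturbs user RNG flow.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}

# Pixel coordinate grids for an image of `rows` x `cols` pixels.
# Convention (shared by all modules): row-major storage, origin at the
# top-left, pixel centers at integer coordinates; a point is (x = column,
# y = row).
coord_grid <- function(rows, cols) {
  list(
    x = matrix(rep(seq_len(cols), each = rows), rows, cols),
    y = matrix(rep(seq_len(rows), cols), rows, cols)
  )
}
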