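# Internal helpers shared across modules.

# Round half away from zero (R's round() rounds half to even).
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards. `seed = NULL` leaves the global stream alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Row-wise log-sum-exp of a matrix.
row_logsumexp <- function(m) {
  mx <- do.call(pmax, as.data.frame(m))
  mx + log(rowSums(exp(m - mx)))
}

# Sample index grid for an epoch window half-open in continuous time
# [tmin, tmax): integer indices relative to the event onset sample.
epoch_index_grid <- function(tmin, tmax, rate) {
  i0 <- round_half_away(tmin * rate)
  i1 <- round_half_away(tmax * rate)
  idx <- seq.int(i0, i1)
  # drop the last index if it lands at or beyond tmax
  if (idx[length(idx)] / rate >= tmax - 1e-12) idx <- idx[-length(idx)]
  idx
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single probability in [0, 1]", name),
         call. = FALSE)
  }
  invisible(x)
}
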