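# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Run `expr` with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Deterministic child seed, kept inside R's 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(offset)) %% 2147483647)
}

## Angle (radians) between two nonnegative spectra.
spectral_angle <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  acos(max(-1, min(1, sum(a * b) / (na * nb))))
}

## Reflect an index vector into 1..n (mirror padding without edge repeat).
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  period <- 2L * (n - 1L)
  j <- (i - 1L) %% period
  j <- ifelse(j < 0, j + period, j)
  as.integer(ifelse(j >= n, period - j, j) + 1L)
}

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a positive finite scalar", name), call. = FALSE)
  invisible(x)
}

## Largest-remainder apportionment of `n` items to nonnegative weights.
apportion <- function(weights, n) {
  stopifnot(all(weights >= 0), sum(weights) > 0)
  frac <- weights / sum(weights) * n
  base <- floor(frac)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(frac - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}
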