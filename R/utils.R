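# Internal helpers shared across modules.

# Run `expr` under a temporary RNG seed, restoring global RNG state after.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Round half away from zero (display convention for integer percentages;
# base round() is round-half-even).
round_half_up <- function(x) floor(x + 0.5)

# Largest-remainder (Hamilton) apportionment of n into counts proportional
# to `props`. Exact: sum(result) == n.
apportion <- function(n, props) {
  stopifnot(n >= 0, all(props >= 0), abs(sum(props) - 1) < 1e-9)
  quota <- n * props
  base <- floor(quota)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(quota - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
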