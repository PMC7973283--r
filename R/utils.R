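# internal helpers shared across modules

# truncate (not round) to one decimal for display; 6.25 displays as 6.2
trunc1 <- function(x) trunc(x * 10) / 10

# log a provenance message to stderr without raising a condition
bp_log <- function(...) {
  message(sprintf(...))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate `expr` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so generators never perturb the session stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  expr
}

# format a coefficient at `decimals` places, trimming trailing zeros but
# keeping at least one decimal digit
fmt_coef <- function(x, decimals = 4L) {
  s <- formatC(round(x, decimals), format = "f", digits = decimals)
  s <- sub("0+$", "", s)
  sub("\\.$", ".0", s)
}
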