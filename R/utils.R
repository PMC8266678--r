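# Seed plumbing: every stochastic routine draws under a local RNG state so
# package calls never disturb the caller's stream, and stage-level
# sub-streams are derived deterministically from one global seed plus the
# stage name (stable under stage re-runs and re-ordering).

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic 31-bit sub-seed from (seed, stage name); FNV-style string
# hash folded with the seed, kept strictly below 2^31.
stage_seed <- function(seed, stage) {
  h <- 2166136261
  for (ch in utf8ToInt(stage)) {
    h <- (h * 16777619) %% 2147483647
    h <- xor_int(h, ch)
  }
  as.integer((h + as.numeric(seed) * 2654435761) %% 2147483629)
}

xor_int <- function(a, b) {
  bitwXor(as.integer(a %% 2147483647), as.integer(b))
}
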