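# internal helpers

# validation failures get their own condition class so the CLI can map them
# to a distinct exit code
stop_validation <- function(...) {
  stop(structure(class = c("pirf_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# deterministic expansion of one user-facing seed into per-stage seeds;
# kept below 2^31 so results are portable across platforms
derive_seed <- function(seed, stage, index = 0L) {
  stage_id <- sum(utf8ToInt(stage)) %% 1000L
  s <- (as.numeric(seed) %% 2147483647) + 1
  s <- (s * 48271 + stage_id * 1299709 + as.numeric(index) * 15485863) %% 2147483647
  as.integer(s)
}

# evaluate expr with a temporary R RNG seed, restoring any prior state
with_rng_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
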