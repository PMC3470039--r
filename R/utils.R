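# Condition helpers. Three classes map onto the CLI exit-code contract:
#   syntrace_validation_error -> exit 2 (bad values, broken invariants)
#   syntrace_format_error     -> exit 3 (unparseable or malformed input files)
#   syntrace_lookup_error     -> exit 2 (unknown identifier)

stop_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("syntrace_validation_error", "syntrace_error")))
}

stop_format <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("syntrace_format_error", "syntrace_error")))
}

stop_lookup <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("syntrace_lookup_error", "syntrace_error")))
}

# Round half away from zero (Table-style presentation rounding); base round()
# uses round-half-even.
round_half_up <- function(x) floor(x + 0.5)

# Run code under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Derive a stream-specific child seed below 2^31 from a user seed.
child_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + 1103 * as.numeric(k)) %% 2147483629
}

`%||%` <- function(a, b) if (is.null(a)) b else a
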