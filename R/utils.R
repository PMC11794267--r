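# Internal helpers shared across modules.

# Evaluate `code` with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed derivation; keeps results < 2^31.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + k) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_emg <- function(msg, class, ...) {
  stop(structure(class = c(class, "emgselect_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

is_count <- function(x) length(x) == 1 && is.finite(x) && x == round(x) && x >= 1
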