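#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards. All randomized operations in the package go
# through this so that a seed argument fully determines the result without
# clobbering the session RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a child seed from a parent seed and a stream label, so that
# independent stages driven by one user seed do not share RNG streams.
# Kept within 32-bit integer range.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((abs(seed) * 7919 + h * 104729 + 13) %% .Machine$integer.max)
}

abort_if <- function(cond, msg) {
  if (cond) stop(msg, call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

log_msg <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) {
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), paste0(...)))
  }
}
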