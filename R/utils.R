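# Shared internal helpers: structured conditions and scoped RNG.

#' Signal a structured museeg error
#'
#' All user-facing failures in the package are classed conditions so callers
#' can branch on the failure mode rather than match message text.
#'
#' @param message human-readable description.
#' @param class condition subclass, prefixed internally with `museeg_error`.
#' @param ... fields attached to the condition (e.g. the offending value).
#' @noRd
abort_museeg <- function(message, class, ...) {
  cond <- structure(
    class = c(class, "museeg_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a bounded child seed from a run seed; keeps every derived seed a
# valid 32-bit integer no matter what the caller passes.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483629L)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
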