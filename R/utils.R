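#' @keywords internal
"_PACKAGE"

# Run `code` under a given RNG seed, restoring the caller's RNG state afterwards.
# All stochastic entry points route their randomness through this so that a
# user-supplied seed fully determines the output without clobbering the session.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a reproducible child seed from a parent seed and a stream index,
# kept inside 32-bit integer range.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 2654435761 + as.numeric(stream) * 40503) %% 2147483647)
}

stop_if_not_finite <- function(x, what) {
  if (any(!is.finite(x))) {
    stop(sprintf("%s contains non-finite values (NaN/Inf)", what), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
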