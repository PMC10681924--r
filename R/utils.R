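#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize gene symbols
#'
#' Trims whitespace, uppercases, drops empty strings. No alias/HGNC
#' resolution is attempted; identifiers are treated as opaque uppercase
#' symbols.
#'
#' @param x character vector of raw symbols.
#' @return character vector of normalized, possibly duplicated symbols.
#' @keywords internal
norm_symbol <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x[nzchar(x)]
}

#' Derive a deterministic per-stream seed
#'
#' One user-facing integer seed drives a named substream per generator so
#' adding a generator never perturbs the draws of another.
#'
#' @param seed integer master seed.
#' @param stream character stream label.
#' @return integer seed below 2^31.
#' @keywords internal
substream_seed <- function(seed, stream) {
  codes <- utf8ToInt(stream)
  h <- sum(codes * seq_along(codes) * 1009)
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483629)
}

# Evaluate `code` under a derived seed, restoring the caller's RNG state.
with_substream <- function(seed, stream, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(substream_seed(seed, stream))
  force(code)
}

# stop() with a consistent prefix, no call in the condition
np_stop <- function(...) stop(sprintf(...), call. = FALSE)
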