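#' @keywords internal
"_PACKAGE"

## Child seeds are derived from one master seed by fixed offsets so that each
## sub-simulation / stage is independently reproducible.  Result kept < 2^31.
#' Derive a reproducible child seed from a master seed
#'
#' @param master integer master seed.
#' @param offset integer offset identifying the consumer (fixed per call site).
#' @return a positive integer seed below 2^31.
#' @export
derive_seed <- function(master, offset) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master),
            is.numeric(offset), length(offset) == 1L, is.finite(offset))
  ## affine hash in double precision; both multipliers fit exactly in a double
  v <- (abs(as.numeric(master)) * 48271 + abs(as.numeric(offset)) * 69621 + 1) %%
    2147483563
  as.integer(v) + 1L
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == floor(x) && x > 0
}

is_fraction <- function(x, open = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!ok) return(FALSE)
  if (open) x > 0 && x < 1 else x >= 0 && x <= 1
}
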