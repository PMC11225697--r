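# Small shared helpers.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round to whole percents, halves away from zero
#'
#' Rounds `x` (already on the percent scale) to integers with ties going up
#' (`29.5 -> 30`), the convention used throughout the package's summary
#' tables. A tiny epsilon guards against binary-representation ties such as
#' `29.499999999999996`.
#'
#' @param x numeric vector on the percent scale.
#' @return integer vector.
#' @export
round_half_up <- function(x) {
  out <- floor(x + 0.5 + 1e-9)
  storage.mode(out) <- "integer"
  out
}

# Derive a reproducible sub-seed (< 2^31) from a master seed and a stream
# index, so pipeline stages draw from independent, order-stable streams.
substream_seed <- function(seed, k) {
  as.integer((as.double(seed) + 104729 * as.double(k)) %% 2147483629 + 1)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
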