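# Internal helpers shared across modules.

#' @importFrom stats cor dnorm pnorm qnorm rbinom rnorm runif sd setNames var
#' @importFrom rlang .data
#' @importFrom Rcpp evalCpp
#' @useDynLib crossplan, .registration = TRUE
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= min && x == round(x)
}

#' Derive a stream-specific seed from a master seed
#'
#' Keeps independent components of an experiment on separate random streams
#' while staying reproducible from a single integer; the result is always a
#' valid 32-bit seed.
#'
#' @param seed master integer seed.
#' @param stream integer stream index.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 101 + as.numeric(stream) * 7919) %%
               2147483399) + 1L
}
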