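#' @importFrom stats rnorm runif rbinom rpois rnbinom sd var quantile predict
#'   prcomp pnorm p.adjust lm coef
#' @importFrom utils head tail write.csv read.csv
#' @importFrom rlang .data
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_hamgcn <- function(..., class = "hamgcn_error") {
  rlang::abort(paste0(...), class = class)
}

assert_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) {
    stop_hamgcn(what, " contains non-finite values", class = "hamgcn_invalid_input")
  }
  invisible(x)
}

#' Derive a stream-specific seed from a global seed
#'
#' A single user-facing seed fans out to independent per-stage seeds so that
#' any stage of a pipeline can be rerun in isolation and still reproduce the
#' exact stream it saw inside the full run. The scheme is a fixed integer
#' counter per named stream, folded into the global seed modulo 2^31 - 1.
#'
#' @param seed integer global seed.
#' @param stream character; one of the known stream names.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, stream) {
  streams <- c(
    simulate = 11L, preprocess = 23L, graph = 37L, split = 53L,
    init = 71L, train = 89L, perturb = 107L, diagnose = 131L,
    sweep = 151L, misc = 173L
  )
  if (!stream %in% names(streams)) {
    stop_hamgcn("unknown seed stream: ", stream)
  }
  as.integer((as.numeric(seed) * 1009 + streams[[stream]]) %% 2147483647)
}

softmax_rows <- function(logits) {
  m <- apply(logits, 1L, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

#' Cosine similarity between paired rows
#' @noRd
row_cosine <- function(a, b) {
  num <- rowSums(a * b)
  den <- sqrt(rowSums(a * a)) * sqrt(rowSums(b * b))
  out <- ifelse(den > 0, num / den, 0)
  out
}
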