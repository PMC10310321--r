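#' Derive a reproducible sub-stream seed
#'
#' Hashes a master seed together with an arbitrary sequence of labels
#' (stage names, sequence ids, image ids, electrode indices, ...) into a
#' 31-bit integer seed. Every stochastic operation in the package draws its
#' randomness from such a sub-stream, so adding more electrodes, subjects or
#' images never perturbs draws made for earlier units.
#'
#' @param master integer master seed.
#' @param ... labels (coerced to character) identifying the sub-stream.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(master, ...) {
  parts <- c(as.character(master), vapply(list(...), as.character, character(1)))
  h <- 5381
  for (p in parts) {
    for (ch in utf8ToInt(paste0(p, "|"))) {
      h <- (h * 33 + ch) %% 2147483629
    }
  }
  as.integer(h)
}

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so package internals never disturb user-level randomness.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @keywords internal
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed %% 2147483647L), code)
}
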