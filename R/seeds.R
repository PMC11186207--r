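#' Derive a stream-specific seed from a master seed
#'
#' All randomness in puconfide flows from one master seed through this
#' counter-based derivation, so that generation, PU relabeling, bootstrap
#' bagging, spy-fold splitting and label permutation each consume an
#' independent, reproducible stream. Results are invariant to execution
#' order because each (stream, index) pair maps to its seed directly.
#'
#' @param master integer master seed.
#' @param stream character; one of `"generate"`, `"relabel"`, `"bag"`,
#'   `"fold"`, `"spy"`, `"permutation"`, `"pipeline"`.
#' @param index nonnegative integer counter within the stream.
#' @return an integer seed in `[1, 2^31)` suitable for [set.seed()].
#' @examples
#' derive_seed(42, "bag", 3)
#' @export
derive_seed <- function(master, stream, index = 0L) {
  streams <- c(generate = 1, relabel = 2, bag = 3, fold = 4,
               spy = 5, permutation = 6, pipeline = 7)
  if (!stream %in% names(streams))
    stop("unknown seed stream: ", stream)
  m <- 2147483629  # prime < 2^31; products below stay exact in doubles
  s <- ((as.double(master) %% m) * 48271 +
        streams[[stream]] * 69621 +
        as.double(index) * 16807) %% m
  as.integer(s + 1)
}
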