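#' Derive a child seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its own RNG stream from a
#' single master seed through this deterministic splitter, so any stage can
#' be reproduced in isolation. The scheme hashes the master seed together
#' with a stage label and an optional index using 32-bit FNV-1a and maps the
#' result into `[1, 2^31 - 2]`.
#'
#' @param seed integer master seed.
#' @param label character stage label (e.g. `"edge_perm"`).
#' @param index optional non-negative integer distinguishing replicates
#'   within a stage.
#' @return A positive integer seed strictly below `2^31 - 1`.
#' @examples
#' child_seed(1L, "sampling")
#' child_seed(1L, "sampling", 2)
#' @export
child_seed <- function(seed, label, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  stopifnot(is.character(label), length(label) == 1L)
  bytes <- c(
    as.integer(charToRaw(label)),
    as.integer(bitwAnd(as.integer(seed), 0xFFL)),
    as.integer(bitwAnd(bitwShiftR(as.integer(seed), 8L), 0xFFL)),
    as.integer(bitwAnd(bitwShiftR(as.integer(seed), 16L), 0xFFL)),
    as.integer(bitwAnd(as.integer(index), 0xFFL)),
    as.integer(bitwAnd(bitwShiftR(as.integer(index), 8L), 0xFFL)),
    as.integer(bitwAnd(bitwShiftR(as.integer(index), 16L), 0xFFL))
  )
  # 32-bit FNV-1a in double arithmetic (all intermediates < 2^53, exact)
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), as.integer(b))
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (((hi * p) %% 65536) * 65536 + lo * p) %% 4294967296
  }
  as.integer(h %% (2^31 - 2)) + 1L
}

#' Require an explicit seed
#'
#' Stochastic operations refuse to run without a seed; silent
#' irreproducibility is worse than an error.
#' @param seed candidate seed.
#' @return The seed as integer, invisibly erroring otherwise.
#' @keywords internal
require_seed <- function(seed) {
  if (missing(seed) || is.null(seed) || length(seed) != 1L || !is.finite(seed))
    stop("an explicit integer `seed` is required for reproducibility", call. = FALSE)
  as.integer(seed)
}
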