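# Per-size caches of upper-triangle masks and index pairs; these are
# rebuilt thousands of times inside permutation loops otherwise.
.ut_cache <- new.env(parent = emptyenv())

ut_mask <- function(n) {
  key <- paste0("m", n)
  v <- .ut_cache[[key]]
  if (is.null(v)) {
    v <- upper.tri(matrix(FALSE, n, n))
    .ut_cache[[key]] <- v
  }
  v
}

ut_pairs <- function(n) {
  key <- paste0("p", n)
  v <- .ut_cache[[key]]
  if (is.null(v)) {
    v <- which(ut_mask(n), arr.ind = TRUE)
    .ut_cache[[key]] <- v
  }
  v
}
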