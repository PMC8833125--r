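#' Read a region atlas table
#'
#' An atlas maps integer region labels to names, abbreviations and
#' hemispheres. Matrices, SUV tables and reports throughout the package
#' are ordered by `id`; in the shipped 96-region rat atlas ids 1-48 are
#' right-hemisphere regions and 49-96 their left-hemisphere homologues.
#'
#' @param path CSV file with columns `id`, `name`, `abbreviation`,
#'   `hemisphere` (`"L"`/`"R"`).
#' @return A `region_atlas` data frame ordered by `id`.
#' @seealso [rat_atlas()] for the bundled 96-region rat brain atlas.
#' @export
read_atlas <- function(path) {
  at <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "name", "abbreviation", "hemisphere")
  miss <- setdiff(need, names(at))
  if (length(miss))
    stop("atlas file is missing column(s): ", paste(miss, collapse = ", "))
  at <- at[order(at$id), need]
  if (anyDuplicated(at$id)) stop("atlas region ids must be unique")
  if (!identical(as.integer(at$id), seq_len(nrow(at))))
    stop("atlas region ids must be contiguous 1..", nrow(at))
  if (anyDuplicated(at$abbreviation)) stop("atlas abbreviations must be unique")
  if (!all(at$hemisphere %in% c("L", "R")))
    stop("hemisphere must be 'L' or 'R'")
  rownames(at) <- NULL
  class(at) <- c("region_atlas", "data.frame")
  at
}

#' The bundled 96-region rat brain atlas
#'
#' Region list of a standard rat brain template: 48 right-hemisphere
#' regions (ids 1-48) and their 48 left-hemisphere homologues (ids
#' 49-96), identified by abbreviation (e.g. `SC_L`, left superior
#' colliculus; `ParA_R`, right parietal association cortex).
#'
#' @return A `region_atlas` data frame with 96 rows.
#' @examples
#' at <- rat_atlas()
#' table(at$hemisphere)
#' @export
rat_atlas <- function() {
  path <- system.file("extdata", "rat_atlas_96.csv", package = "metconn",
                      mustWork = TRUE)
  at <- read_atlas(path)
  stopifnot(nrow(at) == 96L, sum(at$hemisphere == "L") == 48L)
  at
}

#' A reduced atlas for examples and tests
#'
#' First `n/2` region pairs of the full rat atlas, re-indexed 1..n, so
#' toy pipelines keep realistic abbreviations without the full 96-region
#' cost.
#'
#' @param n even region count (default 6).
#' @return A `region_atlas` data frame with `n` rows.
#' @export
toy_atlas <- function(n = 6L) {
  stopifnot(n >= 2L, n %% 2L == 0L)
  full <- rat_atlas()
  at <- rbind(full[seq_len(n / 2L), ], full[48L + seq_len(n / 2L), ])
  at$id <- seq_len(n)
  rownames(at) <- NULL
  class(at) <- c("region_atlas", "data.frame")
  at
}
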