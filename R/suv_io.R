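#' Construct an SUV table
#'
#' Internal constructor shared by the reader and the synthetic
#' generator. An `suv_table` is a data frame with columns `subject`,
#' `group`, then one numeric column per region in atlas order; the
#' attribute `normalized` records whether each row has been divided by
#' its whole-brain mean.
#'
#' @param values subjects x regions numeric matrix with region column
#'   names.
#' @param subject character subject identifiers (unique).
#' @param group character group labels (exactly two distinct values for
#'   group analyses).
#' @param normalized logical flag.
#' @return An `suv_table`.
#' @keywords internal
new_suv_table <- function(values, subject, group, normalized = FALSE) {
  stopifnot(is.matrix(values), nrow(values) == length(subject),
            length(subject) == length(group))
  if (anyDuplicated(subject)) stop("duplicate subject id(s): ",
                                   paste(unique(subject[duplicated(subject)]), collapse = ", "))
  if (any(!is.finite(values))) stop("SUV values must all be finite")
  tab <- data.frame(subject = as.character(subject),
                    group = as.character(group),
                    values, check.names = FALSE,
                    stringsAsFactors = FALSE)
  attr(tab, "normalized") <- isTRUE(normalized)
  class(tab) <- c("suv_table", "data.frame")
  tab
}

#' Extract the numeric value matrix from an SUV table
#' @param table an `suv_table`.
#' @return subjects x regions numeric matrix, subject ids as rownames.
#' @export
suv_values <- function(table) {
  stopifnot(inherits(table, "suv_table"))
  m <- as.matrix(table[, setdiff(names(table), c("subject", "group")), drop = FALSE])
  rownames(m) <- table$subject
  m
}

#' Group labels of an SUV table
#' @param table an `suv_table`.
#' @return Character vector, one label per subject.
#' @export
suv_groups <- function(table) {
  stopifnot(inherits(table, "suv_table"))
  table$group
}

#' Read an SUV table from delimited text
#'
#' The file must have a header naming `subject`, `group` and every
#' region abbreviation of `atlas`; region columns may appear in any
#' order and are coerced to atlas order. Comma and tab delimiters are
#' sniffed from the header line.
#'
#' @param path file path.
#' @param atlas a `region_atlas` (default the bundled rat atlas).
#' @param groups optional allowed group labels; any other label is an
#'   error.
#' @param normalized logical: whether the stored values are already
#'   globally normalized.
#' @return An `suv_table` in atlas region order.
#' @export
read_suv_table <- function(path, atlas = rat_atlas(), groups = NULL,
                           normalized = FALSE) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("subject", "group")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  missing_regions <- setdiff(atlas$abbreviation, names(raw))
  if (length(missing_regions))
    stop("missing region column(s): ", paste(missing_regions, collapse = ", "))
  if (!is.null(groups)) {
    bad <- setdiff(unique(raw$group), groups)
    if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  }
  vals <- raw[, atlas$abbreviation, drop = FALSE]
  for (cn in names(vals)) {
    col <- vals[[cn]]
    if (!is.numeric(col)) {
      bad_rows <- which(is.na(suppressWarnings(as.numeric(col))))
      stop("non-numeric SUV cell(s) in region ", cn, ", row(s) ",
           paste(bad_rows, collapse = ", "))
    }
    if (anyNA(col))
      stop("missing SUV cell(s) in region ", cn, ", row(s) ",
           paste(which(is.na(col)), collapse = ", "))
  }
  new_suv_table(as.matrix(vals), raw$subject, raw$group, normalized = normalized)
}

#' Write an SUV table to delimited text
#'
#' Values are printed with 17 significant digits so a read/write/read
#' cycle reproduces the doubles exactly. A `.tsv` extension selects tab
#' delimiting, anything else comma.
#'
#' @param table an `suv_table`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_suv_table <- function(table, path) {
  stopifnot(inherits(table, "suv_table"))
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  vals <- suv_values(table)
  out <- data.frame(subject = table$subject, group = table$group,
                    apply(vals, 2L, function(x) sprintf("%.17g", x)),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract per-region mean uptake from a labelled volume
#'
#' Given a scalar uptake volume and an integer label volume on the same
#' voxel grid, returns the arithmetic mean uptake over the voxels of
#' each atlas region. Background voxels (label 0) are ignored. File
#' paths are read as NIfTI-1 volumes.
#'
#' @param uptake 3-D numeric array or NIfTI file path.
#' @param labels 3-D integer array (same shape) or NIfTI file path.
#' @param atlas a `region_atlas`; every atlas id must occur in `labels`.
#' @return Named numeric vector of region means in atlas order.
#' @export
extract_region_means <- function(uptake, labels, atlas = rat_atlas()) {
  if (is.character(uptake)) uptake <- RNifti::readNifti(uptake)
  if (is.character(labels)) labels <- RNifti::readNifti(labels)
  uptake <- as.array(uptake)
  labels <- as.array(labels)
  if (!identical(dim(uptake), dim(labels)))
    stop("uptake and label volumes have different shapes")
  lab <- as.integer(round(labels))
  present <- unique(lab)
  missing_ids <- setdiff(atlas$id, present)
  if (length(missing_ids))
    stop("atlas id(s) absent from label volume: ",
         paste(missing_ids, collapse = ", "))
  sums <- vapply(split(as.numeric(uptake), lab), sum, numeric(1))
  counts <- table(lab)
  means <- sums[as.character(atlas$id)] / as.numeric(counts[as.character(atlas$id)])
  names(means) <- atlas$abbreviation
  means
}

#' Globally normalize a regional uptake vector
#'
#' Divides each region's value by the mean over all regions, the
#' region-level analogue of normalizing voxel uptake by the whole-brain
#' mean. The output has mean exactly 1.
#'
#' @param values numeric vector of region uptake values with positive
#'   mean.
#' @return Normalized vector of the same length.
#' @export
normalize_global <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 1L, all(is.finite(values)))
  m <- mean(values)
  if (m <= 0) stop("whole-brain mean must be positive for global normalization")
  values / m
}

#' Globally normalize every subject of an SUV table
#'
#' Applies [normalize_global()] row-wise; idempotent, since a normalized
#' row already has mean 1.
#'
#' @param table an `suv_table`.
#' @return The normalized `suv_table` (attribute `normalized` set).
#' @export
normalize_suv_table <- function(table) {
  vals <- suv_values(table)
  vals <- t(apply(vals, 1L, normalize_global))
  colnames(vals) <- setdiff(names(table), c("subject", "group"))
  new_suv_table(vals, table$subject, table$group, normalized = TRUE)
}
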