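#' Specify a synthetic two-group SUV cohort
#'
#' Defines the generative model for simulated regional-uptake data: a
#' block (community) base correlation structure shared by both groups,
#' plus optional planted edge-level differences (pairs whose correlation
#' differs between groups). Defaults emulate a two-group small-animal
#' FDG-PET study: 96 regions, 23 vs 24 subjects, four communities of 24
#' regions with within-community correlation 0.5 and between-community
#' correlation 0.1, and globally normalized SUV centred at 1.
#'
#' @param n_regions number of atlas regions.
#' @param n_per_group named integer pair, subjects per group; names are
#'   the group labels.
#' @param blocks integer vector of community sizes summing to
#'   `n_regions`.
#' @param r_within,r_between base correlations inside and between
#'   communities, each in `[-1, 1]`.
#' @param planted_edges `NULL` or a data frame with columns `i`, `j`
#'   (region indices), `r_a`, `r_b` (the pair's correlation in the first
#'   and second group).
#' @param suv_mean,suv_sd marginal mean and standard deviation of the
#'   simulated uptake values (dimensionless, globally-normalized SUV
#'   scale).
#' @return A validated `synthetic_spec` list.
#' @examples
#' sp <- synthetic_spec(planted_edges = data.frame(i = 1, j = 5, r_a = 0.8, r_b = 0))
#' @export
synthetic_spec <- function(n_regions = 96L,
                           n_per_group = c(aged = 23L, young = 24L),
                           blocks = NULL,
                           r_within = 0.5,
                           r_between = 0.1,
                           planted_edges = NULL,
                           suv_mean = 1,
                           suv_sd = 0.15) {
  n_regions <- as.integer(n_regions)
  stopifnot(n_regions >= 2L, length(n_per_group) == 2L, all(n_per_group >= 4L))
  if (is.null(names(n_per_group)) || anyDuplicated(names(n_per_group)))
    stop("`n_per_group` must carry two distinct group labels as names")
  if (is.null(blocks)) {
    k <- max(1L, n_regions %/% 24L)
    blocks <- rep(n_regions %/% k, k)
    blocks[k] <- blocks[k] + n_regions - sum(blocks)
  }
  stopifnot(sum(blocks) == n_regions, all(blocks >= 1L))
  stopifnot(abs(r_within) <= 1, abs(r_between) <= 1)
  if (!is.null(planted_edges)) {
    pe <- as.data.frame(planted_edges)
    stopifnot(all(c("i", "j", "r_a", "r_b") %in% names(pe)))
    stopifnot(all(pe$i != pe$j), all(pe$i >= 1L), all(pe$j <= n_regions),
              all(abs(pe$r_a) <= 1), all(abs(pe$r_b) <= 1))
    key <- paste(pmin(pe$i, pe$j), pmax(pe$i, pe$j))
    if (anyDuplicated(key)) stop("planted edges must name distinct region pairs")
    planted_edges <- pe
  }
  stopifnot(suv_mean > 0, suv_sd > 0)
  structure(list(n_regions = n_regions,
                 n_per_group = n_per_group,
                 blocks = as.integer(blocks),
                 r_within = r_within, r_between = r_between,
                 planted_edges = planted_edges,
                 suv_mean = suv_mean, suv_sd = suv_sd),
            class = "synthetic_spec")
}

#' Build one group's generating correlation matrix
#'
#' Realizes the block structure, overwrites planted entries with the
#' group's requested correlations, then repairs to the nearest positive
#' semidefinite correlation matrix by eigenvalue clipping at zero
#' followed by rescaling to unit diagonal. The repair distortion
#' (`max |requested - realized|` over off-diagonal entries) is attached
#' as attribute `"distortion"`; a planted entry moved by more than 0.1
#' is treated as a non-realizable request and is an error.
#'
#' @param spec a [synthetic_spec()].
#' @param group which group (`1`/`2` or a label from `n_per_group`).
#' @return A `group_covariance` object: list with the `matrix`, the
#'   `group_id`, and the realized `distortion`.
#' @export
build_group_covariance <- function(spec, group) {
  stopifnot(inherits(spec, "synthetic_spec"))
  labels <- names(spec$n_per_group)
  if (is.character(group)) group <- match(group, labels)
  stopifnot(group %in% c(1L, 2L))
  n <- spec$n_regions
  community <- rep(seq_along(spec$blocks), spec$blocks)
  C <- matrix(spec$r_between, n, n)
  same <- outer(community, community, "==")
  C[same] <- spec$r_within
  diag(C) <- 1
  pe <- spec$planted_edges
  if (!is.null(pe)) {
    r <- if (group == 1L) pe$r_a else pe$r_b
    C[cbind(pe$i, pe$j)] <- r
    C[cbind(pe$j, pe$i)] <- r
  }
  repaired <- nearest_psd_correlation(C)
  distortion <- max(abs(repaired - C))
  if (!is.null(pe)) {
    moved <- abs(repaired[cbind(pe$i, pe$j)] - C[cbind(pe$i, pe$j)])
    if (any(moved > 0.1)) {
      bad <- which(moved > 0.1)
      stop("planted correlation(s) not realizable as a PSD matrix: pair(s) ",
           paste(sprintf("(%d,%d)", pe$i[bad], pe$j[bad]), collapse = ", "),
           " moved by up to ", signif(max(moved), 3), call. = FALSE)
    }
  }
  structure(list(matrix = repaired,
                 group_id = labels[group],
                 distortion = distortion),
            class = "group_covariance")
}

#' Repair a symmetric matrix to the nearest PSD correlation matrix
#'
#' Higham's alternating-projections algorithm (via [Matrix::nearPD()]
#' with `corr = TRUE`): projects alternately onto the PSD cone
#' (eigenvalue clipping) and the unit-diagonal affine set, converging to
#' the nearest correlation matrix in Frobenius norm, which spreads the
#' distortion thinly across entries instead of concentrating it. An
#' input that is already a PSD correlation matrix is returned unchanged.
#'
#' @param C symmetric matrix with unit diagonal.
#' @return A symmetric PSD matrix with unit diagonal.
#' @keywords internal
nearest_psd_correlation <- function(C) {
  stopifnot(isSymmetric(unname(C)))
  e <- min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
  if (e >= 0) return(C)
  R <- as.matrix(Matrix::nearPD(C, corr = TRUE, maxit = 200,
                                conv.tol = 1e-10)$mat)
  R <- (R + t(R)) / 2
  diag(R) <- 1
  dimnames(R) <- dimnames(C)
  R
}

#' Sample a two-group SUV table from group covariances
#'
#' Subjects are independent multivariate-normal draws with the group's
#' correlation matrix, affinely mapped to marginal mean `suv_mean` and
#' standard deviation `suv_sd`. Pearson correlation, the only downstream
#' consumer, is location/scale invariant, so the Gaussian marginal
#' family is immaterial to the network analysis.
#'
#' @param cov_a,cov_b `group_covariance` objects for the two groups.
#' @param n_a,n_b subjects per group (each at least 4).
#' @param suv_mean,suv_sd affine map parameters.
#' @param seed integer seed; required.
#' @param region_names optional region column names (defaults to the
#'   rat atlas abbreviations for 96 regions, `R1..Rn` otherwise).
#' @return An `suv_table` data frame: columns `subject`, `group`, then
#'   one column per region.
#' @export
sample_suv_table <- function(cov_a, cov_b, n_a, n_b,
                             suv_mean = 1, suv_sd = 0.15, seed,
                             region_names = NULL) {
  seed <- require_seed(seed)
  stopifnot(inherits(cov_a, "group_covariance"),
            inherits(cov_b, "group_covariance"),
            n_a >= 4L, n_b >= 4L,
            nrow(cov_a$matrix) == nrow(cov_b$matrix))
  n_regions <- nrow(cov_a$matrix)
  if (is.null(region_names)) {
    region_names <- if (n_regions == 96L) rat_atlas()$abbreviation
                    else paste0("R", seq_len(n_regions))
  }
  stopifnot(length(region_names) == n_regions)
  draw <- function(covg, n, child) {
    set.seed(child)
    X <- MASS::mvrnorm(n, mu = rep(0, n_regions), Sigma = covg$matrix)
    suv_mean + suv_sd * X
  }
  Xa <- draw(cov_a, n_a, child_seed(seed, "sample_group", 1L))
  Xb <- draw(cov_b, n_b, child_seed(seed, "sample_group", 2L))
  values <- rbind(Xa, Xb)
  colnames(values) <- region_names
  ga <- if (!is.null(cov_a$group_id)) cov_a$group_id else "A"
  gb <- if (!is.null(cov_b$group_id)) cov_b$group_id else "B"
  if (identical(ga, gb)) gb <- paste0(gb, "2")
  new_suv_table(values,
                subject = sprintf("%s_%02d", rep(c(ga, gb), c(n_a, n_b)),
                                  c(seq_len(n_a), seq_len(n_b))),
                group = rep(c(ga, gb), c(n_a, n_b)))
}

#' Simulate a full cohort from a synthetic specification
#'
#' Convenience wrapper: builds both group covariances from `spec` and
#' samples the table.
#'
#' @param spec a [synthetic_spec()].
#' @param seed integer seed; required.
#' @return An `suv_table`.
#' @export
simulate_suv_table <- function(spec, seed) {
  seed <- require_seed(seed)
  cov_a <- build_group_covariance(spec, 1L)
  cov_b <- build_group_covariance(spec, 2L)
  sample_suv_table(cov_a, cov_b,
                   spec$n_per_group[[1L]], spec$n_per_group[[2L]],
                   spec$suv_mean, spec$suv_sd, seed = seed)
}

#' Simulate a null cohort (no group difference)
#'
#' Both groups are drawn from the FIRST group's covariance; any planted
#' between-group differences in `spec` are ignored. Used to calibrate
#' the permutation tests' false-positive rates.
#'
#' @param spec a [synthetic_spec()].
#' @param seed integer seed; required.
#' @return An `suv_table` whose two groups share a generating covariance.
#' @export
make_null_dataset <- function(spec, seed) {
  seed <- require_seed(seed)
  cov_a <- build_group_covariance(spec, 1L)
  cov_b <- cov_a
  cov_b$group_id <- names(spec$n_per_group)[2L]
  sample_suv_table(cov_a, cov_b,
                   spec$n_per_group[[1L]], spec$n_per_group[[2L]],
                   spec$suv_mean, spec$suv_sd, seed = seed)
}
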