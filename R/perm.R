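#' Two-tailed permutation p-value with add-one correction
#'
#' `p = (1 + #\{|null| >= |observed|\}) / (1 + n_perm)`. The add-one form
#' counts the observed labelling as one member of the permutation
#' distribution, so p is never 0 and never below `1/(n_perm + 1)`.
#'
#' @param observed observed statistic.
#' @param null_samples vector of permuted-label statistics.
#' @return p-value in (0, 1].
#' @export
permutation_pvalue <- function(observed, null_samples) {
  stopifnot(length(null_samples) >= 1L)
  (1 + sum(abs(null_samples) >= abs(observed))) / (1 + length(null_samples))
}

#' Benjamini-Hochberg FDR significance mask
#'
#' Step-up control at level `q`: reject the `k*` smallest p-values where
#' `k* = max(k : p_(k) <= k q / m)`.
#'
#' @param p_values vector of p-values in (0, 1].
#' @param q FDR level (default 0.05).
#' @return Logical rejection mask aligned with `p_values`.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  if (!length(p_values)) stop("empty p-value vector")
  stopifnot(all(p_values > 0), all(p_values <= 1))
  stats::p.adjust(p_values, method = "BH") <= q
}

# Shared label-shuffling helper: draws n_perm group-A index sets of the
# original group sizes from one seeded stream. Subsets of the SMALLER
# group are sampled and complemented if needed, so that swapping the two
# group labels reproduces the same index sets (and hence identical
# two-tailed p-values).
permute_labels <- function(n_total, n_a, n_perm, seed) {
  n_small <- min(n_a, n_total - n_a)
  set.seed(child_seed(seed, "label_perm"))
  subs <- lapply(seq_len(n_perm), function(b) sample.int(n_total, n_small))
  if (n_a == n_small) subs
  else lapply(subs, function(s) seq_len(n_total)[-s])
}

# The two groups of a table, in sorted label order (so that group-label
# swaps negate every observed difference, independent of row order).
table_groups <- function(table) {
  g <- sort(unique(suv_groups(table)))
  if (length(g) != 2L) stop("exactly two groups required; found: ",
                            paste(g, collapse = ", "))
  g
}

#' Edge-level permutation test of metabolic connectivity
#'
#' For every region pair, the observed statistic is the difference of
#' group Pearson correlations (`r_A - r_B`). Each of `n_perm`
#' permutations reassigns subjects to two groups of the original sizes,
#' rebuilds both correlation matrices, and records the per-edge
#' difference; two-tailed p-values come from [permutation_pvalue()].
#' Edges are reported as increased (`r_A > r_B`) or decreased at
#' `alpha`, uncorrected.
#'
#' @param table an `suv_table` with two groups.
#' @param n_perm permutations (default 5000).
#' @param seed integer seed; required.
#' @param alpha edge-wise significance level (default 0.001).
#' @return An `edge_test_result`: `p_matrix` (symmetric, diagonal `NA`),
#'   `observed_diff` matrix, data frames `significant_increased` and
#'   `significant_decreased`, plus `groups`, `n_perm`, `seed`, `alpha`.
#' @export
edge_permutation_test <- function(table, n_perm = 5000, seed, alpha = 0.001) {
  seed <- require_seed(seed)
  groups <- table_groups(table)
  X <- suv_values(table)
  memb <- suv_groups(table)
  n_a <- sum(memb == groups[1L])
  n_b <- sum(memb == groups[2L])
  if (n_a < 4L || n_b < 4L) stop("both groups need at least 4 subjects")
  n <- ncol(X)
  ut <- ut_mask(n)
  edge_diff <- function(idx_a) {
    ra <- stats::cor(X[idx_a, , drop = FALSE])
    rb <- stats::cor(X[-idx_a, , drop = FALSE])
    (ra - rb)[ut]
  }
  obs <- edge_diff(which(memb == groups[1L]))
  perms <- permute_labels(nrow(X), n_a, n_perm, seed)
  exceed <- integer(length(obs))
  for (b in seq_len(n_perm)) {
    d <- edge_diff(perms[[b]])
    exceed <- exceed + (abs(d) >= abs(obs))
  }
  p <- (1 + exceed) / (1 + n_perm)
  P <- matrix(NA_real_, n, n, dimnames = list(colnames(X), colnames(X)))
  P[ut] <- p
  P[lower.tri(P)] <- t(P)[lower.tri(P)]
  O <- matrix(0, n, n, dimnames = dimnames(P))
  O[ut] <- obs
  O <- O + t(O)
  pairs <- which(ut, arr.ind = TRUE)
  sig <- p < alpha
  mk <- function(sel) data.frame(
    region_i = colnames(X)[pairs[sel, 1L]],
    region_j = colnames(X)[pairs[sel, 2L]],
    observed_diff = obs[sel], p_value = p[sel],
    stringsAsFactors = FALSE)
  structure(list(p_matrix = P, observed_diff = O,
                 significant_increased = mk(sig & obs > 0),
                 significant_decreased = mk(sig & obs < 0),
                 groups = groups, n_perm = n_perm, seed = seed, alpha = alpha),
            class = "edge_test_result")
}

# AUC of one global metric for a subject subset (rows idx of X).
.group_metric_auc <- function(X, idx, metric, grid, rank_by,
                              ensemble_size, seed) {
  C <- stats::cor(X[idx, , drop = FALSE])
  diag(C) <- 0
  stack <- build_stack(C, grid, rank_by)
  needs_ens <- metric %in% c("gamma", "lambda", "sigma")
  values <- vapply(seq_along(grid), function(l) {
    sd_l <- if (needs_ens) child_seed(seed, "perm_ens", l) else NULL
    unname(global_metrics(stack$adjacencies[[l]], metrics = metric,
                          ensemble_size = ensemble_size, seed = sd_l))
  }, numeric(1))
  list(values = values, auc = auc_over_grid(values, grid))
}

#' Permutation test on a global metric's AUC over sparsity
#'
#' The observed statistic is `AUC(metric, group A) - AUC(metric,
#' group B)` over the sparsity grid. Every permutation reassigns
#' subject labels (group sizes preserved), rebuilds both group networks
#' and graph stacks, recomputes the metric curve of each, and records
#' the AUC difference. Normalized metrics (gamma/lambda/sigma)
#' recompute their random ensemble inside every permutation, at the
#' (reduced, configurable) `ensemble_size`.
#'
#' @param table an `suv_table` with two groups.
#' @param metric one of `"Lp","Cp","Eglob","Eloc","gamma","lambda","sigma"`.
#' @param grid sparsity grid.
#' @param n_perm permutations (default 5000).
#' @param seed integer seed; required.
#' @param ensemble_size rewired-ensemble size for normalized metrics.
#' @param rank_by edge ranking for thresholding.
#' @return A `permutation_result`: `observed_diff`, `null_diffs`,
#'   `p_value`, `n_perm`, `seed`, `metric`, per-group observed AUCs.
#' @export
global_auc_permutation_test <- function(table, metric, grid = sparsity_grid(),
                                        n_perm = 5000, seed,
                                        ensemble_size = 100,
                                        rank_by = "signed") {
  seed <- require_seed(seed)
  stopifnot(metric %in% GLOBAL_METRICS)
  groups <- table_groups(table)
  X <- suv_values(table)
  memb <- suv_groups(table)
  idx_a0 <- which(memb == groups[1L])
  n_a <- length(idx_a0)
  stat <- function(idx_a, tag) {
    a <- .group_metric_auc(X, idx_a, metric, grid, rank_by, ensemble_size,
                           child_seed(seed, tag, 1L))
    b <- .group_metric_auc(X, setdiff(seq_len(nrow(X)), idx_a), metric, grid,
                           rank_by, ensemble_size, child_seed(seed, tag, 2L))
    list(diff = a$auc - b$auc, auc_a = a$auc, auc_b = b$auc,
         values_a = a$values, values_b = b$values)
  }
  obs <- stat(idx_a0, "obs_ens")
  n_undef <- sum(!is.finite(obs$values_a)) + sum(!is.finite(obs$values_b))
  if (n_undef > 0.2 * 2 * length(grid))
    stop("metric '", metric, "' undefined on more than 20% of grid points")
  perms <- permute_labels(nrow(X), n_a, n_perm, seed)
  null_diffs <- vapply(seq_len(n_perm),
                       function(b) stat(perms[[b]], sprintf("perm_ens_%d", b))$diff,
                       numeric(1))
  structure(list(observed_diff = obs$diff,
                 auc_a = obs$auc_a, auc_b = obs$auc_b,
                 null_diffs = null_diffs,
                 p_value = permutation_pvalue(obs$diff, null_diffs),
                 n_perm = n_perm, seed = seed, metric = metric,
                 groups = groups),
            class = "permutation_result")
}

#' Nodal-metric AUC permutation tests with FDR control
#'
#' Per region and per nodal metric (degree `D`, betweenness `BC`, nodal
#' efficiency `Enod`), tests the group difference of the metric's AUC
#' over the sparsity grid by label permutation, then applies
#' Benjamini-Hochberg FDR at level `q` separately within each metric's
#' family of regions.
#'
#' @param table an `suv_table` with two groups.
#' @param grid sparsity grid.
#' @param n_perm permutations (default 5000).
#' @param seed integer seed; required.
#' @param metrics subset of `c("D", "BC", "Enod")`.
#' @param q FDR level (default 0.05).
#' @param rank_by edge ranking for thresholding.
#' @return A `nodal_test_result`: per metric `observed_diff` (vector
#'   over regions), `p_values`, `fdr_mask`; plus `groups`, `n_perm`,
#'   `seed`, `q`.
#' @export
nodal_auc_permutation_test <- function(table, grid = sparsity_grid(),
                                       n_perm = 5000, seed,
                                       metrics = NODAL_METRICS, q = 0.05,
                                       rank_by = "signed") {
  seed <- require_seed(seed)
  stopifnot(all(metrics %in% NODAL_METRICS))
  groups <- table_groups(table)
  X <- suv_values(table)
  memb <- suv_groups(table)
  idx_a0 <- which(memb == groups[1L])
  n_a <- length(idx_a0)
  nodal_auc <- function(idx) {
    C <- stats::cor(X[idx, , drop = FALSE])
    diag(C) <- 0
    cur <- nodal_metric_curves(build_stack(C, grid, rank_by), metrics)
    vapply(metrics, function(mm) cur[[mm]]$auc, numeric(ncol(X)))
  }
  stat <- function(idx_a)
    nodal_auc(idx_a) - nodal_auc(setdiff(seq_len(nrow(X)), idx_a))
  obs <- stat(idx_a0)                       # regions x metrics
  perms <- permute_labels(nrow(X), n_a, n_perm, seed)
  exceed <- matrix(0L, nrow(obs), ncol(obs))
  for (b in seq_len(n_perm)) {
    d <- stat(perms[[b]])
    exceed <- exceed + (abs(d) >= abs(obs))
  }
  p <- (1 + exceed) / (1 + n_perm)
  res <- lapply(seq_along(metrics), function(k) {
    list(observed_diff = stats::setNames(obs[, k], colnames(X)),
         p_values = stats::setNames(p[, k], colnames(X)),
         fdr_mask = stats::setNames(bh_fdr(p[, k], q), colnames(X)))
  })
  names(res) <- metrics
  structure(c(res, list(groups = groups, n_perm = n_perm, seed = seed, q = q)),
            class = "nodal_test_result")
}
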