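#' Largest connected component size
#'
#' Node count of the biggest set of mutually reachable nodes; isolated
#' nodes are components of size 1, and the empty graph has LCC 0.
#'
#' @param adj binary symmetric adjacency matrix (possibly 0 x 0).
#' @return Integer component size.
#' @export
largest_connected_component_size <- function(adj) {
  if (is.null(adj) || length(adj) == 0L) return(0L)
  lcc_size_cpp(as_adj_int(adj))
}

#' Targeted-attack schedule ordered by betweenness centrality
#'
#' Ranks all nodes by the AUC of their betweenness centrality over the
#' sparsity grid of the group's graph stack, descending (ties broken by
#' region index), and returns that single static ordering. The ordering
#' is computed once on the intact network and is not recomputed as
#' nodes are removed (set `recompute = TRUE` in [run_attack()]'s future
#' extensions is deliberately not offered; the static ranking is the
#' modelled attack).
#'
#' @param net a `group_network` (or weight matrix).
#' @param grid sparsity grid for the BC-AUC ranking.
#' @param rank_by edge ranking for thresholding.
#' @return An `attack_schedule`: list with `kind = "targeted"`, a
#'   one-element `orders` list, and the `bc_auc` ranking values.
#' @export
targeted_schedule <- function(net, grid = sparsity_grid(), rank_by = "signed") {
  stack <- build_stack(net, grid, rank_by)
  bc_auc <- nodal_metric_curves(stack, "BC")$BC$auc
  ord <- order(-bc_auc, seq_along(bc_auc))
  structure(list(kind = "targeted", orders = list(ord), bc_auc = bc_auc),
            class = "attack_schedule")
}

#' Random-failure schedules
#'
#' Independent uniform node-removal orderings drawn from seeded child
#' streams; the default 40 repetitions are averaged by [run_attack()].
#'
#' @param n_nodes node count.
#' @param n_reps number of random orderings (default 40).
#' @param seed integer seed; required.
#' @return An `attack_schedule` with `kind = "random"` and `n_reps`
#'   orderings.
#' @export
random_schedules <- function(n_nodes, n_reps = 40, seed) {
  seed <- require_seed(seed)
  stopifnot(n_reps >= 1L)
  orders <- lapply(seq_len(n_reps), function(r) {
    set.seed(child_seed(seed, "attack_order", r))
    sample.int(n_nodes)
  })
  structure(list(kind = "random", orders = orders, seed = seed),
            class = "attack_schedule")
}

#' Simulate node-removal damage to a group network
#'
#' For each removal step (including step 0, the intact network) and each
#' ordering of the schedule: (a) the weighted correlation matrix is
#' restricted to the surviving nodes and re-thresholded at the minimum
#' density with full connectivity, and the requested global metrics are
#' computed on that connected graph; (b) the LCC size is recorded on the
#' intact binary network (binarized once, at its own minimum connected
#' density) with the removed nodes deleted -- the component structure
#' there, unlike the re-thresholded graph, is free to fragment. For
#' random schedules, metrics and LCC are averaged over the orderings.
#'
#' @param net a `group_network` (or weight matrix).
#' @param schedule an `attack_schedule`.
#' @param steps removed-node counts to evaluate (default `0:(n-2)`).
#' @param metrics global metrics to track (default `Lp, Cp, Eglob,
#'   Eloc`; add `gamma`/`lambda`/`sigma` for ensemble-normalized
#'   trajectories).
#' @param ensemble_size rewired-ensemble size for normalized metrics
#'   (default 100 inside attack loops).
#' @param seed seed for the ensembles (required only for normalized
#'   metrics).
#' @param rank_by edge ranking for thresholding.
#' @return An `attack_result`: `steps`, `fraction` (of nodes removed),
#'   `metrics` (step x metric matrix, averaged over orderings),
#'   `lcc` (vector over steps), `kind`, `n_reps`, `min_density`.
#' @export
run_attack <- function(net, schedule, steps = NULL,
                       metrics = c("Lp", "Cp", "Eglob", "Eloc"),
                       ensemble_size = 100, seed = NULL, rank_by = "signed") {
  W <- if (inherits(net, "group_network")) net$matrix else net
  stopifnot(inherits(schedule, "attack_schedule"))
  n <- nrow(W)
  if (is.null(steps)) steps <- 0:(n - 2L)
  steps <- sort(unique(as.integer(steps)))
  stopifnot(all(steps >= 0L), all(steps <= n - 2L))
  needs_ens <- any(metrics %in% c("gamma", "lambda", "sigma"))
  if (needs_ens) seed <- require_seed(seed)
  intact <- min_density_connected(W, rank_by = rank_by)
  n_reps <- length(schedule$orders)
  M <- matrix(0, length(steps), length(metrics),
              dimnames = list(NULL, metrics))
  lcc <- numeric(length(steps))
  for (r in seq_len(n_reps)) {
    ord <- schedule$orders[[r]]
    for (si in seq_along(steps)) {
      k <- steps[si]
      survivors <- if (k == 0L) seq_len(n) else setdiff(seq_len(n), ord[seq_len(k)])
      mdc <- min_density_connected(W, survivors, rank_by = rank_by)
      sd_s <- if (needs_ens) child_seed(seed, "attack_ens", r * 1000L + si) else NULL
      M[si, ] <- M[si, ] + global_metrics(mdc$adjacency, metrics,
                                          ensemble_size = ensemble_size,
                                          seed = sd_s)
      lcc[si] <- lcc[si] + largest_connected_component_size(
        intact$adjacency[survivors, survivors, drop = FALSE])
    }
  }
  structure(list(steps = steps, fraction = steps / n,
                 metrics = M / n_reps, lcc = lcc / n_reps,
                 kind = schedule$kind, n_reps = n_reps,
                 min_density = intact$density),
            class = "attack_result")
}

#' Group comparison of attack trajectories by permutation
#'
#' Observed statistic: per step and metric, the difference of the two
#' groups' [run_attack()] trajectories (group A minus group B). Each
#' permutation reassigns subject labels, rebuilds both group networks,
#' regenerates the targeted schedule from each permuted group's own
#' betweenness ranking (random orderings are reused across permutations
#' for variance reduction), reruns the attacks and records the per-step
#' differences; p-values per step and metric come from
#' [permutation_pvalue()].
#'
#' @param table an `suv_table` with two groups.
#' @param kind `"random"` or `"targeted"`.
#' @param grid sparsity grid (used for the targeted BC ranking).
#' @param n_perm permutations (default 5000).
#' @param seed integer seed; required.
#' @param n_reps random-failure repetitions (default 40; ignored for
#'   targeted).
#' @param steps removed-node counts to compare (default every step; a
#'   subsample keeps permutation budgets tractable).
#' @param metrics global metrics to compare.
#' @param alpha per-step significance level (default 0.05).
#' @param ensemble_size rewired-ensemble size for normalized metrics.
#' @param max_evals guard: refuse runs whose projected number of
#'   attack-step network evaluations exceeds this ceiling.
#' @param rank_by edge ranking for thresholding.
#' @return A `robustness_comparison`: `steps`, `fraction`,
#'   `observed_diff` (step x metric), `p_values` (step x metric),
#'   `significant` (logical, `p < alpha`), per-group `attack_a` /
#'   `attack_b`, and the run settings.
#' @export
compare_robustness <- function(table, kind = c("random", "targeted"),
                               grid = sparsity_grid(), n_perm = 5000, seed,
                               n_reps = 40, steps = NULL,
                               metrics = c("Lp", "Cp", "Eglob", "Eloc"),
                               alpha = 0.05, ensemble_size = 100,
                               max_evals = 5e6, rank_by = "signed") {
  kind <- match.arg(kind)
  seed <- require_seed(seed)
  groups <- table_groups(table)
  X <- suv_values(table)
  memb <- suv_groups(table)
  n <- ncol(X)
  if (is.null(steps)) steps <- 0:(n - 2L)
  steps <- sort(unique(as.integer(steps)))
  reps_eff <- if (kind == "random") n_reps else 1L
  projected <- (n_perm + 1) * 2 * length(steps) * reps_eff
  if (projected > max_evals)
    stop("projected ", projected, " attack evaluations exceed max_evals = ",
         max_evals, "; lower n_perm, n_reps, or subsample steps", call. = FALSE)
  shared_random <- if (kind == "random")
    random_schedules(n, n_reps, seed = child_seed(seed, "random_attack"))
  else NULL
  idx_a0 <- which(memb == groups[1L])
  n_a <- length(idx_a0)
  group_attack <- function(idx) {
    C <- stats::cor(X[idx, , drop = FALSE])
    diag(C) <- 0
    sched <- if (kind == "targeted") targeted_schedule(C, grid, rank_by)
             else shared_random
    run_attack(C, sched, steps = steps, metrics = metrics,
               ensemble_size = ensemble_size,
               seed = child_seed(seed, "attack_metrics"), rank_by = rank_by)
  }
  stat <- function(idx_a) {
    a <- group_attack(idx_a)
    b <- group_attack(setdiff(seq_len(nrow(X)), idx_a))
    list(diff = a$metrics - b$metrics, a = a, b = b)
  }
  obs <- stat(idx_a0)
  perms <- permute_labels(nrow(X), n_a, n_perm, seed)
  exceed <- matrix(0L, length(steps), length(metrics))
  for (b in seq_len(n_perm)) {
    d <- stat(perms[[b]])$diff
    exceed <- exceed + (abs(d) >= abs(obs$diff))
  }
  p <- (1 + exceed) / (1 + n_perm)
  dimnames(p) <- list(NULL, metrics)
  structure(list(steps = steps, fraction = steps / n,
                 observed_diff = obs$diff, p_values = p,
                 significant = p < alpha,
                 attack_a = obs$a, attack_b = obs$b,
                 kind = kind, groups = groups, n_perm = n_perm,
                 seed = seed, alpha = alpha),
            class = "robustness_comparison")
}
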