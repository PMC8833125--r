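#' @name global-metrics
#' @title Global topological metrics of a binary undirected graph
#'
#' @description
#' The global descriptors used throughout the pipeline:
#' characteristic path length `Lp` (mean shortest-path length over
#' connected node pairs; disconnected pairs are excluded from the mean,
#' the usual convention for thresholded connectomes, which keeps `Lp`
#' defined at low sparsity), clustering coefficient `Cp` (mean over all
#' nodes of the fraction of realized edges among each node's
#' neighbours; nodes of degree < 2 contribute 0), global efficiency
#' `Eglob` (mean inverse shortest-path length over all pairs, with
#' 1/infinity = 0 for disconnected pairs) and local efficiency `Eloc`
#' (mean over nodes of the global efficiency of each node's
#' neighbour-induced subgraph).
#'
#' @param adj binary symmetric adjacency matrix with zero diagonal.
#' @return `characteristic_path_length` and `global_efficiency` return a
#'   single number (`NA` when no pair is connected);
#'   `clustering_coefficient` and `local_efficiency` return a list with
#'   `per_node` and the graph-level mean.
NULL

as_adj_int <- function(adj) {
  stopifnot(is.matrix(adj), nrow(adj) == ncol(adj))
  storage.mode(adj) <- "integer"
  adj
}

#' @rdname global-metrics
#' @export
characteristic_path_length <- function(adj) {
  adj <- as_adj_int(adj)
  if (nrow(adj) < 2L) return(NA_real_)
  D <- bfs_distances_cpp(adj)
  d <- D[ut_mask(nrow(adj))]
  d <- d[d > 0L]
  if (!length(d)) return(NA_real_)
  mean(d)
}

#' @rdname global-metrics
#' @export
global_efficiency <- function(adj) {
  adj <- as_adj_int(adj)
  if (nrow(adj) < 2L) return(NA_real_)
  D <- bfs_distances_cpp(adj)
  d <- D[ut_mask(nrow(adj))]
  iv <- 1 / d          # unreachable pairs carry d = -1
  iv[d < 0L] <- 0
  mean(iv)
}

#' @rdname global-metrics
#' @export
clustering_coefficient <- function(adj) {
  adj <- as_adj_int(adj)
  k <- rowSums(adj)
  A2 <- adj %*% adj
  closed <- rowSums(A2 * adj)        # 2 x (edges among neighbours)
  per_node <- ifelse(k >= 2L, closed / (k * (k - 1)), 0)
  list(per_node = per_node, Cp = mean(per_node))
}

#' @rdname global-metrics
#' @export
local_efficiency <- function(adj) {
  adj <- as_adj_int(adj)
  per_node <- local_efficiency_nodes_cpp(adj)
  list(per_node = per_node, Eloc = mean(per_node))
}

#' Nodal metrics: degree, betweenness centrality, nodal efficiency
#'
#' `node_degree` counts each node's neighbours. `betweenness_centrality`
#' is the Brandes shortest-path betweenness of an undirected unweighted
#' graph, unnormalized, with each unordered endpoint pair counted once.
#' `nodal_efficiency` is each node's mean inverse shortest-path length
#' to all other nodes (1/infinity = 0).
#'
#' @param adj binary symmetric adjacency matrix with zero diagonal.
#' @return Numeric vector, one value per node.
#' @export
node_degree <- function(adj) {
  adj <- as_adj_int(adj)
  as.integer(rowSums(adj))
}

#' @rdname node_degree
#' @export
betweenness_centrality <- function(adj) {
  adj <- as_adj_int(adj)
  as.numeric(betweenness_cpp(adj))
}

#' @rdname node_degree
#' @export
nodal_efficiency <- function(adj) {
  adj <- as_adj_int(adj)
  n <- nrow(adj)
  if (n < 2L) return(rep(0, n))
  D <- bfs_distances_cpp(adj)
  inv <- 1 / D
  inv[D <= 0L] <- 0    # diagonal zeros and unreachable (-1) pairs
  rowSums(inv) / (n - 1L)
}

#' Degree-preserving random rewiring (Maslov-Sneppen)
#'
#' Repeated double-edge swaps that reject self-loops and multi-edges,
#' preserving every node's degree exactly. This is the null model behind
#' the small-world indices: gamma and lambda compare the observed
#' clustering and path length to the means of an ensemble of such
#' rewired graphs.
#'
#' @param adj binary symmetric adjacency matrix.
#' @param n_swap_per_edge swap attempts per edge (default 10).
#' @param seed integer seed; required.
#' @return A rewired adjacency matrix with the same degree sequence.
#' @export
rewire_degree_preserving <- function(adj, n_swap_per_edge = 10, seed) {
  seed <- require_seed(seed)
  adj <- as_adj_int(adj)
  m <- sum(adj) / 2
  if (m < 2) {
    warning("graph has fewer than 2 edges; no swap possible, returning input")
    return(adj)
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  set.seed(seed)
  g2 <- igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                                 niter = ceiling(n_swap_per_edge * m)))
  out <- as.matrix(igraph::as_adjacency_matrix(g2, type = "both", sparse = FALSE))
  dimnames(out) <- dimnames(adj)
  storage.mode(out) <- "integer"
  out
}

#' Small-world indices against a degree-matched random ensemble
#'
#' gamma = Cp / mean(Cp) of `ensemble_size` degree-preserving rewired
#' graphs; lambda = Lp / mean(Lp) of the same ensemble; sigma =
#' gamma / lambda. sigma > 1 indicates small-world organization. Each
#' ensemble member uses its own child seed of `seed`, so results are
#' reproducible and members are independent.
#'
#' @param adj binary symmetric adjacency matrix with at least 2 edges.
#' @param ensemble_size number of rewired graphs (default 5000).
#' @param seed integer seed; required.
#' @param n_swap_per_edge swap attempts per edge for each member.
#' @return List with `gamma`, `lambda`, `sigma` and `ensemble`
#'   (`mean_Cp_rand`, `mean_Lp_rand`, `ensemble_size`).
#' @export
small_world <- function(adj, ensemble_size = 5000, seed, n_swap_per_edge = 10) {
  seed <- require_seed(seed)
  adj <- as_adj_int(adj)
  stopifnot(sum(adj) / 2 >= 2)
  Cp <- clustering_coefficient(adj)$Cp
  Lp <- characteristic_path_length(adj)
  cp_r <- lp_r <- numeric(ensemble_size)
  for (b in seq_len(ensemble_size)) {
    R <- rewire_degree_preserving(adj, n_swap_per_edge,
                                  seed = child_seed(seed, "rewire", b))
    cp_r[b] <- clustering_coefficient(R)$Cp
    lp_r[b] <- characteristic_path_length(R)
  }
  mean_cp <- mean(cp_r)
  mean_lp <- mean(lp_r, na.rm = TRUE)
  if (mean_cp == 0) {
    warning("random ensemble has zero mean clustering; gamma and sigma undefined")
    gamma <- sigma <- NA_real_
    lambda <- Lp / mean_lp
  } else {
    gamma <- Cp / mean_cp
    lambda <- Lp / mean_lp
    sigma <- gamma / lambda
  }
  list(gamma = gamma, lambda = lambda, sigma = sigma,
       ensemble = list(mean_Cp_rand = mean_cp, mean_Lp_rand = mean_lp,
                       ensemble_size = ensemble_size))
}

#' Area under a metric-versus-sparsity curve
#'
#' Trapezoidal integral of metric values against the sparsity grid, the
#' scalar on which all group comparisons operate. Grid points with
#' undefined values (`NA`) are dropped, with a warning.
#'
#' @param values metric value per grid point.
#' @param grid sparsity grid (same length).
#' @return The trapezoidal AUC.
#' @export
auc_over_grid <- function(values, grid) {
  stopifnot(length(values) == length(grid))
  ok <- is.finite(values)
  if (!all(ok)) {
    warning(sum(!ok), " undefined grid point(s) dropped from AUC")
    values <- values[ok]
    grid <- grid[ok]
  }
  if (length(grid) < 2L) stop("AUC needs at least 2 defined grid points")
  pracma::trapz(grid, values)
}

# Trapezoid quadrature weights for a grid; AUC = values %*% weights.
trap_weights <- function(grid) {
  L <- length(grid)
  w <- numeric(L)
  w[1L] <- (grid[2L] - grid[1L]) / 2
  w[L] <- (grid[L] - grid[L - 1L]) / 2
  if (L > 2L) w[2:(L - 1L)] <- (grid[3:L] - grid[1:(L - 2L)]) / 2
  w
}

# Names of the global metrics in reporting order.
GLOBAL_METRICS <- c("Lp", "Cp", "Eglob", "Eloc", "gamma", "lambda", "sigma")
NODAL_METRICS <- c("D", "BC", "Enod")

#' Compute selected global metrics of one binary graph
#'
#' @param adj binary adjacency matrix.
#' @param metrics subset of `c("Lp","Cp","Eglob","Eloc","gamma","lambda","sigma")`.
#' @param ensemble_size random-ensemble size for gamma/lambda/sigma.
#' @param seed seed for the ensemble (required only when normalized
#'   metrics are requested).
#' @return Named numeric vector over `metrics`.
#' @export
global_metrics <- function(adj, metrics = GLOBAL_METRICS,
                           ensemble_size = 5000, seed = NULL) {
  stopifnot(all(metrics %in% GLOBAL_METRICS))
  out <- stats::setNames(rep(NA_real_, length(metrics)), metrics)
  if ("Lp" %in% metrics) out["Lp"] <- characteristic_path_length(adj)
  if ("Cp" %in% metrics) out["Cp"] <- clustering_coefficient(adj)$Cp
  if ("Eglob" %in% metrics) out["Eglob"] <- global_efficiency(adj)
  if ("Eloc" %in% metrics) out["Eloc"] <- local_efficiency(adj)$Eloc
  if (any(c("gamma", "lambda", "sigma") %in% metrics)) {
    sw <- small_world(adj, ensemble_size = ensemble_size, seed = require_seed(seed))
    for (mm in intersect(metrics, c("gamma", "lambda", "sigma")))
      out[mm] <- sw[[mm]]
  }
  out
}

#' Global metric curve over a graph stack
#'
#' Evaluates one global metric at every sparsity of a
#' `binary_graph_stack` and integrates the curve.
#'
#' @param stack a `binary_graph_stack`.
#' @param metric one of the global metric names.
#' @param ensemble_size,seed passed to [small_world()] when the metric
#'   is normalized (gamma/lambda/sigma); each sparsity level uses its
#'   own child seed.
#' @return A `metric_curve`: list with `grid`, `values`, `auc`, `metric`.
#' @export
global_metric_curve <- function(stack, metric, ensemble_size = 100, seed = NULL) {
  stopifnot(inherits(stack, "binary_graph_stack"), metric %in% GLOBAL_METRICS)
  needs_ens <- metric %in% c("gamma", "lambda", "sigma")
  if (needs_ens) seed <- require_seed(seed)
  values <- vapply(seq_along(stack$grid), function(l) {
    sd_l <- if (needs_ens) child_seed(seed, "curve_level", l) else NULL
    unname(global_metrics(stack$adjacencies[[l]], metrics = metric,
                          ensemble_size = ensemble_size, seed = sd_l))
  }, numeric(1))
  structure(list(grid = stack$grid, values = values,
                 auc = auc_over_grid(values, stack$grid), metric = metric),
            class = "metric_curve")
}

#' Nodal metric curves and AUCs over a graph stack
#'
#' Evaluates the nodal metrics (degree `D`, betweenness `BC`, nodal
#' efficiency `Enod`) at every sparsity and returns, per metric, the
#' node x sparsity value matrix and the per-node AUC.
#'
#' @param stack a `binary_graph_stack`.
#' @param metrics subset of `c("D", "BC", "Enod")`.
#' @return Named list; per metric a list with `values` (matrix) and
#'   `auc` (vector over nodes).
#' @export
nodal_metric_curves <- function(stack, metrics = NODAL_METRICS) {
  stopifnot(inherits(stack, "binary_graph_stack"), all(metrics %in% NODAL_METRICS))
  n <- nrow(stack$adjacencies[[1L]])
  L <- length(stack$grid)
  fns <- list(D = function(a) as.numeric(node_degree(a)),
              BC = betweenness_centrality,
              Enod = nodal_efficiency)
  w <- trap_weights(stack$grid)
  out <- lapply(metrics, function(mm) {
    V <- vapply(stack$adjacencies, fns[[mm]], numeric(n))
    list(values = V, auc = as.numeric(V %*% w))
  })
  names(out) <- metrics
  out
}
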