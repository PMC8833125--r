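#' Sparsity grid for the binarization sweep
#'
#' The default grid, 0.05 to 0.50 in steps of 0.01 (46 values), spans
#' densities from near the connectivity threshold of a 96-node network
#' up to half of all possible edges; group comparisons integrate metric
#' curves over this grid.
#'
#' @param from,to,by grid limits and step, all in (0, 1).
#' @return Strictly increasing numeric vector of sparsities.
#' @export
sparsity_grid <- function(from = 0.05, to = 0.50, by = 0.01) {
  g <- round(seq(from, to, by = by), 10)
  stopifnot(length(g) >= 1L, all(g > 0), all(g < 1), !is.unsorted(g, strictly = TRUE))
  g
}

#' Round half away from zero
#'
#' Edge counts `k = round(S * n_pairs)` use half-away-from-zero rounding
#' (not banker's rounding) so counts are platform independent.
#' @param x non-negative numeric.
#' @return Integer vector.
#' @keywords internal
round_half_up <- function(x) as.integer(floor(x + 0.5))

#' Group-level inter-subject correlation network
#'
#' The metabolic connectivity of a group: entry (i, j) is the Pearson
#' correlation of regions i and j across the group's subjects. The
#' diagonal is stored as zero (self-edges are excluded throughout).
#'
#' @param table an `suv_table`.
#' @param group group label to select.
#' @return A `group_network`: list with the correlation `matrix`,
#'   `group_id` and `n_subjects`.
#' @export
group_correlation <- function(table, group) {
  stopifnot(inherits(table, "suv_table"))
  rows <- suv_groups(table) == group
  if (sum(rows) < 4L)
    stop("group '", group, "' has ", sum(rows), " subjects; at least 4 required")
  X <- suv_values(table)[rows, , drop = FALSE]
  v <- apply(X, 2L, stats::var)
  if (any(v <= 0))
    stop("zero-variance region(s) in group '", group, "': ",
         paste(colnames(X)[v <= 0], collapse = ", "))
  C <- stats::cor(X)
  diag(C) <- 0
  structure(list(matrix = C, group_id = group, n_subjects = sum(rows)),
            class = "group_network")
}

# Upper-triangle edges of a weight matrix, ordered for thresholding:
# descending signed weight (or |weight| if rank_by = "absolute"), ties by
# descending |weight| then lexicographic (i, j). Returns a data frame
# with 1-based node indices and the weights.
ordered_edges <- function(W, rank_by = c("signed", "absolute")) {
  rank_by <- match.arg(rank_by)
  n <- nrow(W)
  ut <- ut_pairs(n)
  w <- W[ut]
  key <- if (rank_by == "signed") -w else -abs(w)
  ord <- order(key, -abs(w), ut[, 1L], ut[, 2L])
  list(i = ut[ord, 1L], j = ut[ord, 2L], w = w[ord])
}

# Build the n x n binary adjacency containing the first k ordered edges.
adjacency_from_edges <- function(edges, k, n) {
  A <- matrix(0L, n, n)
  if (k > 0L) {
    idx <- seq_len(k)
    A[cbind(edges$i[idx], edges$j[idx])] <- 1L
    A[cbind(edges$j[idx], edges$i[idx])] <- 1L
  }
  A
}

#' Binarize a correlation network at a target sparsity
#'
#' Retains exactly `round(s * n_pairs)` edges -- the strongest
#' correlations by signed value (most-positive first; set
#' `rank_by = "absolute"` to rank by magnitude) -- and returns the
#' unweighted symmetric adjacency. Ties crossing the cut boundary are
#' broken by higher |r| then region order, deterministically, with a
#' warning.
#'
#' @param net a `group_network` (or a bare symmetric weight matrix).
#' @param s sparsity in (0, 1).
#' @param rank_by `"signed"` (default) or `"absolute"` edge ranking.
#' @return Binary integer adjacency matrix with zero diagonal.
#' @export
threshold_sparsity <- function(net, s, rank_by = "signed") {
  W <- if (inherits(net, "group_network")) net$matrix else net
  stopifnot(is.matrix(W), nrow(W) == ncol(W), s > 0, s < 1)
  n <- nrow(W)
  n_pairs <- n * (n - 1L) / 2L
  k <- round_half_up(s * n_pairs)
  edges <- ordered_edges(W, rank_by)
  if (k > 0L && k < n_pairs && edges$w[k] == edges$w[k + 1L])
    warning("tied correlations at the sparsity cut (s = ", s,
            "); broken by |r| then region order", call. = FALSE)
  adjacency_from_edges(edges, k, n)
}

#' Binarize a network over a whole sparsity grid
#'
#' One adjacency per grid value; because all layers take the top-k edges
#' of one fixed ranking, the stack is nested (every edge present at a
#' smaller sparsity is present at every larger one).
#'
#' @param net a `group_network`.
#' @param grid sparsity vector (default [sparsity_grid()]).
#' @param rank_by edge ranking, as in [threshold_sparsity()].
#' @return A `binary_graph_stack`: list with `grid`, `adjacencies`
#'   (list of binary matrices) and `group_id`.
#' @export
build_stack <- function(net, grid = sparsity_grid(), rank_by = "signed") {
  W <- if (inherits(net, "group_network")) net$matrix else net
  n <- nrow(W)
  n_pairs <- n * (n - 1L) / 2L
  edges <- ordered_edges(W, rank_by)
  ks <- round_half_up(grid * n_pairs)
  adjacencies <- lapply(ks, function(k) adjacency_from_edges(edges, k, n))
  structure(list(grid = grid, adjacencies = adjacencies,
                 group_id = if (inherits(net, "group_network")) net$group_id else NA_character_),
            class = "binary_graph_stack")
}

#' Threshold at the minimum density keeping the graph connected
#'
#' Starting from the strongest correlation, edges are added in ranked
#' order until the graph on `active_nodes` is connected; the retained
#' edge count is minimal for that ranking (dropping the last-added edge
#' class disconnects the graph). Used to re-threshold the surviving
#' network after simulated node removal.
#'
#' @param net a `group_network` or symmetric weight matrix.
#' @param active_nodes integer node subset (default all nodes).
#' @param rank_by edge ranking, as in [threshold_sparsity()].
#' @return List with `density` (retained / possible edges), `adjacency`
#'   (binary matrix on the active nodes, in `active_nodes` order), and
#'   `nodes` (the active node indices).
#' @export
min_density_connected <- function(net, active_nodes = NULL, rank_by = "signed") {
  W <- if (inherits(net, "group_network")) net$matrix else net
  n_all <- nrow(W)
  if (is.null(active_nodes)) active_nodes <- seq_len(n_all)
  active_nodes <- sort(unique(as.integer(active_nodes)))
  stopifnot(length(active_nodes) >= 2L, all(active_nodes >= 1L),
            all(active_nodes <= n_all))
  Wsub <- W[active_nodes, active_nodes, drop = FALSE]
  n <- length(active_nodes)
  edges <- ordered_edges(Wsub, rank_by)
  m <- edges_until_connected_cpp(edges$i - 1L, edges$j - 1L, n)
  if (m < 0L) stop("internal: complete edge list failed to connect the graph")
  list(density = m / (n * (n - 1L) / 2L),
       adjacency = adjacency_from_edges(edges, m, n),
       nodes = active_nodes)
}
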