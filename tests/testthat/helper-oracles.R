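# Brute-force oracles, independent of the package's graph kernels.
# All operate on plain 0/1 matrices and are only used at n <= ~20.

# Floyd-Warshall all-pairs distances; Inf marks unreachable pairs.
oracle_distances <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  D[adj > 0] <- 1
  diag(D) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

oracle_lp <- function(adj) {
  D <- oracle_distances(adj)
  d <- D[upper.tri(D)]
  d <- d[is.finite(d) & d > 0]
  if (!length(d)) NA_real_ else mean(d)
}

oracle_eglob <- function(adj) {
  D <- oracle_distances(adj)
  d <- D[upper.tri(D)]
  mean(ifelse(is.finite(d) & d > 0, 1 / d, 0))
}

oracle_cp <- function(adj) {
  n <- nrow(adj)
  per <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    e <- sum(adj[nb, nb]) / 2
    e / (k * (k - 1) / 2)
  }, numeric(1))
  list(per_node = per, Cp = mean(per))
}

oracle_eloc <- function(adj) {
  n <- nrow(adj)
  per <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] > 0)
    if (length(nb) < 2) return(0)
    oracle_eglob(adj[nb, nb, drop = FALSE])
  }, numeric(1))
  list(per_node = per, Eloc = mean(per))
}

oracle_degree <- function(adj) as.integer(rowSums(adj))

oracle_enod <- function(adj) {
  D <- oracle_distances(adj)
  n <- nrow(adj)
  vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    sum(ifelse(is.finite(d) & d > 0, 1 / d, 0)) / (n - 1)
  }, numeric(1))
}

# Betweenness by exhaustive enumeration of all shortest paths.
oracle_bc <- function(adj) {
  n <- nrow(adj)
  D <- oracle_distances(adj)
  bc <- numeric(n)
  all_shortest <- function(s, t) {
    # returns list of node vectors, every shortest s->t path
    if (s == t) return(list(s))
    if (!is.finite(D[s, t])) return(list())
    preds <- which(adj[, t] > 0 & D[s, ] == D[s, t] - 1)
    out <- list()
    for (p in preds)
      for (path in all_shortest(s, p))
        out[[length(out) + 1L]] <- c(path, t)
    out
  }
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- all_shortest(s, t)
    if (!length(paths)) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      thru <- sum(vapply(paths, function(p) v %in% p, logical(1)))
      bc[v] <- bc[v] + thru / length(paths)
    }
  }
  bc
}

# From-definition two-pass Pearson correlation.
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Erdos-Renyi-style random 0/1 symmetric adjacency.
random_adj <- function(n, p = 0.4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(0L, n, n)
  A[upper.tri(A)] <- as.integer(runif(n * (n - 1) / 2) < p)
  A + t(A)
}

# Named small graphs used in the closed-form checks.
graph_complete <- function(n) {
  A <- matrix(1L, n, n); diag(A) <- 0L; A
}
graph_cycle <- function(n) {
  A <- matrix(0L, n, n)
  for (i in seq_len(n)) { j <- i %% n + 1L; A[i, j] <- A[j, i] <- 1L }
  A
}
graph_path <- function(n) {
  A <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) { A[i, i + 1L] <- A[i + 1L, i] <- 1L }
  A
}
graph_star <- function(n_leaves) {
  n <- n_leaves + 1L
  A <- matrix(0L, n, n)
  A[1L, 2:n] <- A[2:n, 1L] <- 1L
  A
}

# Small two-group SUV table built directly from value matrices.
toy_table <- function(values_a, values_b, region_names = NULL) {
  values <- rbind(values_a, values_b)
  if (is.null(region_names)) region_names <- paste0("R", seq_len(ncol(values)))
  colnames(values) <- region_names
  metconn:::new_suv_table(
    values,
    subject = sprintf("s%02d", seq_len(nrow(values))),
    group = rep(c("A", "B"), c(nrow(values_a), nrow(values_b))))
}

# A quick synthetic spec at reduced region count for plumbing tests.
small_spec <- function(n_regions = 20L, n = c(A = 8L, B = 8L), ...)
  synthetic_spec(n_regions = n_regions, n_per_group = n,
                 blocks = c(n_regions %/% 2L, n_regions - n_regions %/% 2L),
                 ...)
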