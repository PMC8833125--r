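test_that("group correlations match the definition and its edge cases", {
  # duplicated region -> r = 1; negated region -> r = -1
  set.seed(4)
  x <- rnorm(6)
  va <- cbind(x, x, -x, rnorm(6))
  tab <- toy_table(va, matrix(rnorm(24), 6))
  net <- group_correlation(tab, "A")
  expect_equal(net$matrix[1, 2], 1)
  expect_equal(net$matrix[1, 3], -1)
  expect_equal(unname(diag(net$matrix)), rep(0, 4))

  # 3-subject toy by hand: dev_x = (-1,0,1), dev_y = (-1/3,-4/3,5/3),
  # cov-sum 2, ss_x 2, ss_y 14/3 -> r = 2/sqrt(28/3)
  expect_equal(oracle_pearson(c(1, 2, 3), c(2, 1, 4)), 2 / sqrt(28 / 3))
  tab2 <- toy_table(cbind(c(1, 2, 3, 4), c(2, 1, 4, 6)),
                    matrix(rnorm(8), 4))
  r <- cor(c(1, 2, 3, 4), c(2, 1, 4, 6))
  expect_equal(group_correlation(tab2, "A")$matrix[1, 2], r)

  # zero-variance region is refused by name
  tab3 <- toy_table(cbind(rep(1, 5), rnorm(5)), matrix(rnorm(10), 5),
                    region_names = c("flat", "ok"))
  expect_error(group_correlation(tab3, "A"), "flat")
  expect_error(group_correlation(toy_table(matrix(rnorm(6), 3),
                                           matrix(rnorm(6), 3)), "A"),
               "at least 4")
})

test_that("group correlation equals a from-definition oracle on random tables", {
  for (s in 1:50) {
    set.seed(s)
    n_sub <- sample(4:9, 1); n_reg <- sample(4:8, 1)
    tab <- toy_table(matrix(rnorm(n_sub * n_reg), n_sub),
                     matrix(rnorm(4 * n_reg), 4))
    M <- group_correlation(tab, "A")$matrix
    X <- suv_values(tab)[suv_groups(tab) == "A", ]
    for (i in seq_len(n_reg - 1)) for (j in (i + 1):n_reg)
      expect_equal(M[i, j], oracle_pearson(X[, i], X[, j]), tolerance = 1e-12)
  }
})

test_that("permuting input regions permutes the correlation matrix identically", {
  set.seed(10)
  va <- matrix(rnorm(6 * 8), 6); vb <- matrix(rnorm(5 * 8), 5)
  tab <- toy_table(va, vb)
  perm <- sample(8)
  tab_p <- toy_table(va[, perm], vb[, perm],
                     region_names = paste0("R", perm))
  M <- group_correlation(tab, "A")$matrix
  Mp <- group_correlation(tab_p, "A")$matrix
  expect_equal(unname(Mp), unname(M[perm, perm]))
})

test_that("sparsity thresholding retains the exact edge count and nests", {
  sp <- synthetic_spec()
  net <- group_correlation(simulate_suv_table(sp, seed = 8), "aged")
  expect_equal(sum(threshold_sparsity(net, 0.05)) / 2, 228)
  expect_equal(sum(threshold_sparsity(net, 0.50)) / 2, 2280)
  a1 <- threshold_sparsity(net, 0.13)
  a2 <- threshold_sparsity(net, 0.37)
  expect_true(all(a2[a1 == 1L] == 1L))          # nesting
  expect_true(isSymmetric(a1))
  expect_equal(unname(diag(a1)), rep(0L, 96))
})

test_that("stacks cover the default grid with exact nested layer counts", {
  sp <- synthetic_spec()
  net <- group_correlation(simulate_suv_table(sp, seed = 8), "young")
  grid <- sparsity_grid()
  expect_length(grid, 46)
  st <- build_stack(net, grid)
  expect_length(st$adjacencies, 46)
  counts <- vapply(st$adjacencies, function(a) sum(a) / 2, numeric(1))
  expect_equal(counts, as.numeric(floor(grid * 4560 + 0.5)))
  for (l in seq_len(45))
    expect_true(all(st$adjacencies[[l + 1]][st$adjacencies[[l]] == 1L] == 1L))
  expect_true(all(vapply(st$adjacencies, isSymmetric, logical(1))))
})

test_that("tied correlations at the cut are resolved deterministically with a warning", {
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 0.9
  W[3, 4] <- W[4, 3] <- 0.5
  W[1, 3] <- W[3, 1] <- 0.5
  # k = round(0.34 * 6) = 2: boundary falls inside the 0.5 tie
  expect_warning(a <- threshold_sparsity(W, 0.34), "tie")
  expect_equal(sum(a) / 2, 2)
  expect_equal(a[1, 3], 1L)                    # lexicographic tie-break
  expect_equal(a[3, 4], 0L)
})

test_that("minimum connected density matches a Kruskal-style oracle", {
  # dominant spanning tree on 5 nodes: tree edges carry the top weights
  W <- matrix(0, 5, 5)
  tree <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5))
  W[tree] <- c(0.9, 0.8, 0.7, 0.6); W <- W + t(W)
  others <- which(upper.tri(W) & W == 0, arr.ind = TRUE)
  W[others] <- runif(nrow(others), 0.0, 0.3)
  W[others[, c(2, 1)]] <- W[others]
  mdc <- min_density_connected(W)
  expect_equal(mdc$density, 4 / 10)
  expect_equal(sum(mdc$adjacency) / 2, 4)
  expect_equal(which(mdc$adjacency[1, ] == 1L), 2L)

  # 2 active nodes -> the single edge, density 1
  mdc2 <- min_density_connected(W, active_nodes = c(2, 5))
  expect_equal(mdc2$density, 1)
  expect_equal(sum(mdc2$adjacency) / 2, 1)
})

test_that("minimum connected density is minimal and connected on random matrices", {
  for (s in 1:100) {
    set.seed(s + 300)
    n <- sample(5:20, 1)
    W <- matrix(rnorm(n * n), n); W <- (W + t(W)) / 2; diag(W) <- 0
    mdc <- min_density_connected(W)
    # sorted-union-find oracle on retained edge count
    ut <- which(upper.tri(W), arr.ind = TRUE)
    ord <- order(-W[ut])
    g <- igraph::make_empty_graph(n, directed = FALSE)
    m_oracle <- 0L
    for (e in ord) {
      g <- igraph::add_edges(g, c(ut[e, 1], ut[e, 2]))
      m_oracle <- m_oracle + 1L
      if (igraph::is_connected(g)) break
    }
    expect_equal(sum(mdc$adjacency) / 2, m_oracle)
    gf <- igraph::graph_from_adjacency_matrix(mdc$adjacency, mode = "undirected")
    expect_true(igraph::is_connected(gf))
  }
})
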