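test_that("closed-form graphs give the textbook metric values", {
  K4 <- graph_complete(4)
  expect_equal(characteristic_path_length(K4), 1)
  expect_equal(clustering_coefficient(K4)$Cp, 1)
  expect_equal(global_efficiency(K4), 1)
  expect_equal(local_efficiency(K4)$Eloc, 1)
  expect_equal(node_degree(K4), rep(3L, 4))
  expect_equal(nodal_efficiency(K4), rep(1, 4))

  C5 <- graph_cycle(5)
  expect_equal(characteristic_path_length(C5), 1.5)
  expect_equal(global_efficiency(C5), 0.75)

  P4 <- graph_path(4)
  expect_equal(characteristic_path_length(P4), 10 / 6)

  star <- graph_star(4)
  expect_equal(clustering_coefficient(star)$Cp, 0)
  expect_equal(local_efficiency(star)$Eloc, 0)
  expect_equal(node_degree(star), c(4L, 1L, 1L, 1L, 1L))
  # star hub: direct edges to leaves, leaves two hops apart
  expect_equal(nodal_efficiency(star)[1], 1)
  expect_equal(nodal_efficiency(star)[2], (1 + 3 * 0.5) / 4)

  star5 <- graph_star(5)
  expect_equal(betweenness_centrality(star5)[1], choose(5, 2))
  expect_equal(betweenness_centrality(star5)[-1], rep(0, 5))

  P3 <- graph_path(3)
  expect_equal(betweenness_centrality(P3), c(0, 1, 0))

  # triangle with a pendant on node 1
  tri <- graph_complete(3)
  tp <- rbind(cbind(tri, c(1L, 0L, 0L)), c(1L, 0L, 0L, 0L))
  expect_equal(clustering_coefficient(tp)$per_node, c(1 / 3, 1, 1, 0))
  expect_equal(clustering_coefficient(tp)$Cp, 7 / 12)
  expect_equal(local_efficiency(tp)$per_node, c(1 / 3, 1, 1, 0))

  # disconnection conventions: two disjoint edges on 4 nodes
  two <- matrix(0L, 4, 4)
  two[1, 2] <- two[2, 1] <- two[3, 4] <- two[4, 3] <- 1L
  expect_equal(global_efficiency(two), 1 / 3)
  expect_equal(characteristic_path_length(two), 1)   # finite pairs only
  edgeless <- matrix(0L, 5, 5)
  expect_true(is.na(characteristic_path_length(edgeless)))
  expect_equal(nodal_efficiency(edgeless), rep(0, 5))
})

test_that("all metrics match brute-force oracles on random small graphs", {
  for (s in 1:50) {
    A <- random_adj(sample(4:10, 1), runif(1, 0.2, 0.8), seed = s)
    expect_equal(node_degree(A), oracle_degree(A))
    expect_equal(betweenness_centrality(A), oracle_bc(A), tolerance = 1e-12)
    lp <- oracle_lp(A)
    if (is.na(lp)) expect_true(is.na(characteristic_path_length(A)))
    else expect_equal(characteristic_path_length(A), lp, tolerance = 1e-12)
    expect_equal(global_efficiency(A), oracle_eglob(A), tolerance = 1e-12)
    expect_equal(clustering_coefficient(A)$per_node, oracle_cp(A)$per_node,
                 tolerance = 1e-12)
    expect_equal(local_efficiency(A)$per_node, oracle_eloc(A)$per_node,
                 tolerance = 1e-12)
    expect_equal(nodal_efficiency(A), oracle_enod(A), tolerance = 1e-12)
  }
})

test_that("relabeling nodes permutes nodal metrics and fixes global ones", {
  for (s in 1:10) {
    A <- random_adj(8, 0.4, seed = 100 + s)
    p <- sample(8)
    Ap <- A[p, p]
    expect_equal(characteristic_path_length(Ap), characteristic_path_length(A))
    expect_equal(clustering_coefficient(Ap)$Cp, clustering_coefficient(A)$Cp)
    expect_equal(global_efficiency(Ap), global_efficiency(A))
    expect_equal(local_efficiency(Ap)$Eloc, local_efficiency(A)$Eloc)
    expect_equal(betweenness_centrality(Ap), betweenness_centrality(A)[p])
    expect_equal(nodal_efficiency(Ap), nodal_efficiency(A)[p])
    expect_equal(node_degree(Ap), node_degree(A)[p])
    expect_equal(sum(node_degree(A)), sum(A))       # handshake
  }
})

test_that("global efficiency is non-decreasing along a nested stack", {
  sp <- small_spec()
  net <- group_correlation(simulate_suv_table(sp, seed = 21), "A")
  st <- build_stack(net, sparsity_grid(0.1, 0.9, 0.05))
  eg <- vapply(st$adjacencies, global_efficiency, numeric(1))
  expect_true(all(diff(eg) >= -1e-12))
})

test_that("degree-preserving rewiring keeps degrees and perturbs edges", {
  C8 <- graph_cycle(8)
  changed <- 0L
  for (s in 1:20) {
    R <- rewire_degree_preserving(C8, n_swap_per_edge = 20, seed = s)
    expect_equal(sort(node_degree(R)), sort(node_degree(C8)))
    expect_equal(unname(diag(R)), rep(0L, 8))
    expect_true(isSymmetric(R))
    if (!identical(R, C8)) changed <- changed + 1L
  }
  expect_gte(changed, 15L)
  expect_identical(rewire_degree_preserving(C8, seed = 5),
                   rewire_degree_preserving(C8, seed = 5))
  # complete graph admits no swap
  expect_identical(rewire_degree_preserving(graph_complete(4), seed = 1),
                   graph_complete(4))
  expect_warning(rewire_degree_preserving(graph_path(2), seed = 1), "swap")
})

test_that("small-world indices satisfy sigma = gamma/lambda and self-calibrate", {
  A <- random_adj(30, 0.3, seed = 77)
  sw <- small_world(A, ensemble_size = 50, seed = 9)
  expect_identical(sw$sigma, sw$gamma / sw$lambda)
  expect_equal(sw$ensemble$ensemble_size, 50)
  # an Erdos-Renyi graph is its own null: gamma and lambda near 1
  cp_r <- lp_r <- numeric(50)
  for (b in 1:50) {
    R <- rewire_degree_preserving(A, seed = child_seed(9, "rewire", b))
    cp_r[b] <- clustering_coefficient(R)$Cp
    lp_r[b] <- characteristic_path_length(R)
  }
  se_g <- sd(cp_r) / sqrt(50) / mean(cp_r)
  se_l <- sd(lp_r) / sqrt(50) / mean(lp_r)
  expect_lt(abs(sw$gamma - 1), max(3 * se_g, 0.15))
  expect_lt(abs(sw$lambda - 1), max(3 * se_l, 0.05))
})

test_that("AUC over the grid matches closed-form integrals", {
  grid <- sparsity_grid()
  expect_equal(auc_over_grid(rep(3, 46), grid), 3 * 0.45)
  expect_equal(auc_over_grid(grid, grid), (0.5^2 - 0.05^2) / 2)
  expect_equal(auc_over_grid(c(1, 3), c(0.1, 0.2)), 0.2)
  expect_warning(v <- auc_over_grid(c(1, NA, 3), c(0.1, 0.2, 0.3)), "undefined")
  expect_equal(v, 0.4)
  expect_error(suppressWarnings(auc_over_grid(c(1, NA), c(0.1, 0.2))), "2 defined")
  # vectorized trapezoid weights agree with pracma's reference quadrature
  set.seed(2)
  vals <- rnorm(46)
  expect_equal(sum(vals * metconn:::trap_weights(grid)),
               pracma::trapz(grid, vals))
})
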