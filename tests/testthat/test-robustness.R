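test_that("LCC sizes follow the component structure", {
  sp <- synthetic_spec()
  net <- group_correlation(simulate_suv_table(sp, seed = 51), "aged")
  mdc <- min_density_connected(net)
  expect_equal(largest_connected_component_size(mdc$adjacency), 96L)
  A <- matrix(0L, 6, 6)                       # components {3, 2, 1}
  A[1, 2] <- A[2, 1] <- A[2, 3] <- A[3, 2] <- 1L
  A[4, 5] <- A[5, 4] <- 1L
  expect_equal(largest_connected_component_size(A), 3L)
  expect_equal(largest_connected_component_size(matrix(0L, 5, 5)), 1L)
  expect_equal(largest_connected_component_size(matrix(0L, 0, 0)), 0L)
})

test_that("targeted schedules rank nodes by betweenness AUC with index tie-breaks", {
  # toy weighted network dominated by a star hub at node 3
  n <- 8
  W <- matrix(0.1, n, n); diag(W) <- 0
  W[3, ] <- W[, 3] <- 0.9; W[3, 3] <- 0
  sched <- targeted_schedule(W, grid = sparsity_grid(0.15, 0.3, 0.05))
  expect_equal(sched$kind, "targeted")
  expect_equal(sched$orders[[1]][1], 3L)
  expect_setequal(sched$orders[[1]], 1:8)
  # all-equal BC (complete graph weights): ordering = index order
  W2 <- matrix(0.5, n, n); diag(W2) <- 0
  sched2 <- suppressWarnings(targeted_schedule(W2, grid = sparsity_grid(0.3, 0.5, 0.1)))
  expect_equal(sched2$orders[[1]], 1:8)
})

test_that("random schedules are reproducible permutations", {
  s1 <- random_schedules(96, n_reps = 40, seed = 6)
  expect_length(s1$orders, 40)
  for (o in s1$orders) expect_setequal(o, 1:96)
  s2 <- random_schedules(96, n_reps = 40, seed = 6)
  expect_identical(s1$orders, s2$orders)
  expect_false(identical(random_schedules(96, 40, seed = 7)$orders, s1$orders))
})

test_that("attack trajectories start at the intact network and never regrow", {
  sp <- small_spec(n_regions = 16, n = c(A = 10, B = 10))
  net <- group_correlation(simulate_suv_table(sp, seed = 52), "A")
  sched <- targeted_schedule(net, grid = sparsity_grid(0.2, 0.5, 0.1))
  res <- run_attack(net, sched, steps = 0:14,
                    metrics = c("Lp", "Cp", "Eglob", "Eloc"))
  # step 0 equals the intact network at its minimum connected density
  mdc <- min_density_connected(net)
  expect_equal(res$metrics[1, "Lp"], characteristic_path_length(mdc$adjacency),
               ignore_attr = TRUE)
  expect_equal(res$metrics[1, "Cp"], clustering_coefficient(mdc$adjacency)$Cp,
               ignore_attr = TRUE)
  expect_equal(res$lcc[1], 16)
  expect_true(all(diff(res$lcc) <= 0))
  expect_true(all(is.finite(res$metrics[, "Lp"])))   # re-thresholded graphs connected
  # random attack: averaged over repetitions, still monotone LCC
  rs <- random_schedules(16, n_reps = 5, seed = 3)
  res_r <- run_attack(net, rs, steps = 0:14, metrics = "Eglob")
  expect_true(all(diff(res_r$lcc) <= 1e-12))
})

test_that("hub removal fragments the intact binary network as the oracle says", {
  # 6-node toy: strong star around node 1 plus one strong edge (2,3)
  W <- matrix(0.05, 6, 6); diag(W) <- 0
  W[1, 2:6] <- W[2:6, 1] <- 0.9
  W[2, 3] <- W[3, 2] <- 0.85
  mdc <- min_density_connected(W)
  expect_equal(sum(mdc$adjacency) / 2, 5)      # the star itself connects all 6
  sched <- structure(list(kind = "targeted", orders = list(c(1L, 2:6))),
                     class = "attack_schedule")
  res <- run_attack(W, sched, steps = 0:1, metrics = "Eglob")
  # the intact min-density graph is exactly the star (edge 2-3 enters only
  # later in the ranking), so deleting the hub leaves 5 singletons
  expect_equal(res$lcc, c(6, 1))
})

test_that("single random repetition equals a targeted-style run on the same order", {
  sp <- small_spec(n_regions = 12)
  net <- group_correlation(simulate_suv_table(sp, seed = 53), "A")
  ord <- sample(12)
  s_rand <- structure(list(kind = "random", orders = list(ord)),
                      class = "attack_schedule")
  s_targ <- structure(list(kind = "targeted", orders = list(ord)),
                      class = "attack_schedule")
  r1 <- run_attack(net, s_rand, steps = 0:10, metrics = c("Cp", "Eglob"))
  r2 <- run_attack(net, s_targ, steps = 0:10, metrics = c("Cp", "Eglob"))
  expect_equal(r1$metrics, r2$metrics)
  expect_equal(r1$lcc, r2$lcc)
})

test_that("identical groups give all-one p-values per step and metric", {
  set.seed(3)
  va <- matrix(rnorm(8 * 12), 8)
  tab <- toy_table(va, va)
  rc <- compare_robustness(tab, kind = "random", grid = sparsity_grid(0.3, 0.5, 0.1),
                           n_perm = 30, seed = 2, n_reps = 2, steps = c(0, 4, 8),
                           metrics = c("Cp", "Eglob"))
  expect_equal(unname(rc$observed_diff), matrix(0, 3, 2))
  expect_true(all(rc$p_values == 1))
  expect_false(any(rc$significant))
})

test_that("robustness comparison is deterministic and budget-guarded", {
  sp <- small_spec(n_regions = 12)
  tab <- simulate_suv_table(sp, seed = 54)
  args <- list(tab, kind = "random", grid = sparsity_grid(0.3, 0.5, 0.1),
               n_perm = 20, seed = 9, n_reps = 2, steps = c(0, 5),
               metrics = "Eglob")
  r1 <- do.call(compare_robustness, args)
  r2 <- do.call(compare_robustness, args)
  expect_identical(r1$p_values, r2$p_values)
  expect_identical(r1$attack_a$metrics, r2$attack_a$metrics)
  expect_error(compare_robustness(tab, kind = "random", n_perm = 5000, seed = 1,
                                  max_evals = 1000),
               "max_evals")
})
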