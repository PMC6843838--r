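test_that("local minima follow the closed-neighborhood lexicographic rule", {
  p <- path_graph(c(3, 1, 2), ids = c("a", "b", "c"))
  expect_identical(find_local_minima(p$graph, p$energies), "b")

  # plateau: equal energies resolve by id
  p2 <- path_graph(c(2, 2), ids = c("a", "b"))
  expect_identical(find_local_minima(p2$graph, p2$energies), "a")

  for (seed in 1:6) {
    inst <- random_instance(50, seed)
    expect_setequal(find_local_minima(inst$graph, inst$energies),
                    oracle_minima(inst$graph, inst$energies[inst$graph$ids]))
  }
})

test_that("steepest-ratio descent reproduces the hand-traced path example", {
  p <- path_graph(c(5, 3, 4, 2, 1))
  basins <- assign_basins(p$graph, p$energies, compute_features = FALSE)
  got <- lapply(basins, function(b) sort(b$members))
  focal <- vapply(basins, `[[`, character(1), "focal_id")
  # v3 descends toward v4: (4-2)/1 beats (4-3)/1
  expect_equal(got[[which(focal == "v5")]], c("v3", "v4", "v5"))
  expect_equal(got[[which(focal == "v2")]], c("v1", "v2"))
})

test_that("basins partition the vertex set and match the descent oracle", {
  for (seed in 1:8) {
    inst <- random_instance(60, seed)
    e <- inst$energies[inst$graph$ids]
    basins <- assign_basins(inst$graph, inst$energies,
                            compute_features = FALSE)
    members <- unlist(lapply(basins, `[[`, "members"))
    expect_setequal(members, inst$graph$ids)     # partition: union
    expect_equal(anyDuplicated(members), 0)      # partition: disjoint

    want <- oracle_basins(inst$graph, e)
    got <- lapply(basins, function(b) sort(b$members))
    names(got) <- vapply(basins, `[[`, character(1), "focal_id")
    expect_setequal(names(got), names(want))
    for (f in names(want)) expect_equal(got[[f]], sort(want[[f]]))

    # each focal minimum is its basin's energy minimum
    for (b in basins)
      expect_equal(b$focal_energy, min(e[b$members]), ignore_attr = TRUE)
  }
})

test_that("single vertices and isolated vertices form their own basins", {
  mat <- matrix(c(0, 9, 9, 0), 2, 2, dimnames = list(c("a", "b"),
                                                     c("a", "b")))
  g <- graph_from_dist(mat, eps = 1)
  basins <- assign_basins(g, c(a = 1, b = 2), compute_features = FALSE)
  expect_length(basins, 2)
  expect_setequal(vapply(basins, `[[`, numeric(1), "size"), c(1, 1))
})

test_that("persistence reproduces the hand union-find trace", {
  p <- path_graph(c(5, 3, 4, 2, 1))
  minima <- find_local_minima(p$graph, p$energies)
  pers <- compute_persistence(p$graph, p$energies, minima)
  expect_setequal(minima, c("v2", "v5"))
  expect_equal(pers[["v2"]], 1)   # dies at the saddle v3: 4 - 3
  expect_equal(pers[["v5"]], 4)   # survivor: 5 - 1
})

test_that("single-minimum funnel persistence equals the energy range", {
  p <- path_graph(c(6, 4, 2.5, 1, 3))
  minima <- find_local_minima(p$graph, p$energies)
  expect_identical(minima, "v4")
  pers <- compute_persistence(p$graph, p$energies, minima)
  expect_equal(unname(pers), 6 - 1)
})

test_that("union-find persistence equals the exhaustive sweep oracle", {
  for (seed in 1:8) {
    inst <- random_instance(30, seed, p_edge = 0.2)
    e <- inst$energies[inst$graph$ids]
    minima <- find_local_minima(inst$graph, inst$energies)
    got <- compute_persistence(inst$graph, inst$energies, minima)
    want <- oracle_persistence(inst$graph, e, minima)
    expect_equal(got[sort(minima)], want[sort(minima)], tolerance = 1e-12)
    expect_true(all(got >= 0))
  }
})

test_that("the deepest minimum per component has maximal persistence", {
  for (seed in 11:16) {
    inst <- random_instance(40, seed)
    e <- inst$energies[inst$graph$ids]
    minima <- find_local_minima(inst$graph, inst$energies)
    pers <- compute_persistence(inst$graph, inst$energies, minima)
    comp <- igraph::components(inst$graph$graph)$membership
    names(comp) <- inst$graph$ids
    idr <- match(inst$graph$ids, sort(inst$graph$ids))
    names(idr) <- inst$graph$ids
    for (cc in unique(comp)) {
      ms <- intersect(names(comp)[comp == cc], minima)
      if (length(ms) < 2) next
      deepest <- ms[order(e[ms], idr[ms])][1]   # lexicographic deepest
      expect_gte(pers[[deepest]], max(pers[ms]))
    }
  }
})

test_that("basin subgraph component counts follow the pdist + 1 rule", {
  b1 <- mk_basin("x", "x", -1)
  expect_equal(basin_subgraph_components(b1, dist_store(matrix(0, 1, 1),
                                                        "x")), 1L)

  # 4 members, all pairwise 1.0 -> eps 2.0 -> complete -> 1 component
  ids <- c("a", "b", "c", "d")
  mat <- matrix(1, 4, 4); diag(mat) <- 0
  dimnames(mat) <- list(ids, ids)
  b <- mk_basin("a", ids, c(-3, 1, 2, 3))
  expect_equal(basin_subgraph_components(b, dist_store(mat, ids)), 1L)

  # two tight clumps far beyond pdist + 1 -> 2 components
  mat2 <- matrix(30, 4, 4); diag(mat2) <- 0
  mat2[1, 2] <- mat2[2, 1] <- 0.5
  mat2[3, 4] <- mat2[4, 3] <- 0.5
  dimnames(mat2) <- list(ids, ids)
  expect_equal(basin_subgraph_components(b, dist_store(mat2, ids)), 2L)
})

test_that("largest-basin selection applies size then energy then id ties", {
  b <- mk_basin_table(c(10, 3, 3), c(0, -1, -2))
  expect_equal(select_largest_basin(b)$size, 10)
  b2 <- mk_basin_table(c(5, 5), c(-2, -7))
  expect_equal(select_largest_basin(b2)$focal_energy, -7)
  for (seed in 1:5) {
    set.seed(seed)
    sizes <- sample(1:20, 8, replace = TRUE)
    b3 <- mk_basin_table(sizes, rnorm(8))
    expect_equal(select_largest_basin(b3)$size, max(sizes))
  }
  expect_error(select_largest_basin(list()), "empty")
})

test_that("planted wells are recovered by the decomposition", {
  sim <- simulate_abstract(n_points = 400, m = 5, seed = 7)
  g <- suppressWarnings(build_nn_graph(sim$distances, epsilon0 = 1))
  basins <- assign_basins(g, sim$energy, compute_features = FALSE)
  lab <- setNames(integer(length(sim$ids)), sim$ids)
  for (i in seq_along(basins)) lab[basins[[i]]$members] <- i
  expect_gte(adjusted_rand(lab[sim$ids], sim$labels[sim$ids]), 0.9)
})
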