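ds_from <- function(mat, ids) dist_store(mat, ids)

test_that("density scores evaluate the printed formulas", {
  ids <- c("a", "b", "c")
  mat <- matrix(c(0, 1, 2,
                  1, 0, 3,
                  2, 3, 0), 3, 3, byrow = TRUE, dimnames = list(ids, ids))
  sc <- density_scores(ids, ds_from(mat, ids))
  expect_equal(sc$S, c(3, 4, 5) / 3, tolerance = 1e-12)
  expect_equal(sc$S_norm, c(-1, 0, 1))

  # all-equal distances: degenerate branches -> all zero
  mat2 <- matrix(2, 3, 3); diag(mat2) <- 0; dimnames(mat2) <- list(ids, ids)
  expect_equal(density_scores(ids, ds_from(mat2, ids))$S_norm, c(0, 0, 0))
  expect_error(density_scores("a", ds_from(mat, ids)), "at least 2")
})

test_that("normalized densities pin min/median/max to -1/0/+1 on random inputs", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(4:30, 1)
    ids <- sprintf("d%02d", 1:n)
    p <- matrix(rnorm(3 * n, 0, 3), n, 3)
    mat <- as.matrix(dist(p)); dimnames(mat) <- list(ids, ids)
    sc <- density_scores(ids, ds_from(mat, ids))
    expect_true(all(sc$S_norm >= -1 - 1e-12 & sc$S_norm <= 1 + 1e-12))
    expect_equal(sc$S_norm[which.min(sc$S)], -1)
    expect_equal(sc$S_norm[which.max(sc$S)], 1)
    if (n %% 2 == 1)
      expect_equal(sc$S_norm[which(sc$S == median(sc$S))[1]], 0)
  }
})

test_that("density weights follow w = exp(-k S')", {
  sc <- structure(list(ids = c("a", "b", "c"), S = c(1, 2, 3),
                       S_norm = c(-1, 0, 1), S_min = 1, S_median = 2,
                       S_max = 3), class = "density_scores")
  w5 <- weights_from_density(sc, k = 5)
  expect_equal(w5$w, c(exp(5), 1, exp(-5)), tolerance = 1e-12)
  w0 <- weights_from_density(sc, k = 0)
  expect_equal(w0$w, c(1, 1, 1))
  expect_equal(sum(w5$p), 1)
  # the most outlying decoy never carries the maximal weight (k > 0)
  expect_true(which.max(w5$w) != which.max(sc$S_norm))
})

test_that("predicted-RMSD weights are order-reversing 1/(x + zeta)", {
  w <- weights_from_predicted_rmsd(c(a = 0), zeta = 1e-6)
  expect_equal(w$w, 1e6)
  w2 <- weights_from_predicted_rmsd(c(a = 1, b = 3))
  expect_equal(w2$w[1] / w2$w[2], 3, tolerance = 1e-5)
  w3 <- weights_from_predicted_rmsd(c(a = 2, b = 2, c = 2))
  expect_equal(w3$p, rep(1 / 3, 3))
  expect_error(weights_from_predicted_rmsd(c(-1, 2)), "non-negative")
})

test_that("weighted purity matches hand values and plain purity", {
  ids <- c("a", "b", "c")
  wv <- basinselect:::weight_vector(ids, c(2, 1, 1), "predicted_rmsd")
  expect_equal(weighted_purity(wv, c(a = 1, b = 0, c = 1)), 0.75)
  expect_equal(weighted_purity(wv, c(a = 1, b = 1, c = 1)), 1)

  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(3:20, 1)
    ids <- sprintf("x%02d", 1:n)
    g <- setNames(rbinom(n, 1, 0.4), ids)
    uni <- basinselect:::weight_vector(ids, rep(1, n), "density")
    expect_equal(weighted_purity(uni, g), sum(g) / n)
    # invariance to positive rescaling
    w <- runif(n, 0.1, 5)
    a <- basinselect:::weight_vector(ids, w, "density")
    b <- basinselect:::weight_vector(ids, 7.3 * w, "density")
    expect_equal(weighted_purity(a, g), weighted_purity(b, g),
                 tolerance = 1e-12)
    wp <- weighted_purity(a, g)
    expect_true(wp >= 0 && wp <= 1)
    expect_equal(wp, sum(a$p * g[ids]), tolerance = 1e-12)
  }
})

test_that("select_decoy takes the top weight with energy/id tie-breaks", {
  b <- mk_basin("b", c("a", "b", "c"), c(-1, -2, -3))
  wv <- basinselect:::weight_vector(c("a", "b", "c"), c(0.1, 0.9, 0.3),
                                    "density")
  expect_equal(select_decoy(b, wv), "b")
  tied <- basinselect:::weight_vector(c("a", "b"), c(1, 1), "density")
  b2 <- mk_basin("b", c("a", "b"), c(-5, -9))
  expect_equal(select_decoy(b2, tied), "b")
  for (seed in 1:10) {
    set.seed(seed)
    w <- runif(3)
    wv <- basinselect:::weight_vector(c("a", "b", "c"), w, "density")
    expect_equal(select_decoy(b, wv), c("a", "b", "c")[which.max(w)])
  }
})

test_that("random_select is seeded, reproducible, and unbiased", {
  b1 <- mk_basin("a", "a", -1)
  expect_equal(unique(random_select(b1, n_draws = 5, seed = 1)), "a")
  b <- mk_basin("m", sprintf("m%02d", 1:10), 1:10)
  expect_identical(random_select(b, seed = 4), random_select(b, seed = 4))
  # long-run near-native fraction matches the basin purity
  g <- setNames(c(rep(1, 3), rep(0, 7)), b$members)
  draws <- random_select(b, n_draws = 1e4, seed = 2)
  expect_equal(mean(g[draws]), 0.3, tolerance = 0.02)
})
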