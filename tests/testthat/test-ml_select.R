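mk_annotated <- function(sizes, energies, ncomp = NULL) {
  b <- mk_basin_table(sizes, energies)
  if (!is.null(ncomp)) for (i in seq_along(b)) b[[i]]$n_components <- ncomp[i]
  for (i in seq_along(b)) b[[i]]$persistence <- abs(energies[i])
  pareto_annotate(b)
}

test_that("dataset features aggregate the basin decomposition", {
  b <- mk_annotated(7, -3, ncomp = 1L)
  b[[1]]$persistence <- 2
  f <- dataset_features(b)
  expect_equal(unname(f[c("min_basin_size", "max_basin_size")]), c(7, 7))
  expect_equal(unname(f[c("min_focal_energy", "max_focal_energy")]),
               c(-3, -3))
  expect_equal(unname(f[c("min_persistence", "max_persistence")]), c(2, 2))
  expect_equal(unname(f[7:11]), c(1, 0, 0, 0, 0))

  b2 <- mk_annotated(c(5, 9), c(-1, -4), ncomp = c(2L, 4L))
  f2 <- dataset_features(b2)
  expect_equal(unname(f2[7:11]), c(0, 1, 1, 0, 0))
  expect_equal(sum(f2[7:11]), 2)          # histogram sums to basin count

  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(3:30, 1)
    sizes <- sample(1:50, n, replace = TRUE)
    en <- rnorm(n)
    cc <- sample(1:15, n, replace = TRUE)
    f3 <- dataset_features(mk_annotated(sizes, en, ncomp = as.integer(cc)))
    expect_equal(unname(f3[1:2]), range(sizes))
    expect_equal(unname(f3[3:4]), range(en))
    expect_equal(unname(f3[7:11]),
                 c(sum(cc == 1), sum(cc == 2), sum(cc %in% 3:5),
                   sum(cc %in% 6:10), sum(cc > 10)))
  }
})

test_that("difficulty classifier memorizes separable training data", {
  X <- rbind(c(rep(1, 6), 5, 0, 0, 0, 0),
             c(rep(9, 6), 0, 0, 0, 0, 5))
  m <- train_difficulty_classifier(X, c("easy", "hard"), seed = 1)
  expect_equal(predict_difficulty(m, X), c("easy", "hard"))
  expect_error(train_difficulty_classifier(X, c("easy", "easy")),
               "two classes")
})

test_that("binary difficulty prediction generalizes on planted features", {
  set.seed(77)
  gen_row <- function(level) {
    mu <- if (level == "easy") 0 else 3
    c(abs(rnorm(2, mu + 1)), rnorm(2, mu), abs(rnorm(2, mu + 2)),
      rmultinom(1, 20, prob = (1:5)^(if (level == "easy") -1 else 1)))
  }
  labels <- rep(c("easy", "hard"), each = 30)
  X <- t(vapply(labels, gen_row, numeric(11)))
  pred <- leave_one_out_difficulty(X, labels, mode = "binary", seed = 3)
  expect_gte(mean(pred == labels), 0.8)
})

test_that("multiclass confusion concentrates on the medium class", {
  set.seed(78)
  gen_row <- function(mu)
    c(abs(rnorm(2, mu + 1)), rnorm(2, mu), abs(rnorm(2, mu + 2)),
      rmultinom(1, 20, prob = (1:5)^(mu - 1.5)))
  labels <- rep(c("easy", "medium", "hard"), each = 20)
  mus <- c(easy = 0, medium = 1.5, hard = 3)[labels]
  X <- t(vapply(mus, gen_row, numeric(11)))
  pred <- leave_one_out_difficulty(X, labels, mode = "multiclass", seed = 3)
  err <- tapply(pred != labels, labels, mean)
  expect_gte(err[["medium"]], max(err[["easy"]], err[["hard"]]))
})

test_that("purity regressor fits constants and monotone Pareto signals", {
  X <- cbind(pareto_rank = 0:5, pareto_count = 5:0, n_components = 1)
  m <- train_purity_regressor(X, rep(0.4, 6), seed = 1)
  expect_equal(unname(predict_purity(m, X)), rep(0.4, 6), tolerance = 1e-3)

  set.seed(10)
  rank <- sample(0:40, 300, replace = TRUE)
  Xtr <- cbind(pareto_rank = rank, pareto_count = sample(0:40, 300, TRUE),
               n_components = sample(1:4, 300, TRUE))
  y <- 1 / (1 + 0.3 * rank)               # noiseless monotone map
  m2 <- train_purity_regressor(Xtr[1:200, ], y[1:200], seed = 2)
  held <- predict_purity(m2, Xtr[201:300, ])
  expect_gte(cor(held, y[201:300], method = "spearman"), 0.9)
  expect_true(all(held >= 0 & held <= 1))
  expect_error(train_purity_regressor(Xtr[0, ], numeric(0)), "at least 2")
  expect_error(train_purity_regressor(Xtr[1:5, ], c(0.1, 0.2, 2, 0.3, 0.1)),
               "0, 1")
})

test_that("phase-1 ranking sorts by predicted purity with stated ties", {
  b <- mk_annotated(c(10, 40, 20), c(-5, -1, -3), ncomp = c(1L, 1L, 1L))
  # a regressor trained to reproduce fixed predictions exposes the sort rule
  X <- cbind(pareto_rank = c(0, 2, 1), pareto_count = c(2, 0, 1),
             n_components = 1)
  m <- train_purity_regressor(rbind(X, X), rep(c(0.9, 0.2, 0.5), 2), seed = 1)
  top2 <- phase1_select(b, m, n = 2)
  preds <- vapply(top2, `[[`, numeric(1), "predicted_purity")
  expect_equal(order(preds, decreasing = TRUE), seq_along(preds))
  all3 <- phase1_select(b, m, n = 99)
  expect_length(all3, 3)

  # sort-oracle property on random prediction vectors via tied features
  for (seed in 1:5) {
    set.seed(seed)
    k <- 6
    bs <- mk_annotated(sample(5:50, k), rnorm(k),
                       ncomp = sample(1:3, k, TRUE))
    p <- predict_purity(m, basinselect:::basin_feature_rows(bs))
    got <- phase1_select(bs, m, n = k)
    sizes <- vapply(bs, `[[`, numeric(1), "size")
    want <- order(-p, -sizes)
    expect_equal(vapply(got, `[[`, character(1), "focal_id"),
                 vapply(bs[want], `[[`, character(1), "focal_id"))
  }
})

test_that("RMSD regressor recovers linear potential encodings", {
  set.seed(20)
  rmsd <- runif(400, 0.5, 10)
  A <- matrix(rnorm(5 * 3), 3, 5)
  pot <- cbind(outer(rmsd, c(1, -0.5, 2)) + 0.1, rnorm(400), rnorm(400))
  m <- train_rmsd_regressor(pot[1:300, ], rmsd[1:300], seed = 1)
  held <- predict_rmsd(m, pot[301:400, ])
  expect_true(mean(abs(held - rmsd[301:400])) < 0.35)
  expect_true(all(held >= 0))

  mc <- train_rmsd_regressor(pot[1:50, ], rep(3, 50), seed = 1)
  expect_equal(unname(predict_rmsd(mc, pot[51:60, ])), rep(3, 10),
               tolerance = 1e-3)
  expect_error(predict_rmsd(m, pot[, 1:3]), "5 potential")
})

test_that("purification removes decoys predicted beyond the threshold", {
  set.seed(30)
  # exact linear encoding so predictions track true RMSD closely
  rmsd_tr <- runif(500, 0, 10)
  enc <- function(r) cbind(r * 2 + 1, -r + 3, r, rnorm(length(r)))
  model <- train_rmsd_regressor(enc(rmsd_tr), rmsd_tr, seed = 1)

  rmsd_b <- c(1, 2, 9)
  ens <- toy_ensemble(n_decoys = 3, n_res = 4)
  ens$potentials <- enc(rmsd_b)
  b <- mk_basin("t01", ens$ids, c(-3, -2, -1))
  out <- purify_basins(list(b), model, ens, dist_thresh = 3, tau_frac = 0)
  expect_equal(out[[1]]$size, 2)
  expect_setequal(out[[1]]$members, c("t01", "t02"))

  # all predictions under threshold: basin unchanged
  out2 <- purify_basins(list(b), model, ens, dist_thresh = 20)
  expect_equal(out2[[1]]$size, 3)

  # focal reassigns to the kept minimum-energy member when removed
  b2 <- mk_basin("t03", ens$ids, c(-3, -2, -10))
  out3 <- purify_basins(list(b2), model, ens, dist_thresh = 3)
  expect_equal(out3[[1]]$focal_id, "t01")
  expect_lte(out3[[1]]$size, b2$size)

  expect_error(purify_basins(list(b), model, ens, dist_thresh = 0.05),
               "tau_frac")
})

test_that("informative purification raises true purity across seeds", {
  set.seed(40)
  enc <- function(r) cbind(r * 2 + 1, -r + 3, r, rnorm(length(r)))
  rmsd_tr <- runif(800, 0, 10)
  model <- train_rmsd_regressor(enc(rmsd_tr) +
                                  matrix(rnorm(3200, 0, 0.3), 800, 4),
                                rmsd_tr, seed = 1)
  thresh <- 3
  improved <- vapply(1:20, function(seed) {
    set.seed(seed)
    n <- 40
    r <- c(runif(n / 2, 0.5, 2.5), runif(n / 2, 4, 9))[sample(n)]
    ens <- toy_ensemble(n_decoys = n, n_res = 4)
    ens$potentials <- enc(r) + matrix(rnorm(4 * n, 0, 0.3), n, 4)
    g <- setNames(as.integer(r < thresh), ens$ids)
    b <- mk_basin(ens$ids[1], ens$ids, rnorm(n))
    before <- mean(g[b$members])
    out <- purify_basins(list(b), model, ens, dist_thresh = thresh,
                         tau_frac = 0)
    after <- mean(g[out[[1]]$members])
    after >= before
  }, logical(1))
  expect_gte(mean(improved), 0.9)
})

test_that("model library round-trips through save/load with equal output", {
  set.seed(50)
  ens_list <- lapply(c(301, 302, 311, 312), function(s)
    simulate_ensemble(sim_spec(n_decoys = 150, n_residues = 15,
                               min_dist = if (s > 310) 1.5 else 0.6,
                               near_native_fraction =
                                 if (s > 310) 0.15 else 0.35,
                               n_false_minima = 2, seed = s)))
  models <- suppressWarnings(train_select_models(ens_list, seed = 2))
  test_ens <- simulate_ensemble(sim_spec(n_decoys = 150, n_residues = 15,
                                         min_dist = 0.6,
                                         near_native_fraction = 0.35,
                                         n_false_minima = 2, seed = 399))
  res1 <- suppressWarnings(ml_select_pipeline(test_ens, models, seed = 1))
  expect_true(res1$level %in% names(models$levels))
  expect_true(all(vapply(res1$basins, `[[`, numeric(1), "size") >= 1))

  path <- withr::local_tempfile()
  save_select_models(models, path)
  models2 <- load_select_models(path)
  res2 <- suppressWarnings(ml_select_pipeline(test_ens, models2, seed = 1))
  expect_identical(res1$level, res2$level)
  expect_identical(lapply(res1$basins, `[[`, "members"),
                   lapply(res2$basins, `[[`, "members"))

  # determinism under a fixed seed
  res3 <- suppressWarnings(ml_select_pipeline(test_ens, models, seed = 1))
  expect_identical(lapply(res1$basins, `[[`, "members"),
                   lapply(res3$basins, `[[`, "members"))

  # missing level is a clear error
  crippled <- models
  crippled$levels <- models$levels["medium"]
  if (res1$level != "medium")
    expect_error(suppressWarnings(
      ml_select_pipeline(test_ens, crippled, seed = 1)), "available")
})
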