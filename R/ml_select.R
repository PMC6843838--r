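# Supervised two-phase selection: dataset-difficulty classification,
# Phase-1 basin-purity regression, Phase-2 per-decoy RMSD purification.
# All learners are gradient-boosted tree ensembles (xgboost) with fixed
# hyperparameters for reproducibility.

# min_child_weight 0 so the trees can split even on the few-dataset
# training regimes (two decoy sets per difficulty category)
bst_params <- function(extra = list()) {
  c(list(max_depth = 3, eta = 0.1, subsample = 1.0, nthread = 1,
         min_child_weight = 0), extra)
}
BST_NROUNDS <- 100L

fit_booster <- function(X, y, objective, seed, extra = list()) {
  params <- bst_params(c(list(objective = objective, seed = seed), extra))
  xgboost::xgb.train(params = params,
                     data = xgboost::xgb.DMatrix(X, label = y),
                     nrounds = BST_NROUNDS, verbose = 0)
}

bst_predict <- function(booster, X) {
  predict(booster, xgboost::xgb.DMatrix(X))
}

DATASET_FEATURE_NAMES <- c("min_basin_size", "max_basin_size",
                           "min_focal_energy", "max_focal_energy",
                           "min_persistence", "max_persistence",
                           "cc_1", "cc_2", "cc_3_5", "cc_6_10", "cc_gt10")
BASIN_FEATURE_NAMES <- c("pareto_rank", "pareto_count", "n_components")

#' Landscape-level feature vector of a decomposed decoy set
#'
#' Aggregates the basin decomposition into the fixed-order feature vector
#' used for difficulty classification: minimum and maximum basin size, focal
#' energy, and persistence, plus the histogram of per-basin subgraph
#' connected-component counts in the bins 1, 2, 3-5, 6-10, >10.
#'
#' @param basins list of `basin` objects with persistence and
#'   `n_components` filled (see [assign_basins()]).
#' @return named numeric vector of length 11.
#' @export
dataset_features <- function(basins) {
  stopifnot(length(basins) >= 1)
  size <- vapply(basins, `[[`, numeric(1), "size")
  fe <- vapply(basins, `[[`, numeric(1), "focal_energy")
  pers <- vapply(basins, `[[`, numeric(1), "persistence")
  cc <- vapply(basins, `[[`, integer(1), "n_components")
  if (anyNA(pers) || anyNA(cc))
    stop("basins must carry persistence and n_components")
  hist <- c(sum(cc == 1), sum(cc == 2), sum(cc >= 3 & cc <= 5),
            sum(cc >= 6 & cc <= 10), sum(cc > 10))
  stats::setNames(c(min(size), max(size), min(fe), max(fe), min(pers),
                    max(pers), hist), DATASET_FEATURE_NAMES)
}

#' Train the dataset-difficulty classifier
#'
#' Boosted-tree classifier over [dataset_features()] vectors. In binary
#' mode targets are easy vs hard (medium collapsed into hard); in
#' multiclass mode easy/medium/hard.
#'
#' @param features matrix (or data.frame) of dataset feature rows in
#'   [dataset_features()] order.
#' @param labels character vector of difficulty labels.
#' @param mode `"multiclass"` (default) or `"binary"`.
#' @param seed integer seed.
#' @return a `difficulty_model`.
#' @export
train_difficulty_classifier <- function(features, labels,
                                        mode = c("multiclass", "binary"),
                                        seed = 0) {
  mode <- match.arg(mode)
  X <- as_feature_matrix(features, DATASET_FEATURE_NAMES)
  labels <- as.character(labels)
  if (mode == "binary") labels[labels == "medium"] <- "hard"
  classes <- intersect(c("easy", "medium", "hard"), unique(labels))
  if (length(classes) < 2) stop("need at least two classes present; got: ",
                                paste(classes, collapse = ", "))
  y <- match(labels, classes) - 1
  booster <- if (length(classes) == 2)
    fit_booster(X, y, "binary:logistic", seed)
  else
    fit_booster(X, y, "multi:softprob", seed,
                extra = list(num_class = length(classes)))
  structure(list(booster = booster, classes = classes, mode = mode,
                 feature_names = DATASET_FEATURE_NAMES, seed = seed),
            class = "difficulty_model")
}

#' @rdname train_difficulty_classifier
#' @param model a `difficulty_model`.
#' @export
predict_difficulty <- function(model, features) {
  X <- as_feature_matrix(features, model$feature_names)
  p <- bst_predict(model$booster, X)
  if (length(model$classes) == 2) {
    model$classes[1 + (p > 0.5)]
  } else {
    p <- matrix(p, ncol = length(model$classes), byrow = TRUE)
    model$classes[max.col(p, ties.method = "first")]
  }
}

#' Leave-one-out difficulty predictions
#'
#' Mirrors the leave-target-out protocol: each dataset is predicted by a
#' model trained on all the others.
#'
#' @inheritParams train_difficulty_classifier
#' @return character vector of held-out predictions, one per row.
#' @export
leave_one_out_difficulty <- function(features, labels,
                                     mode = c("multiclass", "binary"),
                                     seed = 0) {
  mode <- match.arg(mode)
  X <- as_feature_matrix(features, DATASET_FEATURE_NAMES)
  vapply(seq_len(nrow(X)), function(i) {
    m <- train_difficulty_classifier(X[-i, , drop = FALSE], labels[-i],
                                     mode = mode, seed = seed)
    predict_difficulty(m, X[i, , drop = FALSE])
  }, character(1))
}

as_feature_matrix <- function(features, expected) {
  X <- as.matrix(features)
  if (is.null(dim(X)) || ncol(X) == 1 && length(expected) > 1)
    X <- matrix(X, nrow = 1)
  if (ncol(X) != length(expected))
    stop("expected ", length(expected), " feature columns")
  colnames(X) <- expected
  storage.mode(X) <- "double"
  X
}

#' Train the Phase-1 basin-purity regressor
#'
#' Boosted-tree regression of true basin purity on the Pareto- and
#' graph-based features (pareto_rank, pareto_count, n_components);
#' predictions are clamped to [0, 1].
#'
#' @param features matrix/data.frame with columns pareto_rank, pareto_count,
#'   n_components (one row per training basin).
#' @param purities numeric vector of true purities in [0, 1].
#' @param seed integer seed.
#' @return a `purity_model`.
#' @export
train_purity_regressor <- function(features, purities, seed = 0) {
  X <- as_feature_matrix(features, BASIN_FEATURE_NAMES)
  if (nrow(X) < 2) stop("need at least 2 training basins")
  if (any(purities < 0 | purities > 1)) stop("purities must lie in [0, 1]")
  # dominance semantics are enforced as monotone constraints: predicted
  # purity never increases with Pareto Rank (more dominators = worse) and
  # never decreases with Pareto Count (dominating more = better); pure
  # basins are rare in training, and unconstrained trees memorize their
  # exact feature values instead of the ordering
  booster <- fit_booster(X, as.numeric(purities), "reg:squarederror", seed,
                         extra = list(monotone_constraints = "(-1,1,0)"))
  structure(list(booster = booster, feature_names = BASIN_FEATURE_NAMES,
                 seed = seed), class = "purity_model")
}

#' @rdname train_purity_regressor
#' @param model a `purity_model`.
#' @export
predict_purity <- function(model, features) {
  X <- as_feature_matrix(features, model$feature_names)
  pmin(pmax(bst_predict(model$booster, X), 0), 1)
}

basin_feature_rows <- function(basins) {
  X <- cbind(pareto_rank = vapply(basins, `[[`, integer(1), "pareto_rank"),
             pareto_count = vapply(basins, `[[`, integer(1), "pareto_count"),
             n_components = vapply(basins, `[[`, integer(1), "n_components"))
  if (anyNA(X)) stop("basins must carry pareto annotations and n_components")
  X
}

#' Phase 1: rank basins by predicted purity and keep the top n
#'
#' @param basins pareto-annotated basins (see [pareto_annotate()]).
#' @param model a `purity_model`.
#' @param n number of basins passed on to Phase 2 (default 5).
#' @return list of the top min(n, #basins) basins, sorted by predicted
#'   purity descending (ties: larger size, then focal id); each carries
#'   `predicted_purity`.
#' @export
phase1_select <- function(basins, model, n = 5) {
  stopifnot(n >= 1)
  pred <- predict_purity(model, basin_feature_rows(basins))
  size <- vapply(basins, `[[`, numeric(1), "size")
  fid <- vapply(basins, `[[`, character(1), "focal_id")
  o <- order(-pred, -size, id_rank(fid), method = "radix")
  keep <- o[seq_len(min(n, length(basins)))]
  out <- basins[keep]
  for (i in seq_along(out)) out[[i]]$predicted_purity <- pred[keep[i]]
  out
}

#' Train the Phase-2 per-decoy RMSD regressor
#'
#' Boosted-tree regression of true RMSD to the native on the per-decoy
#' knowledge-based-potential feature columns; predictions are clamped at 0.
#'
#' @param potentials numeric matrix, one row per decoy.
#' @param true_rmsd numeric vector of RMSDs in Angstroms.
#' @param seed integer seed.
#' @return an `rmsd_model`.
#' @export
train_rmsd_regressor <- function(potentials, true_rmsd, seed = 0) {
  X <- as.matrix(potentials)
  storage.mode(X) <- "double"
  if (nrow(X) != length(true_rmsd)) stop("one RMSD per potentials row")
  if (anyNA(X)) stop("inconsistent potential feature rows")
  booster <- fit_booster(X, as.numeric(true_rmsd), "reg:squarederror", seed)
  structure(list(booster = booster, n_features = ncol(X), seed = seed),
            class = "rmsd_model")
}

#' @rdname train_rmsd_regressor
#' @param model an `rmsd_model`.
#' @export
predict_rmsd <- function(model, potentials) {
  X <- as.matrix(potentials)
  storage.mode(X) <- "double"
  if (ncol(X) != model$n_features)
    stop("expected ", model$n_features, " potential features")
  pmax(bst_predict(model$booster, X), 0)
}

#' Phase 2: purify basins by predicted RMSD and keep the top l
#'
#' Removes from each basin every decoy whose predicted RMSD exceeds
#' `dist_thresh * (1 + tau_frac)` (tau relaxes the cutoff so borderline
#' near-natives are not discarded), drops emptied basins, re-ranks the
#' survivors by post-purification predicted purity (the fraction of kept
#' decoys predicted under `dist_thresh`), and returns the top l. If a
#' basin's focal decoy is removed, the focal reassigns to the kept member
#' of minimum energy.
#'
#' @param top_basins basins from [phase1_select()].
#' @param model an `rmsd_model`.
#' @param ensemble the [decoy_ensemble] supplying the potentials.
#' @param dist_thresh near-native cutoff in Angstroms.
#' @param tau_frac cutoff relaxation fraction (0, 0.10, 0.20 or 0.25).
#' @param l number of purified basins returned (default 1).
#' @return list of the top l purified basins, each with updated members,
#'   size, energies, and `predicted_purity`.
#' @export
purify_basins <- function(top_basins, model, ensemble, dist_thresh,
                          tau_frac = 0, l = 1) {
  stopifnot(l >= 1, dist_thresh > 0, tau_frac >= 0)
  if (is.null(ensemble$potentials))
    stop("ensemble has no potential features for Phase-2 purification")
  pot <- ensemble$potentials
  rownames(pot) <- ensemble$ids
  cutoff <- dist_thresh * (1 + tau_frac)
  purified <- list()
  for (b in top_basins) {
    pred <- predict_rmsd(model, pot[b$members, , drop = FALSE])
    keep <- pred <= cutoff
    if (!any(keep)) next
    members <- b$members[keep]
    e <- b$member_energies[members]
    nb <- new_basin(focal_id = if (b$focal_id %in% members) b$focal_id
                    else members[order(e, id_rank(members),
                                       method = "radix")[1]],
                    members = members, energies = unname(e))
    nb$persistence <- b$persistence
    nb$n_components <- b$n_components
    nb$pareto_rank <- b$pareto_rank
    nb$pareto_count <- b$pareto_count
    nb$predicted_rmsd <- stats::setNames(pred[keep], members)
    nb$predicted_purity <- mean(pred[keep] < dist_thresh)
    purified <- c(purified, list(nb))
  }
  if (!length(purified))
    stop("purification emptied every basin; consider a larger tau_frac")
  pp <- vapply(purified, `[[`, numeric(1), "predicted_purity")
  size <- vapply(purified, `[[`, numeric(1), "size")
  fid <- vapply(purified, `[[`, character(1), "focal_id")
  o <- order(-pp, -size, id_rank(fid), method = "radix")
  purified[o[seq_len(min(l, length(purified)))]]
}

#' Train the full supervised model library
#'
#' Builds everything [ml_select_pipeline()] needs from a list of training
#' ensembles with known natives: runs the basin decomposition on each,
#' derives ground-truth difficulty labels and per-basin purities at each
#' target's own `dist_thresh`, and fits the difficulty classifier plus one
#' purity regressor and one per-decoy RMSD regressor per difficulty level.
#' Each level also records the median training `dist_thresh`, used at
#' selection time when the native (and hence the true threshold) is
#' unknown.
#'
#' @param ensembles list of [decoy_ensemble] objects with natives and
#'   potential features.
#' @param seed integer seed.
#' @param mode difficulty-classifier mode, `"multiclass"` or `"binary"`.
#' @param epsilon0,max_nn nn-graph tuning.
#' @return a `select_models` library.
#' @export
train_select_models <- function(ensembles, seed = 0,
                                mode = c("multiclass", "binary"),
                                epsilon0 = 1.0, max_nn = 100) {
  mode <- match.arg(mode)
  feats <- list(); labels <- character(0)
  basin_rows <- list(); basin_purity <- list()
  decoy_pot <- list(); decoy_rmsd <- list(); threshes <- list()
  for (i in seq_along(ensembles)) {
    ens <- ensembles[[i]]
    distances <- pairwise_distances(ens)
    graph <- build_nn_graph(distances, epsilon0 = epsilon0, max_nn = max_nn)
    basins <- assign_basins(graph, stats::setNames(ens$energy, ens$ids),
                            distances)
    basins <- pareto_annotate(basins)
    r <- native_rmsds(ens)
    diff <- categorize_difficulty(min(r), function(th) sum(r < th))
    g <- label_near_natives(ens, diff$dist_thresh)
    lvl <- diff$level
    feats[[i]] <- dataset_features(basins)
    labels <- c(labels, lvl)
    basin_rows[[lvl]] <- rbind(basin_rows[[lvl]], basin_feature_rows(basins))
    basin_purity[[lvl]] <- c(basin_purity[[lvl]],
                             vapply(basins, function(b)
                               purity(b$members, g), numeric(1)))
    decoy_pot[[lvl]] <- rbind(decoy_pot[[lvl]], ens$potentials)
    decoy_rmsd[[lvl]] <- c(decoy_rmsd[[lvl]], r)
    threshes[[lvl]] <- c(threshes[[lvl]], diff$dist_thresh)
  }
  if (mode == "binary" && "medium" %in% names(basin_rows)) {
    # binary mode collapses medium into hard
    basin_rows$hard <- rbind(basin_rows$hard, basin_rows$medium)
    basin_purity$hard <- c(basin_purity$hard, basin_purity$medium)
    decoy_pot$hard <- rbind(decoy_pot$hard, decoy_pot$medium)
    decoy_rmsd$hard <- c(decoy_rmsd$hard, decoy_rmsd$medium)
    threshes$hard <- c(threshes$hard, threshes$medium)
    basin_rows$medium <- NULL
  }
  train_levels <- names(basin_rows)
  levels <- lapply(stats::setNames(train_levels, train_levels), function(lvl) {
    list(purity_model = train_purity_regressor(basin_rows[[lvl]],
                                               basin_purity[[lvl]],
                                               seed = seed),
         rmsd_model = train_rmsd_regressor(decoy_pot[[lvl]],
                                           decoy_rmsd[[lvl]], seed = seed),
         dist_thresh = stats::median(threshes[[lvl]]))
  })
  diff_model <- train_difficulty_classifier(do.call(rbind, feats), labels,
                                            mode = mode, seed = seed)
  structure(list(mode = mode, difficulty_model = diff_model,
                 levels = levels, seed = seed,
                 epsilon0 = epsilon0, max_nn = max_nn),
            class = "select_models")
}

#' @export
print.select_models <- function(x, ...) {
  cat("<select_models> mode ", x$mode, "; levels: ",
      paste(names(x$levels), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' ML-Select: the full supervised selection pipeline
#'
#' Decomposes the ensemble into basins, predicts the dataset difficulty
#' level from the landscape features, picks that level's trained purity and
#' RMSD models and near-native threshold, ranks basins by predicted purity
#' (Phase 1, top n), and purifies them by predicted per-decoy RMSD
#' (Phase 2, top l).
#'
#' @param ensemble a [decoy_ensemble] with potential features.
#' @param models a `select_models` library from [train_select_models()].
#' @param n Phase-1 basin count (default 5).
#' @param l Phase-2 basin count (default 1).
#' @param tau_frac Phase-2 cutoff relaxation (default 0).
#' @param seed integer seed.
#' @param distances,graph,basins optional precomputed stages (recomputed
#'   when `NULL`).
#' @return list with `level`, `dist_thresh`, `phase1` (top-n basins),
#'   `basins` (top-l purified basins), and `features`.
#' @export
ml_select_pipeline <- function(ensemble, models, n = 5, l = 1, tau_frac = 0,
                               seed = 0, distances = NULL, graph = NULL,
                               basins = NULL) {
  stopifnot(inherits(models, "select_models"))
  if (is.null(distances)) distances <- pairwise_distances(ensemble)
  if (is.null(graph))
    graph <- build_nn_graph(distances, epsilon0 = models$epsilon0,
                            max_nn = models$max_nn)
  if (is.null(basins))
    basins <- assign_basins(graph, stats::setNames(ensemble$energy,
                                                   ensemble$ids), distances)
  basins <- pareto_annotate(basins)
  feats <- dataset_features(basins)
  level <- predict_difficulty(models$difficulty_model,
                              matrix(feats, nrow = 1))
  if (!level %in% names(models$levels))
    stop("no trained models for predicted level '", level,
         "'; available: ", paste(names(models$levels), collapse = ", "))
  lv <- models$levels[[level]]
  top_n <- phase1_select(basins, lv$purity_model, n = n)
  # hard-case escalation: when purification empties every Phase-1 basin the
  # near-native cutoff is raised in 0.5 A steps until the selected basins
  # retain decoys (the level's pooled threshold can undershoot the hardest
  # targets' attainable RMSD range)
  thresh <- lv$dist_thresh
  repeat {
    top_l <- tryCatch(
      purify_basins(top_n, lv$rmsd_model, ensemble, dist_thresh = thresh,
                    tau_frac = tau_frac, l = l),
      error = function(e) e)
    if (!inherits(top_l, "error")) break
    thresh <- thresh + 0.5
    if (thresh > lv$dist_thresh + 10)
      stop("purification empties every basin even after threshold ",
           "escalation to ", thresh, " A")
  }
  list(level = level, dist_thresh = thresh, phase1 = top_n,
       basins = top_l, features = feats)
}

# predicted per-decoy RMSD for a member set, using the level picked by the
# pipeline result
predict_decoy_rmsd <- function(models, ml_result, members, ensemble) {
  pot <- ensemble$potentials
  rownames(pot) <- ensemble$ids
  predict_rmsd(models$levels[[ml_result$level]]$rmsd_model,
               pot[members, , drop = FALSE])
}

#' Save / load a trained model library
#'
#' Persists the boosted-tree ensembles (as xgboost raw vectors) together
#' with a format version and the feature-order manifest.
#'
#' @param models a `select_models` library.
#' @param path file path.
#' @return `save_select_models` the path, invisibly; `load_select_models`
#'   the restored library.
#' @export
save_select_models <- function(models, path) {
  pack <- function(b) xgboost::xgb.save.raw(b)
  obj <- list(format = 1L, mode = models$mode, seed = models$seed,
              epsilon0 = models$epsilon0, max_nn = models$max_nn,
              dataset_feature_names = DATASET_FEATURE_NAMES,
              basin_feature_names = BASIN_FEATURE_NAMES,
              difficulty = list(raw = pack(models$difficulty_model$booster),
                                classes = models$difficulty_model$classes,
                                mode = models$difficulty_model$mode),
              levels = lapply(models$levels, function(lv)
                list(purity_raw = pack(lv$purity_model$booster),
                     rmsd_raw = pack(lv$rmsd_model$booster),
                     n_features = lv$rmsd_model$n_features,
                     dist_thresh = lv$dist_thresh)))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_select_models
#' @export
load_select_models <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, 1L)) stop("unknown model file format")
  dm <- structure(list(booster = xgboost::xgb.load.raw(obj$difficulty$raw),
                       classes = obj$difficulty$classes,
                       mode = obj$difficulty$mode,
                       feature_names = obj$dataset_feature_names,
                       seed = obj$seed), class = "difficulty_model")
  levels <- lapply(obj$levels, function(lv)
    list(purity_model = structure(
           list(booster = xgboost::xgb.load.raw(lv$purity_raw),
                feature_names = obj$basin_feature_names, seed = obj$seed),
           class = "purity_model"),
         rmsd_model = structure(
           list(booster = xgboost::xgb.load.raw(lv$rmsd_raw),
                n_features = lv$n_features, seed = obj$seed),
           class = "rmsd_model"),
         dist_thresh = lv$dist_thresh))
  structure(list(mode = obj$mode, difficulty_model = dm, levels = levels,
                 seed = obj$seed, epsilon0 = obj$epsilon0,
                 max_nn = obj$max_nn), class = "select_models")
}
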