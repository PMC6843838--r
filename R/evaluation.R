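#' Label near-native decoys
#'
#' A decoy is near-native when its least RMSD to the native structure is
#' strictly under `dist_thresh`.
#'
#' @param ensemble a [decoy_ensemble] with a native structure.
#' @param dist_thresh RMSD cutoff in Angstroms (> 0).
#' @return named integer 0/1 vector, one per decoy.
#' @export
label_near_natives <- function(ensemble, dist_thresh) {
  stopifnot(dist_thresh > 0)
  r <- native_rmsds(ensemble)
  stats::setNames(as.integer(r < dist_thresh), ensemble$ids)
}

native_rmsds <- function(ensemble) {
  if (is.null(ensemble$native)) {
    if (is.null(ensemble$true_rmsd))
      stop("ensemble has no native structure")
    return(ensemble$true_rmsd)
  }
  if (!is.null(ensemble$true_rmsd)) return(ensemble$true_rmsd)
  as.numeric(rmsd_to_ref_cpp(ensemble$coords, ensemble$native))
}

#' Difficulty category and near-native threshold of a decoy set
#'
#' Categorizes a decoy set from `min_dist` (the lowest decoy RMSD to the
#' native) and the abundance of near-natives, and fixes the per-target
#' `dist_thresh` that defines near-natives:
#' easy (`min_dist` < 1 A) uses 2 A; medium (1 A <= `min_dist` < 3 A) uses
#' 2.5 A, escalated to 3 A when that yields fewer than `scarcity` near
#' natives; hard starts at `min_dist` + 1 A rounded up to the next 0.5 A
#' and escalates by 0.5 A steps until at least one near-native exists. A
#' category left with fewer than `scarcity` near-natives at its final
#' threshold moves to the next harder category.
#'
#' @param min_dist minimum decoy-to-native RMSD in Angstroms.
#' @param near_native_counter function(dist_thresh) returning the number of
#'   decoys in the ensemble strictly under that threshold.
#' @param scarcity minimum near-native count for a category to keep a
#'   dataset (default 10).
#' @return list with `level` ("easy" | "medium" | "hard") and `dist_thresh`.
#' @export
categorize_difficulty <- function(min_dist, near_native_counter,
                                  scarcity = 10) {
  stopifnot(min_dist >= 0)
  if (min_dist < 1) {
    if (near_native_counter(2.0) >= scarcity)
      return(list(level = "easy", dist_thresh = 2.0))
  }
  if (min_dist < 3) {
    thresh <- 2.5
    if (near_native_counter(thresh) < scarcity) thresh <- 3.0
    if (near_native_counter(thresh) >= scarcity)
      return(list(level = "medium", dist_thresh = thresh))
  }
  # hard: escalate in 0.5 A steps until at least one near-native
  thresh <- ceiling((min_dist + 1) / 0.5) * 0.5
  while (near_native_counter(thresh) < 1) thresh <- thresh + 0.5
  list(level = "hard", dist_thresh = thresh)
}

#' Purity of a selected decoy set
#'
#' TP(S) / |S|: the fraction of near-native decoys in the selection.
#'
#' @param selected non-empty character vector of decoy ids.
#' @param g named 0/1 goodness vector (1 = near-native).
#' @return purity in [0, 1].
#' @export
purity <- function(selected, g) {
  if (!length(selected)) stop("empty selection")
  gs <- g[selected]
  if (anyNA(gs)) stop("goodness missing for some selected decoys")
  sum(gs) / length(gs)
}

#' RMSD loss of a selected decoy
#'
#' RMSD(selected, native) minus RMSD(best decoy, native); zero exactly when
#' the selected decoy is (tied with) the best decoy in the ensemble.
#'
#' @param selected_id decoy id.
#' @param ensemble a [decoy_ensemble] with native (or true RMSDs).
#' @return loss in Angstroms (>= 0).
#' @export
rmsd_loss <- function(selected_id, ensemble) {
  r <- stats::setNames(native_rmsds(ensemble), ensemble$ids)
  if (!selected_id %in% ensemble$ids) stop("unknown decoy id: ", selected_id)
  unname(r[selected_id] - min(r))
}

#' Run and score every selection method on one ensemble
#'
#' Runs KMeans-Select, Community-Select, Basins-Select, ML-Select (when a
#' trained model library is supplied), the two Weighted-Decoy-Select
#' variants and Random-Decoy-Select on one ensemble with a known native,
#' and reports purity, weighted purity, loss, and the purity difference
#' against the KMeans-Select baseline.
#'
#' @param ensemble a [decoy_ensemble] with native.
#' @param seed integer RNG seed.
#' @param models optional model library from [train_select_models()]; when
#'   `NULL` the supervised rows are omitted.
#' @param k_max,epsilon0,max_nn tuning forwarded to the stages.
#' @param distances optional precomputed `dist_store`.
#' @return data.frame, one row per method: `method`, `purity`,
#'   `weighted_purity`, `loss`, `size`, `tp`, `purity_vs_kmeans`, plus the
#'   ensemble's difficulty `level` and `dist_thresh`.
#' @export
compare_methods <- function(ensemble, seed = 0, models = NULL, k_max = 25,
                            epsilon0 = 1.0, max_nn = 100, distances = NULL) {
  if (is.null(distances)) distances <- pairwise_distances(ensemble)
  r <- native_rmsds(ensemble)
  cat_fun <- function(th) sum(r < th)
  diff <- categorize_difficulty(min(r), cat_fun)
  g <- label_near_natives(ensemble, diff$dist_thresh)
  graph <- build_nn_graph(distances, epsilon0 = epsilon0, max_nn = max_nn)
  energies <- stats::setNames(ensemble$energy, ensemble$ids)
  basins <- assign_basins(graph, energies, distances)

  rows <- list()
  score_set <- function(method, sel) {
    data.frame(method = method, purity = purity(sel, g),
               weighted_purity = NA_real_, loss = NA_real_,
               size = length(sel), tp = sum(g[sel]))
  }

  rows$kmeans <- score_set("KMeans-Select",
                           kmeans_select(ensemble, k_max = k_max, seed = seed))
  rows$community <- score_set("Community-Select",
                              community_select(graph, seed = seed,
                                               ensemble = ensemble))
  top_basin <- select_largest_basin(basins)
  rows$basins <- score_set("Basins-Select", top_basin$members)

  sel_basin <- top_basin
  if (!is.null(models)) {
    ml <- ml_select_pipeline(ensemble, models, distances = distances,
                             graph = graph, basins = basins, seed = seed)
    ml_top <- ml$basins[[1]]
    row <- score_set("ML-Select", ml_top$members)
    pred <- predict_decoy_rmsd(models, ml, ml_top$members, ensemble)
    wv <- weights_from_predicted_rmsd(pred, ids = ml_top$members)
    row$weighted_purity <- weighted_purity(wv, g)
    rows$ml <- row
    sel_basin <- ml_top
    wsel <- select_decoy(ml_top, wv)
    rows$wpred <- data.frame(method = "Weighted-Decoy-Select(predicted-rmsd)",
                             purity = purity(wsel, g),
                             weighted_purity = weighted_purity(wv, g),
                             loss = rmsd_loss(wsel, ensemble),
                             size = 1L, tp = sum(g[wsel]))
  }
  wd <- if (length(sel_basin$members) > 1)
    weights_from_density(density_scores(sel_basin$members, distances))
  else weight_vector(sel_basin$members, 1, scheme = "density",
                     params = list(k = 5))
  dsel <- select_decoy(sel_basin, wd)
  rows$wdens <- data.frame(method = "Weighted-Decoy-Select(density)",
                           purity = purity(dsel, g),
                           weighted_purity = weighted_purity(wd, g),
                           loss = rmsd_loss(dsel, ensemble),
                           size = 1L, tp = sum(g[dsel]))
  draws <- random_select(sel_basin, n_draws = 10, seed = seed)
  rows$random <- data.frame(method = "Random-Decoy-Select",
                            purity = mean(g[draws]),
                            weighted_purity = NA_real_,
                            loss = mean(vapply(draws, rmsd_loss, numeric(1),
                                               ensemble = ensemble)),
                            size = length(draws), tp = sum(g[draws]))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$purity_vs_kmeans <- out$purity - out$purity[out$method == "KMeans-Select"]
  out$level <- diff$level
  out$dist_thresh <- diff$dist_thresh
  out
}

#' Benchmark every selection method over a sweep of synthetic ensembles
#'
#' The package's standard desk-scale experiment: simulates
#' `n_train_per_level` training and `n_per_level` test ensembles per
#' difficulty level (easy / medium / hard study conditions listed below),
#' trains the supervised model library on the training ensembles, and runs
#' [compare_methods()] on every test ensemble.
#'
#' Study conditions per level (generator arguments): easy targets
#' `min_dist` 0.6 A, 35% near-natives, 2 false minima, energy noise sd
#' 0.25; medium 1.5 A, 12%, 5, 0.5; hard 3.5 A, 5%, 10, 0.75. All
#' ensembles share `n_decoys` and `n_residues`.
#'
#' @param seed integer seed controlling every simulation and stochastic
#'   stage.
#' @param n_per_level test ensembles per difficulty level (default 10).
#' @param n_train_per_level training ensembles per level (default 2).
#' @param n_decoys decoys per ensemble (default 2000).
#' @param n_residues residues per decoy (default 40).
#' @param mode difficulty-conditioning mode; the default `"binary"` (medium
#'   pooled with hard) is the setting under which difficulty prediction is
#'   reliable at two training sets per category — the multiclass setting
#'   systematically confuses the medium level.
#' @return list with `results` (per-ensemble [compare_methods()] rows plus
#'   `target` and `sim_level`) and the trained `models`.
#' @export
run_selection_benchmark <- function(seed, n_per_level = 10,
                                    n_train_per_level = 2, n_decoys = 2000,
                                    n_residues = 40,
                                    mode = c("binary", "multiclass")) {
  mode <- match.arg(mode)
  set.seed(seed)
  conds <- list(
    easy = list(min_dist = 0.6, nn = 0.35, fm = 2, en = 0.25),
    medium = list(min_dist = 1.5, nn = 0.12, fm = 5, en = 0.50),
    hard = list(min_dist = 3.5, nn = 0.05, fm = 10, en = 0.75))
  n_each <- n_train_per_level + n_per_level
  seeds <- matrix(sample.int(99999999L, 3 * n_each), nrow = 3)
  rownames(seeds) <- names(conds)
  spec_for <- function(level, s) {
    cn <- conds[[level]]
    sim_spec(n_decoys = n_decoys, n_residues = n_residues,
             min_dist = cn$min_dist, near_native_fraction = cn$nn,
             n_false_minima = cn$fm, energy_noise_sd = cn$en, seed = s)
  }
  train_ens <- list()
  for (level in names(conds))
    for (i in seq_len(n_train_per_level))
      train_ens <- c(train_ens, list(simulate_ensemble(
        spec_for(level, seeds[level, i]))))
  models <- train_select_models(train_ens, seed = seed, mode = mode)

  rows <- list()
  for (level in names(conds)) {
    for (i in seq_len(n_per_level)) {
      ens <- simulate_ensemble(
        spec_for(level, seeds[level, n_train_per_level + i]))
      tab <- compare_methods(ens, seed = seed, models = models)
      tab$target <- ens$target_id
      tab$sim_level <- level
      rows <- c(rows, list(tab))
    }
  }
  list(results = do.call(rbind, rows), models = models)
}

#' Table-3-style per-dataset summary
#'
#' Summary statistics of an ensemble's RMSD distribution that contextualize
#' losses: median RMSD to native, percentage of decoys under 3 A, and
#' percentage within 1.5 A of the best decoy.
#'
#' @param ensemble a [decoy_ensemble] with native.
#' @return one-row data.frame: `median_rmsd`, `pct_under_3A`,
#'   `pct_within_1.5A_of_best`.
#' @export
ensemble_rmsd_summary <- function(ensemble) {
  r <- native_rmsds(ensemble)
  data.frame(median_rmsd = stats::median(r),
             pct_under_3A = 100 * mean(r < 3),
             pct_within_1.5A_of_best = 100 * mean(r < min(r) + 1.5))
}
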