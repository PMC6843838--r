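#' Density scores of decoys within a basin
#'
#' For m decoys, the raw density score of decoy i is
#' \eqn{S_i = \sum_{j \ne i} r_{ij} / m} (r = pairwise C-alpha least RMSD);
#' high scores mark outliers far from the rest of the basin. Scores are
#' normalized to \eqn{S'_i \in [-1, 1]} piecewise about the median:
#' \eqn{(S_i - S_{med})/(S_{med} - S_{min})} below the median, 0 at it, and
#' \eqn{(S_i - S_{med})/(S_{max} - S_{med})} above. A degenerate branch
#' denominator (median equal to the extreme) maps that branch to 0, so an
#' all-equal basin is uniformly scored.
#'
#' @param members character vector of at least 2 decoy ids.
#' @param distances a `dist_store` covering the members.
#' @return a `density_scores` list: `ids`, raw `S`, normalized `S_norm`,
#'   and `S_min`, `S_median`, `S_max`.
#' @export
density_scores <- function(members, distances) {
  m <- length(members)
  if (m < 2) stop("density scores need at least 2 decoys")
  sub <- ds_lookup(distances, members)
  S <- rowSums(sub) / m                       # diagonal is 0
  s_min <- min(S); s_med <- stats::median(S); s_max <- max(S)
  S_norm <- numeric(m)
  lo <- S < s_med; hi <- S > s_med
  if (s_med > s_min) S_norm[lo] <- (S[lo] - s_med) / (s_med - s_min)
  if (s_max > s_med) S_norm[hi] <- (S[hi] - s_med) / (s_max - s_med)
  structure(list(ids = members, S = unname(S), S_norm = S_norm,
                 S_min = s_min, S_median = s_med, S_max = s_max),
            class = "density_scores")
}

#' Decoy weights from density scores
#'
#' \eqn{w_i = e^{-k S'_i}}: dense (central) decoys get large weights,
#' outliers small ones; k amplifies the effect (k = 0 is uniform).
#'
#' @param scores a `density_scores` object.
#' @param k non-negative amplification constant (default 5).
#' @return a `weight_vector`: `ids`, weights `w`, selection probabilities
#'   `p = w / sum(w)`, `scheme = "density"`.
#' @export
weights_from_density <- function(scores, k = 5) {
  stopifnot(inherits(scores, "density_scores"), k >= 0)
  w <- exp(-k * scores$S_norm)
  weight_vector(scores$ids, w, scheme = "density", params = list(k = k))
}

#' Decoy weights from predicted RMSD
#'
#' \eqn{w_i = 1 / (\hat{r}_i + \zeta)} with \eqn{\hat{r}_i} the predicted
#' RMSD in Angstroms: a non-increasing, non-negative weighting so decoys
#' predicted closer to the native get larger weights. zeta guards against
#' division by zero.
#'
#' @param predicted numeric vector of non-negative predicted RMSDs, named by
#'   decoy id (or `ids` supplied separately).
#' @param zeta small positive guard (default 1e-6).
#' @param ids optional character vector of decoy ids.
#' @return a `weight_vector` with `scheme = "predicted_rmsd"`.
#' @export
weights_from_predicted_rmsd <- function(predicted, zeta = 1e-6, ids = NULL) {
  if (any(predicted < 0)) stop("predicted RMSDs must be non-negative")
  ids <- ids %||% names(predicted) %||% as.character(seq_along(predicted))
  w <- 1 / (predicted + zeta)
  weight_vector(ids, unname(w), scheme = "predicted_rmsd",
                params = list(zeta = zeta))
}

weight_vector <- function(ids, w, scheme, params = list()) {
  if (any(w < 0)) stop("weights must be non-negative")
  total <- sum(w)
  structure(list(ids = as.character(ids), w = w,
                 p = if (total > 0) w / total else rep(NA_real_, length(w)),
                 scheme = scheme, params = params), class = "weight_vector")
}

#' @export
print.weight_vector <- function(x, ...) {
  cat("<weight_vector> ", length(x$ids), " decoys, scheme ", x$scheme,
      ", max p ", signif(max(x$p), 4), "\n", sep = "")
  invisible(x)
}

#' Weighted purity of a basin
#'
#' \eqn{wp(B) = \sum_i w_i g_i / \sum_i w_i}, where the goodness g_i of a
#' decoy is 1 if it is near-native and 0 otherwise. Equals the probability
#' of drawing a near-native decoy when sampling proportionally to the
#' weights; with uniform weights it reduces to the plain purity TP/|B|.
#'
#' @param weights a `weight_vector`.
#' @param goodness 0/1 vector, either named by decoy id or in weight order.
#' @return weighted purity in [0, 1].
#' @export
weighted_purity <- function(weights, goodness) {
  stopifnot(inherits(weights, "weight_vector"))
  g <- if (!is.null(names(goodness))) as.numeric(goodness[weights$ids])
       else as.numeric(goodness)
  if (length(g) != length(weights$w) || anyNA(g))
    stop("goodness must cover every weighted decoy")
  if (!all(g %in% c(0, 1))) stop("goodness must be 0/1")
  tot <- sum(weights$w)
  if (tot <= 0) stop("all-zero weights")
  sum(weights$w * g) / tot
}

#' Weighted-Decoy-Select: single decoy with the largest weight
#'
#' Ranks basin decoys from larger to lower weight and offers the top decoy
#' as the prediction; ties broken by lower decoy energy, then id.
#'
#' @param basin a `basin` (or any object with `members` and
#'   `member_energies`).
#' @param weights a `weight_vector` over the basin members.
#' @return the selected decoy id.
#' @export
select_decoy <- function(basin, weights) {
  stopifnot(inherits(weights, "weight_vector"))
  ids <- weights$ids
  if (!length(ids)) stop("empty basin")
  e <- basin$member_energies[ids]
  o <- order(-weights$w, e, id_rank(ids), method = "radix")
  ids[o[1]]
}

#' Random-Decoy-Select baseline
#'
#' Uniform draws (with replacement) of decoys from a basin; the caller
#' averages losses over the draws.
#'
#' @param basin a `basin`.
#' @param n_draws number of draws (default 10).
#' @param seed integer RNG seed.
#' @return character vector of n_draws decoy ids.
#' @export
random_select <- function(basin, n_draws = 10, seed = 0) {
  if (!length(basin$members)) stop("empty basin")
  set.seed(seed)
  basin$members[sample.int(length(basin$members), n_draws, replace = TRUE)]
}

#' Export a weight vector as TSV
#'
#' @param weights a `weight_vector`.
#' @param path output TSV (columns id, w, p, scheme).
#' @return invisibly, the path.
#' @export
write_weights <- function(weights, path) {
  write.table(data.frame(id = weights$ids, w = weights$w, p = weights$p,
                         scheme = weights$scheme),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
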