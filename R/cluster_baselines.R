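#' K-means grouping of a decoy ensemble
#'
#' Energy-blind baseline. Decoys are represented as flattened C-alpha
#' coordinate vectors after Kabsch superposition of every decoy onto the
#' first decoy, so Euclidean distance between vectors approximates pairwise
#' RMSD scaled by sqrt(residues). For a given k, Lloyd k-means (at most 10
#' iterations) is restarted `n_restarts` times with centroids initialized at
#' k decoys drawn uniformly at random; the restart minimizing the
#' within-cluster scatter
#' \deqn{L(C) = \tfrac12 \sum_l \sum_{i \in C_l} \sum_{j \in C_l, j \ne i}
#'   D(x_i, x_j)}
#' (D = Euclidean distance) is kept.
#'
#' @param ensemble a [decoy_ensemble].
#' @param k number of clusters, 1 <= k <= number of decoys.
#' @param n_restarts number of seeded restarts (default 10).
#' @param seed integer RNG seed.
#' @return a `cluster_set`: list with `method`, `clusters` (list of id
#'   vectors), `loss`, `k`, and `sse` of the winning assignment.
#' @export
kmeans_group <- function(ensemble, k, n_restarts = 10, seed = 0) {
  X <- superposed_vectors(ensemble)
  D <- as.matrix(stats::dist(X))
  res <- kmeans_group_impl(X, D, ensemble$ids, k, n_restarts, seed)
  res$method <- "kmeans"
  res
}

# flatten decoys after superposing each onto the first decoy
superposed_vectors <- function(ensemble) {
  n <- length(ensemble$ids)
  ref <- ensemble$coords[, , 1]
  ref_c <- sweep(ref, 2, colMeans(ref))
  X <- matrix(0, n, 3 * nrow(ref))
  for (i in seq_len(n)) {
    M <- ensemble$coords[, , i]
    Mc <- sweep(M, 2, colMeans(M))
    sv <- svd(crossprod(Mc, ref_c))
    d <- sign(det(sv$v %*% t(sv$u)))
    if (d == 0) d <- 1
    R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
    X[i, ] <- as.numeric(Mc %*% t(R))
  }
  rownames(X) <- ensemble$ids
  X
}

kmeans_group_impl <- function(X, D, ids, k, n_restarts = 10, seed = 0) {
  n <- nrow(X)
  if (k < 1 || k > n) stop("k must satisfy 1 <= k <= |ensemble| (got ", k, ")")
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- sample.int(n, k)
    fit <- tryCatch(
      suppressWarnings(stats::kmeans(X, centers = X[init, , drop = FALSE],
                                     iter.max = 10, algorithm = "Lloyd")),
      error = function(e) NULL)               # empty-cluster init: skip
    if (is.null(fit)) next
    loss <- scatter_loss(D, fit$cluster)
    if (is.null(best) || loss < best$loss - 1e-12)
      best <- list(loss = loss, fit = fit)
  }
  if (is.null(best)) {
    # fewer distinct decoys than k (duplicate conformations): each distinct
    # conformation forms one cluster
    uniq <- unique(X)
    if (nrow(uniq) >= k) stop("all k-means restarts failed")
    cl <- match(data.frame(t(X)), data.frame(t(uniq)))
    clusters <- lapply(sort(unique(cl)), function(l) ids[cl == l])
    return(structure(list(method = "kmeans", clusters = clusters,
                          assignment = stats::setNames(cl, ids),
                          loss = scatter_loss(D, cl), k = length(clusters),
                          sse = 0), class = "cluster_set"))
  }
  cl <- best$fit$cluster
  clusters <- lapply(sort(unique(cl)), function(l) ids[cl == l])
  structure(list(method = "kmeans",
                 clusters = clusters, assignment = stats::setNames(cl, ids),
                 loss = best$loss, k = length(clusters),
                 sse = best$fit$tot.withinss), class = "cluster_set")
}

# within-cluster scatter: half the sum of pairwise Euclidean distances
scatter_loss <- function(D, assignment) {
  tot <- 0
  for (l in unique(assignment)) {
    idx <- which(assignment == l)
    if (length(idx) > 1) tot <- tot + sum(D[idx, idx]) / 2
  }
  tot
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("<cluster_set> ", x$method, ": ", length(x$clusters), " clusters, sizes ",
      paste(sort(lengths(x$clusters), decreasing = TRUE), collapse = "/"),
      "\n", sep = "")
  invisible(x)
}

#' Choose k at the knee of the SSE curve
#'
#' Runs [kmeans_group()] for k = 1..k_max, records the sum of squared
#' distances of members to their centroid (SSE), and returns the k whose
#' point on the SSE curve has maximal perpendicular distance from the chord
#' joining (1, SSE(1)) and (k_max, SSE(k_max)); ties go to the smaller k.
#' A flat SSE curve (no curvature) returns 1 with a warning.
#'
#' @inheritParams kmeans_group
#' @param k_max largest k scanned (default 25, capped at |ensemble| - 1).
#' @return the chosen integer k; the scanned curve is attached as attribute
#'   `sse_curve`.
#' @export
knee_select_k <- function(ensemble, k_max = 25, seed = 0, n_restarts = 10) {
  X <- superposed_vectors(ensemble)
  D <- as.matrix(stats::dist(X))
  knee_select_k_impl(X, D, ensemble$ids, k_max, seed, n_restarts)
}

knee_select_k_impl <- function(X, D, ids, k_max = 25, seed = 0,
                               n_restarts = 10) {
  n <- nrow(X)
  k_max <- min(k_max, n - 1L)
  if (k_max < 2) stop("k_max must be at least 2 (and < |ensemble|)")
  sse <- vapply(seq_len(k_max), function(k)
    kmeans_group_impl(X, D, ids, k, n_restarts, seed + k)$sse, numeric(1))
  knee <- knee_of_curve(seq_len(k_max), sse)
  attr(knee, "sse_curve") <- sse
  knee
}

# max perpendicular distance to the chord; ties -> smaller x
knee_of_curve <- function(x, y) {
  if (max(y) - min(y) < 1e-12 * max(1, abs(max(y)))) {
    warning("SSE curve is constant; returning k = 1")
    return(1L)
  }
  x1 <- x[1]; y1 <- y[1]; x2 <- x[length(x)]; y2 <- y[length(y)]
  num <- abs((y2 - y1) * x - (x2 - x1) * y + x2 * y1 - y2 * x1)
  den <- sqrt((y2 - y1)^2 + (x2 - x1)^2)
  d <- num / den
  as.integer(x[which.max(d)])
}

#' KMeans-Select: largest cluster at the knee-selected k
#'
#' Composes [knee_select_k()] and [kmeans_group()] and returns the largest
#' cluster (ties broken by lower mean energy, then id).
#'
#' @inheritParams knee_select_k
#' @return character vector of the selected decoy ids; attributes `k` and
#'   `cluster_set` carry the full grouping.
#' @export
kmeans_select <- function(ensemble, k_max = 25, seed = 0, n_restarts = 10) {
  X <- superposed_vectors(ensemble)
  D <- as.matrix(stats::dist(X))
  k <- knee_select_k_impl(X, D, ensemble$ids, k_max, seed, n_restarts)
  cs <- kmeans_group_impl(X, D, ensemble$ids, as.integer(k), n_restarts, seed)
  sel <- largest_id_set(cs$clusters, ensemble)
  attr(sel, "k") <- as.integer(k)
  attr(sel, "cluster_set") <- cs
  sel
}

# largest id set; ties -> lower mean energy, then lowest id
largest_id_set <- function(sets, ensemble) {
  sizes <- lengths(sets)
  e <- stats::setNames(ensemble$energy, ensemble$ids)
  mean_e <- vapply(sets, function(s) mean(e[s]), numeric(1))
  first_id <- vapply(sets, function(s)
    s[order(id_rank(s))][1], character(1))
  sets[[order(-sizes, mean_e, id_rank(first_id), method = "radix")[1]]]
}

#' Community-Select: largest Louvain community of the nn-graph
#'
#' Runs Louvain modularity optimization on the (unweighted) epsilon
#' nn-graph and returns the largest community; ties broken by lower mean
#' energy (when `ensemble` is given), then id. An edgeless graph yields
#' singleton communities and a warning.
#'
#' @param graph an `nn_graph`.
#' @param seed integer RNG seed (Louvain's vertex sweep is randomized).
#' @param ensemble optional [decoy_ensemble] supplying energies for the tie
#'   rule.
#' @return character vector of selected decoy ids; attribute `communities`
#'   carries the full partition (list of id vectors).
#' @export
community_select <- function(graph, seed = 0, ensemble = NULL) {
  stopifnot(inherits(graph, "nn_graph"))
  g <- graph$graph
  if (igraph::ecount(g) == 0) {
    warning("edgeless nn-graph: every decoy is its own community")
    comms <- as.list(graph$ids)
  } else {
    set.seed(seed)
    cl <- igraph::cluster_louvain(g, weights = NA)
    mem <- igraph::membership(cl)
    comms <- lapply(sort(unique(mem)), function(l) graph$ids[mem == l])
  }
  sel <- if (!is.null(ensemble)) largest_id_set(comms, ensemble) else {
    sizes <- lengths(comms)
    fid <- vapply(comms, function(s) s[order(id_rank(s))][1], character(1))
    comms[[order(-sizes, id_rank(fid), method = "radix")[1]]]
  }
  attr(sel, "communities") <- comms
  sel
}
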