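# Programmatic fixtures; nothing is read from disk except what the tests
# themselves write to tempdirs.

# nn_graph from an explicit symmetric distance matrix (no growth, no cap
# unless asked): mirrors the public builder but lets tests plant exact edges
graph_from_dist <- function(mat, eps, ids = NULL, max_nn = Inf) {
  if (is.null(ids)) ids <- rownames(mat) %||% paste0("v", seq_len(nrow(mat)))
  dimnames(mat) <- list(ids, ids)
  ds <- dist_store(mat, ids)
  suppressWarnings(build_nn_graph(ds, epsilon0 = eps, max_iter = 0,
                                  max_nn = max_nn))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# path graph v1 - v2 - ... - vn with unit edge distances
path_graph <- function(energies, ids = paste0("v", seq_along(energies))) {
  n <- length(energies)
  mat <- matrix(100, n, n)
  diag(mat) <- 0
  for (i in seq_len(n - 1)) mat[i, i + 1] <- mat[i + 1, i] <- 1
  g <- graph_from_dist(mat, eps = 1, ids = ids)
  list(graph = g, energies = setNames(energies, ids))
}

# random connected-ish graph + energies for oracle equivalence tests
random_instance <- function(n, seed, p_edge = 0.15) {
  set.seed(seed)
  mat <- matrix(100, n, n)
  diag(mat) <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (runif(1) < p_edge) mat[i, j] <- mat[j, i] <- runif(1, 0.1, 1)
  }
  ids <- sprintf("r%03d", sample.int(n))   # shuffled ids stress tie-breaks
  g <- graph_from_dist(mat, eps = 1, ids = ids)
  # a few exact energy ties to exercise plateau handling
  e <- round(runif(n, -5, 5), 1)
  list(graph = g, energies = setNames(e, ids))
}

# tiny molecular ensemble built from explicit coordinates
toy_ensemble <- function(n_decoys = 4, n_res = 5, seed = 1, native = NULL,
                         energy = NULL) {
  set.seed(seed)
  base <- cbind(3.8 * seq_len(n_res), 0, 0) + matrix(rnorm(n_res * 3, 0, .5),
                                                     n_res, 3)
  coords <- array(0, c(n_res, 3, n_decoys))
  for (i in seq_len(n_decoys))
    coords[, , i] <- base + matrix(rnorm(n_res * 3, 0, 0.3 * i), n_res, 3)
  decoy_ensemble("toy", sprintf("t%02d", seq_len(n_decoys)), coords,
                 energy %||% seq_len(n_decoys), native = native)
}

# ensemble with k planted conformational clusters: each cluster has its own
# random chain SHAPE (translations/rotations are removed by superposition,
# so separation must live in shape space), decoys are tight perturbations
planted_cluster_ensemble <- function(sizes, sep = 15, sd = 0.05, seed = 1) {
  set.seed(seed)
  k <- length(sizes)
  n <- sum(sizes)
  n_res <- 6
  shapes <- lapply(seq_len(k), function(i)
    matrix(rnorm(n_res * 3, 0, sep), n_res, 3))
  coords <- array(0, c(n_res, 3, n))
  lab <- rep(seq_len(k), sizes)
  for (i in seq_len(n))
    coords[, , i] <- shapes[[lab[i]]] +
      matrix(rnorm(n_res * 3, 0, sd), n_res, 3)
  ens <- decoy_ensemble("planted", sprintf("c%03d", seq_len(n)), coords,
                        energy = rnorm(n))
  list(ensemble = ens, labels = lab)
}

# basin object straight from members/energies (unit-testing selectors)
mk_basin <- function(focal, members, energies, size = NULL, pr = NA_integer_,
                     pc = NA_integer_, ncomp = 1L, pers = 1) {
  b <- basinselect:::new_basin(focal, members, energies)
  b$pareto_rank <- pr; b$pareto_count <- pc
  b$n_components <- ncomp; b$persistence <- pers
  if (!is.null(size)) b$size <- size
  b
}

# plain basin list with given (size, energy) pairs for pareto tests
mk_basin_table <- function(sizes, energies) {
  lapply(seq_along(sizes), function(i)
    mk_basin(sprintf("b%02d", i), sprintf("b%02d", i), energies[i],
             size = sizes[i]))
}
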