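# Independent oracles, deliberately implemented by different algorithms
# than the package internals they check.

# Least RMSD via the quaternion method: the optimal superposition RMSD is
# sqrt((GA + GB - 2*lambda_max)/n) with lambda_max the largest eigenvalue of
# the 4x4 quaternion key matrix built from the cross-covariance.
quat_rmsd <- function(A, B) {
  n <- nrow(A)
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  M <- crossprod(Ac, Bc)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(Ac^2) + sum(Bc^2) - 2 * lam) / n
  sqrt(max(msd, 0))
}

# random 3D rigid motion (proper rotation + translation)
random_rigid <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
  list(R = R, t = rnorm(3, 0, 5))
}

apply_rigid <- function(A, rt) sweep(A %*% t(rt$R), 2, -rt$t)

# igraph neighbor sets of an nn_graph, recomputed directly
oracle_adj <- function(graph) {
  lapply(igraph::as_adj_list(graph$graph, mode = "all"), as.integer)
}

oracle_edge_dist <- function(graph) {
  el <- igraph::as_edgelist(graph$graph, names = FALSE)
  d <- igraph::edge_attr(graph$graph, "dist")
  function(u, v) {
    hit <- (el[, 1] == u & el[, 2] == v) | (el[, 1] == v & el[, 2] == u)
    d[hit][1]
  }
}

# lexicographic (energy, id-rank) comparison
lex_lt <- function(e, idr, a, b) e[a] < e[b] || (e[a] == e[b] && idr[a] < idr[b])

# brute-force closed-neighborhood minima scan
oracle_minima <- function(graph, e) {
  ids <- graph$ids
  idr <- match(ids, sort(unique(ids), method = "radix"))
  adj <- oracle_adj(graph)
  keep <- vapply(seq_along(ids), function(u)
    all(vapply(adj[[u]], function(v) lex_lt(e, idr, u, v), logical(1))),
    logical(1))
  ids[keep]
}

# step-by-step steepest-ratio descent, one vertex at a time, no memoization
oracle_basins <- function(graph, e) {
  ids <- graph$ids
  idr <- match(ids, sort(unique(ids), method = "radix"))
  adj <- oracle_adj(graph)
  ed <- oracle_edge_dist(graph)
  mins <- match(oracle_minima(graph, e), ids)
  descend <- function(u) {
    while (!(u %in% mins)) {
      nb <- adj[[u]]
      ratio <- vapply(nb, function(v) (e[u] - e[v]) / ed(u, v), numeric(1))
      cand <- nb[ratio == max(ratio)]
      u <- cand[which.min(idr[cand])]
    }
    u
  }
  roots <- vapply(seq_along(ids), descend, integer(1))
  split(ids, ids[roots])
}

# exhaustive sublevel-sweep persistence: recompute induced-subgraph
# components from scratch after every vertex insertion
oracle_persistence <- function(graph, e, minima) {
  ids <- graph$ids
  idr <- match(ids, sort(unique(ids), method = "radix"))
  n <- length(ids)
  ord <- order(e, idr, method = "radix")
  g0 <- graph$graph
  pers <- setNames(rep(NA_real_, length(minima)), minima)
  lowest_min <- function(active) {
    # per component of the induced subgraph, the lex-lowest vertex
    sub <- igraph::induced_subgraph(g0, active)
    mem <- igraph::components(sub)$membership
    vn <- match(igraph::V(sub)$name, ids)
    vapply(split(vn, mem), function(vs)
      vs[order(e[vs], idr[vs])][1], integer(1))
  }
  active <- integer(0)
  for (u in ord) {
    before <- if (length(active)) lowest_min(active) else integer(0)
    active <- c(active, u)
    after <- lowest_min(active)
    died <- setdiff(before, after)
    for (m in died) pers[ids[m]] <- e[u] - e[m]
  }
  # survivors get the component energy range
  comp <- igraph::components(g0)$membership
  for (cc in unique(comp)) {
    vs <- which(comp == cc)
    surv <- intersect(ids[vs], minima)
    surv <- surv[is.na(pers[surv])]
    if (length(surv)) {
      m <- match(surv, ids)
      m <- m[order(e[m], idr[m])][1]
      pers[ids[m]] <- max(e[vs]) - e[m]
    }
  }
  pers
}

# O(n^2) Pareto dominance oracle
oracle_pareto <- function(size, energy) {
  n <- length(size)
  rank <- integer(n); count <- integer(n)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a == b) next
    if (size[a] >= size[b] && energy[a] <= energy[b] &&
        (size[a] > size[b] || energy[a] < energy[b])) {
      count[a] <- count[a] + 1L
      rank[b] <- rank[b] + 1L
    }
  }
  list(rank = rank, count = count)
}

# adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab))
  si <- sum(ch2(rowSums(tab)))
  sj <- sum(ch2(colSums(tab)))
  n2 <- ch2(sum(tab))
  exp_idx <- si * sj / n2
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}
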