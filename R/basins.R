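#' Local minima of the energy landscape on an nn-graph
#'
#' A vertex is a local minimum when its energy is no higher than that of any
#' 1-neighbor; plateaus (exact energy ties) are resolved by the lexicographic
#' (energy, id) key so each flat region contributes exactly one minimum.
#' Isolated vertices are minima.
#'
#' @param graph an `nn_graph`.
#' @param energies named numeric vector of per-decoy energies (names = decoy
#'   ids), or unnamed in graph vertex order.
#' @return character vector of minimum ids.
#' @export
find_local_minima <- function(graph, energies) {
  ids <- graph$ids
  e <- align_energies(energies, ids)
  idr <- id_rank(ids)
  adj <- graph_adjacency(graph)
  mins <- vapply(seq_along(ids), function(u) {
    nb <- adj$nbr[[u]]
    all(e[u] < e[nb] | (e[u] == e[nb] & idr[u] < idr[nb]))
  }, logical(1))
  ids[mins]
}

align_energies <- function(energies, ids) {
  if (!is.null(names(energies))) {
    if (!all(ids %in% names(energies)))
      stop("energies missing for some graph vertices")
    e <- as.numeric(energies[ids])
  } else {
    if (length(energies) != length(ids))
      stop("unnamed energies must have one value per vertex")
    e <- as.numeric(energies)
  }
  if (any(!is.finite(e))) stop("energies must be finite")
  e
}

#' Decompose an nn-graph plus energies into basins
#'
#' Implements discrete steepest-ratio negative-gradient descent: every
#' non-minimum vertex u follows the incident edge (u,v) maximizing
#' \code{(e(u) - e(v)) / d(u,v)} (ties broken by smaller id), iterated until
#' a local minimum is reached. Vertices reaching the same minimum form one
#' basin; the basins partition the vertex set. Basin persistence is filled
#' in via [compute_persistence()] and per-basin subgraph component counts
#' via [basin_subgraph_components()] when `distances` is supplied.
#'
#' @inheritParams find_local_minima
#' @param distances optional `dist_store`; when present, each basin's
#'   `n_components` feature is computed.
#' @param compute_features logical; fill persistence (and n_components if
#'   distances given). Default TRUE.
#' @return list of `basin` objects (focal_id, members, size, focal_energy,
#'   min_energy, avg_energy, persistence, n_components), ordered by
#'   decreasing size (ties by focal energy then id).
#' @export
assign_basins <- function(graph, energies, distances = NULL,
                          compute_features = TRUE) {
  ids <- graph$ids
  e <- align_energies(energies, ids)
  idr <- id_rank(ids)
  n <- length(ids)
  adj <- graph_adjacency(graph)

  # steepest-ratio successor for every vertex (NA for minima)
  succ <- rep(NA_integer_, n)
  is_min <- rep(TRUE, n)
  for (u in seq_len(n)) {
    nb <- adj$nbr[[u]]
    if (!length(nb)) next
    lower <- e[nb] < e[u] | (e[nb] == e[u] & idr[nb] < idr[u])
    if (!any(lower)) next                      # u is a local minimum
    is_min[u] <- FALSE
    ratio <- (e[u] - e[nb]) / adj$dist[[u]]
    best <- max(ratio)
    cand <- nb[ratio == best]
    succ[u] <- cand[which.min(idr[cand])]
  }

  # follow descent paths with memoization
  root <- rep(NA_integer_, n)
  for (u in seq_len(n)) {
    if (!is.na(root[u])) next
    path <- integer(0)
    v <- u
    steps <- 0L
    while (is.na(root[v]) && !is_min[v]) {
      path <- c(path, v)
      v <- succ[v]
      steps <- steps + 1L
      if (steps > n) stop("descent cycle detected: internal inconsistency")
    }
    r <- if (is_min[v]) v else root[v]
    root[c(path, u)] <- r
  }

  basins <- lapply(sort(unique(root)), function(m) {
    mem <- which(root == m)
    new_basin(focal_id = ids[m], members = ids[mem], energies = e[mem])
  })
  basins <- order_basins(basins)
  if (compute_features) {
    pers <- compute_persistence(graph, e, ids[is_min])
    for (i in seq_along(basins))
      basins[[i]]$persistence <- unname(pers[basins[[i]]$focal_id])
    if (!is.null(distances))
      for (i in seq_along(basins))
        basins[[i]]$n_components <- basin_subgraph_components(basins[[i]],
                                                             distances)
  }
  basins
}

new_basin <- function(focal_id, members, energies) {
  structure(list(focal_id = focal_id, members = members,
                 size = length(members),
                 focal_energy = min(energies),
                 min_energy = min(energies),
                 avg_energy = mean(energies),
                 member_energies = stats::setNames(energies, members),
                 persistence = NA_real_, n_components = NA_integer_,
                 pareto_rank = NA_integer_, pareto_count = NA_integer_),
            class = "basin")
}

#' @export
print.basin <- function(x, ...) {
  cat("<basin> focal ", x$focal_id, ": ", x$size, " decoys, focal energy ",
      signif(x$focal_energy, 4),
      if (!is.na(x$persistence)) paste0(", persistence ",
                                        signif(x$persistence, 4)) else "",
      "\n", sep = "")
  invisible(x)
}

# decreasing size, then lower focal energy, then id
order_basins <- function(basins) {
  sizes <- vapply(basins, `[[`, numeric(1), "size")
  fe <- vapply(basins, `[[`, numeric(1), "focal_energy")
  fid <- vapply(basins, `[[`, character(1), "focal_id")
  basins[order(-sizes, fe, id_rank(fid), method = "radix")]
}

#' Sublevel-set persistence of local minima
#'
#' Union-find persistence over the graph filtered by ascending (energy, id):
#' when a vertex first connects two growing components, the component whose
#' minimum is lexicographically younger (higher) dies and receives
#' persistence equal to the merge energy minus its focal energy. The minimum
#' surviving in each connected component receives the component's energy
#' range (max energy - focal energy), so all persistences stay finite.
#'
#' @inheritParams find_local_minima
#' @param minima character vector of minimum ids, as returned by
#'   [find_local_minima()].
#' @return named numeric vector of persistences (>= 0), one per minimum.
#' @export
compute_persistence <- function(graph, energies, minima) {
  ids <- graph$ids
  e <- align_energies(energies, ids)
  idr <- id_rank(ids)
  n <- length(ids)
  adj <- graph_adjacency(graph)

  ord <- order(e, idr, method = "radix")
  pos <- integer(n); pos[ord] <- seq_len(n)   # filtration position
  parent <- seq_len(n)
  comp_min <- integer(n)                       # representative -> minimum vtx
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  pers <- stats::setNames(rep(NA_real_, n), ids)
  processed <- logical(n)
  for (u in ord) {
    nb <- adj$nbr[[u]]
    nb <- nb[processed[nb]]
    processed[u] <- TRUE
    comp_min[u] <- u
    if (!length(nb)) next                      # birth of a new component
    roots <- unique(vapply(nb, find, integer(1)))
    # attach u to the eldest (lexicographically lowest minimum) component
    mins <- comp_min[roots]
    eldest <- roots[order(e[mins], idr[mins], method = "radix")[1]]
    for (r in roots) {
      if (r == eldest) next
      m <- comp_min[r]
      pers[ids[m]] <- e[u] - e[m]              # younger minimum dies at u
      parent[r] <- eldest
    }
    parent[u] <- eldest
  }
  # survivors: persistence = component energy range
  comp <- igraph::components(graph$graph)$membership
  for (cc in unique(comp)) {
    vs <- which(comp == cc)
    alive <- vs[ids[vs] %in% minima & is.na(pers[ids[vs]])]
    if (length(alive)) {
      # exactly one survivor per component: its component's global minimum
      m <- alive[order(e[alive], idr[alive], method = "radix")[1]]
      pers[ids[m]] <- max(e[vs]) - e[m]
    }
  }
  out <- pers[minima]
  if (any(is.na(out))) stop("persistence undefined for some minima")
  out
}

#' Connected components of a basin's internal nn-graph
#'
#' Re-embeds only the basin's members in an nn-graph with
#' `epsilon = pdist + 1` Angstrom, where pdist is the mean pairwise member
#' distance (no epsilon growth, no neighbor cap), and counts connected
#' components. A size-1 basin has 1 component.
#'
#' @param basin a `basin`.
#' @param distances a `dist_store` covering the basin members.
#' @return integer component count.
#' @export
basin_subgraph_components <- function(basin, distances) {
  stopifnot(inherits(basin, "basin"))
  m <- basin$size
  if (m == 1) return(1L)
  sub <- ds_lookup(distances, basin$members)
  pdist <- mean(sub[upper.tri(sub)])
  eps <- pdist + 1
  adjm <- (sub <= eps)
  diag(adjm) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adjm, mode = "undirected")
  as.integer(igraph::components(g)$no)
}

#' Largest basin (the Basins-Select prediction)
#'
#' @param basins list of `basin` objects.
#' @return the basin with maximal size; ties broken by lower focal energy,
#'   then focal id.
#' @export
select_largest_basin <- function(basins) {
  if (!length(basins)) stop("empty basin list")
  order_basins(basins)[[1]]
}

#' Write a basin report (JSON + flat TSV)
#'
#' @param basins list of `basin` objects.
#' @param prefix output path prefix; writes `<prefix>-basins.json` (one
#'   record per basin) and `<prefix>-membership.tsv` (decoy id -> basin id).
#' @return invisibly, the two paths.
#' @export
write_basin_report <- function(basins, prefix) {
  recs <- lapply(basins, function(b)
    list(focal_id = b$focal_id, size = b$size,
         focal_energy = b$focal_energy, avg_energy = b$avg_energy,
         persistence = b$persistence, n_components = b$n_components,
         pareto_rank = b$pareto_rank, pareto_count = b$pareto_count,
         members = b$members))
  jp <- paste0(prefix, "-basins.json")
  jsonlite::write_json(recs, jp, auto_unbox = TRUE, digits = NA, na = "null")
  flat <- do.call(rbind, lapply(basins, function(b)
    data.frame(id = b$members, basin = b$focal_id)))
  tp <- paste0(prefix, "-membership.tsv")
  write.table(flat, tp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(jp, tp))
}
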