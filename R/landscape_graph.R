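#' Build an epsilon nearest-neighbor graph over a decoy ensemble
#'
#' Embeds the decoys in an undirected graph: vertices are decoy ids and an
#' edge joins u,v when their least RMSD d(u,v) <= epsilon. If the graph is
#' disconnected, epsilon is grown additively until it connects or the
#' iteration budget is exhausted; graph density is controlled by a cap on
#' the number of nearest neighbors kept per vertex.
#'
#' @param distances a `dist_store` over at least two decoys.
#' @param epsilon0 initial neighborhood radius in Angstroms (default 1).
#' @param max_iter maximum number of epsilon growth steps (default 10).
#' @param eps_step additive epsilon increment per growth step, in Angstroms
#'   (default 0.5).
#' @param max_nn per-vertex cap on retained nearest neighbors (default 100).
#'   An edge is kept only if it survives the cap at both endpoints, so the
#'   graph stays undirected; ties in the cap are broken by (distance, id).
#' @return an `nn_graph`: list with the igraph `graph` (edge attribute
#'   `dist`), `epsilon_used`, `connected`, and `ids`. If still disconnected
#'   after `max_iter` growth steps the graph is returned with
#'   `connected = FALSE` and a warning; downstream stages then operate per
#'   connected component.
#' @export
build_nn_graph <- function(distances, epsilon0 = 1.0, max_iter = 10,
                           eps_step = 0.5, max_nn = 100) {
  stopifnot(inherits(distances, "dist_store"))
  n <- length(distances$ids)
  if (n < 2) stop("need at least 2 decoys to build an nn-graph")

  eps <- epsilon0
  for (iter in 0:max_iter) {
    if (iter > 0) eps <- eps + eps_step
    g <- nn_graph_at_eps(distances, eps, max_nn)
    if (igraph::is_connected(g)) {
      return(structure(list(graph = g, epsilon_used = eps, connected = TRUE,
                            ids = distances$ids), class = "nn_graph"))
    }
  }
  warning("nn-graph still disconnected after ", max_iter,
          " epsilon growth steps (epsilon = ", eps,
          " A); downstream runs per component")
  structure(list(graph = g, epsilon_used = eps, connected = FALSE,
                 ids = distances$ids), class = "nn_graph")
}

# edge set at a fixed epsilon with the two-sided neighbor cap
nn_graph_at_eps <- function(distances, eps, max_nn) {
  mat <- distances$mat
  ids <- distances$ids
  n <- length(ids)
  idr <- id_rank(ids)

  # per-vertex surviving neighbor sets under the (distance, id) capped order
  keep <- vector("list", n)
  for (u in seq_len(n)) {
    nb <- which(mat[u, ] <= eps)
    nb <- nb[nb != u]
    if (length(nb) > max_nn) {
      o <- order(mat[u, nb], idr[nb], method = "radix")
      nb <- nb[o[seq_len(max_nn)]]
    }
    keep[[u]] <- nb
  }
  from <- rep.int(seq_len(n), lengths(keep))
  to <- unlist(keep, use.names = FALSE)
  if (length(from)) {
    # keep u-v once, and only if both directions survived the cap
    key <- (from - 1) * n + to
    rev <- (to - 1) * n + from
    sel <- (key %in% rev) & from < to
    from <- from[sel]; to <- to[sel]
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (length(from)) {
    g <- igraph::add_edges(g, rbind(from, to))
    g <- igraph::set_edge_attr(g, "dist", value = mat[cbind(from, to)])
  }
  g
}

# adjacency lists with aligned edge distances, indexed by vertex position
graph_adjacency <- function(graph) {
  n <- length(graph$ids)
  el <- igraph::as_edgelist(graph$graph, names = FALSE)
  if (nrow(el) == 0)
    return(list(nbr = rep(list(integer(0)), n),
                dist = rep(list(numeric(0)), n)))
  d <- igraph::edge_attr(graph$graph, "dist")
  idx <- as.integer(c(el[, 1], el[, 2]))
  nbr <- as.integer(c(el[, 2], el[, 1]))
  dd <- c(d, d)
  o <- order(idx, method = "radix")
  idx <- idx[o]; nbr <- nbr[o]; dd <- dd[o]
  f <- factor(idx, levels = seq_len(n))
  list(nbr = split(nbr, f), dist = split(dd, f))
}

#' @export
print.nn_graph <- function(x, ...) {
  cat("<nn_graph> ", length(x$ids), " vertices, ",
      igraph::ecount(x$graph), " edges; epsilon ", x$epsilon_used, " A; ",
      if (x$connected) "connected" else "disconnected", "\n", sep = "")
  invisible(x)
}

#' Export an nn-graph as edge-list TSV plus JSON header
#'
#' @param graph an `nn_graph`.
#' @param prefix output path prefix; writes `<prefix>-edges.tsv` and
#'   `<prefix>-graph.json`.
#' @return invisibly, the two paths.
#' @export
write_nn_graph <- function(graph, prefix) {
  stopifnot(inherits(graph, "nn_graph"))
  el <- igraph::as_data_frame(graph$graph, what = "edges")
  names(el) <- c("u", "v", "distance")
  edge_path <- paste0(prefix, "-edges.tsv")
  write.table(el, edge_path, sep = "\t", quote = FALSE, row.names = FALSE)
  hdr_path <- paste0(prefix, "-graph.json")
  jsonlite::write_json(list(epsilon_used = graph$epsilon_used,
                            connected = graph$connected,
                            n = length(graph$ids),
                            m = igraph::ecount(graph$graph)),
                       hdr_path, auto_unbox = TRUE, digits = NA)
  invisible(c(edge_path, hdr_path))
}
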