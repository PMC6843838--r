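#' Pareto Rank and Pareto Count of basins
#'
#' Annotates each basin with two dominance features over the (size, group
#' energy) objectives: basin a dominates basin b when
#' `size(a) >= size(b)` and `energy(a) <= energy(b)` with at least one
#' inequality strict (bigger is better for size, lower is better for
#' energy). The Pareto Rank of b is the number of basins dominating it
#' (0 = non-dominated); the Pareto Count of a is the number of basins it
#' dominates.
#'
#' @param basins list of `basin` objects.
#' @param energy_mode group energy: `"min"` (the focal energy, default) or
#'   `"avg"` (mean member energy).
#' @return the basin list with `pareto_rank` and `pareto_count` filled; the
#'   annotation table is attached as attribute `pareto` (data.frame with
#'   focal_id, size, energy, pareto_rank, pareto_count).
#' @export
pareto_annotate <- function(basins, energy_mode = c("min", "avg")) {
  energy_mode <- match.arg(energy_mode)
  if (!length(basins)) stop("need at least one basin")
  size <- vapply(basins, `[[`, numeric(1), "size")
  energy <- vapply(basins, `[[`,  numeric(1),
                   if (energy_mode == "min") "focal_energy" else "avg_energy")
  n <- length(basins)
  dom <- matrix(FALSE, n, n)           # dom[a, b]: a dominates b
  for (a in seq_len(n)) {
    ge_size <- size[a] >= size
    le_energy <- energy[a] <= energy
    strict <- size[a] > size | energy[a] < energy
    dom[a, ] <- ge_size & le_energy & strict
  }
  rank <- colSums(dom)
  count <- rowSums(dom)
  for (i in seq_len(n)) {
    basins[[i]]$pareto_rank <- as.integer(rank[i])
    basins[[i]]$pareto_count <- as.integer(count[i])
  }
  attr(basins, "pareto") <- data.frame(
    focal_id = vapply(basins, `[[`, character(1), "focal_id"),
    size = size, energy = energy,
    pareto_rank = as.integer(rank), pareto_count = as.integer(count),
    group_energy_mode = energy_mode)
  basins
}
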