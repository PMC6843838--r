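#' Least RMSD between two conformations
#'
#' Optimal-superposition root-mean-square deviation between two ordered
#' C-alpha coordinate sets: the RMSD that remains after removing rigid
#' translation and rotation, computed by the Kabsch algorithm with the
#' determinant correction that disallows reflections.
#'
#' @param A,B numeric matrices of dimension n x 3 (one row per C-alpha atom,
#'   in Angstroms), with the same n >= 3.
#' @return the least RMSD in Angstroms (non-negative scalar).
#' @details Degenerate inputs (e.g. collinear points) are handled by the
#'   proper-rotation correction: the rotation with determinant +1 closest to
#'   the unconstrained optimum is used, so a finite value is always returned.
#' @examples
#' A <- cbind(0:3, 0, 0)
#' least_rmsd(A, A)                      # 0
#' R <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3)  # 90 deg about z
#' least_rmsd(A %*% t(R) + 5, A)         # 0 up to round-off
#' @export
least_rmsd <- function(A, B) {
  A <- as_coord_matrix(A)
  B <- as_coord_matrix(B)
  if (nrow(A) != nrow(B))
    stop("coordinate sets differ in residue count (", nrow(A), " vs ",
         nrow(B), ")")
  if (nrow(A) < 3) stop("need at least 3 atoms")
  kabsch_rmsd(A, B)
}

as_coord_matrix <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) != 3) stop("coordinates must be an n x 3 matrix")
  storage.mode(x) <- "double"
  if (anyNA(x) || any(!is.finite(x))) stop("non-finite coordinates")
  x
}

# Kabsch with proper-rotation (det +1) correction, pure R reference.
kabsch_rmsd <- function(A, B) {
  n <- nrow(A)
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  H <- crossprod(Ac, Bc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  s <- sv$d
  msd <- (sum(Ac^2) + sum(Bc^2) - 2 * (s[1] + s[2] + d * s[3])) / n
  sqrt(max(msd, 0))
}

#' Pairwise least-RMSD distance store
#'
#' Computes the symmetric matrix of pairwise least RMSD values r_ij over an
#' ensemble (or a subset of it). The heavy all-pairs Kabsch loop runs in
#' compiled code. Optionally persists the matrix to a TSV cache file keyed by
#' a hash of the coordinates, so repeated runs on the same ensemble skip
#' recomputation.
#'
#' @param ensemble a [decoy_ensemble].
#' @param subset optional character vector of decoy ids.
#' @param cache_dir optional directory for the distance cache; `NULL`
#'   (default) disables caching.
#' @return a `dist_store`: list with `ids` and the symmetric matrix `mat`
#'   (dimnames = ids).
#' @export
pairwise_distances <- function(ensemble, subset = NULL, cache_dir = NULL) {
  stopifnot(inherits(ensemble, "decoy_ensemble"))
  ids <- ensemble$ids
  if (!is.null(subset)) {
    if (!all(subset %in% ids)) stop("subset contains unknown decoy ids")
    keep <- match(subset, ids)
    ids <- ids[keep]
  } else keep <- seq_along(ids)
  coords <- ensemble$coords[, , keep, drop = FALSE]

  cache_file <- NULL
  if (!is.null(cache_dir)) {
    key <- ensemble_hash(coords, ids)
    cache_file <- file.path(cache_dir, paste0("rmsd-", key, ".tsv"))
    if (file.exists(cache_file)) {
      mat <- as.matrix(read.table(cache_file, sep = "\t", header = TRUE,
                                  row.names = 1, check.names = FALSE))
      dimnames(mat) <- list(ids, ids)
      return(dist_store(mat, ids))
    }
  }

  mat <- pairwise_rmsd_cpp(coords)
  dimnames(mat) <- list(ids, ids)
  if (!is.null(cache_file)) {
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(format(mat, digits = 17), cache_file, sep = "\t",
                quote = FALSE, col.names = NA)
  }
  dist_store(mat, ids)
}

# stable content hash for the cache key (md5 of a full-precision dump)
ensemble_hash <- function(coords, ids) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(c(ids, format(c(coords), digits = 17)), f)
  unname(tools::md5sum(f))
}

#' @rdname pairwise_distances
#' @param mat symmetric numeric matrix of distances.
#' @param ids character vector of decoy ids matching `mat`'s order.
#' @export
dist_store <- function(mat, ids = rownames(mat)) {
  mat <- as.matrix(mat)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(mat)))
  stopifnot(nrow(mat) == ncol(mat), length(ids) == nrow(mat))
  if (any(mat < 0)) stop("distances must be non-negative")
  dimnames(mat) <- list(ids, ids)
  structure(list(ids = as.character(ids), mat = mat), class = "dist_store")
}

#' @export
print.dist_store <- function(x, ...) {
  cat("<dist_store> ", length(x$ids), " decoys, mean pairwise ",
      signif(mean(x$mat[upper.tri(x$mat)]), 4), " A\n", sep = "")
  invisible(x)
}

ds_lookup <- function(store, ids) {
  store$mat[ids, ids, drop = FALSE]
}
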