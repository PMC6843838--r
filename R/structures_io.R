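#' Decoy ensemble container
#'
#' Holds the decoy set Omega for one target: per-decoy C-alpha coordinates,
#' Rosetta-style total energies (lower is better), optional knowledge-based
#' potential feature columns, optional true RMSD to the native structure, and
#' optionally the native structure itself.
#'
#' @param target_id character scalar.
#' @param ids character vector of unique decoy ids.
#' @param coords numeric array `n_res x 3 x n_decoys` of C-alpha positions in
#'   Angstroms (all decoys share the residue count).
#' @param energy numeric vector of finite per-decoy energies.
#' @param potentials optional numeric matrix `n_decoys x p` of feature
#'   columns (pluggable stand-ins for knowledge-based potentials).
#' @param true_rmsd optional numeric vector of least RMSD to the native, in
#'   Angstroms (evaluation only).
#' @param native optional `n_res x 3` matrix of native C-alpha coordinates.
#' @return an object of class `decoy_ensemble`.
#' @export
decoy_ensemble <- function(target_id, ids, coords, energy, potentials = NULL,
                           true_rmsd = NULL, native = NULL) {
  ids <- as.character(ids)
  n <- length(ids)
  if (anyDuplicated(ids)) stop("decoy ids must be unique")
  if (length(dim(coords)) != 3 || dim(coords)[2] != 3 || dim(coords)[3] != n)
    stop("coords must be an n_res x 3 x n_decoys array")
  if (dim(coords)[1] < 3) stop("decoys need at least 3 residues")
  if (length(energy) != n || any(!is.finite(energy)))
    stop("energy must be a finite vector with one value per decoy")
  if (!is.null(potentials)) {
    potentials <- as.matrix(potentials)
    if (nrow(potentials) != n) stop("potentials must have one row per decoy")
  }
  if (!is.null(native)) {
    native <- as_coord_matrix(native)
    if (nrow(native) != dim(coords)[1])
      stop("native residue count differs from the decoys")
  }
  obj <- structure(list(
    target_id = as.character(target_id), ids = ids, coords = coords,
    energy = as.numeric(energy), potentials = potentials,
    true_rmsd = if (is.null(true_rmsd)) NULL else as.numeric(true_rmsd),
    native = native, min_dist = NULL), class = "decoy_ensemble")
  if (!is.null(native)) {
    if (is.null(obj$true_rmsd))
      obj$true_rmsd <- as.numeric(rmsd_to_ref_cpp(coords, native))
    obj$min_dist <- min(obj$true_rmsd)
  }
  obj
}

#' @export
print.decoy_ensemble <- function(x, ...) {
  cat("<decoy_ensemble> target ", x$target_id, ": ", length(x$ids),
      " decoys x ", dim(x$coords)[1], " residues", sep = "")
  if (!is.null(x$min_dist)) cat("; min_dist ", round(x$min_dist, 3), " A",
                                sep = "")
  if (!is.null(x$potentials)) cat("; ", ncol(x$potentials),
                                  " potential features", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
length.decoy_ensemble <- function(x) length(x$ids)

#' Read a decoy ensemble from PDB files and a score table
#'
#' Matches PDB structure files to rows of a score table by decoy id (the file
#' basename without extension) and assembles a [decoy_ensemble]. Only
#' C-alpha atoms of the first model are used; ids present in only one of the
#' two sources are reported in a warning and dropped.
#'
#' @param structure_files character vector of PDB file paths.
#' @param score_table path to a tab- or comma-separated table with a header;
#'   required columns `id` and `energy`. Any further numeric columns become
#'   the `potentials` matrix, in header order.
#' @param native_file optional PDB path for the native structure.
#' @param target_id target name; default basename of the score table.
#' @return a [decoy_ensemble] with decoys in score-table order.
#' @export
read_decoy_set <- function(structure_files, score_table,
                           native_file = NULL,
                           target_id = tools::file_path_sans_ext(
                             basename(score_table))) {
  tab <- read_score_table(score_table)
  file_ids <- tools::file_path_sans_ext(basename(structure_files))
  names(structure_files) <- file_ids

  common <- intersect(tab$id, file_ids)
  dropped <- union(setdiff(tab$id, file_ids), setdiff(file_ids, tab$id))
  if (length(dropped))
    warning("dropping ", length(dropped),
            " id(s) present in only one source: ",
            paste(sort(dropped), collapse = ", "))
  if (!length(common)) stop("no decoy ids shared by structures and table")
  tab <- tab[tab$id %in% common, , drop = FALSE]   # score-table order

  coord_list <- lapply(tab$id, function(id) read_ca_coords(structure_files[[id]]))
  nres <- vapply(coord_list, nrow, integer(1))
  if (length(unique(nres)) > 1) {
    bad <- tab$id[nres != nres[1]][1]
    stop("residue count mismatch across decoys (file for id '", bad,
         "' has ", nres[tab$id == bad][1], " C-alpha atoms, first decoy has ",
         nres[1], ")")
  }
  coords <- array(unlist(coord_list), dim = c(nres[1], 3, nrow(tab)))

  native <- if (!is.null(native_file)) read_ca_coords(native_file) else NULL
  pot_cols <- setdiff(names(tab), c("id", "energy"))
  potentials <- if (length(pot_cols))
    as.matrix(tab[, pot_cols, drop = FALSE]) else NULL
  decoy_ensemble(target_id, tab$id, coords, tab$energy,
                 potentials = potentials, native = native)
}

read_score_table <- function(path) {
  if (!file.exists(path)) stop("score table not found: ", path)
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- read.table(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
  if (!all(c("id", "energy") %in% names(tab)))
    stop("score table must have 'id' and 'energy' columns: ", path)
  if (any(!is.finite(tab$energy))) stop("non-finite energies in ", path)
  tab$id <- as.character(tab$id)
  keep <- c("id", "energy",
            names(tab)[!(names(tab) %in% c("id", "energy")) &
                         vapply(tab, is.numeric, logical(1))])
  tab[, keep, drop = FALSE]
}

# C-alpha coordinates of the first model of a PDB file, via bio3d
read_ca_coords <- function(path) {
  if (!file.exists(path)) stop("structure file not found: ", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
  sel <- bio3d::atom.select(pdb, elety = "CA", verbose = FALSE)
  if (!length(sel$xyz)) stop("no CA atoms in ", path)
  if (any(nzchar(pdb$atom$insert[sel$atom]) & !is.na(pdb$atom$insert[sel$atom])))
    warning("insertion codes ignored in ", path)
  matrix(pdb$xyz[1, sel$xyz], ncol = 3, byrow = TRUE)
}

#' Write a decoy ensemble to PDB files and a score table
#'
#' Inverse of [read_decoy_set()]: one C-alpha-trace PDB per decoy (id.pdb),
#' a `scores.tsv` with `id`, `energy` and any potential columns, and, when
#' ground truth is present, `native.pdb` plus a `truth.tsv` with per-decoy
#' true RMSD.
#'
#' @param ensemble a [decoy_ensemble].
#' @param dir output directory (created if needed).
#' @return invisibly, the path to the score table.
#' @export
write_decoy_set <- function(ensemble, dir) {
  stopifnot(inherits(ensemble, "decoy_ensemble"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(ensemble$ids))
    write_ca_pdb(ensemble$coords[, , i],
                 file.path(dir, paste0(ensemble$ids[i], ".pdb")))
  tab <- data.frame(id = ensemble$ids, energy = ensemble$energy,
                    check.names = FALSE)
  if (!is.null(ensemble$potentials)) {
    pot <- as.data.frame(ensemble$potentials)
    if (is.null(colnames(ensemble$potentials)))
      names(pot) <- paste0("pot", seq_len(ncol(pot)))
    tab <- cbind(tab, pot)
  }
  score_path <- file.path(dir, "scores.tsv")
  write.table(tab, score_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(ensemble$native))
    write_ca_pdb(ensemble$native, file.path(dir, "native.pdb"))
  if (!is.null(ensemble$true_rmsd))
    write.table(data.frame(id = ensemble$ids, true_rmsd = ensemble$true_rmsd),
                file.path(dir, "truth.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(score_path)
}

write_ca_pdb <- function(coords, path) {
  coords <- as_coord_matrix(coords)
  n <- nrow(coords)
  bio3d::write.pdb(file = path, xyz = as.numeric(t(coords)),
                   type = rep("ATOM", n), resno = seq_len(n),
                   resid = rep("ALA", n), elety = rep("CA", n),
                   chain = rep("A", n))
  invisible(path)
}
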