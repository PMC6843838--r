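#' Simulation specification for synthetic decoy ensembles
#'
#' Collects the knobs of the seeded generator: ensemble size, chain length,
#' the target minimum decoy-to-native RMSD, the fraction of near-native
#' decoys, the ruggedness of the energy surface (number of planted false
#' minima, funnel slope, energy noise), and the pseudo-potential feature
#' columns that stand in for knowledge-based potentials.
#'
#' @param n_decoys number of decoys (default 2000).
#' @param n_residues chain length in C-alpha atoms (default 40).
#' @param min_dist target minimum RMSD to the native, in Angstroms
#'   (default 0.6).
#' @param near_native_fraction expected fraction of decoys under the
#'   near-native threshold (default 0.3).
#' @param n_false_minima planted deceptive low-energy wells centered at
#'   non-native decoys (default 3).
#' @param funnel_strength energy-funnel slope in energy units per Angstrom
#'   of true RMSD (default 1).
#' @param energy_noise_sd standard deviation of additive energy noise
#'   (default 0.25).
#' @param feature_noise_sd noise on the pseudo-potential columns, in
#'   Angstrom-equivalents (default 0.5).
#' @param n_pseudo_potentials number of feature columns (default 20; the
#'   last few columns are pure noise so downstream regressors must select
#'   features implicitly).
#' @param seed mandatory integer seed.
#' @return a `sim_spec` list.
#' @export
sim_spec <- function(n_decoys = 2000, n_residues = 40, min_dist = 0.6,
                     near_native_fraction = 0.3, n_false_minima = 3,
                     funnel_strength = 1, energy_noise_sd = 0.25,
                     feature_noise_sd = 0.5, n_pseudo_potentials = 20,
                     seed) {
  if (missing(seed)) stop("sim_spec requires an explicit seed")
  stopifnot(n_decoys >= 2, n_residues >= 3, min_dist >= 0,
            near_native_fraction >= 0, near_native_fraction <= 1,
            n_false_minima >= 0, energy_noise_sd >= 0, feature_noise_sd >= 0,
            n_pseudo_potentials >= 1)
  structure(as.list(environment()), class = "sim_spec")
}

# difficulty-consistent near-native threshold implied by a target min_dist
implied_dist_thresh <- function(min_dist) {
  if (min_dist < 1) 2.0
  else if (min_dist < 3) 2.5
  else ceiling((min_dist + 1) / 0.5) * 0.5
}

#' Simulate a synthetic decoy ensemble
#'
#' Generates a native structure as a self-avoiding random C-alpha walk with
#' 3.8-Angstrom virtual bonds, then decoys emulating template-free sampling
#' on a rugged funnel landscape:
#' \itemize{
#'   \item a near-native component (mass = `near_native_fraction`) of
#'     perturbed natives with RMSDs between `min_dist` and just under the
#'     difficulty-implied `dist_thresh`;
#'   \item `n_false_minima` deceptive attractors — non-native reference
#'     conformations in the far RMSD band around which most far decoys
#'     concentrate as tight conformational clusters (cluster radius 0.3-1.5
#'     Angstrom, random multinomial cluster sizes), emulating sampling that
#'     pools in false minima of an overly rugged landscape;
#'   \item a diffuse far component of scattered perturbed natives.
#' }
#' Energies follow a funnel increasing in true RMSD plus Gaussian energy
#' wells centered at the false-minimum conformations (so the deceptive
#' clusters are also low-energy) plus noise. Pseudo-potential columns are
#' fixed linear maps of true RMSD with additive noise; the last quarter of
#' the columns is pure noise.
#'
#' @param spec a [sim_spec].
#' @return a [decoy_ensemble] with native, true RMSDs, potentials, and the
#'   realized `min_dist`; the implied threshold is attached as attribute
#'   `dist_thresh`.
#' @export
simulate_ensemble <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  native <- sa_walk(spec$n_residues)
  thresh <- implied_dist_thresh(spec$min_dist)

  n <- spec$n_decoys
  near <- runif(n) < spec$near_native_fraction
  far_lo <- thresh * 1.15 + 0.5
  far_hi <- thresh + 10

  # false-minimum attractor conformations in the far band
  n_fm <- spec$n_false_minima
  fm_centers <- vector("list", n_fm)
  if (n_fm > 0) {
    fm_rmsd <- runif(n_fm, far_lo + 1, far_hi - 1)
    for (w in seq_len(n_fm))
      fm_centers[[w]] <- perturb_to_rmsd(native, fm_rmsd[w])$coords
    fm_weights <- stats::rgamma(n_fm, 1)
    fm_weights <- fm_weights / sum(fm_weights)
  }

  # far decoys: 70% pooled in the attractor clusters, the rest diffuse
  cluster_of <- rep(0L, n)
  far_idx <- which(!near)
  if (n_fm > 0 && length(far_idx)) {
    pooled <- far_idx[runif(length(far_idx)) < 0.7]
    cluster_of[pooled] <- sample.int(n_fm, length(pooled), replace = TRUE,
                                     prob = fm_weights)
  }

  target <- numeric(n)
  target[near] <- runif(sum(near), spec$min_dist, thresh * 0.95)
  diffuse <- !near & cluster_of == 0L
  target[diffuse] <- far_lo + (far_hi - far_lo) *
    stats::rbeta(sum(diffuse), 1.3, 1.3)
  if (any(near)) target[which(near)[1]] <- spec$min_dist

  coords <- array(0, dim = c(spec$n_residues, 3, n))
  for (i in seq_len(n)) {
    if (cluster_of[i] > 0L) {
      coords[, , i] <- perturb_to_rmsd(fm_centers[[cluster_of[i]]],
                                       runif(1, 0.3, 1.5))$coords
    } else {
      coords[, , i] <- perturb_to_rmsd(native, target[i])$coords
    }
  }
  true_rmsd <- as.numeric(rmsd_to_ref_cpp(coords, native))
  if (any(near) && abs(min(true_rmsd) - spec$min_dist) > 0.25)
    stop("unreachable target min_dist (realized ",
         round(min(true_rmsd), 3), ")")

  energy <- spec$funnel_strength * true_rmsd
  if (n_fm > 0) {
    # deep enough to dent the local funnel (cluster radius 1.5 A), shallow
    # enough that false bottoms only occasionally undercut the native basin
    depth <- 2 * spec$funnel_strength
    width <- 1.5
    for (w in seq_len(n_fm)) {
      d <- as.numeric(rmsd_to_ref_cpp(coords, fm_centers[[w]]))
      energy <- energy - depth * exp(-d^2 / (2 * width^2))
    }
  }
  energy <- energy + rnorm(n, 0, spec$energy_noise_sd)

  # pseudo-potential columns: fixed (ensemble-independent) linear maps of
  # true RMSD plus noise, like real knowledge-based potentials, which are
  # the same functions for every target; the last quarter is pure noise
  p <- spec$n_pseudo_potentials
  n_noise <- max(0L, as.integer(floor(p / 4)))
  n_info <- p - n_noise
  pot <- matrix(0, n, p)
  for (j in seq_len(p)) {
    if (j > n_info) {
      pot[, j] <- rnorm(n)
    } else {
      a <- (-1)^j * (0.5 + 1.5 * (j - 1) / max(1, n_info - 1))
      b <- 0.3 * j
      pot[, j] <- a * true_rmsd + b + rnorm(n, 0, spec$feature_noise_sd)
    }
  }
  colnames(pot) <- sprintf("pot%02d", seq_len(p))

  ids <- sprintf("d%05d", seq_len(n))
  ens <- decoy_ensemble(sprintf("sim%08d", spec$seed), ids, coords, energy,
                        potentials = pot, true_rmsd = true_rmsd,
                        native = native)
  attr(ens, "dist_thresh") <- thresh
  attr(ens, "sim_spec") <- spec
  ens
}

# self-avoiding random walk with 3.8 A virtual bonds and soft angle memory
sa_walk <- function(n_res, bond = 3.8, min_sep = 3.5) {
  xyz <- matrix(0, n_res, 3)
  dir <- c(1, 0, 0)
  for (i in 2:n_res) {
    for (try in 1:60) {
      prop <- dir + rnorm(3, 0, 0.8)
      prop <- prop / sqrt(sum(prop^2))
      cand <- xyz[i - 1, ] + bond * prop
      if (i <= 3) break
      d2 <- rowSums(sweep(xyz[1:(i - 2), , drop = FALSE], 2, cand)^2)
      if (min(d2) >= min_sep^2) break
    }
    xyz[i, ] <- xyz[i - 1, ] + bond * prop
    dir <- prop
  }
  xyz
}

# Gaussian Cartesian perturbation rescaled so the least RMSD to `ref` hits
# `target` (two secant refinements; the map is near-linear in the scale)
perturb_to_rmsd <- function(ref, target) {
  n <- nrow(ref)
  D <- matrix(rnorm(3 * n), n, 3)
  if (target <= 0) return(list(coords = ref, rmsd = 0))
  c1 <- target / sqrt(mean(rowSums(D^2)))
  r1 <- kabsch_rmsd(ref + c1 * D, ref)
  c2 <- c1 * target / max(r1, 1e-9)
  r2 <- kabsch_rmsd(ref + c2 * D, ref)
  c3 <- c2 * target / max(r2, 1e-9)
  list(coords = ref + c3 * D, rmsd = kabsch_rmsd(ref + c3 * D, ref))
}

#' Simulate an abstract planted-basin landscape
#'
#' Fast fixture without molecular geometry: points in low-dimensional
#' Euclidean space drawn around m well centers, with energies quadratic in
#' the distance from the well center plus per-well depth offsets and noise.
#' Distances are plain Euclidean; planted well labels are exported for
#' recovery tests (e.g. adjusted Rand index against basin membership).
#'
#' @param n_points total number of points (default 400).
#' @param m number of planted wells (default 5).
#' @param dim Euclidean dimension (default 2).
#' @param well_sd within-well point spread (default 0.35).
#' @param separation distance scale between well centers (default 6).
#' @param depths optional numeric vector (length m) of well depths in energy
#'   units; default equally spaced in [4, 6].
#' @param energy_noise_sd additive energy noise (default 0.05).
#' @param seed mandatory integer seed.
#' @return list with `ids`, `points`, `energy` (named), `labels` (planted
#'   well of each point), `distances` (a `dist_store`), and `centers`.
#' @export
simulate_abstract <- function(n_points = 400, m = 5, dim = 2,
                              well_sd = 0.35, separation = 6,
                              depths = NULL, energy_noise_sd = 0.05, seed) {
  if (missing(seed)) stop("simulate_abstract requires an explicit seed")
  set.seed(seed)
  if (is.null(depths)) depths <- seq(4, 6, length.out = m)
  stopifnot(length(depths) == m)
  # well centers placed by rejection so wells stay well separated
  centers <- matrix(0, m, dim)
  if (m > 1) {
    min_gap <- separation / 2
    for (i in 2:m) {
      for (try in 1:500) {
        cand <- rnorm(dim, 0, separation)
        if (min(sqrt(rowSums(sweep(centers[1:(i - 1), , drop = FALSE], 2,
                                   cand)^2))) >= min_gap) break
      }
      centers[i, ] <- cand
    }
  }
  lab <- sort(rep_len(seq_len(m), n_points))
  pts <- centers[lab, , drop = FALSE] +
    matrix(rnorm(n_points * dim, 0, well_sd), n_points, dim)
  dcen <- sqrt(rowSums((pts - centers[lab, , drop = FALSE])^2))
  energy <- -depths[lab] + 2 * dcen^2 + rnorm(n_points, 0, energy_noise_sd)
  ids <- sprintf("p%04d", seq_len(n_points))
  dmat <- as.matrix(stats::dist(pts))
  dimnames(dmat) <- list(ids, ids)
  list(ids = ids, points = pts, energy = stats::setNames(energy, ids),
       labels = stats::setNames(lab, ids), distances = dist_store(dmat, ids),
       centers = centers)
}
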