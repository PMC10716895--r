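# Deterministic generators for every fixture the engine needs: a toy pocket
# receptor, active/decoy ligand sets with calibrated well depths, harmonic
# trajectories with analytically known covariance, and Gaussian delta-U
# samples. All generators are pure functions of their seed and parameters.

#' Toy pocket receptor
#'
#' A rigid cage of ~20 carbon atoms on a sphere with an opening at +z, forming
#' a concave binding site around the origin, with a `search_box` attribute
#' covering the pocket. Deterministic per seed (the seed adds a small
#' coordinate jitter so distinct seeds give distinct cages).
#'
#' @param seed integer seed.
#' @param radius cage radius in A.
#' @param n_cage number of cage atoms before the opening is cut.
#' @return A `molecular_system` with a `search_box` attribute.
#' @export
make_pocket_receptor <- function(seed = 1, radius = 5, n_cage = 26) {
  pts <- .sphere_points(n_cage) * radius
  pts <- pts[pts[, 3] < 0.55 * radius, , drop = FALSE]   # opening at +z
  pts <- with_seed(seed, pts + matrix(stats::rnorm(length(pts), sd = 0.05),
                                      nrow(pts), 3))
  sys <- molecular_system(
    data.frame(element = "C", x = pts[, 1], y = pts[, 2], z = pts[, 3],
               charge = 0, lj_radius = 1.7, lj_epsilon = 0.15,
               mass = 12.011, gb_radius = 1.7, role = "receptor",
               stringsAsFactors = FALSE),
    name = sprintf("pocket_%d", seed))
  sys <- assign_dock_types(sys)
  attr(sys, "search_box") <- search_box(c(0, 0, 0), c(3, 3, 3))
  sys
}

#' Specification of a toy active/decoy screening set
#'
#' @param n_active,n_decoy ligand counts (>= 0).
#' @param active_well_depth,decoy_well_depth pocket interaction minima in
#'   kcal/mol; actives must be deeper (more negative).
#' @param seed integer seed.
#' @return A `toy_screen_spec` object.
#' @export
toy_screen_spec <- function(n_active = 3, n_decoy = 17,
                            active_well_depth = -8, decoy_well_depth = -2,
                            seed = 1) {
  if (n_active < 0 || n_decoy < 0) stop("counts must be non-negative")
  if (active_well_depth >= decoy_well_depth)
    stop("active wells must be deeper (more negative) than decoy wells")
  structure(list(n_active = n_active, n_decoy = n_decoy,
                 active_well_depth = active_well_depth,
                 decoy_well_depth = decoy_well_depth, seed = seed),
            class = "toy_screen_spec")
}

# compact random carbon cluster, spacing ~1.3 A. The cluster is bonded as a
# complete graph: every atom pair is a harmonic bond, which makes the toy
# ligand an elastically rigid body and removes all intra-ligand nonbonded
# pairs (they are 1-2 exclusions), so the calibrated LJ epsilons act purely
# intermolecularly.
.make_toy_ligand <- function(n_atoms, name) {
  xyz <- matrix(0, n_atoms, 3)
  if (n_atoms > 1L) {
    for (i in 2:n_atoms) {
      repeat {
        dirn <- stats::rnorm(3); dirn <- dirn / sqrt(sum(dirn^2))
        cand <- xyz[i - 1L, ] + 1.3 * dirn
        dmin <- min(sqrt(rowSums(sweep(xyz[seq_len(i - 1L), , drop = FALSE],
                                       2, cand)^2)))
        if (dmin > 1.1 && sqrt(sum(cand^2)) < 2.2) { xyz[i, ] <- cand; break }
      }
    }
    xyz <- sweep(xyz, 2, colMeans(xyz))
  }
  bonds <- if (n_atoms > 1L) t(utils::combn(n_atoms, 2L)) else NULL
  molecular_system(
    data.frame(element = "C", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               charge = 0, lj_radius = 1.2, lj_epsilon = 0.1, mass = 12.011,
               gb_radius = 1.2, role = "ligand", stringsAsFactors = FALSE),
    bonds, name = name)
}

#' Pocket interaction energy scan along the pocket axis
#'
#' Rigidly translates the ligand along +z through the pocket of `receptor`
#' and evaluates the intermolecular LJ + Coulomb energy at each offset.
#'
#' @param ligand,receptor `molecular_system`s; the ligand is scanned from its
#'   current placement.
#' @param offsets numeric vector of z offsets (A).
#' @return data.frame with `offset` and `energy` (kcal/mol).
#' @export
pocket_energy_scan <- function(ligand, receptor, offsets = seq(0, 6, by = 0.1)) {
  lx <- coords(ligand); rx <- coords(receptor)
  la <- ligand$atoms; ra <- receptor$atoms
  rmin <- outer(la$lj_radius, ra$lj_radius, "+")
  eps <- sqrt(outer(la$lj_epsilon, ra$lj_epsilon))
  qq <- .ls_const$k_e * outer(la$charge, ra$charge)
  energy <- vapply(offsets, function(dz) {
    xyz <- sweep(lx, 2, c(0, 0, dz), "+")
    d <- sqrt(pmax(outer(rowSums(xyz^2), rowSums(rx^2), "+") -
                     2 * xyz %*% t(rx), 0))
    x6 <- (rmin / d)^6
    sum(eps * (x6^2 - 2 * x6)) + sum(qq / d)
  }, numeric(1))
  data.frame(offset = offsets, energy = energy)
}

#' Generate a labeled active/decoy ligand set
#'
#' Small rigid carbon-cluster ligands whose LJ parameters are calibrated so
#' that a rigid translation scan through the pocket reaches the requested well
#' depth: actives are larger (6-8 atoms) with deep wells, decoys smaller (3-5
#' atoms) with shallow wells. Labels are returned alongside the systems.
#' Deterministic per spec seed.
#'
#' @param spec a [toy_screen_spec()].
#' @param receptor the pocket receptor the well depths are calibrated against.
#' @return List with `systems` (named list of `molecular_system`s) and
#'   `labels` (named character vector, "active"/"decoy").
#' @export
make_ligand_set <- function(spec, receptor = make_pocket_receptor(spec$seed)) {
  stopifnot(inherits(spec, "toy_screen_spec"))
  build <- function(idx, label, depth) {
    id <- sprintf("%s%02d", if (label == "active") "ACT" else "DEC", idx)
    n_at <- if (label == "active") sample(6:8, 1) else sample(3:5, 1)
    lig <- .make_toy_ligand(n_at, id)
    scan <- pocket_energy_scan(lig, receptor)
    emin <- min(scan$energy)
    if (emin >= 0) stop("toy ligand has no attractive well; geometry degenerate")
    lig$atoms$lj_epsilon <- lig$atoms$lj_epsilon * (depth / emin)^2
    lig
  }
  with_seed(spec$seed, {
    systems <- c(
      lapply(seq_len(spec$n_active), build, label = "active",
             depth = spec$active_well_depth),
      lapply(seq_len(spec$n_decoy), build, label = "decoy",
             depth = spec$decoy_well_depth))
    labels <- c(rep("active", spec$n_active), rep("decoy", spec$n_decoy))
    ids <- vapply(systems, function(s) s$name, character(1))
    names(systems) <- ids; names(labels) <- ids
    list(systems = systems, labels = labels)
  })
}

#' Harmonic toy trajectory with known covariance
#'
#' Frames are independent draws from the exact Boltzmann distribution of
#' independent harmonic modes, one per Cartesian coordinate, centred on the
#' system's current coordinates: each coordinate fluctuates with variance
#' k_B T / k. This provides ensembles whose covariance (and hence
#' quasiharmonic spectrum) is known analytically.
#'
#' @param system a `molecular_system` (its coordinates are the means).
#' @param k mode force constants, kcal mol^-1 A^-2; scalar or length 3N, all
#'   positive.
#' @param temperature temperature in K.
#' @param n_frames number of frames (>= 1).
#' @param seed integer seed.
#' @return A `trajectory`.
#' @export
harmonic_trajectory <- function(system, k, temperature = 300, n_frames = 100,
                                seed = 1) {
  n <- n_atoms(system)
  k <- rep_len(k, 3L * n)
  if (any(k <= 0)) stop("mode force constants must be positive")
  sdv <- sqrt(.ls_const$k_B * temperature / k)
  mu <- as.vector(t(coords(system)))
  frames <- with_seed(seed, lapply(seq_len(n_frames), function(i)
    matrix(mu + stats::rnorm(3L * n, sd = sdv), ncol = 3L, byrow = TRUE)))
  trajectory(system, frames, temperature)
}

#' Seeded Gaussian delta-U samples
#'
#' @param mu mean (kcal/mol).
#' @param sigma standard deviation (>= 0).
#' @param n sample count (>= 1).
#' @param seed integer seed.
#' @return Numeric vector of n draws.
#' @export
gaussian_du <- function(mu, sigma, n, seed = 1) {
  if (sigma < 0) stop("sigma must be non-negative")
  if (n < 1) stop("need at least one sample")
  with_seed(seed, stats::rnorm(n, mean = mu, sd = sigma))
}
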