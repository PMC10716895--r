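# Empirical pairwise docking score (two steric Gaussians, quadratic clash
# repulsion, piecewise-linear hydrophobic and hydrogen-bond terms over the
# surface distance between atom pairs) and a rigid-body iterated-local-search
# pose optimizer confined to a rectangular search box.

#' Docking search box
#' @param center numeric length-3, box center (A).
#' @param half_lengths numeric length-3, positive half-extents (A).
#' @return A `search_box` object.
#' @export
search_box <- function(center, half_lengths) {
  center <- as.numeric(center); half_lengths <- as.numeric(half_lengths)
  stopifnot(length(center) == 3L, length(half_lengths) == 3L)
  if (any(half_lengths <= 0)) stop("box half-lengths must be positive")
  structure(list(center = center, half_lengths = half_lengths),
            class = "search_box")
}

#' Default empirical scoring weights
#'
#' Weighted sum of two attractive Gaussians of the surface distance, a
#' quadratic penetration penalty, a hydrophobic contact term and a
#' hydrogen-bond term; interactions beyond `cutoff` (surface distance, A)
#' contribute nothing. All weights are dimensionless multipliers producing a
#' kcal/mol-scaled score.
#'
#' @param w_gauss1,w_gauss2,w_repulsion,w_hydrophobic,w_hbond term weights.
#' @param cutoff surface-distance cutoff in A.
#' @return A named list of class `dock_weights`.
#' @export
dock_weights <- function(w_gauss1 = -0.0356, w_gauss2 = -0.00516,
                         w_repulsion = 0.840, w_hydrophobic = -0.0351,
                         w_hbond = -0.587, cutoff = 8) {
  if (cutoff <= 0) stop("cutoff must be positive")
  structure(list(w_gauss1 = w_gauss1, w_gauss2 = w_gauss2,
                 w_repulsion = w_repulsion, w_hydrophobic = w_hydrophobic,
                 w_hbond = w_hbond, cutoff = cutoff), class = "dock_weights")
}

#' Surface distance between two atoms
#'
#' The pairwise score terms act on the surface distance
#' `d = r - radius1 - radius2`, i.e. the gap between the van der Waals
#' surfaces (negative when the atoms interpenetrate).
#'
#' @param r center-center distance (A), non-negative.
#' @param t1_radius,t2_radius atom radii (A).
#' @return Surface distance in A (may be negative).
#' @export
surface_distance <- function(r, t1_radius, t2_radius) {
  if (any(r < 0)) stop("distance r must be non-negative")
  r - t1_radius - t2_radius
}

# raw (unweighted) term values at surface distance d; vectorized over d
.dock_terms_raw <- function(d) {
  list(
    gauss1      = exp(-(d / 0.5)^2),
    gauss2      = exp(-((d - 3) / 2)^2),
    repulsion   = ifelse(d < 0, d^2, 0),
    hydrophobic = pmin(1, pmax(0, (1.5 - d))),    # 1 for d<=0.5, 0 for d>=1.5
    hbond       = pmin(1, pmax(0, -d / 0.7))      # 1 for d<=-0.7, 0 for d>=0
  )
}

.is_hydrophobic_pair <- function(t1, t2)
  t1 == "carbon_hydrophobic" & t2 == "carbon_hydrophobic"

.is_hbond_pair <- function(t1, t2) {
  don <- c("polar_donor", "donor_acceptor")
  acc <- c("polar_acceptor", "donor_acceptor")
  (t1 %in% don & t2 %in% acc) | (t2 %in% don & t1 %in% acc)
}

#' Pairwise score contribution of one atom pair
#'
#' @param d surface distance (A); vectorized.
#' @param types character length-2 (or 2-column matrix matching `d`) of dock
#'   types for the pair.
#' @param weights a [dock_weights()] object.
#' @return Weighted score contribution(s); zero beyond the cutoff.
#' @export
pair_term <- function(d, types, weights = dock_weights()) {
  if (is.matrix(types)) { t1 <- types[, 1]; t2 <- types[, 2] }
  else { t1 <- types[1]; t2 <- types[2] }
  tm <- .dock_terms_raw(d)
  val <- weights$w_gauss1 * tm$gauss1 + weights$w_gauss2 * tm$gauss2 +
    weights$w_repulsion * tm$repulsion +
    weights$w_hydrophobic * tm$hydrophobic * .is_hydrophobic_pair(t1, t2) +
    weights$w_hbond * tm$hbond * .is_hbond_pair(t1, t2)
  ifelse(d > weights$cutoff, 0, val)
}

## ------------------------------------------------------------- poses ------

.quat_normalize <- function(q) q / sqrt(sum(q^2))

.quat_to_matrix <- function(q) {
  q <- .quat_normalize(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

.rotvec_to_quat <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-12) return(c(1, 0, 0, 0))
  c(cos(th / 2), sin(th / 2) * v / th)
}

#' Rigid-body pose of a ligand
#'
#' A pose rotates the ligand about its own centroid by a unit quaternion and
#' then translates the centroid.
#'
#' @param translation numeric length-3 (A).
#' @param rotation unit quaternion (w, x, y, z).
#' @return A `pose` object (score and term breakdown empty until scored).
#' @export
pose <- function(translation = c(0, 0, 0), rotation = c(1, 0, 0, 0)) {
  translation <- as.numeric(translation); rotation <- as.numeric(rotation)
  stopifnot(length(translation) == 3L, length(rotation) == 4L)
  nrm <- sqrt(sum(rotation^2))
  if (abs(nrm - 1) > 1e-9) stop("pose rotation must be a unit quaternion")
  structure(list(translation = translation, rotation = rotation,
                 score = NA_real_, term_breakdown = NULL), class = "pose")
}

#' Apply a pose to a ligand
#' @param ligand a `molecular_system`.
#' @param pose a [pose()].
#' @return The ligand with transformed coordinates.
#' @export
apply_pose <- function(ligand, pose) {
  xyz <- coords(ligand)
  cen <- colMeans(xyz)
  R <- .quat_to_matrix(pose$rotation)
  new <- sweep(sweep(xyz, 2, cen) %*% t(R), 2, cen + pose$translation, "+")
  set_coords(ligand, new)
}

#' Score a rigid ligand pose against a receptor
#'
#' Sums the pairwise empirical term over all intermolecular atom pairs within
#' the surface-distance cutoff. Intraligand pairs are excluded: rigid-body
#' moves leave them fixed. The returned pose carries the score and the raw
#' (unweighted) per-term sums; the score equals the weighted sum of the
#' breakdown.
#'
#' @param ligand,receptor `molecular_system`s with dock types assigned.
#' @param pose a [pose()].
#' @param weights a [dock_weights()].
#' @return The pose with `score` and `term_breakdown` filled.
#' @export
score_pose <- function(ligand, receptor, pose = NULL, weights = dock_weights()) {
  if (is.null(pose)) pose <- ligscreen::pose()
  for (s in list(ligand, receptor))
    if (anyNA(s$atoms$dock_type))
      stop("dock types not assigned; call assign_dock_types() first")
  lig <- apply_pose(ligand, pose)
  lx <- coords(lig); rx <- coords(receptor)
  # pair distances: n_lig x n_rec
  d2 <- outer(rowSums(lx^2), rowSums(rx^2), "+") - 2 * lx %*% t(rx)
  r <- sqrt(pmax(d2, 0))
  d <- r - outer(lig$atoms$lj_radius, receptor$atoms$lj_radius, "+")
  within <- d <= weights$cutoff
  tm <- .dock_terms_raw(d)
  t1 <- matrix(lig$atoms$dock_type, nrow(d), ncol(d))
  t2 <- matrix(receptor$atoms$dock_type, nrow(d), ncol(d), byrow = TRUE)
  hyd <- .is_hydrophobic_pair(t1, t2)
  hbd <- matrix(.is_hbond_pair(as.vector(t1), as.vector(t2)), nrow(d))
  breakdown <- c(
    gauss1      = sum(tm$gauss1[within]),
    gauss2      = sum(tm$gauss2[within]),
    repulsion   = sum(tm$repulsion[within]),
    hydrophobic = sum((tm$hydrophobic * hyd)[within]),
    hbond       = sum((tm$hbond * hbd)[within])
  )
  w <- c(weights$w_gauss1, weights$w_gauss2, weights$w_repulsion,
         weights$w_hydrophobic, weights$w_hbond)
  pose$score <- sum(w * breakdown)
  pose$term_breakdown <- breakdown
  pose
}

#' Optimize a ligand pose by iterated local search
#'
#' Starting from the supplied pose (default: ligand as placed), a
#' derivative-free simplex local minimization over the six rigid-body degrees
#' of freedom is followed by `n_restarts` rounds of random rigid perturbation
#' plus re-minimization, accepting a round only when it improves the score.
#' The ligand centroid is constrained to the search box by a quadratic
#' penalty. Deterministic for a fixed seed.
#'
#' @param ligand,receptor `molecular_system`s with dock types assigned.
#' @param box a [search_box()].
#' @param weights a [dock_weights()].
#' @param n_restarts number of perturb-and-minimize rounds; 0 returns the
#'   scored input pose unchanged.
#' @param seed integer RNG seed.
#' @param start_pose optional starting [pose()].
#' @return The best `pose` found, scored.
#' @export
optimize_pose <- function(ligand, receptor, box, weights = dock_weights(),
                          n_restarts = 8, seed = 1, start_pose = NULL) {
  if (is.null(start_pose)) start_pose <- pose()
  lig_cen <- colMeans(coords(ligand))
  lig_ext <- max(sqrt(rowSums(sweep(coords(ligand), 2, lig_cen)^2)))
  if (any(lig_ext > box$half_lengths))
    warning("ligand extent exceeds the search box; centroid moves are tightly constrained")
  clamp_pen <- function(tr) {
    cen <- lig_cen + tr
    over <- pmax(0, abs(cen - box$center) - box$half_lengths)
    1e4 * sum(over^2)
  }
  objective <- function(par) {
    p <- pose(translation = par[1:3],
              rotation = .rotvec_to_quat(par[4:6]))
    score_pose(ligand, receptor, p, weights)$score + clamp_pen(par[1:3])
  }
  start_rv <- {
    q <- start_pose$rotation
    th <- 2 * acos(max(-1, min(1, q[1])))
    ax <- q[2:4]; nx <- sqrt(sum(ax^2))
    if (nx < 1e-12 || th < 1e-12) c(0, 0, 0) else ax / nx * th
  }
  minimize <- function(par) {
    res <- stats::optim(par, objective, method = "Nelder-Mead",
                        control = list(maxit = 600, reltol = 1e-12))
    res
  }
  scored_input <- score_pose(ligand, receptor, start_pose, weights)
  if (n_restarts == 0) return(scored_input)
  with_seed(seed, {
    best <- minimize(c(start_pose$translation, start_rv))
    if (scored_input$score <= best$value) {
      best <- list(par = c(start_pose$translation, start_rv),
                   value = scored_input$score)
    }
    for (k in seq_len(n_restarts)) {
      trial <- best$par
      trial[1:3] <- (box$center - lig_cen) +
        stats::runif(3, -box$half_lengths, box$half_lengths)
      trial[4:6] <- stats::rnorm(3, sd = pi / 3)
      cand <- minimize(trial)
      if (cand$value < best$value) best <- cand
    }
    p <- pose(translation = best$par[1:3],
              rotation = .rotvec_to_quat(best$par[4:6]))
    score_pose(ligand, receptor, p, weights)
  })
}
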