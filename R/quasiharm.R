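# Quasiharmonic entropy: rigid-body motion is removed by Kabsch superposition
# on a reference selection, the mass-weighted covariance of the Cartesian
# coordinates is diagonalized, and each retained eigenmode is scored with the
# quantum-harmonic-oscillator entropy.

.kabsch_rotation <- function(P, Q) {
  # rotation matrix mapping P (moving, centered) onto Q (reference, centered)
  H <- t(P) %*% Q
  sv <- svd(H)
  dsign <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, dsign))
  sv$v %*% D %*% t(sv$u)
}

#' Rigid-body alignment of a trajectory (Kabsch superposition)
#'
#' Each frame is superposed onto the first frame by the translation and
#' rotation minimizing the RMSD over the selected atoms; the transform is then
#' applied to all atoms. With fewer than 3 selected atoms the rotation is
#' under-determined: a warning is emitted and only the translation is removed.
#'
#' @param traj a `trajectory`.
#' @param selection integer indices of the atoms to superpose on (e.g.
#'   receptor alpha-carbons); defaults to all atoms.
#' @return The aligned `trajectory`.
#' @export
kabsch_align <- function(traj, selection = seq_len(n_atoms(traj$system))) {
  selection <- as.integer(selection)
  if (!length(selection)) stop("alignment selection is empty")
  rot <- length(selection) >= 3L
  if (!rot)
    warning("fewer than 3 atoms selected; rotation under-determined, applying translation-only alignment")
  ref <- traj$frames[[1]][selection, , drop = FALSE]
  ref_cen <- colMeans(ref)
  refc <- sweep(ref, 2, ref_cen)
  traj$frames <- lapply(traj$frames, function(f) {
    sel <- f[selection, , drop = FALSE]
    cen <- colMeans(sel)
    if (rot) {
      R <- .kabsch_rotation(sweep(sel, 2, cen), refc)
      sweep(sweep(f, 2, cen) %*% t(R), 2, ref_cen, "+")
    } else {
      sweep(f, 2, cen - ref_cen)
    }
  })
  traj
}

#' Coordinate covariance matrix of a trajectory
#'
#' Population covariance sigma = <(x - <x>)(x - <x>)^T> of the flattened
#' Cartesian coordinates over frames (3N x 3N, A^2); symmetric positive
#' semidefinite by construction.
#'
#' @param traj a `trajectory` with at least 2 frames.
#' @return 3N x 3N covariance matrix.
#' @export
covariance_matrix <- function(traj) {
  m <- length(traj$frames)
  if (m < 2L) stop("covariance undefined for a single frame")
  X <- t(vapply(traj$frames, function(f) as.vector(t(f)),
                numeric(3L * n_atoms(traj$system))))
  Xc <- sweep(X, 2, colMeans(X))
  crossprod(Xc) / m
}

#' Quasiharmonic mode frequencies from a covariance matrix
#'
#' Eigenvalues lambda_k of M^(1/2) sigma M^(1/2) (amu A^2) define mode
#' frequencies omega_k = sqrt(k_B T c / lambda_k) in rad/ps, where c converts
#' kcal/mol to amu A^2 ps^-2. Eigenvalues at or below the floor (numerically
#' null modes left by alignment) are discarded and counted.
#'
#' @param sigma 3N x 3N coordinate covariance (A^2), symmetric.
#' @param masses atomic masses (amu), length N.
#' @param temperature temperature in K.
#' @param floor eigenvalue floor in amu A^2 below which modes are discarded.
#' @return List of class `qh_spectrum`: `frequencies` (rad/ps, ascending),
#'   `n_discarded`, `temperature`.
#' @export
quasiharmonic_frequencies <- function(sigma, masses, temperature,
                                      floor = 1e-8) {
  sigma <- as.matrix(sigma)
  if (max(abs(sigma - t(sigma))) > 1e-8 * max(1, max(abs(sigma))))
    stop("covariance matrix is not symmetric")
  if (nrow(sigma) != 3L * length(masses))
    stop("covariance dimension does not match 3 x number of masses")
  msq <- rep(sqrt(masses), each = 3L)
  mw <- sigma * outer(msq, msq)
  ev <- eigen((mw + t(mw)) / 2, symmetric = TRUE, only.values = TRUE)$values
  keep <- ev > floor
  lam <- ev[keep]
  omega <- sort(sqrt(.ls_const$k_B * temperature *
                       .ls_const$kcal_to_amuA2ps2 / lam))
  structure(list(frequencies = omega, n_discarded = sum(!keep),
                 temperature = temperature), class = "qh_spectrum")
}

#' Quasiharmonic entropy of a mode spectrum
#'
#' Quantum-harmonic-oscillator entropy per retained mode,
#' S = k_B sum_k [ u_k / (exp(u_k) - 1) - ln(1 - exp(-u_k)) ] with
#' u_k = hbar omega_k / (k_B T). Stiff modes (large u) contribute nothing;
#' in the classical limit u << 1 the per-mode entropy approaches
#' k_B (1 - ln u).
#'
#' @param spectrum a `qh_spectrum` from [quasiharmonic_frequencies()].
#' @return Entropy S in kcal mol^-1 K^-1.
#' @export
quasiharmonic_entropy <- function(spectrum) {
  omega <- spectrum$frequencies
  if (!length(omega)) return(0)
  u <- .ls_const$hbar * omega / (.ls_const$k_B * spectrum$temperature)
  per_mode <- ifelse(u > 500, 0, u / expm1(u) - log1p(-exp(-u)))
  .ls_const$k_B * sum(per_mode)
}

#' Entropy of a trajectory via the aligned quasiharmonic pipeline
#'
#' @param traj a `trajectory`.
#' @param align_selection atom indices for the Kabsch superposition; `NULL`
#'   skips alignment (e.g. when frames carry no rigid-body motion by
#'   construction).
#' @param floor eigenvalue floor passed to [quasiharmonic_frequencies()].
#' @return Entropy in kcal mol^-1 K^-1.
#' @export
trajectory_entropy <- function(traj, align_selection = NULL, floor = 1e-8) {
  if (!is.null(align_selection)) traj <- kabsch_align(traj, align_selection)
  sp <- quasiharmonic_frequencies(covariance_matrix(traj),
                                  traj$system$atoms$mass, traj$temperature,
                                  floor = floor)
  quasiharmonic_entropy(sp)
}

#' Binding entropy change from three trajectories
#'
#' Delta S = S_C - S_R - S_L. Trajectories containing the receptor (complex
#' and receptor alone) are aligned on the receptor alpha-carbon selection to
#' remove the receptor's rigid-body motion; the ligand-alone trajectory is
#' aligned on all its non-hydrogen atoms, so the change captures the ligand's
#' total entropy and the receptor's vibrational entropy.
#'
#' @param traj_C,traj_R,traj_L trajectories of the complex, receptor and
#'   ligand (consistent temperatures).
#' @param receptor_selection indices of the receptor alignment atoms, valid in
#'   both the receptor system and the complex (receptor atoms first).
#' @return Delta S in kcal mol^-1 K^-1.
#' @export
binding_entropy <- function(traj_C, traj_R, traj_L,
                            receptor_selection = seq_len(n_atoms(traj_R$system))) {
  temps <- c(traj_C$temperature, traj_R$temperature, traj_L$temperature)
  if (max(temps) - min(temps) > 1e-9)
    stop("temperature mismatch between trajectories")
  lig_sel <- which(traj_L$system$atoms$element != "H")
  if (!length(lig_sel)) lig_sel <- seq_len(n_atoms(traj_L$system))
  s_C <- trajectory_entropy(traj_C, receptor_selection)
  s_R <- trajectory_entropy(traj_R, receptor_selection)
  s_L <- trajectory_entropy(traj_L, lig_sel)
  s_C - s_R - s_L
}
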