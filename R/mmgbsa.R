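# Stage-2 estimator: trajectory-averaged MM/GBSA free energies and the binding
# free energy delta G0 = G_C - G_L - G_R from three separate trajectories
# (complex, receptor, ligand), with 2N+1 simulation bookkeeping.

#' Trajectory-averaged free energy (MM/GBSA)
#'
#' Per-frame molecular-mechanics, generalized-Born polar and SASA nonpolar
#' energies are averaged over the trajectory after discarding an initial
#' equilibration fraction; the entropy comes from the quasiharmonic pipeline
#' on the same retained frames. The total is
#' G = <E_MM> + <G_polar> + <G_nonpolar> - T S.
#'
#' @param traj a `trajectory` (>= 2 retained frames).
#' @param params bonded parameters for [mm_energy()]; defaults to harmonic
#'   bonds at the first frame's geometry.
#' @param model a [solvent_model()].
#' @param equil_fraction fraction of initial frames discarded as
#'   equilibration.
#' @param align_selection atom indices for entropy alignment (`NULL` = none).
#' @return List of class `free_energy_report`: `mean_e_mm`, `mean_g_polar`,
#'   `mean_g_nonpolar`, `entropy`, `temperature`, `g_total`, `n_frames`.
#' @export
trajectory_free_energy <- function(traj, params = NULL,
                                   model = solvent_model(),
                                   equil_fraction = 0.1,
                                   align_selection = NULL) {
  nf <- n_frames(traj)
  if (nf < 2L) stop("free energy undefined for a single frame (no entropy)")
  drop <- min(floor(equil_fraction * nf), nf - 2L)
  frames <- traj$frames[(drop + 1L):nf]
  # bond rest lengths default from the system's reference geometry, not from a
  # sampled frame, so the bonded baseline is unbiased
  if (is.null(params)) params <- auto_bond_params(traj$system)
  per_frame <- vapply(seq_along(frames), function(i) {
    sys <- set_coords(traj$system, frames[[i]])
    e <- tryCatch(configuration_energy(sys, params, model),
                  error = function(err)
                    stop(sprintf("frame %d: %s", i + drop, conditionMessage(err)),
                         call. = FALSE))
    c(e$total_mm, e$g_polar, e$g_nonpolar)
  }, numeric(3))
  sub <- trajectory(traj$system, frames, traj$temperature)
  S <- trajectory_entropy(sub, align_selection)
  rep <- list(mean_e_mm = mean(per_frame[1, ]),
              mean_g_polar = mean(per_frame[2, ]),
              mean_g_nonpolar = mean(per_frame[3, ]),
              entropy = S, temperature = traj$temperature,
              n_frames = length(frames))
  rep$g_total <- rep$mean_e_mm + rep$mean_g_polar + rep$mean_g_nonpolar -
    rep$temperature * rep$entropy
  structure(rep, class = "free_energy_report")
}

#' MM/GBSA binding free energy from three trajectories
#'
#' Three-trajectory protocol: separate complex (C), receptor (R) and ligand
#' (L) trajectories each yield a [trajectory_free_energy()] report, and
#' delta G0 = G_C - G_L - G_R, with the per-term differences (delta E_MM,
#' delta G_polar, delta G_nonpolar, -T delta S) reported alongside.
#' Receptor-containing trajectories are aligned on `receptor_selection`
#' (receptor alpha-carbons for proteins); the ligand trajectory on its
#' non-hydrogen atoms.
#'
#' @param traj_C,traj_R,traj_L trajectories with consistent temperatures.
#' @param params list with optional elements `C`, `R`, `L` of bonded
#'   parameters per system.
#' @param model a [solvent_model()] shared by the three evaluations.
#' @param equil_fraction equilibration fraction (see
#'   [trajectory_free_energy()]).
#' @param receptor_selection receptor alignment atom indices (valid in both
#'   receptor and complex; receptor atoms come first in the complex).
#' @return List of class `binding_report`: reports for C/R/L, `delta_g0` and
#'   `term_deltas`.
#' @export
binding_free_energy <- function(traj_C, traj_R, traj_L,
                                params = list(C = NULL, R = NULL, L = NULL),
                                model = solvent_model(),
                                equil_fraction = 0.1,
                                receptor_selection = seq_len(n_atoms(traj_R$system))) {
  temps <- c(traj_C$temperature, traj_R$temperature, traj_L$temperature)
  if (max(temps) - min(temps) > 1e-9)
    stop("inconsistent temperatures across trajectories")
  lig_sel <- which(traj_L$system$atoms$element != "H")
  if (!length(lig_sel)) lig_sel <- seq_len(n_atoms(traj_L$system))
  rC <- trajectory_free_energy(traj_C, params$C, model, equil_fraction,
                               align_selection = receptor_selection)
  rR <- trajectory_free_energy(traj_R, params$R, model, equil_fraction,
                               align_selection = receptor_selection)
  rL <- trajectory_free_energy(traj_L, params$L, model, equil_fraction,
                               align_selection = lig_sel)
  term_deltas <- c(
    delta_e_mm = rC$mean_e_mm - rR$mean_e_mm - rL$mean_e_mm,
    delta_g_polar = rC$mean_g_polar - rR$mean_g_polar - rL$mean_g_polar,
    delta_g_nonpolar = rC$mean_g_nonpolar - rR$mean_g_nonpolar - rL$mean_g_nonpolar,
    minus_t_delta_s = -traj_C$temperature *
      (rC$entropy - rR$entropy - rL$entropy)
  )
  structure(list(report_C = rC, report_R = rR, report_L = rL,
                 delta_g0 = rC$g_total - rL$g_total - rR$g_total,
                 term_deltas = term_deltas),
            class = "binding_report")
}

#' @export
print.binding_report <- function(x, ...) {
  cat("MM/GBSA binding free energy report\n")
  td <- x$term_deltas
  cat(sprintf("  delta E_MM        %10.3f kcal/mol\n", td["delta_e_mm"]))
  cat(sprintf("  delta G_polar     %10.3f kcal/mol\n", td["delta_g_polar"]))
  cat(sprintf("  delta G_nonpolar  %10.3f kcal/mol\n", td["delta_g_nonpolar"]))
  cat(sprintf("  -T delta S        %10.3f kcal/mol\n", td["minus_t_delta_s"]))
  cat(sprintf("  delta G0          %10.3f kcal/mol\n", x$delta_g0))
  invisible(x)
}

#' Plan the 2N+1 simulation batch of the MD stage
#'
#' For N promoted ligands the MD stage runs 2N+1 simulations: one of the
#' receptor alone, one of each ligand alone, and one of each complex.
#'
#' @param n_ligands number of ligands N (>= 0).
#' @param ligand_ids optional identifiers (defaults to L1..LN).
#' @return data.frame of job descriptors with columns `job`, `kind`,
#'   `ligand_id`.
#' @export
plan_md_batch <- function(n_ligands, ligand_ids = NULL) {
  if (n_ligands < 0) stop("n_ligands must be non-negative")
  if (is.null(ligand_ids))
    ligand_ids <- if (n_ligands > 0) paste0("L", seq_len(n_ligands))
                  else character(0)
  stopifnot(length(ligand_ids) == n_ligands)
  data.frame(
    job = seq_len(2L * n_ligands + 1L),
    kind = c("receptor", rep("ligand", n_ligands), rep("complex", n_ligands)),
    ligand_id = c(NA_character_, ligand_ids, ligand_ids),
    stringsAsFactors = FALSE)
}
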