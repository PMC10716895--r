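# Three-stage screening pipeline: rank all ligands by docking score, promote
# the best to MM/GBSA on toy trajectories (2N+1 jobs), promote the best of
# those to the alchemical FEP cycle, and report per-stage ranked tables.
# Any per-ligand failure is caught and the ligand is ranked worst.

#' Screening plan
#'
#' @param n_to_md ligands promoted from docking to the MD (MM/GBSA) stage.
#' @param n_to_fep ligands promoted from MD to the FEP stage (<= n_to_md).
#' @param seed master seed; all per-ligand seeds derive from it.
#' @param weights [dock_weights()] for stage 1.
#' @param solvent [solvent_model()] for stage 2.
#' @param n_restarts iterated-local-search restarts per docking.
#' @param md list of MD-stage settings: `n_frames`, `jiggle_k`
#'   (kcal mol^-1 A^-2 harmonic mode stiffness of the toy trajectories),
#'   `equil_fraction`.
#' @param fep list of FEP-stage settings: `K` (lambda states), `n_steps`,
#'   `step_size`, `restraint_k`.
#' @return A `screen_plan` object.
#' @export
screen_plan <- function(n_to_md = 100, n_to_fep = 15, seed = 1,
                        weights = dock_weights(), solvent = solvent_model(),
                        n_restarts = 8,
                        md = list(n_frames = 80, jiggle_k = 200,
                                  equil_fraction = 0.1),
                        fep = list(K = 8, n_steps = 600, step_size = 0.12,
                                   restraint_k = 10)) {
  if (n_to_fep > n_to_md) stop("n_to_fep must not exceed n_to_md")
  structure(list(n_to_md = n_to_md, n_to_fep = n_to_fep, seed = seed,
                 weights = weights, solvent = solvent,
                 n_restarts = n_restarts, md = md, fep = fep),
            class = "screen_plan")
}

#' Rigid-body relaxation of a placed ligand against the MM potential
#'
#' System preparation between the docking and MD stages: the empirical docking
#' score and the molecular-mechanics force field place their contact minima at
#' slightly different separations, so the docked pose is relaxed (rigid-body
#' translation + rotation, derivative-free simplex) against the
#' intermolecular LJ + Coulomb energy before trajectories are generated.
#'
#' @param ligand ligand `molecular_system`, already placed (posed).
#' @param receptor receptor `molecular_system`.
#' @return The ligand with relaxed coordinates.
#' @export
relax_pose <- function(ligand, receptor) {
  lx0 <- coords(ligand); rx <- coords(receptor)
  cen <- colMeans(lx0)
  la <- ligand$atoms; ra <- receptor$atoms
  rmin <- outer(la$lj_radius, ra$lj_radius, "+")
  eps <- sqrt(outer(la$lj_epsilon, ra$lj_epsilon))
  qq <- .ls_const$k_e * outer(la$charge, ra$charge)
  inter <- function(par) {
    R <- .quat_to_matrix(.rotvec_to_quat(par[4:6]))
    xyz <- sweep(sweep(lx0, 2, cen) %*% t(R), 2, cen + par[1:3], "+")
    d <- sqrt(pmax(outer(rowSums(xyz^2), rowSums(rx^2), "+") -
                     2 * xyz %*% t(rx), 1e-12))
    x6 <- (rmin / d)^6
    sum(eps * (x6^2 - 2 * x6)) + sum(qq / d)
  }
  res <- stats::optim(rep(0, 6), inter, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-10))
  R <- .quat_to_matrix(.rotvec_to_quat(res$par[4:6]))
  set_coords(ligand, sweep(sweep(lx0, 2, cen) %*% t(R), 2,
                           cen + res$par[1:3], "+"))
}

.stage_score_col <- function(stage) {
  switch(stage, dock = "dock_score", md = "md_score", fep = "fep_score",
         stop("unknown stage: ", stage))
}

#' Rank ligand records within a stage
#'
#' Ascending by the stage score (more negative = better). Records that failed,
#' or carry no finite score for the stage, are placed after every scored
#' record. Ties break lexicographically by ligand id, so the ordering is
#' deterministic.
#'
#' @param records data.frame with columns `id`, `status` and the stage score
#'   column (`dock_score`, `md_score` or `fep_score`).
#' @param stage "dock", "md" or "fep".
#' @return The records ordered, with a `rank` column added.
#' @export
rank_stage <- function(records, stage = c("dock", "md", "fep")) {
  stage <- match.arg(stage)
  col <- .stage_score_col(stage)
  sc <- if (col %in% names(records)) records[[col]] else
    rep(NA_real_, nrow(records))
  failed <- records$status != "ok" | !is.finite(sc)
  sc_key <- ifelse(failed, Inf, sc)
  ord <- order(sc_key, records$id)
  out <- records[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Promote the top of a ranked stage table
#'
#' Returns the first `min(n, number of non-failed records)` rows; failed
#' records are never promoted (with a warning when fewer than `n` are
#' available).
#'
#' @param ranked output of [rank_stage()].
#' @param n number of ligands to promote (>= 0).
#' @param stage the stage the ranking came from.
#' @return Subset of `ranked`.
#' @export
promote <- function(ranked, n, stage = c("dock", "md", "fep")) {
  stage <- match.arg(stage)
  if (n < 0) stop("n must be non-negative")
  col <- .stage_score_col(stage)
  ok <- ranked$status == "ok" & is.finite(ranked[[col]])
  avail <- sum(ok)
  if (n > avail)
    warning(sprintf("requested %d promotions but only %d scored ligands", n, avail))
  ranked[ok, , drop = FALSE][seq_len(min(n, avail)), , drop = FALSE]
}

.stage_csv <- function(records, stage, path) {
  col <- .stage_score_col(stage)
  out <- data.frame(id = records$id,
                    score = signif(records[[col]], 10),
                    status = records$status, rank = records$rank,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

#' Run the full three-stage screen
#'
#' Docks every ligand into the receptor search box, ranks by docking score and
#' promotes the top `n_to_md`; runs the 2N+1 toy-trajectory MM/GBSA batch and
#' re-ranks by binding free energy; promotes the top `n_to_fep` to the
#' restrained alchemical cycle and ranks by FEP binding free energy. Every
#' exception raised while processing one ligand is converted to a failure
#' status (`failed_dock`, `failed_params`, `failed_sim`) and the ligand is
#' ranked worst; the run itself never aborts on a per-ligand problem.
#' Deterministic for a fixed plan seed.
#'
#' @param receptor receptor `molecular_system` (fatal if missing/invalid).
#' @param ligands named list of ligand `molecular_system`s.
#' @param plan a [screen_plan()].
#' @param box a [search_box()]; defaults to the `search_box` attribute of the
#'   receptor (as set by [make_pocket_receptor()]).
#' @param out_dir optional directory to write `stage1.csv`, `stage2.csv`,
#'   `stage3.csv` (columns id, score, status, rank).
#' @return List of class `screen_report`: per-stage ranked tables `stage1`,
#'   `stage2`, `stage3`, the full per-ligand `records` table, the MD `batch`
#'   plan and the `plan`.
#' @export
run_screen <- function(receptor, ligands, plan = screen_plan(),
                       box = attr(receptor, "search_box"), out_dir = NULL) {
  if (!inherits(receptor, "molecular_system"))
    stop("receptor is not a molecular_system")
  if (is.null(box)) {
    xyz <- coords(receptor)
    box <- search_box(colMeans(xyz),
                      pmax(apply(xyz, 2, function(v) diff(range(v)) / 2), 1))
  }
  receptor <- assign_dock_types(receptor)
  ids <- names(ligands)
  if (is.null(ids)) ids <- sprintf("LIG%03d", seq_along(ligands))
  n <- length(ligands)
  records <- data.frame(id = ids, status = rep("ok", n),
                        dock_score = rep(NA_real_, n),
                        md_score = rep(NA_real_, n),
                        fep_score = rep(NA_real_, n), stringsAsFactors = FALSE)
  if (n == 0L) {
    empty <- cbind(records, rank = integer(0))
    rep0 <- structure(list(stage1 = empty, stage2 = empty, stage3 = empty,
                           records = records, batch = plan_md_batch(0),
                           poses = list(), plan = plan),
                      class = "screen_report")
    return(rep0)
  }
  poses <- vector("list", n); names(poses) <- ids

  ## stage 1: docking
  for (i in seq_len(n)) {
    res <- tryCatch({
      lig <- assign_dock_types(ligands[[i]])
      p <- optimize_pose(lig, receptor, box, plan$weights,
                         n_restarts = plan$n_restarts,
                         seed = plan$seed + 131L * i)
      if (!is.finite(p$score)) stop("non-finite docking score")
      list(score = p$score, pose = p, lig = lig)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      records$status[i] <- "failed_dock"
    } else {
      records$dock_score[i] <- res$score
      poses[[i]] <- res
    }
  }
  stage1 <- rank_stage(records, "dock")
  to_md <- promote(stage1, plan$n_to_md, "dock")
  batch <- plan_md_batch(nrow(to_md), to_md$id)

  ## stage 2: MM/GBSA on toy harmonic trajectories (2N+1 jobs)
  mdset <- plan$md
  traj_R <- harmonic_trajectory(receptor, k = mdset$jiggle_k,
                                temperature = plan$solvent$temperature,
                                n_frames = mdset$n_frames,
                                seed = plan$seed + 7L)
  for (id in to_md$id) {
    i <- match(id, records$id)
    res <- tryCatch({
      posed <- relax_pose(apply_pose(poses[[i]]$lig, poses[[i]]$pose), receptor)
      traj_L <- harmonic_trajectory(posed, k = mdset$jiggle_k,
                                    temperature = plan$solvent$temperature,
                                    n_frames = mdset$n_frames,
                                    seed = plan$seed + 977L * i)
      cmplx <- combine_systems(receptor, posed, name = paste0("C_", id))
      traj_C <- harmonic_trajectory(cmplx, k = mdset$jiggle_k,
                                    temperature = plan$solvent$temperature,
                                    n_frames = mdset$n_frames,
                                    seed = plan$seed + 1409L * i)
      br <- binding_free_energy(traj_C, traj_R, traj_L,
                                model = plan$solvent,
                                equil_fraction = mdset$equil_fraction)
      if (!is.finite(br$delta_g0)) stop("non-finite MM/GBSA estimate")
      br$delta_g0
    }, error = function(e) e)
    if (inherits(res, "error")) records$status[i] <- "failed_sim"
    else records$md_score[i] <- res
  }
  stage2 <- rank_stage(records[records$id %in% to_md$id, , drop = FALSE], "md")
  to_fep <- promote(stage2, plan$n_to_fep, "md")

  ## stage 3: alchemical FEP cycle
  fset <- plan$fep
  fep_box <- rbind(box$center - box$half_lengths,
                   box$center + box$half_lengths)
  for (id in to_fep$id) {
    i <- match(id, records$id)
    res <- tryCatch({
      posed <- relax_pose(apply_pose(poses[[i]]$lig, poses[[i]]$pose), receptor)
      anchors <- which(receptor$atoms$element != "H")
      target <- sqrt(sum((colMeans(coords(posed)) -
                            colMeans(coords(receptor)[anchors, , drop = FALSE]))^2))
      fsys <- fep_system(
        posed, receptor,
        restraints = list(
          restraint("distance", anchor_atoms = anchors, target = target,
                    force_constant = fset$restraint_k),
          restraint("rmsd", force_constant = fset$restraint_k)),
        box = fep_box)
      fr <- run_fep_cycle(fsys, lambda_schedule(fset$K),
                          temperature = plan$solvent$temperature,
                          n_steps = fset$n_steps,
                          step_size = fset$step_size,
                          seed = plan$seed + 2713L * i)
      if (!is.finite(fr$delta_g_binding)) stop("non-finite FEP estimate")
      fr$delta_g_binding
    }, error = function(e) e)
    if (inherits(res, "error")) records$status[i] <- "failed_sim"
    else records$fep_score[i] <- res
  }
  stage3 <- rank_stage(records[records$id %in% to_fep$id, , drop = FALSE], "fep")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    .stage_csv(stage1, "dock", file.path(out_dir, "stage1.csv"))
    .stage_csv(stage2, "md", file.path(out_dir, "stage2.csv"))
    .stage_csv(stage3, "fep", file.path(out_dir, "stage3.csv"))
  }
  structure(list(stage1 = stage1, stage2 = stage2, stage3 = stage3,
                 records = records, batch = batch, poses = poses, plan = plan),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("<screen_report: %d ligands; %d to MD, %d to FEP>\n",
              nrow(x$records), nrow(x$stage2), nrow(x$stage3)))
  if (nrow(x$stage3)) {
    cat("final FEP ranking:\n")
    print(x$stage3[, c("id", "fep_score", "status", "rank")])
  }
  invisible(x)
}
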