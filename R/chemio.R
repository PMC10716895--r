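# Structure and trajectory containers plus readers/writers for the small
# plain-text formats the engine consumes (PDB incl. multi-MODEL, XYZ incl.
# multi-frame, mol2 ATOM/BOND records) and the per-atom parameter table.

.dock_types <- c("carbon_hydrophobic", "polar_donor", "polar_acceptor",
                 "donor_acceptor", "other")

# Bondi-like vdW radii (A), covalent radii (A) and atomic masses (amu) used to
# default missing per-atom parameters for toy fixtures.
.element_defaults <- data.frame(
  element    = c("H", "C", "N", "O", "S", "P", "F", "Cl", "Br"),
  lj_radius  = c(1.20, 1.70, 1.55, 1.52, 1.80, 1.80, 1.47, 1.75, 1.85),
  lj_epsilon = c(0.02, 0.10, 0.10, 0.10, 0.10, 0.10, 0.10, 0.10, 0.10),
  mass       = c(1.008, 12.011, 14.007, 15.999, 32.06, 30.974,
                 18.998, 35.45, 79.904),
  cov_radius = c(0.31, 0.76, 0.71, 0.66, 1.05, 1.07, 0.57, 1.02, 1.20),
  stringsAsFactors = FALSE
)

.element_default_row <- function(el) {
  i <- match(el, .element_defaults$element)
  if (is.na(i)) {
    # unknown element: generic heavy-atom defaults
    return(list(lj_radius = 1.7, lj_epsilon = 0.1, mass = 1.0,
                cov_radius = 0.8))
  }
  as.list(.element_defaults[i, -1])
}

#' Construct a molecular system
#'
#' A molecular system is the basic container for a ligand, a receptor, or a
#' ligand-receptor complex: an ordered atom table plus an explicit bond list.
#'
#' @param atoms data.frame with one row per atom. Required columns: `element`,
#'   `x`, `y`, `z`. Optional columns `name`, `charge` (e), `lj_radius` (A,
#'   Rmin/2 convention), `lj_epsilon` (kcal/mol), `mass` (amu), `gb_radius`
#'   (intrinsic Born radius, A), `dock_type`, `role` ("ligand" or "receptor")
#'   are defaulted from a bundled element table when absent; defaulted atoms
#'   are flagged in the `param_defaulted` column.
#' @param bonds two-column integer matrix of 1-based atom index pairs (may have
#'   zero rows).
#' @param name system identifier.
#' @return An object of class `molecular_system`.
#' @export
molecular_system <- function(atoms, bonds = NULL, name = "system") {
  if (!is.data.frame(atoms) || nrow(atoms) == 0L)
    stop("empty structure: a molecular system needs at least one atom")
  need <- c("element", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms table lacks columns: ", paste(miss, collapse = ", "))
  n <- nrow(atoms)
  atoms$element <- as.character(atoms$element)
  if (is.null(atoms$name)) atoms$name <- paste0(atoms$element, seq_len(n))
  defaulted <- rep(FALSE, n)
  fill <- function(col, getter) {
    if (is.null(atoms[[col]])) atoms[[col]] <<- rep(NA_real_, n)
    isna <- is.na(atoms[[col]])
    if (any(isna)) {
      atoms[[col]][isna] <<- vapply(atoms$element[isna],
                                    function(e) getter(.element_default_row(e)),
                                    numeric(1))
      defaulted <<- defaulted | isna
    }
  }
  if (is.null(atoms$charge)) atoms$charge <- rep(NA_real_, n)
  chna <- is.na(atoms$charge)
  if (any(chna)) { atoms$charge[chna] <- 0; defaulted <- defaulted | chna }
  fill("lj_radius", function(d) d$lj_radius)
  fill("lj_epsilon", function(d) d$lj_epsilon)
  fill("mass", function(d) d$mass)
  fill("gb_radius", function(d) d$lj_radius)  # intrinsic Born radius ~ vdW radius
  if (is.null(atoms$dock_type)) atoms$dock_type <- rep(NA_character_, n)
  if (is.null(atoms$role)) atoms$role <- rep("ligand", n)
  atoms$param_defaulted <- defaulted

  if (any(atoms$mass <= 0)) stop("atom masses must be positive")
  if (any(atoms$lj_radius < 0) || any(atoms$lj_epsilon < 0))
    stop("LJ parameters must be non-negative")
  if (any(atoms$gb_radius <= 0)) stop("intrinsic Born radii must be positive")
  ok_type <- is.na(atoms$dock_type) | atoms$dock_type %in% .dock_types
  if (!all(ok_type)) stop("unknown dock_type: ",
                          paste(unique(atoms$dock_type[!ok_type]), collapse = ", "))

  if (is.null(bonds)) bonds <- matrix(integer(0), ncol = 2)
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (nrow(bonds)) {
    if (any(bonds < 1L) || any(bonds > n)) stop("bond index out of range")
    if (any(bonds[, 1] == bonds[, 2])) stop("bond joins an atom to itself")
    key <- paste(pmin(bonds[, 1], bonds[, 2]), pmax(bonds[, 1], bonds[, 2]))
    if (anyDuplicated(key)) stop("duplicate bond pair")
  }
  structure(list(atoms = atoms, bonds = bonds, name = name),
            class = "molecular_system")
}

#' @export
print.molecular_system <- function(x, ...) {
  cat(sprintf("<molecular_system '%s': %d atoms, %d bonds>\n",
              x$name, nrow(x$atoms), nrow(x$bonds)))
  invisible(x)
}

#' Number of atoms in a system
#' @param system a `molecular_system`.
#' @return Integer atom count.
#' @export
n_atoms <- function(system) nrow(system$atoms)

#' Coordinates of a system as a matrix
#' @param system a `molecular_system`.
#' @return n x 3 numeric matrix (A).
#' @export
coords <- function(system) {
  m <- as.matrix(system$atoms[, c("x", "y", "z"), drop = FALSE])
  dimnames(m) <- NULL
  m
}

#' Replace the coordinates of a system
#' @param system a `molecular_system`.
#' @param xyz n x 3 matrix of new coordinates (A).
#' @return The modified system.
#' @export
set_coords <- function(system, xyz) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) != n_atoms(system) || ncol(xyz) != 3L)
    stop("coordinate matrix must be n_atoms x 3")
  system$atoms$x <- xyz[, 1]; system$atoms$y <- xyz[, 2]; system$atoms$z <- xyz[, 3]
  system
}

#' Concatenate a receptor and a ligand into one complex system
#'
#' Atom order is receptor first, then ligand; bond indices are offset
#' accordingly and roles are set so the two subsystems remain identifiable.
#'
#' @param receptor,ligand `molecular_system` objects.
#' @param name identifier for the complex.
#' @return A `molecular_system` holding the complex.
#' @export
combine_systems <- function(receptor, ligand, name = "complex") {
  ra <- receptor$atoms; la <- ligand$atoms
  ra$role <- "receptor"; la$role <- "ligand"
  cols <- union(names(ra), names(la))
  for (cl in setdiff(cols, names(ra))) ra[[cl]] <- NA
  for (cl in setdiff(cols, names(la))) la[[cl]] <- NA
  atoms <- rbind(ra[cols], la[cols])
  bonds <- rbind(receptor$bonds,
                 if (nrow(ligand$bonds)) ligand$bonds + nrow(ra) else ligand$bonds)
  molecular_system(atoms, bonds, name = name)
}

#' Construct a trajectory
#'
#' @param system the `molecular_system` the frames belong to.
#' @param frames list of n_atoms x 3 coordinate matrices (A), in time order.
#' @param temperature simulation temperature in K.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(system, frames, temperature = 300) {
  stopifnot(inherits(system, "molecular_system"))
  if (!is.list(frames) || length(frames) < 1L)
    stop("a trajectory needs at least one frame")
  n <- n_atoms(system)
  for (i in seq_along(frames)) {
    f <- as.matrix(frames[[i]])
    if (nrow(f) != n || ncol(f) != 3L)
      stop(sprintf("frame %d has %d atoms, system has %d", i, nrow(f), n))
    frames[[i]] <- f
  }
  if (!is.numeric(temperature) || temperature <= 0)
    stop("temperature must be positive")
  structure(list(system = system, frames = frames, temperature = temperature),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory: %d frames of '%s' (%d atoms) at %g K>\n",
              length(x$frames), x$system$name, n_atoms(x$system), x$temperature))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) length(traj$frames)

## ---------------------------------------------------------------- PDB ------

.parse_pdb_atoms <- function(lines, path) {
  rec <- substr(lines, 1, 6)
  sel <- rec %in% c("ATOM  ", "HETATM")
  al <- lines[sel]
  if (!length(al)) stop("empty structure in PDB file: ", path)
  fx <- function(a, b) trimws(substr(al, a, b))
  name <- fx(13, 16)
  altloc <- fx(17, 17)
  x <- suppressWarnings(as.numeric(substr(al, 31, 38)))
  y <- suppressWarnings(as.numeric(substr(al, 39, 46)))
  z <- suppressWarnings(as.numeric(substr(al, 47, 54)))
  if (anyNA(x) || anyNA(y) || anyNA(z)) {
    bad <- which(is.na(x) | is.na(y) | is.na(z))[1]
    stop(sprintf("cannot parse coordinates in PDB record %d of %s", bad, path))
  }
  el <- fx(77, 78)
  # fall back to first alphabetic character of the atom name
  noel <- el == ""
  if (any(noel)) el[noel] <- toupper(substr(gsub("[^A-Za-z].*", "",
                                                 gsub("^[0-9]+", "", name[noel])), 1, 1))
  el <- paste0(toupper(substr(el, 1, 1)), tolower(substr(el, 2, 2)))
  keep <- altloc %in% c("", "A")
  if (!all(keep)) warning("alternate locations found; keeping first altloc only")
  data.frame(element = el, name = name, x = x, y = y, z = z,
             stringsAsFactors = FALSE)[keep, , drop = FALSE]
}

.split_pdb_models <- function(lines) {
  starts <- grep("^MODEL", lines)
  if (!length(starts)) return(list(lines))
  ends <- grep("^ENDMDL", lines)
  if (length(ends) < length(starts)) ends <- c(ends, length(lines))
  lapply(seq_along(starts), function(i) lines[starts[i]:ends[i]])
}

.read_pdb_structure <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(trimws(lines)) || all(trimws(lines) == ""))
    stop("empty structure: no atoms in ", path)
  models <- .split_pdb_models(lines)
  if (length(models) > 1L)
    warning(sprintf("PDB %s has %d MODEL records; reading first model only",
                    path, length(models)))
  atoms <- .parse_pdb_atoms(models[[1]], path)
  # CONECT records (serial numbers are 1-based file serials == row order here)
  con <- grep("^CONECT", lines, value = TRUE)
  bonds <- NULL
  if (length(con)) {
    prs <- do.call(rbind, lapply(con, function(l) {
      f <- suppressWarnings(as.integer(strsplit(trimws(substr(l, 7, nchar(l))),
                                                "\\s+")[[1]]))
      f <- f[!is.na(f)]
      if (length(f) >= 2) cbind(f[1], f[-1]) else NULL
    }))
    if (!is.null(prs)) {
      prs <- t(apply(prs, 1, sort))
      prs <- unique(prs)
      prs <- prs[prs[, 1] <= nrow(atoms) & prs[, 2] <= nrow(atoms), , drop = FALSE]
      bonds <- prs
    }
  }
  molecular_system(atoms, bonds, name = sub("\\.[^.]*$", "", basename(path)))
}

.read_xyz_blocks <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[seq_len(length(lines))]
  blocks <- list(); i <- 1L
  while (i <= length(lines)) {
    if (trimws(lines[i]) == "") { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L)
      stop(sprintf("format error in XYZ file %s at line %d: expected atom count", path, i))
    if (i + 1L + n > length(lines))
      stop(sprintf("format error in XYZ file %s at line %d: truncated frame", path, i))
    body <- lines[(i + 2L):(i + 1L + n)]
    tok <- strsplit(trimws(body), "\\s+")
    el <- vapply(tok, `[`, "", 1)
    xyz <- suppressWarnings(
      t(vapply(tok, function(t) as.numeric(t[2:4]), numeric(3))))
    if (anyNA(xyz))
      stop(sprintf("format error in XYZ file %s near line %d: bad coordinates", path, i + 2L))
    blocks[[length(blocks) + 1L]] <- list(element = el, xyz = xyz)
    i <- i + 2L + n
  }
  if (!length(blocks)) stop("empty structure: no atoms in ", path)
  blocks
}

.read_mol2_structure <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sec <- grep("^@<TRIPOS>", lines)
  if (!length(sec)) stop("format error: no TRIPOS records in ", path)
  get_section <- function(tag) {
    s <- grep(paste0("^@<TRIPOS>", tag, "\\s*$"), lines)
    if (!length(s)) return(character(0))
    s <- s[1] + 1L
    e <- sec[sec > s - 1L][1]
    e <- if (is.na(e)) length(lines) else e - 1L
    body <- lines[s:e]
    body[trimws(body) != ""]
  }
  at <- get_section("ATOM")
  if (!length(at)) stop("empty structure: no atoms in ", path)
  tok <- strsplit(trimws(at), "\\s+")
  name <- vapply(tok, `[`, "", 2)
  xyz <- t(vapply(tok, function(t) as.numeric(t[3:5]), numeric(3)))
  if (anyNA(xyz)) stop("format error in mol2 ATOM records of ", path)
  type <- vapply(tok, `[`, "", 6)
  el <- sub("\\..*$", "", type)
  charge <- vapply(tok, function(t) {
    if (length(t) >= 9) suppressWarnings(as.numeric(t[9])) else NA_real_
  }, numeric(1))
  bd <- get_section("BOND")
  bonds <- NULL
  if (length(bd)) {
    bt <- strsplit(trimws(bd), "\\s+")
    bonds <- t(vapply(bt, function(t) as.integer(t[2:3]), integer(2)))
  }
  molecular_system(
    data.frame(element = el, name = name, x = xyz[, 1], y = xyz[, 2],
               z = xyz[, 3], charge = charge, stringsAsFactors = FALSE),
    bonds, name = sub("\\.[^.]*$", "", basename(path)))
}

#' Read a molecular structure file
#'
#' Supports PDB (first MODEL of a multi-model file, with a warning), XYZ and
#' mol2 (ATOM/BOND records). Per-atom parameters missing from the file
#' (charge, LJ, mass, Born radius) are defaulted from a bundled element table
#' and flagged in the `param_defaulted` atom column.
#'
#' @param path file path.
#' @param format one of "pdb", "xyz", "mol2"; guessed from the file extension
#'   when omitted.
#' @return A `molecular_system`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "xyz", "mol2")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)),
                     pdb = "pdb", xyz = "xyz", mol2 = "mol2",
                     stop("cannot guess format of ", path))
  if (file.size(path) == 0L) stop("empty structure: file ", path, " is empty")
  switch(format,
         pdb = .read_pdb_structure(path),
         xyz = {
           b <- .read_xyz_blocks(path)[[1]]
           molecular_system(
             data.frame(element = b$element, x = b$xyz[, 1], y = b$xyz[, 2],
                        z = b$xyz[, 3], stringsAsFactors = FALSE),
             name = sub("\\.[^.]*$", "", basename(path)))
         },
         mol2 = .read_mol2_structure(path))
}

#' Read a trajectory
#'
#' Frames are returned in file order. Every frame must contain exactly the
#' same number of atoms as `system`.
#'
#' @param path file path (multi-MODEL PDB or multi-frame XYZ).
#' @param system the `molecular_system` the frames belong to.
#' @param format "pdb" or "xyz"; guessed from the extension when omitted.
#' @param temperature temperature (K) to attach to the trajectory.
#' @return A `trajectory`.
#' @export
read_trajectory <- function(path, system, format = c("auto", "pdb", "xyz"),
                            temperature = 300) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)), pdb = "pdb", xyz = "xyz",
                     stop("cannot guess format of ", path))
  n <- n_atoms(system)
  if (format == "pdb") {
    lines <- readLines(path, warn = FALSE)
    models <- .split_pdb_models(lines)
    frames <- lapply(seq_along(models), function(i) {
      a <- .parse_pdb_atoms(models[[i]], path)
      if (nrow(a) != n)
        stop(sprintf("frame %d has %d atoms but system has %d", i, nrow(a), n))
      as.matrix(a[, c("x", "y", "z")])
    })
  } else {
    blocks <- .read_xyz_blocks(path)
    frames <- lapply(seq_along(blocks), function(i) {
      if (nrow(blocks[[i]]$xyz) != n)
        stop(sprintf("frame %d has %d atoms but system has %d",
                     i, nrow(blocks[[i]]$xyz), n))
      blocks[[i]]$xyz
    })
  }
  trajectory(system, frames, temperature)
}

.format_pdb_frame <- function(system, xyz, serial_offset = 0L) {
  a <- system$atoms
  sprintf("ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          seq_len(nrow(a)) + serial_offset,
          substr(a$name, 1, 4), "MOL", "A", 1L,
          xyz[, 1], xyz[, 2], xyz[, 3], 1.0, 0.0,
          toupper(substr(a$element, 1, 2)))
}

#' Write a structure to PDB or XYZ
#' @param system a `molecular_system`.
#' @param path output path.
#' @param format "pdb" or "xyz"; guessed from the extension when omitted.
#' @return Invisibly, the path.
#' @export
write_structure <- function(system, path, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)), pdb = "pdb", xyz = "xyz",
                     stop("cannot guess format of ", path))
  xyz <- coords(system)
  if (format == "pdb") {
    out <- c(.format_pdb_frame(system, xyz),
             if (nrow(system$bonds))
               sprintf("CONECT%5d%5d", system$bonds[, 1], system$bonds[, 2]),
             "END")
  } else {
    out <- c(as.character(n_atoms(system)), system$name,
             sprintf("%s %12.6f %12.6f %12.6f", system$atoms$element,
                     xyz[, 1], xyz[, 2], xyz[, 3]))
  }
  writeLines(out, path)
  invisible(path)
}

#' Write a trajectory to multi-MODEL PDB or multi-frame XYZ
#' @param traj a `trajectory`.
#' @param path output path.
#' @param format "pdb" or "xyz"; guessed from the extension when omitted.
#' @return Invisibly, the path.
#' @export
write_trajectory <- function(traj, path, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)), pdb = "pdb", xyz = "xyz",
                     stop("cannot guess format of ", path))
  if (format == "pdb") {
    out <- unlist(lapply(seq_along(traj$frames), function(i) {
      c(sprintf("MODEL %8d", i),
        .format_pdb_frame(traj$system, traj$frames[[i]]),
        "ENDMDL")
    }))
    out <- c(out, "END")
  } else {
    out <- unlist(lapply(seq_along(traj$frames), function(i) {
      f <- traj$frames[[i]]
      c(as.character(n_atoms(traj$system)), sprintf("frame %d", i),
        sprintf("%s %12.6f %12.6f %12.6f", traj$system$atoms$element,
                f[, 1], f[, 2], f[, 3]))
    }))
  }
  writeLines(out, path)
  invisible(path)
}

## --------------------------------------------------- typing & parameters --

#' Infer bonds from a covalent-radius heuristic
#'
#' Used only when a file format carries no bond records: two atoms are bonded
#' when their distance is below 1.2 x the sum of covalent radii.
#'
#' @param system a `molecular_system`.
#' @return The system with the inferred bond list.
#' @export
perceive_bonds <- function(system) {
  xyz <- coords(system)
  n <- nrow(xyz)
  if (n < 2L) return(system)
  rc <- vapply(system$atoms$element,
               function(e) .element_default_row(e)$cov_radius, numeric(1))
  d <- as.matrix(stats::dist(xyz))
  thr <- outer(rc, rc, "+") * 1.2
  hit <- which(d < thr & upper.tri(d), arr.ind = TRUE)
  system$bonds <- matrix(as.integer(hit), ncol = 2)
  system
}

.bond_neighbors <- function(system) {
  n <- n_atoms(system)
  nb <- vector("list", n)
  if (nrow(system$bonds))
    for (k in seq_len(nrow(system$bonds))) {
      i <- system$bonds[k, 1]; j <- system$bonds[k, 2]
      nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
    }
  nb
}

#' Assign docking atom types
#'
#' Closed five-way typing used by the empirical docking score: carbon bonded
#' only to carbon/hydrogen is `carbon_hydrophobic`; nitrogen with an attached
#' hydrogen is `polar_donor`; oxygen is `polar_acceptor`, or `donor_acceptor`
#' when it carries a hydrogen (hydroxyl); everything else is `other`. The
#' assignment is total: every atom receives a type.
#'
#' @param system a `molecular_system`; if it has no bonds they are first
#'   perceived with [perceive_bonds()].
#' @return The system with the `dock_type` atom column filled.
#' @export
assign_dock_types <- function(system) {
  if (!nrow(system$bonds) && n_atoms(system) > 1L)
    system <- perceive_bonds(system)
  nb <- .bond_neighbors(system)
  el <- system$atoms$element
  system$atoms$dock_type <- vapply(seq_along(el), function(i) {
    nbe <- el[nb[[i]]]
    switch(el[i],
           C = if (all(nbe %in% c("C", "H"))) "carbon_hydrophobic" else "other",
           N = if ("H" %in% nbe) "polar_donor" else "other",
           O = if ("H" %in% nbe) "donor_acceptor" else "polar_acceptor",
           "other")
  }, character(1))
  system
}

#' Read a per-atom parameter table
#'
#' CSV with columns `name,element,charge,lj_radius,lj_epsilon,mass,gb_radius`.
#' Rows are matched to atoms by `name` first, then by `element`.
#'
#' @param path CSV file path.
#' @return data.frame of parameters.
#' @export
read_param_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "element", "charge", "lj_radius", "lj_epsilon", "mass",
            "gb_radius")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("parameter table lacks columns: ",
                         paste(miss, collapse = ", "))
  tab
}

#' Apply a parameter table to a system
#' @param system a `molecular_system`.
#' @param table data.frame from [read_param_table()].
#' @return The system with matched per-atom parameters replaced.
#' @export
apply_param_table <- function(system, table) {
  a <- system$atoms
  idx <- match(a$name, table$name)
  fallback <- match(a$element, table$element)
  idx[is.na(idx)] <- fallback[is.na(idx)]
  hit <- !is.na(idx)
  for (col in c("charge", "lj_radius", "lj_epsilon", "mass", "gb_radius"))
    a[[col]][hit] <- table[[col]][idx[hit]]
  a$param_defaulted[hit] <- FALSE
  system$atoms <- a
  system
}
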