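# Single-configuration energetics: molecular-mechanics bonded and nonbonded
# terms, generalized-Born polar solvation with Debye ionic screening (OBC
# effective radii, Still pair function), and Shrake-Rupley solvent-accessible
# surface area with a linear surface-tension nonpolar term.

#' Implicit-solvent model parameters
#'
#' @param epsilon_s solvent dielectric constant (dimensionless, > 1).
#' @param ion_concentration monovalent salt concentration I in mol/L.
#' @param gamma surface tension for the nonpolar term, kcal mol^-1 A^-2.
#' @param probe_radius solvent probe radius for SASA, A.
#' @param temperature temperature in K.
#' @param sasa_points quadrature points per atom for SASA.
#' @return A `solvent_model` object.
#' @export
solvent_model <- function(epsilon_s = 78.5, ion_concentration = 0,
                          gamma = 0.005, probe_radius = 1.4,
                          temperature = 300, sasa_points = 960) {
  if (epsilon_s <= 1) stop("solvent dielectric must exceed 1")
  if (ion_concentration < 0) stop("ion concentration must be non-negative")
  if (gamma < 0) stop("surface tension must be non-negative")
  if (temperature <= 0) stop("temperature must be positive")
  structure(list(epsilon_s = epsilon_s, ion_concentration = ion_concentration,
                 gamma = gamma, probe_radius = probe_radius,
                 temperature = temperature, sasa_points = sasa_points),
            class = "solvent_model")
}

## --------------------------------------------------------------- MM -------

#' Harmonic bond parameters generated from the current geometry
#'
#' Convenience for toy systems: every listed bond gets a harmonic term with
#' its current length as the rest length, so the reference configuration has
#' zero bond energy.
#'
#' @param system a `molecular_system`.
#' @param k force constant, kcal mol^-1 A^-2.
#' @return A bonded-parameter list usable by [mm_energy()].
#' @export
auto_bond_params <- function(system, k = 300) {
  b <- system$bonds
  if (!nrow(b)) return(list(bonds = NULL, angles = NULL, dihedrals = NULL))
  xyz <- coords(system)
  r0 <- sqrt(rowSums((xyz[b[, 1], , drop = FALSE] -
                        xyz[b[, 2], , drop = FALSE])^2))
  list(bonds = data.frame(i = b[, 1], j = b[, 2], k = k, r0 = r0),
       angles = NULL, dihedrals = NULL)
}

.angle_rad <- function(xyz, i, j, k) {
  v1 <- xyz[i, ] - xyz[j, ]; v2 <- xyz[k, ] - xyz[j, ]
  acos(max(-1, min(1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))))
}

.dihedral_rad <- function(xyz, i, j, k, l) {
  b1 <- xyz[j, ] - xyz[i, ]; b2 <- xyz[k, ] - xyz[j, ]; b3 <- xyz[l, ] - xyz[k, ]
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

# 1-2 and 1-3 nonbonded exclusion mask (n x n logical, TRUE = excluded)
.exclusion_mask <- function(system) {
  n <- n_atoms(system)
  excl <- matrix(FALSE, n, n)
  b <- system$bonds
  if (nrow(b)) {
    excl[b] <- TRUE; excl[b[, 2:1, drop = FALSE]] <- TRUE
    nb <- .bond_neighbors(system)
    for (j in seq_len(n)) {
      nbs <- nb[[j]]
      if (length(nbs) > 1L)
        for (a in nbs) for (c in nbs) if (a != c) excl[a, c] <- TRUE
    }
  }
  diag(excl) <- TRUE
  excl
}

#' Molecular-mechanics energy of a configuration
#'
#' Harmonic bonds k(r - r0)^2 and angles k(theta - theta0)^2, cosine dihedrals
#' k(1 + cos(n phi - delta)), 12-6 Lennard-Jones with Lorentz-Berthelot
#' combining (`lj_radius` is Rmin/2), and Coulomb k_e qi qj / r with interior
#' dielectric 1. Nonbonded pairs exclude 1-2 and 1-3 neighbours.
#'
#' @param system a `molecular_system`.
#' @param params bonded-parameter list with data.frames `bonds` (i, j, k, r0),
#'   `angles` (i, j, k, k_theta, theta0 in degrees) and `dihedrals`
#'   (i, j, k, l, k_phi, n, delta in degrees); see [auto_bond_params()].
#'   Every bond listed in the system must have a parameter row.
#' @return List of class `energy_terms` with `e_bond`, `e_angle`,
#'   `e_dihedral`, `e_lj`, `e_coulomb` and their sum `total_mm` (kcal/mol).
#' @export
mm_energy <- function(system, params = auto_bond_params(system)) {
  xyz <- coords(system)
  n <- nrow(xyz)
  e_bond <- e_angle <- e_dih <- 0
  if (nrow(system$bonds)) {
    pb <- params$bonds
    if (is.null(pb)) stop("missing parameter: no bond parameters supplied")
    key <- function(i, j) paste(pmin(i, j), pmax(i, j))
    pk <- key(pb$i, pb$j)
    sk <- key(system$bonds[, 1], system$bonds[, 2])
    lost <- setdiff(sk, pk)
    if (length(lost))
      stop("missing parameter for bond ", lost[1])
  }
  if (!is.null(params$bonds) && nrow(params$bonds)) {
    pb <- params$bonds
    r <- sqrt(rowSums((xyz[pb$i, , drop = FALSE] - xyz[pb$j, , drop = FALSE])^2))
    e_bond <- sum(pb$k * (r - pb$r0)^2)
  }
  if (!is.null(params$angles) && nrow(params$angles)) {
    pa <- params$angles
    th <- vapply(seq_len(nrow(pa)),
                 function(m) .angle_rad(xyz, pa$i[m], pa$j[m], pa$k[m]),
                 numeric(1))
    e_angle <- sum(pa$k_theta * (th - pa$theta0 * pi / 180)^2)
  }
  if (!is.null(params$dihedrals) && nrow(params$dihedrals)) {
    pd <- params$dihedrals
    ph <- vapply(seq_len(nrow(pd)),
                 function(m) .dihedral_rad(xyz, pd$i[m], pd$j[m], pd$k[m], pd$l[m]),
                 numeric(1))
    e_dih <- sum(pd$k_phi * (1 + cos(pd$n * ph - pd$delta * pi / 180)))
  }
  e_lj <- e_coul <- 0
  if (n > 1L) {
    d <- as.matrix(stats::dist(xyz))
    excl <- .exclusion_mask(system)
    use <- upper.tri(d) & !excl
    if (any(use)) {
      if (any(d[use] == 0)) stop("overlapping atoms in nonbonded pair")
      a <- system$atoms
      rmin <- outer(a$lj_radius, a$lj_radius, "+")
      eps <- sqrt(outer(a$lj_epsilon, a$lj_epsilon))
      x6 <- (rmin / d)^6
      e_lj <- sum((eps * (x6^2 - 2 * x6))[use])
      qq <- outer(a$charge, a$charge)
      e_coul <- sum((.ls_const$k_e * qq / d)[use])
    }
  }
  terms <- list(e_bond = e_bond, e_angle = e_angle, e_dihedral = e_dih,
                e_lj = e_lj, e_coulomb = e_coul)
  terms$total_mm <- e_bond + e_angle + e_dih + e_lj + e_coul
  structure(terms, class = "energy_terms")
}

## ------------------------------------------------------- Born radii -------

# HCT pairwise descreening integral of atom j (scaled radius sr at distance r)
# over the solvent-excluded region seen from atom i of intrinsic radius rho.
.hct_integral <- function(rho, r, sr) {
  out <- numeric(length(r))
  act <- (rho < r + sr)
  if (any(act)) {
    rr <- r[act]; ss <- sr[act]
    L <- pmax(abs(rr - ss), rho)
    U <- rr + ss
    h <- 0.5 * (1 / L - 1 / U + (rr - ss^2 / rr) / 4 * (1 / U^2 - 1 / L^2) +
                  1 / (2 * rr) * log(L / U))
    inside <- rho < (ss - rr)
    h[inside] <- h[inside] + (1 / rho - 1 / L[inside])
    out[act] <- h
  }
  out
}

#' Effective Born radii
#'
#' Pairwise-descreening effective radii with the tanh rescaling of Onufriev,
#' Bashford and Case (coefficients 1.0, 0.8, 4.85). The per-atom `gb_radius`
#' is used directly as the intrinsic radius, so an isolated atom's effective
#' radius equals its intrinsic radius exactly; burial only ever increases the
#' effective radius.
#'
#' @param system a `molecular_system` with `gb_radius` set.
#' @param scale uniform descreening scale factor applied to neighbour radii.
#' @return Numeric vector of effective Born radii (A), one per atom.
#' @export
born_radii <- function(system, scale = 0.8) {
  rho <- system$atoms$gb_radius
  if (any(rho <= 0)) stop("intrinsic Born radii must be positive")
  n <- length(rho)
  if (n == 1L) return(rho)
  xyz <- coords(system)
  d <- as.matrix(stats::dist(xyz))
  alpha <- numeric(n)
  for (i in seq_len(n)) {
    r <- d[i, -i]; sr <- scale * rho[-i]
    I <- sum(.hct_integral(rho[i], r, sr))
    psi <- rho[i] * I
    inv <- 1 / rho[i] - tanh(psi - 0.8 * psi^2 + 4.85 * psi^3) / rho[i]
    alpha[i] <- if (inv <= 1e-6) 1e6 else 1 / inv
  }
  alpha
}

#' Still pair function
#'
#' Effective interaction distance g = sqrt(r^2 + ai aj exp(-r^2 / (4 ai aj)))
#' interpolating between the Born self term (g -> sqrt(ai aj) at r = 0) and
#' plain Coulomb behaviour (g -> r at large separation).
#'
#' @param r distance(s), A.
#' @param alpha_i,alpha_j effective Born radii, A.
#' @return g in A, vectorized.
#' @export
still_g <- function(r, alpha_i, alpha_j) {
  if (any(alpha_i <= 0) || any(alpha_j <= 0)) stop("Born radii must be positive")
  if (any(r < 0)) stop("distance must be non-negative")
  aa <- alpha_i * alpha_j
  sqrt(r^2 + aa * exp(-r^2 / (4 * aa)))
}

#' Inverse Debye screening length
#'
#' kappa = sqrt(8 pi k_e n / (eps_s k_B T)) in A^-1, with the ion
#' concentration converted from mol/L to an A^-3 number density. Zero salt
#' gives kappa = 0 (no screening).
#'
#' @param model a [solvent_model()].
#' @return kappa in A^-1.
#' @export
debye_kappa <- function(model) {
  if (model$ion_concentration == 0) return(0)
  n_dens <- model$ion_concentration * .ls_const$molar_to_per_A3
  sqrt(8 * pi * .ls_const$k_e * n_dens /
         (model$epsilon_s * .ls_const$k_B * model$temperature))
}

#' Generalized-Born polar solvation energy
#'
#' G_polar = -(k_e / 2) sum_ij D_ij qi qj / g_ij over the full double sum
#' (self terms i = j included), with the screening factor
#' D_ij = 1 - exp(-kappa g_ij) / eps_s. With kappa = 0 and a single unit
#' charge this reduces to the Born ion -(k_e/2)(1 - 1/eps_s)/alpha.
#'
#' @param system a `molecular_system`.
#' @param alphas effective Born radii for this configuration; computed with
#'   [born_radii()] when omitted.
#' @param model a [solvent_model()].
#' @return G_polar in kcal/mol.
#' @export
gb_polar_energy <- function(system, alphas = born_radii(system),
                            model = solvent_model()) {
  q <- system$atoms$charge
  if (all(q == 0)) return(0)
  n <- length(q)
  xyz <- coords(system)
  d <- if (n > 1L) as.matrix(stats::dist(xyz)) else matrix(0, 1, 1)
  g <- still_g(d, matrix(alphas, n, n), matrix(alphas, n, n, byrow = TRUE))
  kap <- debye_kappa(model)
  D <- 1 - exp(-kap * g) / model$epsilon_s
  -(.ls_const$k_e / 2) * sum(D * outer(q, q) / g)
}

## ------------------------------------------------------------- SASA -------

# deterministic Fibonacci-lattice points on the unit sphere
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Numeric SASA with a fixed deterministic sphere quadrature: points are laid
#' on each atom's solvent-expanded sphere (vdW radius + probe) and counted as
#' accessible when outside every neighbour's expanded sphere.
#'
#' @param system a `molecular_system` with `lj_radius` set.
#' @param probe_radius probe radius in A.
#' @param n_points quadrature points per atom.
#' @return Total SASA in A^2.
#' @export
sasa <- function(system, probe_radius = 1.4, n_points = 960) {
  xyz <- coords(system)
  n <- nrow(xyz)
  R <- system$atoms$lj_radius + probe_radius
  pts <- .sphere_points(n_points)
  if (n == 1L) return(4 * pi * R^2)
  d <- as.matrix(stats::dist(xyz))
  total <- 0
  for (i in seq_len(n)) {
    nbr <- which(d[i, ] < (R[i] + R) & seq_len(n) != i)
    p <- sweep(pts * R[i], 2, xyz[i, ], "+")
    if (length(nbr)) {
      buried <- rep(FALSE, n_points)
      for (j in nbr) {
        dj2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
          (p[, 3] - xyz[j, 3])^2
        buried <- buried | (dj2 < R[j]^2)
        if (all(buried)) break
      }
      frac <- mean(!buried)
    } else frac <- 1
    total <- total + 4 * pi * R[i]^2 * frac
  }
  total
}

#' Nonpolar solvation energy
#'
#' Linear surface-area model G_nonpolar = gamma * A_SA.
#'
#' @param area SASA in A^2 (non-negative).
#' @param model a [solvent_model()] supplying gamma.
#' @return G_nonpolar in kcal/mol.
#' @export
nonpolar_energy <- function(area, model = solvent_model()) {
  if (any(area < 0)) stop("area must be non-negative")
  model$gamma * area
}

#' Full single-configuration energy decomposition
#'
#' Combines [mm_energy()], [gb_polar_energy()] and the SASA nonpolar term for
#' one configuration.
#'
#' @param system a `molecular_system`.
#' @param params bonded parameters (see [mm_energy()]).
#' @param model a [solvent_model()].
#' @return `energy_terms` list extended with `g_polar` and `g_nonpolar`.
#' @export
configuration_energy <- function(system, params = auto_bond_params(system),
                                 model = solvent_model()) {
  terms <- mm_energy(system, params)
  terms$g_polar <- gb_polar_energy(system, model = model)
  terms$g_nonpolar <- nonpolar_energy(
    sasa(system, model$probe_radius, model$sasa_points), model)
  terms
}
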