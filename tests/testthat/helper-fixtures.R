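# Shared fixture builders. Everything is generated in code; no binary files.

# minimal n-atom system on the x-axis
axis_system <- function(x, element = "C", charge = 0, lj_radius = 1.7,
                        lj_epsilon = 0.1, gb_radius = 1.7, mass = 12.011,
                        bonds = NULL, role = "ligand") {
  n <- length(x)
  molecular_system(
    data.frame(element = rep_len(element, n), x = x, y = 0, z = 0,
               charge = rep_len(charge, n),
               lj_radius = rep_len(lj_radius, n),
               lj_epsilon = rep_len(lj_epsilon, n),
               gb_radius = rep_len(gb_radius, n),
               mass = rep_len(mass, n),
               role = rep_len(role, n), stringsAsFactors = FALSE),
    bonds)
}

# single typed atom at a position
typed_atom <- function(xyz = c(0, 0, 0), element = "C", lj_radius = 1.7,
                       role = "ligand") {
  assign_dock_types(molecular_system(
    data.frame(element = element, x = xyz[1], y = xyz[2], z = xyz[3],
               lj_radius = lj_radius, role = role, stringsAsFactors = FALSE)))
}

# random rotation matrix
random_rotation <- function() {
  v <- stats::rnorm(3); v <- v / sqrt(sum(v^2))
  th <- stats::runif(1, 0, pi)
  K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

# 1-D toy dimer for the alchemical cycle: one fixed receptor atom at the
# origin, one ligand atom on the x-axis confined to [1, 8], LJ well depth
# `eps` at contact distance 3 A
dimer_fep_system <- function(eps = 2.0, restraint_k = 1) {
  rec <- axis_system(0, lj_radius = 1.5, lj_epsilon = eps, role = "receptor")
  lig <- axis_system(3, lj_radius = 1.5, lj_epsilon = eps)
  box <- rbind(c(1, -1e-9, -1e-9), c(8, 1e-9, 1e-9))
  rs <- restraint("distance", anchor_atoms = 1, target = 3,
                  force_constant = restraint_k)
  fep_system(lig, rec, restraints = list(rs), box = box)
}

# direct quadrature of the dimer's binding free energy over the same box
dimer_direct_dg <- function(eps = 2.0, temperature = 300) {
  kT <- ls_constants()$k_B * temperature
  U <- function(x) { x6 <- (3 / x)^6; eps * (x6^2 - 2 * x6) }
  Zb <- stats::integrate(function(x) exp(-U(x) / kT), 1, 8,
                         rel.tol = 1e-10)$value
  -kT * log(Zb / 7)
}
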