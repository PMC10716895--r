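test_that("MM terms match their closed forms", {
  # two neutral atoms at the LJ minimum: e_lj = -sqrt(eps_i eps_j)
  sys <- axis_system(c(0, 3.4), lj_epsilon = c(0.2, 0.3), charge = 0)
  expect_equal(mm_energy(sys)$e_lj, -sqrt(0.2 * 0.3), tolerance = 1e-12)
  # bond at rest length contributes nothing
  b <- axis_system(c(0, 1.5), bonds = rbind(c(1, 2)))
  expect_equal(mm_energy(b, auto_bond_params(b))$e_bond, 0)
  # opposite unit charges at k_e/100 A give exactly -100 kcal/mol
  q <- axis_system(c(0, 3.320636), charge = c(1, -1), lj_epsilon = 0)
  expect_equal(mm_energy(q)$e_coulomb, -100, tolerance = 1e-4)
  # total_mm is the sum of its parts
  e <- mm_energy(q)
  expect_equal(e$total_mm,
               e$e_bond + e$e_angle + e$e_dihedral + e$e_lj + e$e_coulomb,
               tolerance = 1e-9)
})

test_that("bonded terms use supplied parameters and report missing ones", {
  sys <- axis_system(c(0, 1.5, 3.0), bonds = rbind(c(1, 2), c(2, 3)))
  pars <- list(bonds = data.frame(i = 1, j = 2, k = 300, r0 = 1.5))
  expect_error(mm_energy(sys, pars), "missing parameter")
  # harmonic angle at its rest value is zero; displaced it is k (dtheta)^2
  tri <- molecular_system(
    data.frame(element = "C", x = c(1.5, 0, 0), y = c(0, 0, 1.5), z = 0),
    bonds = rbind(c(1, 2), c(2, 3)))
  pars <- auto_bond_params(tri)
  pars$angles <- data.frame(i = 1, j = 2, k = 3, k_theta = 50, theta0 = 90)
  expect_equal(mm_energy(tri, pars)$e_angle, 0, tolerance = 1e-12)
  pars$angles$theta0 <- 60
  expect_equal(mm_energy(tri, pars)$e_angle, 50 * (pi / 6)^2,
               tolerance = 1e-9)
})

test_that("1-2 and 1-3 pairs are excluded from nonbonded sums", {
  sys <- axis_system(c(0, 1.0, 2.0), charge = 1, lj_epsilon = 0,
                     bonds = rbind(c(1, 2), c(2, 3)))
  # atoms 1-3 are a 1-3 pair through the chain: no Coulomb at all
  expect_equal(mm_energy(sys, auto_bond_params(sys))$e_coulomb, 0)
})

test_that("effective Born radii: isolated, symmetric and buried atoms", {
  one <- axis_system(0, gb_radius = 1.5)
  expect_equal(born_radii(one), 1.5, tolerance = 1e-6)
  two <- axis_system(c(0, 3), gb_radius = 1.5)
  a <- born_radii(two)
  expect_equal(a[1], a[2], tolerance = 1e-12)
  expect_gt(a[1], 1.5)  # descreening by the neighbour
  # an atom buried in a dense shell has a larger radius than when isolated
  sph <- ligscreen:::.sphere_points(30) * 2.5
  buried <- molecular_system(
    data.frame(element = "C", x = c(0, sph[, 1]), y = c(0, sph[, 2]),
               z = c(0, sph[, 3]), gb_radius = 1.5))
  expect_gt(born_radii(buried)[1], born_radii(two)[1])
  bad <- axis_system(0); bad$atoms$gb_radius <- -1
  expect_error(born_radii(bad), "positive")
})

test_that("Still pair function interpolates between Born and Coulomb limits", {
  expect_equal(still_g(0, 2, 2), 2.0, tolerance = 1e-12)
  expect_equal(still_g(2, 2, 2), sqrt(4 + 4 * exp(-0.25)), tolerance = 1e-12)
  expect_equal(still_g(50, 2, 2), 50, tolerance = 1e-3)
})

test_that("Debye screening: zero salt, physiological length, monotonicity", {
  expect_equal(debye_kappa(solvent_model(ion_concentration = 0)), 0)
  kap <- debye_kappa(solvent_model(ion_concentration = 0.1, temperature = 300))
  expect_gt(1 / kap, 9); expect_lt(1 / kap, 11)
  kaps <- vapply(c(0.01, 0.05, 0.1, 0.5),
                 function(I) debye_kappa(solvent_model(ion_concentration = I)),
                 numeric(1))
  expect_true(all(diff(kaps) > 0))
})

test_that("GB polar energy recovers the Born ion and its limits", {
  ion <- axis_system(0, charge = 1, gb_radius = 2)
  k_e <- ls_constants()$k_e
  expect_equal(gb_polar_energy(ion, alphas = 2, model = solvent_model()),
               -(k_e / 2) * (1 - 1 / 78.5) / 2, tolerance = 1e-6)
  # no charges, no polar energy
  expect_equal(gb_polar_energy(axis_system(c(0, 3))), 0)
  # no dielectric contrast, (almost) no energy
  expect_lt(abs(gb_polar_energy(ion, alphas = 2,
                                model = solvent_model(epsilon_s = 1 + 1e-9))),
            1e-7)
  # any single-charge system solvates favourably
  expect_lt(gb_polar_energy(ion, alphas = 2), 0)
})

test_that("screened pair interaction approaches k_e q1 q2 / (eps r) at large r", {
  sys <- axis_system(c(0, 50), charge = c(1, 1), lj_epsilon = 0,
                     gb_radius = 1.5)
  model <- solvent_model()
  alphas <- born_radii(sys)
  e_coul <- mm_energy(sys)$e_coulomb
  # cross GB term only (subtract the distance-independent self terms)
  self <- sum(vapply(1:2, function(i) {
    one <- axis_system(0, charge = 1, gb_radius = 1.5)
    gb_polar_energy(one, alphas = alphas[i], model = model)
  }, numeric(1)))
  cross <- gb_polar_energy(sys, alphas, model) - self
  target <- ls_constants()$k_e / (78.5 * 50)
  expect_equal(e_coul + cross, target, tolerance = 0.01 * target)
})

test_that("Shrake-Rupley SASA: sphere, burial, additivity and convergence", {
  one <- axis_system(0, lj_radius = 1.5)
  expect_equal(sasa(one, 1.4), 4 * pi * 2.9^2, tolerance = 0.01)
  # an atom enclosed in a tight shell is inaccessible
  sph <- ligscreen:::.sphere_points(40) * 2.0
  shell <- molecular_system(
    data.frame(element = "C", x = c(0, sph[, 1]), y = c(0, sph[, 2]),
               z = c(0, sph[, 3]), lj_radius = 1.5))
  inner <- molecular_system(shell$atoms[1, , drop = FALSE])
  # total shell SASA minus the shell-only SASA: the central atom adds ~0
  shell_only <- molecular_system(shell$atoms[-1, , drop = FALSE])
  expect_lt(sasa(shell) - sasa(shell_only), 1e-6)
  # far-separated atoms are additive
  two <- axis_system(c(0, 100), lj_radius = 1.5)
  expect_equal(sasa(two), 2 * sasa(one), tolerance = 1e-9)
  # doubling the quadrature changes a small cluster by < 0.5%
  set.seed(8)
  cl <- molecular_system(data.frame(element = "C", x = rnorm(5, sd = 1.5),
                                    y = rnorm(5, sd = 1.5),
                                    z = rnorm(5, sd = 1.5), lj_radius = 1.7))
  a1 <- sasa(cl, n_points = 960); a2 <- sasa(cl, n_points = 1920)
  expect_lt(abs(a1 - a2) / a2, 0.005)
})

test_that("nonpolar energy is gamma times area", {
  m <- solvent_model(gamma = 0.005)
  expect_equal(nonpolar_energy(100, m), 0.5)
  expect_equal(nonpolar_energy(0, m), 0)
  expect_equal(nonpolar_energy(200, m), 2 * nonpolar_energy(100, m))
  expect_error(nonpolar_energy(-1, m), "non-negative")
})
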