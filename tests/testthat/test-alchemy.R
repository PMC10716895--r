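test_that("lambda schedules enforce endpoints and monotonicity", {
  s <- lambda_schedule(5)
  expect_equal(as.numeric(s), c(0, 0.25, 0.5, 0.75, 1))
  expect_error(lambda_schedule(1), "at least 2")
  expect_error(lambda_schedule(c(0, 0.5, 0.9)), "endpoints")
  expect_error(lambda_schedule(c(0, 0.5, 0.5, 1)), "increasing")
})

test_that("Zwanzig increments: constant integrand, Gaussian identity, Jensen bound", {
  kT <- ls_constants()$k_B * 300
  expect_equal(zwanzig_increment(rep(2.5, 100), 300), 2.5, tolerance = 1e-12)
  expect_error(zwanzig_increment(numeric(0), 300), "samples")
  # Gaussian closed form: dG = mu - sigma^2 / (2 kT)
  du <- gaussian_du(1.0, sqrt(0.5), 1e5, seed = 11)
  expect_equal(zwanzig_increment(du, 300), 1.0 - 0.5 / (2 * kT),
               tolerance = 0.02)
  # Jensen: dG <= mean(dU), for any sample
  for (s in 1:5) {
    x <- gaussian_du(0.3, 1.7, 500, seed = s)
    expect_lte(zwanzig_increment(x, 300), mean(x))
  }
  # convergence improves with sample size (n^-1/2 scaling, checked loosely)
  truth <- 1.0 - 0.5 / (2 * kT)
  err <- vapply(c(1e3, 1e5), function(n)
    abs(zwanzig_increment(gaussian_du(1, sqrt(0.5), n, seed = 4), 300) - truth),
    numeric(1))
  expect_lt(err[2], err[1])
})

test_that("window sums are plain arithmetic", {
  expect_equal(sum_windows(c(1.0, -0.5, 0.25)), 0.75)
  expect_equal(sum_windows(numeric(0)), 0)
})

test_that("the coupled potential has correct endpoints and stays finite", {
  fsys <- dimer_fep_system(eps = 2.0)
  st <- c(3, 0, 0)
  # lambda = 0, no restraints: the full physical interaction (LJ well depth)
  expect_equal(coupled_potential(fsys, st, 0, 0), -2.0, tolerance = 1e-9)
  # lambda = 1: ligand annihilated, only restraints remain
  expect_equal(coupled_potential(fsys, st, 1, 0), 0, tolerance = 1e-12)
  expect_equal(coupled_potential(fsys, st, 1, 1),
               1 * (3 - 3)^2, tolerance = 1e-12)
  # restraint energy at displaced centroid
  expect_equal(coupled_potential(fsys, c(4, 0, 0), 1, 1), 1 * 1^2,
               tolerance = 1e-9)
  # overlapping atoms remain finite near full decoupling (soft core);
  # use an unconfined copy so the clash sits inside the allowed region
  fs_open <- fep_system(axis_system(3, lj_radius = 1.5, lj_epsilon = 2),
                        axis_system(0, lj_radius = 1.5, lj_epsilon = 2,
                                    role = "receptor"))
  u_sc <- coupled_potential(fs_open, c(0.3, 0, 0), 0.999, 0)
  expect_true(is.finite(u_sc))
  expect_lt(abs(u_sc), 50)  # soft core caps the clash
  # the physical (lambda = 0) potential at the same clash is astronomically steep
  expect_gt(coupled_potential(fs_open, c(0.3, 0, 0), 0, 0), 1e6)
  # outside the confinement box the move is forbidden
  expect_identical(coupled_potential(fsys, c(9, 0, 0), 0, 0), Inf)
  expect_error(coupled_potential(fsys, st, 1.5, 0), "\\[0, 1\\]")
})

test_that("Metropolis sampling reproduces Boltzmann statistics deterministically", {
  k <- 2
  pot <- function(x) 0.5 * k * x^2
  ch <- metropolis_sample(pot, 0, 3e4, 0.5, 300, seed = 2)
  expect_equal(var(ch$states[, 1]), ls_constants()$k_B * 300 / k,
               tolerance = 0.05)
  expect_gt(ch$acceptance_rate, 0.2)
  # zero steps returns only the initial state
  ch0 <- metropolis_sample(pot, c(1, 2), 0, 0.1, 300, seed = 1)
  expect_equal(ch0$states, matrix(c(1, 2), 1))
  # same seed, same chain
  ch1 <- metropolis_sample(pot, 0, 100, 0.5, 300, seed = 7)
  ch2 <- metropolis_sample(pot, 0, 100, 0.5, 300, seed = 7)
  expect_identical(ch1$states, ch2$states)
})

test_that("null transformations and zero-force restraints cost nothing", {
  # ligand alone (unbound): decoupling changes nothing
  lig <- axis_system(0, lj_epsilon = 0.2)
  fsys <- fep_system(lig, receptor = NULL, bound = FALSE)
  leg <- run_leg(fsys, "unbound_decouple", lambda_schedule(4),
                 n_steps = 100, seed = 3)
  expect_equal(leg$total, 0, tolerance = 1e-9)
  expect_equal(leg$backward_total, 0, tolerance = 1e-9)
  # a restraint with zero force constant contributes nothing in any window
  fsys2 <- dimer_fep_system(restraint_k = 0)
  leg2 <- run_leg(fsys2, "unbound_restrain", lambda_schedule(4),
                  n_steps = 100, step_size = c(0.3, 0, 0), seed = 3)
  expect_equal(leg2$total, 0, tolerance = 1e-9)
  expect_error(run_leg(fsys2, "bound_decouple", lambda_schedule(c(0, 1))[1],
                       n_steps = 10), "at least 2|unknown")
})

test_that("leg bookkeeping: totals are window sums and the cycle needs all four legs", {
  fsys <- dimer_fep_system()
  leg <- run_leg(fsys, "bound_decouple", lambda_schedule(5), n_steps = 200,
                 step_size = c(0.3, 0, 0), seed = 5)
  expect_equal(leg$total, sum(leg$per_window_dg), tolerance = 1e-9)
  expect_equal(leg$hysteresis, abs(leg$total + leg$backward_total),
               tolerance = 1e-12)
  zero_leg <- function(nm) structure(
    list(name = nm, per_window_dg = 0, total = 0, backward_per_window = 0,
         backward_total = 0, combined = 0, hysteresis = 0, se = 0),
    class = "fep_leg")
  legs <- lapply(c("bound_restrain", "bound_decouple", "unbound_decouple",
                   "unbound_restrain"), zero_leg)
  names(legs) <- vapply(legs, `[[`, "", "name")
  res <- binding_dg_from_cycle(legs)
  expect_equal(res$delta_g_binding, 0)
  expect_error(binding_dg_from_cycle(legs[-2]), "missing leg")
})
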