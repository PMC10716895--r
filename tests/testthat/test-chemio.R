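test_that("XYZ structures parse and round-trip", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("3", "water-ish toy", "O 0.0 0.0 0.0", "H 0.96 0.0 0.0",
               "H -0.24 0.93 0.0"), f)
  sys <- read_structure(f)
  expect_equal(n_atoms(sys), 3L)
  expect_equal(sys$atoms$element, c("O", "H", "H"))
  expect_equal(coords(sys)[2, 1], 0.96)

  out <- withr::local_tempfile(fileext = ".xyz")
  write_structure(sys, out)
  back <- read_structure(out)
  expect_equal(back$atoms$element, sys$atoms$element)
  expect_equal(coords(back), coords(sys), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("empty or malformed files raise format errors", {
  f <- withr::local_tempfile(fileext = ".xyz")
  file.create(f)
  expect_error(read_structure(f), "empty structure")
  writeLines(c("2", "x", "C 0 0 0"), f)
  expect_error(read_structure(f), "truncated|format")
  writeLines(c("1", "x", "C a b c"), f)
  expect_error(read_structure(f), "format error")
})

test_that("multi-MODEL PDB reads as first model with a warning", {
  sys <- axis_system(c(0, 1.5, 3.0))
  traj <- trajectory(sys, list(coords(sys), coords(sys) + 0.5), 300)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(traj, f)
  expect_warning(first <- read_structure(f), "MODEL")
  expect_equal(n_atoms(first), 3L)
  expect_equal(coords(first), coords(sys), tolerance = 1e-3,
               ignore_attr = TRUE)
})

test_that("structure PDB round trip preserves order, elements and coordinates", {
  set.seed(21)
  xyz <- matrix(rnorm(12, sd = 4), 4, 3)
  sys <- molecular_system(
    data.frame(element = c("C", "N", "O", "S"), x = xyz[, 1], y = xyz[, 2],
               z = xyz[, 3]), bonds = rbind(c(1, 2), c(2, 3)))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(sys, f)
  back <- read_structure(f)
  expect_equal(back$atoms$element, sys$atoms$element)
  expect_equal(coords(back), coords(sys), tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_equal(nrow(back$bonds), 2L)  # CONECT records survive
})

test_that("trajectory I/O keeps frame order and flags atom-count mismatches", {
  sys <- axis_system(c(0, 1.5, 3.0, 4.5))
  frames <- lapply(1:5, function(i) coords(sys) + i * 0.1)
  traj <- trajectory(sys, frames, 310)
  for (ext in c(".pdb", ".xyz")) {
    f <- withr::local_tempfile(fileext = ext)
    write_trajectory(traj, f)
    back <- read_trajectory(f, sys, temperature = 310)
    expect_equal(n_frames(back), 5L)
    for (i in 1:5)
      expect_equal(back$frames[[i]], frames[[i]], tolerance = 1e-3,
                   ignore_attr = TRUE)
  }
  # frame 3 with one atom missing is named in the error
  f <- withr::local_tempfile(fileext = ".xyz")
  blocks <- vapply(1:5, function(i) {
    n <- if (i == 3) 3L else 4L
    paste(c(n, paste("frame", i),
            sprintf("C %f 0 0", seq_len(n))), collapse = "\n")
  }, character(1))
  writeLines(blocks, f)
  expect_error(read_trajectory(f, sys), "frame 3")
})

test_that("mol2 ATOM/BOND records parse with charges", {
  f <- withr::local_tempfile(fileext = ".mol2")
  writeLines(c("@<TRIPOS>MOLECULE", "toy", " 3 2 0 0 0", "SMALL",
               "USER_CHARGES",
               "@<TRIPOS>ATOM",
               "1 C1 0.0 0.0 0.0 C.3 1 LIG -0.10",
               "2 O1 1.4 0.0 0.0 O.3 1 LIG -0.40",
               "3 H1 2.0 0.8 0.0 H   1 LIG  0.50",
               "@<TRIPOS>BOND", "1 1 2 1", "2 2 3 1"), f)
  sys <- read_structure(f)
  expect_equal(sys$atoms$element, c("C", "O", "H"))
  expect_equal(sys$atoms$charge, c(-0.1, -0.4, 0.5))
  expect_equal(nrow(sys$bonds), 2L)
})

test_that("dock typing is total, deterministic and follows the chemistry rules", {
  # methane: C bonded only to H
  methane <- molecular_system(
    data.frame(element = c("C", "H", "H", "H", "H"),
               x = c(0, 1.09, -1.09, 0, 0), y = c(0, 0, 0, 1.09, -1.09),
               z = 0),
    bonds = cbind(1, 2:5))
  expect_equal(assign_dock_types(methane)$atoms$dock_type[1],
               "carbon_hydrophobic")
  # carbonyl O (no H) vs hydroxyl O (bonded H); amine N; C next to O; metal
  sys <- molecular_system(
    data.frame(element = c("C", "O", "O", "H", "N", "H", "Fe"),
               x = c(0, 1.2, 3, 3.9, 6, 6.9, 9), y = 0, z = 0),
    bonds = rbind(c(1, 2), c(3, 4), c(5, 6)))
  ty <- assign_dock_types(sys)$atoms$dock_type
  expect_equal(ty, c("other",            # carbon bonded to O
                     "polar_acceptor",   # carbonyl oxygen
                     "donor_acceptor",   # hydroxyl oxygen
                     "other", "polar_donor", "other", "other"))
  expect_false(anyNA(ty))
  expect_identical(ty, assign_dock_types(sys)$atoms$dock_type)
})

test_that("missing per-atom parameters default from the element table and are flagged", {
  sys <- molecular_system(data.frame(element = c("C", "Zz"), x = c(0, 3),
                                     y = 0, z = 0))
  expect_true(all(sys$atoms$param_defaulted))
  expect_equal(sys$atoms$mass[1], 12.011)
  expect_equal(sys$atoms$lj_radius[1], 1.7)
  # unknown element still gets usable defaults
  expect_true(sys$atoms$gb_radius[2] > 0)

  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,element,charge,lj_radius,lj_epsilon,mass,gb_radius",
               "C1,C,-0.2,1.8,0.12,12.011,1.6"), f)
  tab <- read_param_table(f)
  sys2 <- apply_param_table(sys, tab)
  expect_equal(sys2$atoms$charge[1], -0.2)
  expect_equal(sys2$atoms$lj_radius[1], 1.8)
  expect_false(sys2$atoms$param_defaulted[1])
  expect_true(sys2$atoms$param_defaulted[2])
})

test_that("system and trajectory invariants are enforced", {
  expect_error(molecular_system(data.frame()), "empty structure")
  expect_error(axis_system(c(0, 1), bonds = rbind(c(1, 3))), "out of range")
  expect_error(axis_system(c(0, 1), bonds = rbind(c(1, 1))), "itself")
  expect_error(axis_system(c(0, 1), bonds = rbind(c(1, 2), c(2, 1))),
               "duplicate")
  sys <- axis_system(c(0, 1.5))
  expect_error(trajectory(sys, list(matrix(0, 3, 3))), "3 atoms")
  expect_error(trajectory(sys, list(), 300), "at least one frame")
  expect_error(trajectory(sys, list(coords(sys)), -5), "positive")
})
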