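test_that("Kabsch alignment removes rigid-body motion exactly", {
  set.seed(11)
  base <- matrix(rnorm(15, sd = 2), 5, 3)
  sys <- molecular_system(data.frame(element = "C", x = base[, 1],
                                     y = base[, 2], z = base[, 3]))
  # identical frames stay identical
  tr0 <- trajectory(sys, list(base, base, base))
  al0 <- kabsch_align(tr0)
  expect_equal(al0$frames[[2]], base, tolerance = 1e-12, ignore_attr = TRUE)
  # frames differing by random rigid transforms collapse to zero covariance
  frames <- lapply(1:8, function(i)
    sweep(base %*% t(random_rotation()), 2, rnorm(3, sd = 5), "+"))
  al <- kabsch_align(trajectory(sys, frames))
  expect_lt(max(abs(covariance_matrix(al))), 1e-10)
})

test_that("alignment agrees with an independent least-squares superposition", {
  set.seed(12)
  base <- matrix(rnorm(18, sd = 3), 6, 3)
  sys <- molecular_system(data.frame(element = "C", x = base[, 1],
                                     y = base[, 2], z = base[, 3]))
  moved <- sweep((base + matrix(rnorm(18, sd = 0.3), 6, 3)) %*%
                   t(random_rotation()), 2, c(4, -2, 1), "+")
  al <- kabsch_align(trajectory(sys, list(base, moved)))
  ours <- al$frames[[2]]
  ref <- suppressWarnings(  # bio3d warns about its default fitting subset
    bio3d::fit.xyz(fixed = as.vector(t(base)),
                   mobile = matrix(as.vector(t(moved)), nrow = 1)))
  expect_equal(ours, matrix(ref, ncol = 3, byrow = TRUE), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("under-determined selections fall back to translation-only with a warning", {
  sys <- axis_system(c(0, 1.5, 3, 4.5))
  frames <- list(coords(sys), coords(sys) + 2)
  expect_warning(al <- kabsch_align(trajectory(sys, frames), selection = 1:2),
                 "translation-only")
  expect_equal(al$frames[[2]], al$frames[[1]], tolerance = 1e-12)
})

test_that("coordinate covariance matches hand calculations", {
  sys <- axis_system(0)
  # one atom mirrored at +/- a on x: sigma_xx = a^2, everything else 0
  a <- 1.3
  tr <- trajectory(sys, list(matrix(c(a, 0, 0), 1), matrix(c(-a, 0, 0), 1)))
  sg <- covariance_matrix(tr)
  expect_equal(sg[1, 1], a^2, tolerance = 1e-12)
  expect_equal(sum(abs(sg)) - abs(sg[1, 1]), 0, tolerance = 1e-12)
  # identical frames give the zero matrix; single frames are an error
  tr2 <- trajectory(sys, list(matrix(0, 1, 3), matrix(0, 1, 3)))
  expect_equal(max(abs(covariance_matrix(tr2))), 0)
  expect_error(covariance_matrix(trajectory(sys, list(matrix(0, 1, 3)))),
               "single frame")
  # symmetric by construction
  set.seed(3)
  tr3 <- harmonic_trajectory(axis_system(c(0, 2)), k = 5, n_frames = 50)
  sg3 <- covariance_matrix(tr3)
  expect_lt(max(abs(sg3 - t(sg3))), 1e-12)
})

test_that("quasiharmonic frequencies recover the analytic oscillator", {
  sys <- axis_system(0, mass = 12.011)
  k <- c(1, 50, 200)
  tr <- harmonic_trajectory(sys, k = k, temperature = 300, n_frames = 1e4,
                            seed = 3)
  sp <- quasiharmonic_frequencies(covariance_matrix(tr), 12.011, 300)
  omega_true <- sort(sqrt(k * ls_constants()$kcal_to_amuA2ps2 / 12.011))
  expect_equal(sp$n_discarded, 0L)
  expect_false(is.unsorted(sp$frequencies))
  expect_equal(sp$frequencies, omega_true, tolerance = 0.05)
  # zero covariance: every mode discarded, empty spectrum
  sp0 <- quasiharmonic_frequencies(matrix(0, 3, 3), 12.011, 300)
  expect_equal(length(sp0$frequencies), 0L)
  expect_equal(sp0$n_discarded, 3L)
  expect_error(quasiharmonic_frequencies(matrix(c(0, 1, 0, 0, 0, 0, 0, 0, 0),
                                                3, 3), 12.011, 300),
               "symmetric")
})

test_that("oscillator entropy: scalar value, stiff limit, monotonicity, classical limit", {
  kB <- ls_constants()$k_B; hbar <- ls_constants()$hbar
  u_to_spec <- function(u, temperature = 300) {
    structure(list(frequencies = u * kB * temperature / hbar, n_discarded = 0L,
                   temperature = temperature), class = "qh_spectrum")
  }
  # single mode at u = 1: S/k_B = 1/(e-1) - ln(1 - 1/e) = 1.040652...
  expect_equal(quasiharmonic_entropy(u_to_spec(1)) / kB,
               1 / (exp(1) - 1) - log(1 - exp(-1)), tolerance = 1e-9)
  expect_equal(quasiharmonic_entropy(u_to_spec(1)) / kB, 1.040652,
               tolerance = 1e-5)
  # stiff modes contribute nothing
  expect_lt(quasiharmonic_entropy(u_to_spec(100)) / kB, 1e-10)
  # entropy decreases as any frequency increases
  us <- c(0.5, 1, 2, 5, 10)
  ss <- vapply(us, function(u) quasiharmonic_entropy(u_to_spec(u)),
               numeric(1))
  expect_true(all(diff(ss) < 0))
  # classical limit: S/k_B -> 1 - ln u for u << 1
  u <- 1e-4
  expect_equal(quasiharmonic_entropy(u_to_spec(u)) / kB, 1 - log(u),
               tolerance = 1e-3)
  # empty spectrum has zero entropy
  expect_equal(quasiharmonic_entropy(
    structure(list(frequencies = numeric(0), n_discarded = 3L,
                   temperature = 300), class = "qh_spectrum")), 0)
})

test_that("harmonic sampler covariance converges to its target", {
  sys <- axis_system(c(0, 2), mass = 1)
  k <- c(1, 2, 4, 8, 16, 32)
  tr <- harmonic_trajectory(sys, k = k, temperature = 300, n_frames = 1e4,
                            seed = 17)
  sg <- covariance_matrix(tr)
  target <- ls_constants()$k_B * 300 / k
  expect_equal(diag(sg), target, tolerance = 0.05, ignore_attr = TRUE)
})

test_that("entropy is invariant under rigid rotation of the whole trajectory", {
  set.seed(5)
  sys <- molecular_system(data.frame(element = "C",
                                     x = rnorm(4, sd = 2), y = rnorm(4, sd = 2),
                                     z = rnorm(4, sd = 2)))
  tr <- harmonic_trajectory(sys, k = 20, n_frames = 300, seed = 8)
  R <- random_rotation()
  tr_rot <- trajectory(sys, lapply(tr$frames, function(f) f %*% t(R)), 300)
  s1 <- trajectory_entropy(tr, align_selection = 1:4)
  s2 <- trajectory_entropy(tr_rot, align_selection = 1:4)
  expect_equal(s1, s2, tolerance = 1e-9)
})

test_that("binding entropy: exact cancellation, entropy loss, frame-order invariance", {
  rec <- make_pocket_receptor(seed = 2)
  set.seed(9)
  lig <- molecular_system(data.frame(element = "C", x = rnorm(4, sd = 0.8),
                                     y = rnorm(4, sd = 0.8),
                                     z = rnorm(4, sd = 0.8), mass = 12.011))
  cx <- combine_systems(rec, lig)
  nR <- n_atoms(rec)
  # rigid construction: complex frames are rigid transforms of (receptor +
  # frozen ligand); alignment removes everything, so Delta S = 0 exactly
  base_c <- rbind(coords(rec), coords(lig))
  frames_C <- lapply(1:6, function(i)
    sweep(base_c %*% t(random_rotation()), 2, rnorm(3, sd = 4), "+"))
  tr_C <- trajectory(cx, frames_C, 300)
  tr_R <- trajectory(rec, lapply(frames_C, function(f) f[1:nR, ]), 300)
  tr_L <- trajectory(lig, list(coords(lig), coords(lig)), 300)
  expect_equal(binding_entropy(tr_C, tr_R, tr_L, 1:nR), 0, tolerance = 1e-9)
  # ligand mobile alone but frozen in the complex: binding loses entropy
  tr_Lm <- harmonic_trajectory(lig, k = 100, n_frames = 200, seed = 6)
  expect_lt(binding_entropy(tr_C, tr_R, tr_Lm, 1:nR), 0)
  # permuting frames leaves Delta S unchanged
  perm <- c(4, 1, 6, 3, 2, 5)
  tr_Cp <- trajectory(cx, frames_C[perm], 300)
  tr_Rp <- trajectory(rec, tr_R$frames[perm], 300)
  expect_equal(binding_entropy(tr_Cp, tr_Rp, tr_Lm, 1:nR),
               binding_entropy(tr_C, tr_R, tr_Lm, 1:nR), tolerance = 1e-9)
  # temperature mismatch is an error
  tr_bad <- trajectory(lig, tr_Lm$frames, 310)
  expect_error(binding_entropy(tr_C, tr_R, tr_bad, 1:nR), "emperature")
})
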