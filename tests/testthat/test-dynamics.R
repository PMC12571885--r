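# Langevin dynamics: velocity initialization, energy conservation in the
# frictionless limit, bookkeeping and continuation semantics.

test_that("Maxwell-Boltzmann initialization is seeded and COM-free", {
  mol <- harmonic_diatomic()
  g0 <- init_velocities(mol$geometry, 0, seed = 1)
  expect_equal(g0$velocities, matrix(0, 2, 3))
  a <- init_velocities(mol$geometry, 300, seed = 7)
  b <- init_velocities(mol$geometry, 300, seed = 7)
  expect_identical(a$velocities, b$velocities)
  expect_false(identical(a$velocities,
                         init_velocities(mol$geometry, 300, seed = 8)$velocities))
  # COM momentum removed
  p <- colSums(a$velocities * a$masses)
  expect_equal(p, c(0, 0, 0), tolerance = 1e-12)
  # equipartition at large N: instantaneous kinetic T within 10%
  big <- geometry(rep("O", 1000),
                  matrix(seq_len(3000), ncol = 3), masses = rep(15.999, 1000))
  bv <- init_velocities(big, 300, seed = 3)
  expect_equal(kinetic_temperature(bv), 300, tolerance = 0.1)
})

test_that("frictionless MD conserves energy (velocity-Verlet limit)", {
  mol <- harmonic_diatomic(k = 1, r0 = 1)
  g <- geometry(c("H", "H"), rbind(c(0, 0, 0), c(1.1, 0, 0)),
                velocities = matrix(0, 2, 3), masses = c(1, 1))
  traj <- run_md(oracle_calculator(mol), g,
                 md_settings(dt = 0.5, friction = 0, temperature = 0,
                             n_steps = 10000, record_every = 10))
  etot <- traj$energies + traj$kinetic
  expect_lt(max(etot) - min(etot), 1e-5)
})

test_that("trajectory bookkeeping: frame counts, zero steps, dipoles", {
  mol <- harmonic_diatomic()
  calc <- oracle_calculator(mol)
  g <- init_velocities(mol$geometry, 300, seed = 2)
  tr <- run_md(calc, g, md_settings(n_steps = 100, record_every = 7, seed = 1))
  expect_length(tr$frames, 100 %/% 7 + 1)
  expect_equal(nrow(tr$dipoles), length(tr$frames))
  expect_equal(tr$dt, 0.5 * 7)
  tr0 <- run_md(calc, g, md_settings(n_steps = 0, seed = 1))
  expect_length(tr0$frames, 1)
  expect_equal(tr0$frames[[1]]$positions, g$positions)
})

test_that("continuation with a shared noise stream equals one long run", {
  mol <- harmonic_diatomic()
  calc <- oracle_calculator(mol)
  g <- init_velocities(mol$geometry, 300, seed = 4)
  long <- run_md(calc, g, md_settings(n_steps = 400, seed = 99,
                                      record_every = 10))
  half <- run_md(calc, g, md_settings(n_steps = 200, seed = 99,
                                      record_every = 10))
  # seed = NULL continues the thermostat noise stream
  joined <- continue_md(half, calc, md_settings(n_steps = 200, seed = NULL,
                                                record_every = 10))
  expect_length(joined$frames, length(long$frames))
  expect_equal(joined$frames[[length(joined$frames)]]$positions,
               long$frames[[length(long$frames)]]$positions,
               tolerance = 1e-12)
  expect_equal(joined$energies, long$energies, tolerance = 1e-12)
  # zero-step continuation is the identity
  same <- continue_md(half, calc, md_settings(n_steps = 0, seed = NULL))
  expect_identical(same, half)
  # continuation needs velocities
  bare <- trajectory(list(mol$geometry), dt = 0.5)
  expect_error(continue_md(bare, calc, md_settings(n_steps = 10)),
               "velocities")
  # aborted trajectories must be re-seeded explicitly
  ab <- half
  ab$aborted <- TRUE
  expect_error(continue_md(ab, calc, md_settings(n_steps = 10)), "aborted")
})

test_that("long Langevin runs reproduce the Boltzmann position variance", {
  # detailed-balance proxy: var(r - r0) = kB T / k for the harmonic stretch
  mol <- harmonic_diatomic(k = 1, r0 = 1)
  uc <- unit_constants()
  g <- init_velocities(mol$geometry, 300, seed = 6)
  tr <- run_md(oracle_calculator(mol), g,
               md_settings(dt = 0.5, friction = 0.02, temperature = 300,
                           n_steps = 60000, seed = 11, record_every = 5))
  r <- vapply(tr$frames, function(f)
    sqrt(sum((f$positions[1, ] - f$positions[2, ])^2)), numeric(1))
  r <- r[-seq_len(1000)]                   # discard thermalization
  expect_equal(stats::var(r), uc$kB_eV * 300 / 1, tolerance = 0.05)
})

test_that("rotation-free dynamics keeps angular momentum at zero", {
  mol <- harmonic_diatomic()
  g <- init_velocities(mol$geometry, 300, seed = 3)
  tr <- run_md(oracle_calculator(mol), g,
               md_settings(n_steps = 200, seed = 5, remove_rotation = TRUE))
  f <- tr$frames[[length(tr$frames)]]
  com <- center_of_mass(f)
  rel <- sweep(f$positions, 2, com)
  L <- colSums(f$masses * cbind(
    rel[, 2] * f$velocities[, 3] - rel[, 3] * f$velocities[, 2],
    rel[, 3] * f$velocities[, 1] - rel[, 1] * f$velocities[, 3],
    rel[, 1] * f$velocities[, 2] - rel[, 2] * f$velocities[, 1]))
  expect_equal(L, c(0, 0, 0), tolerance = 1e-10)
})
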