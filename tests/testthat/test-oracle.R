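# The analytic labelling oracle: closed-form energies/forces/dipoles,
# gradient correctness, symmetry properties and the surrogate generator.

test_that("harmonic diatomic matches the closed forms", {
  mol <- harmonic_diatomic(k = 1, r0 = 1)
  # at the reference geometry: zero energy and forces
  at_min <- oracle_evaluate(mol, mol$geometry)
  expect_equal(at_min$energy, 0, tolerance = 1e-14)
  expect_equal(max(abs(at_min$forces)), 0, tolerance = 1e-14)
  # stretched to 1.2 A: E = k/2 (dr)^2, |F| = k dr on each atom
  g <- geometry(c("H", "H"), rbind(c(0, 0, 0), c(1.2, 0, 0)), masses = c(1, 1))
  s <- oracle_evaluate(mol, g)
  expect_equal(s$energy, 0.02, tolerance = 1e-12)
  expect_equal(sqrt(sum(s$forces[1, ]^2)), 0.2, tolerance = 1e-12)
  expect_equal(sqrt(sum(s$forces[2, ]^2)), 0.2, tolerance = 1e-12)
  expect_equal(s$forces[1, ], -s$forces[2, ])
  # dipole: charges +-0.2 e at 1.2 A separation -> 0.24 e*A in Debye
  expect_equal(sqrt(sum(s$dipole^2)), 0.24 * unit_constants()$eA_to_debye,
               tolerance = 1e-10)
})

test_that("analytic forces match central differences", {
  mol <- harmonic_diatomic()
  g <- geometry(c("H", "H"), rbind(c(0.1, 0.2, -0.1), c(1.15, -0.3, 0.2)),
                masses = c(1, 1))
  expect_lt(finite_difference_check(mol, g, h = 1e-4), 1e-6)

  # Morse + angle triatomic, randomized geometries
  suite <- make_surrogate_suite(3, c(3, 4), seed = 4)
  for (m in suite) {
    g0 <- m$geometry
    gp <- withr::with_seed(9, geometry(
      g0$symbols, g0$positions + matrix(stats::rnorm(length(g0$positions),
                                                     sd = 0.05), ncol = 3),
      masses = g0$masses))
    expect_lt(finite_difference_check(m, gp, h = 1e-4), 1e-5)
  }
  expect_error(finite_difference_check(mol, g, h = 0), "h must be > 0")
})

test_that("oracle is translation invariant and rotation covariant", {
  suite <- make_surrogate_suite(2, c(3, 4), seed = 21)
  mol <- suite[[1]]
  g0 <- mol$geometry
  gp <- withr::with_seed(3, geometry(
    g0$symbols, g0$positions + matrix(stats::rnorm(length(g0$positions),
                                                   sd = 0.04), ncol = 3),
    masses = g0$masses))
  base <- oracle_evaluate(mol, gp)
  # rigid translation: energy and dipole unchanged
  gt <- geometry(gp$symbols, sweep(gp$positions, 2, c(3.1, -2.2, 0.7), "+"),
                 masses = gp$masses)
  st <- oracle_evaluate(mol, gt)
  expect_equal(st$energy, base$energy, tolerance = 1e-12)
  expect_equal(st$dipole, base$dipole, tolerance = 1e-10)
  # rigid rotation: energy invariant, forces and dipole co-rotate
  for (sd in 1:3) {
    R <- random_rotation(sd)
    gr <- geometry(gp$symbols, gp$positions %*% t(R), masses = gp$masses)
    sr <- oracle_evaluate(mol, gr)
    expect_equal(sr$energy, base$energy, tolerance = 1e-10)
    expect_equal(sr$forces, base$forces %*% t(R), tolerance = 1e-8)
    expect_equal(sr$dipole, as.vector(R %*% base$dipole), tolerance = 1e-8)
  }
})

test_that("coincident bonded atoms raise an evaluation error", {
  mol <- harmonic_diatomic()
  g <- geometry(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 0)), masses = c(1, 1))
  expect_error(oracle_evaluate(mol, g), "coincident")
})

test_that("charges are recentred to exact zero sum", {
  g <- geometry(c("C", "H"), rbind(c(0, 0, 0), c(1.1, 0, 0)))
  mol <- surrogate_molecule(
    g, list(list(i = 1L, j = 2L, style = "harmonic", k = 2, r0 = 1.1)),
    charges = c(0.3, 0.2))
  expect_equal(sum(mol$charges), 0)
  expect_equal(mol$charges, c(0.05, -0.05))
})

test_that("the surrogate suite is deterministic, minimized and serializable", {
  a <- make_surrogate_suite(3, c(2, 5), seed = 42)
  b <- make_surrogate_suite(3, c(2, 5), seed = 42)
  expect_identical(a, b)
  expect_length(make_surrogate_suite(5, c(2, 4), seed = 1), 5)
  for (m in a) {
    f <- oracle_evaluate(m, m$geometry)$forces
    expect_lt(max(abs(f)), 1e-3)          # relaxed reference geometry
    expect_equal(sum(m$charges), 0, tolerance = 1e-15)
  }
  # diatomics only when the size range collapses
  dia <- make_surrogate_suite(3, c(2, 2), seed = 5)
  expect_true(all(vapply(dia, function(m) length(m$geometry$symbols),
                         integer(1)) == 2L))
  expect_error(make_surrogate_suite(2, c(1, 4)), "size_range")
  expect_error(make_surrogate_suite(2, c(2, 13)), "size_range")
  # text serialization round-trip
  path <- withr::local_tempfile(fileext = ".yml")
  write_surrogate(a[[1]], path)
  back <- read_surrogate(path)
  expect_equal(back$geometry$positions, a[[1]]$geometry$positions,
               tolerance = 1e-12)
  expect_equal(back$charges, a[[1]]$charges, tolerance = 1e-12)
  expect_equal(oracle_evaluate(back, back$geometry)$energy,
               oracle_evaluate(a[[1]], a[[1]]$geometry)$energy,
               tolerance = 1e-12)
})
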