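# Hessians, normal modes, harmonic stick spectra and normal-mode sampling.

test_that("finite-difference Hessian matches the analytic harmonic form", {
  mol <- harmonic_diatomic(k = 1, r0 = 1)
  H <- hessian(oracle_calculator(mol), mol$geometry, h = 1e-3)
  # stretch block along the bond axis: +-k
  expect_equal(H[1, 1], 1, tolerance = 1e-6)
  expect_equal(H[4, 4], 1, tolerance = 1e-6)
  expect_equal(H[1, 4], -1, tolerance = 1e-6)
  expect_lt(attr(H, "asymmetry"), 1e-6)
  expect_equal(H, t(H))
  expect_error(hessian(oracle_calculator(mol), mol$geometry, h = 0),
               "h must be > 0")
})

test_that("normal modes recover the closed-form diatomic frequency", {
  mol <- harmonic_diatomic(k = 1, r0 = 1)
  nm <- normal_modes(hessian(oracle_calculator(mol), mol$geometry),
                     c(1, 1))
  vib <- vibrational_frequencies(nm)
  expect_length(vib, 1)
  expect_equal(vib, diatomic_wavenumber(1), tolerance = 1e-4)
  expect_equal(sum(nm$rigid), 5)          # linear molecule: 5 rigid modes
  # reduced mass of the stretch in the 1/sum(l^2) convention: 1 amu here
  expect_equal(nm$reduced_masses[!nm$rigid], 1, tolerance = 1e-6)
  # mass-weighted eigenvectors orthonormal
  V <- nm$modes
  expect_lt(max(abs(crossprod(V) - diag(ncol(V)))), 1e-8)
  # zero Hessian: all frequencies zero
  nm0 <- normal_modes(matrix(0, 6, 6), c(1, 1))
  expect_equal(nm0$frequencies, rep(0, 6))
  expect_error(normal_modes(matrix(NA_real_, 6, 6), c(1, 1)), "non-finite")
})

test_that("a minimized non-linear triatomic has 3 vibrations and 6 rigid modes", {
  suite <- make_surrogate_suite(2, c(3, 3), seed = 8)
  mol <- suite[[1]]
  nm <- normal_modes(hessian(oracle_calculator(mol), mol$geometry),
                     mol$geometry$masses)
  expect_equal(sum(nm$rigid), 6)
  expect_length(vibrational_frequencies(nm), 3)
  expect_true(all(vibrational_frequencies(nm) > 100))
})

test_that("frequencies are invariant under rigid rotation of the input", {
  suite <- make_surrogate_suite(1, c(3, 4), seed = 15)
  mol <- suite[[1]]
  nm <- normal_modes(hessian(oracle_calculator(mol), mol$geometry),
                     mol$geometry$masses)
  R <- random_rotation(2)
  grot <- geometry(mol$geometry$symbols, mol$geometry$positions %*% t(R),
                   masses = mol$geometry$masses)
  nmr <- normal_modes(hessian(oracle_calculator(mol), grot),
                      mol$geometry$masses)
  expect_equal(vibrational_frequencies(nmr), vibrational_frequencies(nm),
               tolerance = 0.1 / max(vibrational_frequencies(nm)))
})

test_that("harmonic stick spectrum follows the dipole derivative", {
  # uncharged diatomic: no dipole derivative, zero intensity
  mol0 <- surrogate_diatomic("harmonic", k = 1, r0 = 1, q = 0)
  calc0 <- oracle_calculator(mol0)
  nm <- normal_modes(hessian(calc0, mol0$geometry), c(1, 1))
  st0 <- harmonic_ir(calc0, mol0$geometry, nm)
  expect_equal(st0$intensities, 0, tolerance = 1e-12)
  # charged diatomic: one stick at the stretch; intensity scales as q^2
  mol1 <- harmonic_diatomic(q = 0.2)
  st1 <- harmonic_ir(oracle_calculator(mol1), mol1$geometry, nm)
  expect_length(st1$wavenumbers, 1)
  expect_equal(st1$wavenumbers, diatomic_wavenumber(1), tolerance = 1e-4)
  mol2 <- harmonic_diatomic(q = 0.4)
  st2 <- harmonic_ir(oracle_calculator(mol2), mol2$geometry, nm)
  expect_equal(st2$intensities / st1$intensities, 4, tolerance = 1e-6)
  expect_equal(st2$wavenumbers, st1$wavenumbers)
  expect_error(harmonic_ir(oracle_calculator(mol1), mol1$geometry, nm,
                           dq = -1), "dq must be > 0")
})

test_that("normal-mode sampling counts, direction and energy bound", {
  suite <- make_surrogate_suite(1, c(3, 3), seed = 8)
  mol <- suite[[1]]
  calc <- oracle_calculator(mol)
  nm <- normal_modes(hessian(calc, mol$geometry), mol$geometry$masses)
  # 3 vibrational modes x 10 phases
  geoms <- normal_mode_sample(mol$geometry, nm, frames_per_mode = 10)
  expect_length(geoms, 30)
  # one frame per mode: small displacement along the mode direction
  one <- normal_mode_sample(mol$geometry, nm, frames_per_mode = 1)
  expect_length(one, 3)
  keep <- which(!nm$rigid)
  invsqm <- rep(1 / sqrt(mol$geometry$masses), each = 3)
  for (i in seq_along(one)) {
    disp <- as.vector(t(one[[i]]$positions - mol$geometry$positions))
    mw <- disp / invsqm                    # back to mass-weighted coords
    mw <- mw / sqrt(sum(mw^2))
    overlap <- abs(sum(mw * nm$modes[, keep[i]]))
    expect_equal(overlap, 1, tolerance = 1e-8)
  }
  # sampled energies stay below k_B T_ref + 10% anharmonic slack
  uc <- unit_constants()
  energies <- vapply(geoms, function(g) calc_eval(calc, g)$energy, numeric(1))
  expect_lt(max(energies), 1.1 * uc$kB_eV * 300)
  expect_error(normal_mode_sample(mol$geometry, nm, frames_per_mode = 0),
               "frames_per_mode")
  expect_warning(
    normal_mode_sample(geometry(mol$geometry$symbols,
                                mol$geometry$positions * 1.2,
                                masses = mol$geometry$masses),
                       nm, check_forces = matrix(1, 3, 3)),
    "unminimized")
})
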