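# Reference kernel potential, committee statistics and the dipole model.

test_that("kernel model interpolates and generalizes on a diatomic", {
  mol <- harmonic_diatomic()
  samp <- stretch_samples(mol, n = 250, seed = 2)
  m <- fit_reference_model(samp[1:200])
  held <- samp[201:250]
  pe <- vapply(held, function(s) predict_potential(m, s$geometry)$energy,
               numeric(1))
  te <- vapply(held, `[[`, numeric(1), "energy")
  expect_lt(sqrt(mean((pe - te)^2)), 0.010)       # < 10 meV
  # near-interpolation limit: training labels reproduced with a tiny ridge
  few <- samp[seq(1, 40, by = 8)]
  m0 <- fit_reference_model(few, list(lambda = 1e-12, force_weight = 0))
  for (s in few)
    expect_lt(abs(predict_potential(m0, s$geometry)$energy - s$energy), 1e-8)
  expect_error(fit_reference_model(samp[1:3]), "at least 5")
  expect_error(predict_potential(m, ch_diatomic()$geometry), "composition")
})

test_that("model forces are the analytic gradient of the model energy", {
  suite <- make_surrogate_suite(1, c(3, 3), seed = 31)
  mol <- suite[[1]]
  samp <- perturbed_samples(mol, n = 40, sd = 0.05, seed = 3)
  m <- fit_reference_model(samp)
  g <- samp[[7]]$geometry
  pf <- predict_potential(m, g)$forces
  h <- 1e-5
  for (idx in list(c(1, 1), c(2, 3), c(3, 2))) {
    pp <- g$positions; pp[idx[1], idx[2]] <- pp[idx[1], idx[2]] + h
    pm <- g$positions; pm[idx[1], idx[2]] <- pm[idx[1], idx[2]] - h
    fd <- -(predict_potential(m, geometry(g$symbols, pp))$energy -
            predict_potential(m, geometry(g$symbols, pm))$energy) / (2 * h)
    expect_equal(pf[idx[1], idx[2]], fd, tolerance = 1e-6)
  }
})

test_that("held-out error shrinks as the training set doubles", {
  mol <- morse_diatomic()
  pool <- stretch_samples(mol, n = 260, seed = 4)
  held <- pool[201:260]
  te <- vapply(held, `[[`, numeric(1), "energy")
  rmse_at <- function(n, seed) {
    idx <- withr::with_seed(seed, sample(200, n))
    m <- fit_reference_model(pool[idx])
    pe <- vapply(held, function(s) predict_potential(m, s$geometry)$energy,
                 numeric(1))
    sqrt(mean((pe - te)^2))
  }
  med <- vapply(c(25, 50, 100, 200), function(n)
    stats::median(vapply(1:5, function(sd) rmse_at(n, sd), numeric(1))),
    numeric(1))
  expect_true(all(diff(med) <= 0))
})

test_that("committee statistics follow the closed forms", {
  mol <- harmonic_diatomic()
  samp <- stretch_samples(mol, n = 40, seed = 5)
  com <- fit_committee(samp, M = 3, seed_base = 1)
  g <- mol$geometry
  cp <- committee_predict(com, g)
  expect_equal(dim(cp$forces), c(2, 3))
  expect_equal(dim(cp$force_std), c(2, 3))
  # identical members: zero spread, zero relative error, zero uncertainty
  same <- structure(list(members = list(com$members[[1]], com$members[[1]]),
                         member_seeds = c(1, 1)), class = "committee")
  cps <- committee_predict(same, g)
  expect_equal(max(cps$force_std), 0)
  expect_equal(relative_force_error(same, g), 0)
  expect_equal(frame_uncertainty(same, g), 0)
  # single member: uncertainty query refused
  one <- structure(list(members = com$members[1], member_seeds = 1),
                   class = "committee")
  expect_error(committee_predict(one, g), "at least 2")
  expect_error(relative_force_error(com, g, eps = 0), "eps must be > 0")
})

test_that("committee spread matches the population std of member forces", {
  mol <- morse_diatomic()
  samp <- stretch_samples(mol, n = 60, seed = 9)
  com <- fit_committee(samp, M = 3, seed_base = 4)
  g <- geometry(c("H", "H"), rbind(c(0, 0, 0), c(1.22, 0, 0)),
                masses = c(1, 1))
  preds <- lapply(com$members, function(m) predict_potential(m, g)$forces)
  arr <- array(unlist(preds), dim = c(2, 3, 3))
  cp <- committee_predict(com, g)
  expect_equal(cp$forces, apply(arr, c(1, 2), mean), tolerance = 1e-12)
  expect_equal(cp$force_std,
               apply(arr, c(1, 2), function(x) sqrt(mean((x - mean(x))^2))),
               tolerance = 1e-12)
  # frame uncertainty is the max per-atom norm of that spread; a synthetic
  # spread of (3,4,0)e-3 on one atom gives exactly 5e-3
  expect_equal(frame_uncertainty(com, g),
               max(sqrt(rowSums(cp$force_std^2))), tolerance = 1e-12)
  expect_equal(sqrt(sum(c(3e-3, 4e-3, 0)^2)), 5e-3)
})

test_that("relative force error reduces to sqrt(v)/eps at zero mean force", {
  mol <- harmonic_diatomic()
  samp <- stretch_samples(mol, n = 40, seed = 6)
  com <- fit_committee(samp, M = 3, seed_base = 2)
  g <- mol$geometry
  cp <- committee_predict(com, g)
  eps <- 1e-3
  expect_equal(relative_force_error(com, g, eps = eps),
               sqrt(mean(cp$force_std^2)) / (sqrt(mean(cp$forces^2)) + eps),
               tolerance = 1e-12)
})

test_that("adding a mean-identical member never raises the uncertainty", {
  mol <- morse_diatomic()
  samp <- stretch_samples(mol, n = 50, seed = 7)
  for (sd in 1:5) {
    com <- fit_committee(samp, M = 3, seed_base = sd)
    g <- withr::with_seed(sd, geometry(
      c("H", "H"), rbind(c(0, 0, 0), c(stats::runif(1, 0.9, 1.3), 0, 0)),
      masses = c(1, 1)))
    base <- frame_uncertainty(com, g)
    # a pseudo-member that predicts exactly the committee mean shrinks the
    # population variance by M/(M+1)
    preds <- lapply(com$members, function(m) predict_potential(m, g)$forces)
    arr <- array(unlist(preds), dim = c(2, 3, 3))
    grown_std <- apply(arr, c(1, 2), function(x)
      sqrt(mean(c(x - mean(x), 0)^2)))
    grown <- max(sqrt(rowSums(grown_std^2)))
    expect_lte(grown, base + 1e-15)
  }
})

test_that("uncertainty is larger far outside the training manifold", {
  suite <- make_surrogate_suite(4, c(2, 3), seed = 17)
  ratio <- vapply(suite, function(mol) {
    samp <- c(initial_dataset(list(mol))[[1]],
              perturbed_samples(mol, n = 20, sd = 0.03, seed = 2))
    com <- fit_committee(samp, M = 3, seed_base = 3)
    g0 <- mol$geometry
    far <- geometry(g0$symbols,
                    sweep(g0$positions, 2, center_of_mass(g0)) * 2,
                    masses = g0$masses)     # all bonds stretched x2
    frame_uncertainty(com, far) / max(frame_uncertainty(com, g0), 1e-12)
  }, numeric(1))
  expect_gt(stats::median(ratio), 1)
})

test_that("dipole model recovers fixed charges and is translation invariant", {
  mol <- ch_diatomic()
  samp <- stretch_samples(mol, n = 100, lo = 0.95, hi = 1.25, seed = 8)
  dm <- fit_dipole_model(samp[1:80])
  held <- samp[81:100]
  mae <- mean(vapply(held, function(s)
    mean(abs(predict_dipole(dm, s$geometry) - s$dipole)), numeric(1)))
  expect_lt(mae, 0.020)                     # < 20 mDebye
  g <- held[[1]]$geometry
  gt <- geometry(g$symbols, sweep(g$positions, 2, c(12, -5, 3), "+"))
  expect_equal(predict_dipole(dm, gt), predict_dipole(dm, g),
               tolerance = 1e-10)
  # training set without dipole labels is refused
  nolab <- lapply(samp[1:10], function(s)
    labeled_sample(s$geometry, energy = s$energy, forces = s$forces))
  expect_error(fit_dipole_model(nolab), "dipole label")
})
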