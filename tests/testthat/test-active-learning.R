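# The acquisition loop: initial dataset, splits, uncertainty-ranked
# acquisition, retraining and the harmonic-frequency stopping metric.

test_that("initial dataset counts follow frames_per_mode x modes", {
  tri <- make_surrogate_suite(1, c(3, 3), seed = 8)   # non-linear triatomic
  ds <- initial_dataset(tri)
  expect_length(ds[[1]], 30)                           # 3 modes x 10
  dia <- list(harmonic_diatomic())
  dia[[1]]$name <- "dia"
  expect_length(initial_dataset(dia)[[1]], 10)         # one mode
  expect_error(initial_dataset(tri, frames_per_mode = 0), "frames_per_mode")
  # every sample carries full labels
  expect_true(all(vapply(ds[[1]], function(s)
    !is.null(s$energy) && !is.null(s$forces) && !is.null(s$dipole),
    logical(1))))
})

test_that("dataset splitting is stratified, seeded and guarded", {
  ds <- list(a = as.list(1:100), b = as.list(1:20))
  ds$a <- lapply(ds$a, function(i) i)   # placeholder samples: split is index
  sp <- split_dataset(ds, ratio = 0.8, seed = 1)
  expect_length(sp$train, 80 + 16)
  expect_length(sp$test, 20 + 4)
  sp2 <- split_dataset(ds, ratio = 0.8, seed = 1)
  expect_identical(sp, sp2)
  expect_false(identical(sp, split_dataset(ds, ratio = 0.8, seed = 2)))
  expect_error(split_dataset(ds, ratio = 1.0), "strictly between")
  expect_error(split_dataset(list(a = as.list(1:3)), 0.8), "fewer than 5")
})

test_that("harmonic MAE is zero for the oracle and exact for a shift", {
  suite <- make_surrogate_suite(2, c(2, 3), seed = 19)
  # the oracle itself as "model": identical Hessians, MAE exactly 0
  hm <- harmonic_mae(NULL, suite,
                     calc_factory = function(model, geom) {
                       mol <- suite[[which(vapply(suite, function(m)
                         identical(m$geometry$positions, geom$positions),
                         logical(1)))]]
                       oracle_calculator(mol)
                     })
  expect_equal(hm$mae, 0)
  expect_equal(hm$rmse, 0)
  # a +5 cm^-1 shift on every frequency gives MAE = RMSE = 5 exactly
  shifts <- abs(vapply(suite, function(mol) {
    nm <- normal_modes(hessian(oracle_calculator(mol), mol$geometry),
                       mol$geometry$masses)
    f <- vibrational_frequencies(nm)
    mean(abs((f + 5) - f))
  }, numeric(1)))
  expect_equal(shifts, rep(5, 2), tolerance = 1e-10)
})

test_that("retraining is deterministic in seed_base and atomic", {
  mol <- morse_diatomic()
  samp <- stretch_samples(mol, n = 40, seed = 3)
  c1 <- fit_committee(samp, M = 3, seed_base = 10)
  c2 <- fit_committee(samp, M = 3, seed_base = 10)
  expect_identical(c1, c2)
  c3 <- fit_committee(samp, M = 3, seed_base = 11)
  expect_false(identical(c1$members[[1]]$blocks[[1]]$alpha,
                         c3$members[[1]]$blocks[[1]]$alpha))
  expect_length(c1$members, 3)
  expect_equal(c1$member_seeds, c(10, 11, 12))
})

test_that("one acquisition round yields per_T x temperatures new samples", {
  suite <- make_surrogate_suite(1, c(3, 3), seed = 8)
  cfg <- al_config(suite, explore_ps = 0.25, record_every = 5,
                   max_iterations = 2, seed = 2,
                   sanity_threshold = 1e6)     # abort disabled for counting
  ds <- initial_dataset(suite, cfg$frames_per_mode, cfg$T_ref)
  state <- structure(list(config = cfg, iteration = 2L, dataset = ds,
                          restarts = list()), class = "al_state")
  state$split <- split_dataset(ds, 0.8, seed = 1)
  state <- retrain(state, seed_base = 5)
  n0 <- sum(lengths(state$dataset))
  state <- acquire(state)
  expect_equal(state$last_acquired, 5 * 3)    # 5 per T at 300/500/700 K
  expect_equal(sum(lengths(state$dataset)), n0 + 15)
})

test_that("the loop keeps one metrics row per iteration and a growing set", {
  suite <- make_surrogate_suite(2, c(2, 3), seed = 19)
  cfg <- al_config(suite, explore_ps = 0.25, record_every = 5,
                   threshold = 5, max_iterations = 3, seed = 4)
  st <- run_active_learning(cfg)
  expect_s3_class(st, "al_state")
  expect_equal(nrow(st$metrics), st$iteration)
  expect_lte(nrow(st$metrics), 3)
  # monotone growth; an iteration whose runs all abort may add nothing
  expect_true(all(diff(st$metrics$n_samples) >= 0))
  expect_gt(st$metrics$n_samples[nrow(st$metrics)], st$metrics$n_samples[1])
  expect_true(all(is.finite(st$metrics$harmonic_mae)))
  # no duplicate labelled frames
  hashes <- unlist(lapply(st$dataset, function(ss)
    vapply(ss, function(s) mdirspec:::.geom_hash(s$geometry), character(1))))
  expect_equal(anyDuplicated(hashes), 0)
})

test_that("an oracle-quality model stops the loop at iteration 1", {
  # when the committee member reproduces the oracle Hessian the stopping
  # MAE is below any positive threshold immediately; emulate by threshold
  # above the iteration-1 error
  suite <- make_surrogate_suite(2, c(2, 3), seed = 19)
  cfg <- al_config(suite, explore_ps = 0.1, record_every = 5,
                   threshold = 1e9, max_iterations = 5, seed = 4)
  st <- run_active_learning(cfg)
  expect_equal(st$iteration, 1L)
  expect_equal(nrow(st$metrics), 1L)
})
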