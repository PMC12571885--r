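# Committee active learning: multi-temperature MD exploration with the
# sanity abort, uncertainty-ranked acquisition, oracle labelling, retraining
# from scratch, and harmonic-frequency-MAE stopping.

.geom_hash <- function(geom) {
  paste(paste(geom$symbols, collapse = ""),
        paste(sprintf("%.8f", geom$positions), collapse = ","))
}

#' Initial training dataset by normal-mode sampling
#'
#' For each (minimized) molecule, samples `frames_per_mode` geometries along
#' every vibrational normal mode at the `T_ref` amplitude and labels them
#' with the oracle. Per-molecule count = frames_per_mode x (vibrational
#' modes).
#'
#' @param molecules list of [surrogate_molecule()] with minimized reference
#'   geometries.
#' @param frames_per_mode geometries kept per mode; default 10.
#' @param T_ref amplitude-setting temperature, K; default 300.
#' @return named list: molecule name -> list of [labeled_sample()].
#' @export
initial_dataset <- function(molecules, frames_per_mode = 10, T_ref = 300) {
  if (frames_per_mode < 1) stop("frames_per_mode must be >= 1")
  out <- list()
  for (mol in molecules) {
    calc <- oracle_calculator(mol)
    nm <- normal_modes(hessian(calc, mol$geometry), mol$geometry$masses)
    geoms <- normal_mode_sample(mol$geometry, nm,
                                frames_per_mode = frames_per_mode,
                                T_ref = T_ref,
                                check_forces = calc_eval(calc, mol$geometry)$forces)
    out[[mol$name]] <- lapply(geoms, oracle_evaluate, mol = mol)
  }
  out
}

#' Split a per-molecule dataset into train and test subsets
#'
#' Stratified per molecule: each molecule's samples are split at `ratio`
#' (default 80:20) by a seeded random permutation.
#'
#' @param dataset named list of per-molecule sample lists.
#' @param ratio training fraction in (0, 1); default 0.8.
#' @param seed integer seed (same seed, same split).
#' @return list with `train` and `test`, both flat sample lists; attribute
#'   `assignment` records molecule and subset per sample.
#' @export
split_dataset <- function(dataset, ratio = 0.8, seed = 1) {
  if (ratio <= 0 || ratio >= 1)
    stop("ratio must be strictly between 0 and 1 (both subsets non-empty)")
  train <- test <- list()
  for (name in names(dataset)) {
    sub <- dataset[[name]]
    n <- length(sub)
    if (n < 5) stop("molecule ", name, " has fewer than 5 samples")
    n_train <- max(1L, min(n - 1L, floor(ratio * n)))
    perm <- with_seed(seed + sum(as.integer(charToRaw(name))), sample.int(n))
    train <- c(train, sub[perm[seq_len(n_train)]])
    test <- c(test, sub[perm[(n_train + 1):n]])
  }
  list(train = train, test = test)
}

#' Harmonic-frequency validation error of a model
#'
#' For each molecule, compares the vibrational frequencies of the model's
#' finite-difference Hessian at the oracle minimum with the oracle's own
#' frequencies. Rigid modes are excluded (the model's mode count is aligned
#' to the oracle's by keeping its largest-|frequency| modes); imaginary
#' frequencies enter via absolute value. MAE/RMSE are pooled over all
#' vibrational modes of all molecules.
#'
#' @param model a `ref_potential` (typically the first committee member), or
#'   any object accepted by `calc_factory`.
#' @param molecules list of [surrogate_molecule()].
#' @param calc_factory function(model, template_geometry) -> calculator;
#'   default [model_calculator_for()].
#' @return list: `mae`, `rmse` (cm^-1), `per_molecule` data.frame.
#' @export
harmonic_mae <- function(model, molecules,
                         calc_factory = model_calculator_for) {
  errs <- numeric(0)
  rows <- list()
  for (mol in molecules) {
    geom <- mol$geometry
    nm_o <- normal_modes(hessian(oracle_calculator(mol), geom), geom$masses)
    ref <- sort(abs(vibrational_frequencies(nm_o)))
    nm_m <- normal_modes(hessian(calc_factory(model, geom), geom), geom$masses)
    fm <- sort(abs(nm_m$frequencies), decreasing = TRUE)[seq_along(ref)]
    fm <- sort(fm)
    e <- abs(fm - ref)
    errs <- c(errs, e)
    rows[[length(rows) + 1]] <- data.frame(molecule = mol$name,
                                           mae = mean(e))
  }
  list(mae = mean(errs), rmse = sqrt(mean(errs^2)),
       per_molecule = do.call(rbind, rows))
}

#' Active-learning configuration
#'
#' Protocol defaults follow the production recipe: 10 frames per normal
#' mode initially; exploration at 300/500/700 K for 5 ps per temperature;
#' the 5 most uncertain frames per temperature (15 per molecule per
#' iteration); committee of 3 retrained from scratch each iteration;
#' stopping at a harmonic MAE of 5 cm^-1 or 40 iterations.
#'
#' @param molecules list of [surrogate_molecule()].
#' @param frames_per_mode,T_ref initial-dataset settings.
#' @param temperatures exploration temperatures, K.
#' @param per_T frames acquired per temperature.
#' @param explore_ps exploration MD length per iteration, ps.
#' @param dt,friction,record_every MD settings (fs, 1/fs, steps).
#' @param sanity_threshold relative-force-error abort level; default 0.5.
#' @param M committee size.
#' @param split_ratio train fraction.
#' @param threshold stopping harmonic MAE, cm^-1; default 5.
#' @param max_iterations iteration cap; default 40.
#' @param hyperparams reference-model hyperparameters.
#' @param eps relative-force-error regularization, eV/Angstrom.
#' @param seed base seed for every stochastic stage.
#' @return list of class `al_config`.
#' @export
al_config <- function(molecules, frames_per_mode = 10, T_ref = 300,
                      temperatures = c(300, 500, 700), per_T = 5,
                      explore_ps = 5, dt = 0.5, friction = 0.01,
                      record_every = 10, sanity_threshold = 0.5, M = 3,
                      split_ratio = 0.8, threshold = 5, max_iterations = 40,
                      hyperparams = list(), eps = 1e-3, seed = 1) {
  stopifnot(length(molecules) >= 1, per_T >= 1, M >= 2,
            max_iterations >= 1, threshold > 0)
  structure(as.list(environment()), class = "al_config")
}

#' Acquire new labelled samples by uncertainty-ranked exploration
#'
#' Per molecule and temperature, continues the stored restart frame with
#' committee-mean forces (sanity abort active), ranks the recorded frames by
#' [frame_uncertainty()] and labels the top `per_T` with the oracle (ties
#' break toward earlier frames). Aborted runs contribute the frames recorded
#' before the abort and are re-seeded from the last valid frame with fresh
#' velocities.
#'
#' @param state an `al_state` (see [run_active_learning()]).
#' @return the state with dataset, restarts and `last_acquired` updated.
#' @export
acquire <- function(state) {
  cfg <- state$config
  n_steps <- round(cfg$explore_ps * 1000 / cfg$dt)
  acquired <- 0L
  for (mi in seq_along(cfg$molecules)) {
    mol <- cfg$molecules[[mi]]
    calc <- committee_calculator(state$committee, mol$geometry, eps = cfg$eps)
    seen <- vapply(state$dataset[[mol$name]],
                   function(s) .geom_hash(s$geometry), character(1))
    for (ti in seq_along(cfg$temperatures)) {
      Tt <- cfg$temperatures[ti]
      rs <- (cfg$seed + 40013 * state$iteration + 977 * mi + 31 * ti) %% 2147483647
      rmol <- state$restarts[[mol$name]]
      restart <- if (!is.null(rmol) && length(rmol) >= ti) rmol[[ti]] else NULL
      if (is.null(restart))
        restart <- init_velocities(mol$geometry, Tt, seed = rs)
      traj <- run_md(calc, restart,
                     md_settings(dt = cfg$dt, friction = cfg$friction,
                                 temperature = Tt, n_steps = n_steps,
                                 seed = rs + 1L,
                                 record_every = cfg$record_every,
                                 sanity_threshold = cfg$sanity_threshold))
      cand_idx <- seq_along(traj$frames)[-1]       # skip the restart frame
      if (length(cand_idx) > 0) {
        unc <- vapply(cand_idx, function(kf)
          frame_uncertainty(state$committee, traj$frames[[kf]]), numeric(1))
        pick <- cand_idx[order(-unc, cand_idx)]
        pick <- utils::head(pick, cfg$per_T)
        for (kf in pick) {
          g <- traj$frames[[kf]]
          h <- .geom_hash(g)
          if (h %in% seen) next
          seen <- c(seen, h)
          smp <- oracle_evaluate(mol, geometry(g$symbols, g$positions,
                                               masses = mol$geometry$masses))
          state$dataset[[mol$name]] <-
            c(state$dataset[[mol$name]], list(smp))
          acquired <- acquired + 1L
        }
      }
      last <- traj$frames[[length(traj$frames)]]
      state$restarts[[mol$name]][[ti]] <-
        if (traj$aborted)
          init_velocities(geometry(last$symbols, last$positions,
                                   masses = mol$geometry$masses),
                          Tt, seed = rs + 2L)
        else geometry(last$symbols, last$positions,
                      velocities = last$velocities,
                      masses = mol$geometry$masses)
    }
  }
  state$last_acquired <- acquired
  state
}

#' Retrain the committee from scratch
#'
#' Discards previous members and fits `M` fresh members on the current
#' training split with member seeds `seed_base + 0 ... M-1`.
#'
#' @param state an `al_state` with a current `split`.
#' @param seed_base integer.
#' @return the state with a new committee.
#' @export
retrain <- function(state, seed_base) {
  cfg <- state$config
  state$committee <- fit_committee(state$split$train, M = cfg$M,
                                   hyperparams = cfg$hyperparams,
                                   seed_base = seed_base)
  state
}

.test_errors <- function(committee, test) {
  if (length(test) == 0) return(c(NA_real_, NA_real_))
  ee <- fe <- numeric(0)
  for (s in test) {
    cp <- committee_predict(committee, s$geometry)
    ee <- c(ee, cp$energy - s$energy)
    fe <- c(fe, as.vector(cp$forces - s$forces))
  }
  c(sqrt(mean(ee^2)), sqrt(mean(fe^2)))
}

#' Run the active-learning loop
#'
#' Iteration 1 trains the committee on the normal-mode initial dataset;
#' each later iteration runs [acquire()] (multi-temperature exploration,
#' uncertainty ranking, oracle labelling), re-splits, retrains from scratch
#' and evaluates the harmonic-frequency MAE of the first committee member.
#' The loop stops when that MAE falls below `config$threshold` or after
#' `config$max_iterations` iterations.
#'
#' @param config an [al_config()].
#' @return object of class `al_state`: `iteration`, `dataset`, `split`,
#'   `restarts`, `committee`, and `metrics` (one row per completed
#'   iteration: dataset size, harmonic MAE/RMSE, held-out energy/force
#'   RMSE).
#' @export
run_active_learning <- function(config) {
  stopifnot(inherits(config, "al_config"))
  state <- structure(list(config = config, iteration = 1L,
                          dataset = initial_dataset(config$molecules,
                                                    config$frames_per_mode,
                                                    config$T_ref),
                          restarts = list(), metrics = NULL,
                          last_acquired = NA_integer_),
                     class = "al_state")
  state$split <- split_dataset(state$dataset, config$split_ratio,
                               seed = config$seed)
  state <- retrain(state, seed_base = config$seed + 1000L)
  record <- function(state) {
    hm <- harmonic_mae(state$committee$members[[1]], config$molecules)
    te <- .test_errors(state$committee, state$split$test)
    state$metrics <- rbind(state$metrics, data.frame(
      iteration = state$iteration,
      n_samples = sum(lengths(state$dataset)),
      acquired = state$last_acquired,
      harmonic_mae = hm$mae, harmonic_rmse = hm$rmse,
      energy_rmse_test = te[1], force_rmse_test = te[2]))
    state
  }
  state <- record(state)
  while (state$metrics$harmonic_mae[nrow(state$metrics)] >= config$threshold &&
         state$iteration < config$max_iterations) {
    state$iteration <- state$iteration + 1L
    state <- acquire(state)
    state$split <- split_dataset(state$dataset, config$split_ratio,
                                 seed = config$seed + state$iteration)
    state <- retrain(state, seed_base = config$seed + 1000L * state$iteration)
    state <- record(state)
  }
  state
}

#' @export
print.al_state <- function(x, ...) {
  cat(sprintf("<active-learning state: iteration %d, %d samples, MAE %.2f cm^-1>\n",
              x$iteration, sum(lengths(x$dataset)),
              x$metrics$harmonic_mae[nrow(x$metrics)]))
  invisible(x)
}
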