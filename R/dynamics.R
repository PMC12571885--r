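# Langevin molecular dynamics (BAOAB splitting). Drives both oracle-labelled
# exploration and committee-model production runs. At friction = 0 the
# integrator reduces to velocity Verlet and conserves energy.

#' MD settings
#'
#' @param dt timestep, fs (> 0); default 0.5.
#' @param friction Langevin friction coefficient, 1/fs (>= 0); default 0.01.
#' @param temperature bath temperature, K (>= 0).
#' @param n_steps number of integration steps.
#' @param seed integer seed for the thermostat noise, or NULL to continue
#'   the current RNG stream.
#' @param record_every record a frame every this many steps; default 1.
#' @param sanity_threshold abort threshold on the calculator's relative
#'   force error (committee sanity check), or NULL to disable; default NULL.
#' @param remove_rotation project rigid-body rotation and translation out of
#'   the velocities after every thermostat step. For an isolated molecule
#'   the Langevin noise continuously pumps angular momentum; a light rotor
#'   then smears its vibrational bands into wide rotational P/R branches.
#'   Rotation-free dynamics isolates the vibrational spectrum. Default
#'   FALSE (plain Langevin).
#' @return list of class `md_settings`.
#' @export
md_settings <- function(dt = 0.5, friction = 0.01, temperature = 300,
                        n_steps = 1000L, seed = NULL, record_every = 1L,
                        sanity_threshold = NULL, remove_rotation = FALSE) {
  if (dt <= 0) stop("dt must be > 0")
  if (friction < 0) stop("friction must be >= 0")
  if (temperature < 0) stop("temperature must be >= 0")
  if (n_steps < 0) stop("n_steps must be >= 0")
  if (record_every < 1) stop("record_every must be >= 1")
  structure(list(dt = dt, friction = friction, temperature = temperature,
                 n_steps = as.integer(n_steps), seed = seed,
                 record_every = as.integer(record_every),
                 sanity_threshold = sanity_threshold,
                 remove_rotation = isTRUE(remove_rotation)),
            class = "md_settings")
}

#' Draw Maxwell-Boltzmann velocities
#'
#' Per-component normal draws with variance \eqn{k_B T / m_i}; the
#' centre-of-mass linear momentum is removed afterwards.
#'
#' @param geom a [geometry()].
#' @param temperature K (>= 0).
#' @param seed integer seed (deterministic for fixed seed), or NULL to use
#'   the current RNG stream.
#' @return the geometry with velocities set (Angstrom/fs).
#' @export
init_velocities <- function(geom, temperature, seed = NULL) {
  if (temperature < 0) stop("temperature must be >= 0")
  n <- n_atoms(geom)
  draw <- function() {
    if (temperature == 0) return(matrix(0, n, 3))
    uc <- unit_constants()
    sd <- sqrt(uc$kB_eV * temperature * uc$acc_ev_A_amu / geom$masses)
    v <- matrix(stats::rnorm(3 * n), n, 3) * sd
    # remove COM momentum
    p <- colSums(v * geom$masses) / sum(geom$masses)
    sweep(v, 2, p)
  }
  v <- if (is.null(seed)) draw() else with_seed(seed, draw())
  geometry(geom$symbols, geom$positions, velocities = v, masses = geom$masses)
}

#' Instantaneous kinetic temperature
#' @param geom geometry with velocities.
#' @return temperature, K (over all 3N degrees of freedom).
#' @export
kinetic_temperature <- function(geom) {
  if (is.null(geom$velocities)) stop("geometry has no velocities")
  uc <- unit_constants()
  ke <- 0.5 * sum(geom$masses * rowSums(geom$velocities^2)) / uc$acc_ev_A_amu
  2 * ke / (3 * n_atoms(geom) * uc$kB_eV)
}

#' Run Langevin molecular dynamics
#'
#' BAOAB-split Langevin integration. Frames (with per-frame dipole when the
#' calculator provides one, plus potential and kinetic energies) are recorded
#' every `record_every` steps, including the initial state, so the frame
#' count is `floor(n_steps / record_every) + 1`. The final frame carries
#' velocities, making runs continuable. If the calculator reports a relative
#' force error above `settings$sanity_threshold` the run terminates and the
#' truncated trajectory is flagged `aborted`.
#'
#' @param calc an [new_calculator()].
#' @param geom starting [geometry()]; velocities are initialized at
#'   `settings$temperature` when absent.
#' @param settings an [md_settings()].
#' @return a [trajectory()] whose `dt` is the recording interval in fs.
#' @export
run_md <- function(calc, geom, settings) {
  stopifnot(inherits(settings, "md_settings"))
  if (!is.null(settings$seed)) set.seed(settings$seed)
  if (is.null(geom$velocities))
    geom <- init_velocities(geom, settings$temperature)
  uc <- unit_constants()
  n <- n_atoms(geom)
  m <- geom$masses
  dt <- settings$dt
  gam <- settings$friction
  x <- geom$positions
  v <- geom$velocities
  # O-step coefficients
  c1 <- exp(-gam * dt)
  vtherm <- sqrt(uc$kB_eV * settings$temperature * uc$acc_ev_A_amu / m)
  c2 <- sqrt(1 - c1^2) * vtherm
  acc <- function(f) f * (uc$acc_ev_A_amu / m)
  # project rigid-body translation + rotation out of the velocities
  strip_rigid <- function(x, v) {
    com <- colSums(x * m) / sum(m)
    rel <- sweep(x, 2, com)
    vcom <- colSums(v * m) / sum(m)
    v <- sweep(v, 2, vcom)
    L <- colSums(m * cbind(rel[, 2] * v[, 3] - rel[, 3] * v[, 2],
                           rel[, 3] * v[, 1] - rel[, 1] * v[, 3],
                           rel[, 1] * v[, 2] - rel[, 2] * v[, 1]))
    r2 <- rowSums(rel^2)
    I3 <- diag(sum(m * r2) - colSums(m * rel^2))
    for (a in 1:2) for (b in (a + 1):3)
      I3[a, b] <- I3[b, a] <- -sum(m * rel[, a] * rel[, b])
    # pseudo-inverse: linear molecules have a singular axis
    eg <- eigen(I3, symmetric = TRUE)
    pos_ev <- eg$values > 1e-10 * max(eg$values, 1e-300)
    omega <- eg$vectors %*% ((crossprod(eg$vectors, L) ) *
                               ifelse(pos_ev, 1 / eg$values, 0))
    v - cbind(omega[2] * rel[, 3] - omega[3] * rel[, 2],
              omega[3] * rel[, 1] - omega[1] * rel[, 3],
              omega[1] * rel[, 2] - omega[2] * rel[, 1])
  }

  res <- calc_eval(calc, x)
  a <- acc(res$forces)
  nrec <- settings$n_steps %/% settings$record_every + 1L
  frames <- vector("list", nrec)
  dip <- if (isTRUE(calc$provides_dipole)) matrix(NA_real_, nrec, 3) else NULL
  epot <- ekin <- numeric(nrec)
  rec <- function(k) {
    # validation-free construction: this is the innermost loop
    frames[[k]] <<- structure(
      list(symbols = geom$symbols, positions = x, velocities = v, masses = m),
      class = "geometry")
    if (!is.null(dip)) dip[k, ] <<- res$dipole
    epot[k] <<- res$energy
    ekin[k] <<- 0.5 * sum(m * rowSums(v^2)) / uc$acc_ev_A_amu
  }
  rec(1L)
  k <- 1L
  aborted <- FALSE
  if (settings$n_steps > 0) for (step in seq_len(settings$n_steps)) {
    v <- v + 0.5 * dt * a                       # B
    x <- x + 0.5 * dt * v                       # A
    if (gam > 0) {                              # O
      v <- c1 * v + c2 * matrix(stats::rnorm(3 * n), n, 3)
    }
    if (settings$remove_rotation) v <- strip_rigid(x, v)
    x <- x + 0.5 * dt * v                       # A
    res <- calc_eval(calc, x)
    if (!is.null(settings$sanity_threshold) &&
        !is.null(res$rel_force_error) &&
        res$rel_force_error > settings$sanity_threshold) {
      aborted <- TRUE
      break
    }
    a <- acc(res$forces)
    v <- v + 0.5 * dt * a                       # B
    if (step %% settings$record_every == 0L) { k <- k + 1L; rec(k) }
  }
  if (k < nrec) {   # aborted: drop unfilled slots
    frames <- frames[seq_len(k)]
    if (!is.null(dip)) dip <- dip[seq_len(k), , drop = FALSE]
    epot <- epot[seq_len(k)]; ekin <- ekin[seq_len(k)]
  }
  trajectory(frames, dt = dt * settings$record_every, dipoles = dip,
             energies = epot, kinetic = ekin, aborted = aborted)
}

#' Continue a trajectory
#'
#' Restarts [run_md()] from the final frame (which must carry velocities)
#' and concatenates, excluding the duplicated junction frame. With
#' `settings$seed = NULL` the thermostat noise continues the current RNG
#' stream, so a 5 ps run continued for 5 ps reproduces a single seeded
#' 10 ps run exactly.
#'
#' @param traj a [trajectory()] from [run_md()].
#' @param calc an [new_calculator()].
#' @param settings an [md_settings()].
#' @return the concatenated [trajectory()].
#' @export
continue_md <- function(traj, calc, settings) {
  stopifnot(inherits(traj, "trajectory"))
  if (traj$aborted)
    stop("cannot continue an aborted trajectory; re-seed from a valid frame")
  last <- traj$frames[[length(traj$frames)]]
  if (is.null(last$velocities))
    stop("final frame carries no velocities; cannot continue")
  ext <- run_md(calc, last, settings)
  if (settings$n_steps == 0) return(traj)
  trajectory(c(traj$frames, ext$frames[-1]), dt = traj$dt,
             dipoles = if (!is.null(traj$dipoles) && !is.null(ext$dipoles))
               rbind(traj$dipoles, ext$dipoles[-1, , drop = FALSE]) else NULL,
             energies = c(traj$energies, ext$energies[-1]),
             kinetic = c(traj$kinetic, ext$kinetic[-1]),
             aborted = ext$aborted)
}
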