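#' Surrogate molecule: analytic labelling oracle
#'
#' A bonded anharmonic force field with a point-charge dipole surface. It
#' plays the role the first-principles labeller plays in a production
#' active-learning workflow: exact energies (eV), analytic forces (eV/A) and
#' a configuration-dependent dipole (Debye) for any geometry.
#'
#' The potential is a sum of bond terms (Morse
#' \eqn{D_e(1 - e^{-a(r - r_0)})^2} or harmonic \eqn{\frac{1}{2}k(r-r_0)^2})
#' and harmonic angle terms \eqn{\frac{1}{2}k_\theta(\theta-\theta_0)^2};
#' the dipole is \eqn{\sum_i q_i (r_i - r_{COM})} with fixed zero-sum partial
#' charges, converted e*Angstrom to Debye.
#'
#' @param geometry reference [geometry()] (ideally a local minimum; see
#'   [minimize_geometry()]).
#' @param bonds list of bond terms: each a list with integer atom indices
#'   `i`, `j`, `style` ("morse" or "harmonic"), `r0` (Angstrom) and either
#'   `De` (eV) + `a` (1/Angstrom) or `k` (eV/Angstrom^2).
#' @param angles list of angle terms: `i`, `j`, `k` (angle at `j`),
#'   `ktheta` (eV/rad^2), `theta0` (rad). May be empty.
#' @param charges per-atom partial charges, e; recentred to sum exactly to 0.
#' @param name optional identifier.
#' @return An object of class `surrogate_molecule`.
#' @export
surrogate_molecule <- function(geometry, bonds, angles = list(), charges,
                               name = "surrogate") {
  stopifnot(inherits(geometry, "geometry"))
  n <- n_atoms(geometry)
  if (length(charges) != n) stop("one charge per atom required")
  if (length(bonds) < 1) stop("at least one bond required")
  for (b in bonds) {
    if (b$i < 1 || b$j < 1 || b$i > n || b$j > n || b$i == b$j)
      stop("invalid bond indices")
    if (!b$style %in% c("morse", "harmonic")) stop("unknown bond style: ", b$style)
    if (b$r0 <= 0) stop("bond r0 must be positive")
    if (b$style == "morse" && (b$De <= 0 || b$a <= 0))
      stop("Morse bonds need De > 0 and a > 0")
    if (b$style == "harmonic" && b$k <= 0) stop("harmonic bonds need k > 0")
  }
  for (a in angles) {
    if (a$ktheta <= 0) stop("angle force constants must be positive")
  }
  # connectivity of the bond graph
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (b in bonds) {
    adj[[b$i]] <- c(adj[[b$i]], b$j); adj[[b$j]] <- c(adj[[b$j]], b$i)
  }
  seen <- logical(n); queue <- 1L; seen[1] <- TRUE
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    nb <- adj[[v]][!seen[adj[[v]]]]
    seen[nb] <- TRUE; queue <- c(queue, nb)
  }
  if (!all(seen)) stop("bond graph must be connected")
  charges <- as.numeric(charges) - mean(charges)
  structure(list(geometry = geometry, bonds = bonds, angles = angles,
                 charges = charges, name = name),
            class = "surrogate_molecule")
}

#' @export
print.surrogate_molecule <- function(x, ...) {
  cat(sprintf("<surrogate '%s': %d atoms [%s], %d bonds, %d angles>\n",
              x$name, length(x$geometry$symbols),
              paste(x$geometry$symbols, collapse = ""),
              length(x$bonds), length(x$angles)))
  invisible(x)
}

# energy + analytic gradient for a position matrix; core of the oracle
.oracle_energy_forces <- function(mol, pos) {
  n <- nrow(pos)
  e <- 0
  f <- matrix(0, n, 3)
  for (b in mol$bonds) {
    d <- pos[b$i, ] - pos[b$j, ]
    r <- sqrt(sum(d * d))
    if (r < 1e-10) stop("bonded atoms ", b$i, " and ", b$j, " are coincident")
    u <- d / r
    if (b$style == "harmonic") {
      e <- e + 0.5 * b$k * (r - b$r0)^2
      dvdr <- b$k * (r - b$r0)
    } else {
      ex <- exp(-b$a * (r - b$r0))
      e <- e + b$De * (1 - ex)^2
      dvdr <- 2 * b$De * b$a * ex * (1 - ex)
    }
    f[b$i, ] <- f[b$i, ] - dvdr * u
    f[b$j, ] <- f[b$j, ] + dvdr * u
  }
  for (a in mol$angles) {
    va <- pos[a$i, ] - pos[a$j, ]
    vb <- pos[a$k, ] - pos[a$j, ]
    ra <- sqrt(sum(va * va)); rb <- sqrt(sum(vb * vb))
    ct <- sum(va * vb) / (ra * rb)
    ct <- max(-1, min(1, ct))
    th <- acos(ct)
    st <- sqrt(max(1 - ct * ct, 1e-12))
    e <- e + 0.5 * a$ktheta * (th - a$theta0)^2
    dvdth <- a$ktheta * (th - a$theta0)
    ga <- -(vb / (ra * rb) - ct * va / ra^2) / st   # dtheta/d(va)
    gb <- -(va / (ra * rb) - ct * vb / rb^2) / st
    f[a$i, ] <- f[a$i, ] - dvdth * ga
    f[a$k, ] <- f[a$k, ] - dvdth * gb
    f[a$j, ] <- f[a$j, ] + dvdth * (ga + gb)
  }
  list(energy = e, forces = f)
}

.oracle_dipole <- function(mol, pos, masses) {
  com <- colSums(pos * masses) / sum(masses)
  rel <- sweep(pos, 2, com)
  colSums(rel * mol$charges) * unit_constants()$eA_to_debye
}

#' Evaluate the oracle on a geometry
#'
#' @param mol a [surrogate_molecule()].
#' @param geom a [geometry()] with the same atom ordering as `mol`.
#' @return a [labeled_sample()] with energy, forces and dipole.
#' @export
oracle_evaluate <- function(mol, geom) {
  stopifnot(inherits(mol, "surrogate_molecule"), inherits(geom, "geometry"))
  if (!identical(geom$symbols, mol$geometry$symbols))
    stop("geometry atom ordering does not match the surrogate molecule")
  ef <- .oracle_energy_forces(mol, geom$positions)
  labeled_sample(geom, energy = ef$energy, forces = ef$forces,
                 dipole = .oracle_dipole(mol, geom$positions, geom$masses))
}

#' Calculator view of a surrogate molecule
#' @param mol a [surrogate_molecule()].
#' @return an [new_calculator()] providing energy, forces and dipole.
#' @export
oracle_calculator <- function(mol) {
  masses <- mol$geometry$masses
  new_calculator(function(pos) {
    ef <- .oracle_energy_forces(mol, pos)
    ef$dipole <- .oracle_dipole(mol, pos, masses)
    ef
  }, label = paste0("oracle:", mol$name), provides_dipole = TRUE)
}

#' Check analytic forces against central differences
#'
#' @param mol a [surrogate_molecule()].
#' @param geom a [geometry()].
#' @param h finite-difference step, Angstrom (> 0).
#' @return maximum absolute deviation over atoms and components, eV/Angstrom.
#' @export
finite_difference_check <- function(mol, geom, h = 1e-4) {
  if (!is.numeric(h) || h <= 0) stop("h must be > 0")
  pos <- geom$positions
  ana <- .oracle_energy_forces(mol, pos)$forces
  dev <- 0
  for (i in seq_len(nrow(pos))) for (c in 1:3) {
    pp <- pos; pp[i, c] <- pp[i, c] + h
    pm <- pos; pm[i, c] <- pm[i, c] - h
    ffd <- -(.oracle_energy_forces(mol, pp)$energy -
             .oracle_energy_forces(mol, pm)$energy) / (2 * h)
    dev <- max(dev, abs(ffd - ana[i, c]))
  }
  dev
}

#' Relax a geometry on the oracle surface
#'
#' BFGS minimization of the oracle energy with its analytic gradient, to a
#' maximum-force tolerance of 1e-3 eV/Angstrom by default (the meV/A scale
#' typical of structure optimizers).
#'
#' @param mol a [surrogate_molecule()].
#' @param geom starting [geometry()]; defaults to the reference geometry.
#' @param fmax force-norm tolerance, eV/Angstrom.
#' @param maxit iteration cap per BFGS restart.
#' @return relaxed [geometry()]; attribute `fmax` holds the residual force.
#' @export
minimize_geometry <- function(mol, geom = mol$geometry, fmax = 1e-3,
                              maxit = 500) {
  n <- n_atoms(geom)
  efun <- function(x) .oracle_energy_forces(mol, matrix(x, n, 3))$energy
  gfun <- function(x) -as.vector(.oracle_energy_forces(mol, matrix(x, n, 3))$forces)
  x <- as.vector(geom$positions)
  for (attempt in 1:4) {
    opt <- stats::optim(x, efun, gfun, method = "BFGS",
                        control = list(maxit = maxit, reltol = 1e-14))
    x <- opt$par
    if (max(abs(gfun(x))) < fmax) break
  }
  res <- max(abs(gfun(x)))
  if (res >= fmax)
    warning("minimization stalled at max|F| = ", signif(res, 3), " eV/A")
  out <- geometry(geom$symbols, matrix(x, n, 3), masses = geom$masses)
  attr(out, "fmax") <- res
  out
}
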