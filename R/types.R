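#' Molecular geometry
#'
#' A gas-phase molecular configuration: element symbols, free-space Cartesian
#' coordinates and (optionally) velocities. Masses are resolved from the
#' symbols unless overridden.
#'
#' @param symbols character vector of element symbols.
#' @param positions numeric matrix, one row per atom, 3 columns, Angstrom.
#' @param velocities optional numeric matrix of the same shape, Angstrom/fs.
#' @param masses optional numeric vector, amu; defaults to standard atomic
#'   masses looked up from `symbols`.
#' @return An object of class `geometry`.
#' @export
geometry <- function(symbols, positions, velocities = NULL, masses = NULL) {
  positions <- as.matrix(positions)
  n <- length(symbols)
  if (n < 1) stop("geometry needs at least one atom")
  if (!is.numeric(positions) || nrow(positions) != n || ncol(positions) != 3)
    stop("positions must be an n x 3 numeric matrix matching symbols")
  if (!is.null(velocities)) {
    velocities <- as.matrix(velocities)
    if (!is.numeric(velocities) || !all(dim(velocities) == dim(positions)))
      stop("velocities must match the shape of positions")
  }
  if (is.null(masses)) masses <- atomic_masses(symbols)
  if (length(masses) != n || any(!is.finite(masses)) || any(masses <= 0))
    stop("masses must be strictly positive, one per atom")
  structure(
    list(symbols = as.character(symbols), positions = unname(positions),
         velocities = if (is.null(velocities)) NULL else unname(velocities),
         masses = as.numeric(masses)),
    class = "geometry")
}

#' @export
print.geometry <- function(x, ...) {
  cat(sprintf("<geometry: %d atoms [%s]%s>\n", length(x$symbols),
              paste(x$symbols, collapse = ""),
              if (is.null(x$velocities)) "" else ", with velocities"))
  invisible(x)
}

n_atoms <- function(geom) length(geom$symbols)

#' Centre of mass of a geometry
#' @param geom a [geometry()].
#' @return length-3 numeric vector, Angstrom.
#' @export
center_of_mass <- function(geom) {
  colSums(geom$positions * geom$masses) / sum(geom$masses)
}

#' Labelled sample
#'
#' A geometry together with reference labels: total energy (eV), per-atom
#' forces (eV/Angstrom) and the molecular dipole vector (Debye). Any label
#' may be absent (`NULL`), e.g. for unlabelled exploration frames.
#'
#' @param geometry a [geometry()].
#' @param energy scalar eV, or NULL.
#' @param forces n x 3 matrix eV/Angstrom, or NULL.
#' @param dipole length-3 vector, Debye, or NULL.
#' @return An object of class `labeled_sample`.
#' @export
labeled_sample <- function(geometry, energy = NULL, forces = NULL,
                           dipole = NULL) {
  stopifnot(inherits(geometry, "geometry"))
  if (!is.null(energy) && (length(energy) != 1 || !is.finite(energy)))
    stop("energy must be a finite scalar")
  if (!is.null(forces)) {
    forces <- as.matrix(forces)
    if (!all(dim(forces) == dim(geometry$positions)))
      stop("forces shape must match the geometry atom count")
  }
  if (!is.null(dipole) && length(dipole) != 3)
    stop("dipole must be a 3-vector")
  structure(list(geometry = geometry,
                 energy = if (is.null(energy)) NULL else as.numeric(energy),
                 forces = if (is.null(forces)) NULL else unname(forces),
                 dipole = if (is.null(dipole)) NULL else as.numeric(dipole)),
            class = "labeled_sample")
}

#' Molecular-dynamics trajectory
#'
#' Time-ordered frames with a fixed timestep, plus optional per-frame dipoles
#' and potential/kinetic energies.
#'
#' @param frames list of [geometry()] objects sharing atom count and symbol
#'   order.
#' @param dt timestep between recorded frames, fs (> 0).
#' @param dipoles optional n_frames x 3 matrix, Debye.
#' @param energies optional per-frame potential energies, eV.
#' @param kinetic optional per-frame kinetic energies, eV.
#' @param aborted logical flag: TRUE when the run was terminated by the
#'   committee sanity check.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(frames, dt, dipoles = NULL, energies = NULL,
                       kinetic = NULL, aborted = FALSE) {
  if (length(frames) < 1) stop("trajectory needs at least one frame")
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0")
  sym0 <- frames[[1]]$symbols
  ok <- vapply(frames, function(f) identical(f$symbols, sym0), logical(1))
  if (!all(ok)) stop("all frames must share the same atom count and symbol order")
  if (!is.null(dipoles)) {
    dipoles <- as.matrix(dipoles)
    if (nrow(dipoles) != length(frames) || ncol(dipoles) != 3)
      stop("dipoles must be an n_frames x 3 matrix")
  }
  structure(list(frames = frames, dt = dt, dipoles = dipoles,
                 energies = energies, kinetic = kinetic,
                 aborted = isTRUE(aborted)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory: %d frames x %d atoms, dt = %g fs%s%s>\n",
              length(x$frames), length(x$frames[[1]]$symbols), x$dt,
              if (is.null(x$dipoles)) "" else ", dipoles",
              if (x$aborted) ", ABORTED" else ""))
  invisible(x)
}

#' Spectrum on a wavenumber grid
#'
#' @param wavenumbers strictly ascending grid, cm^-1.
#' @param intensities non-negative intensities, arbitrary units.
#' @return An object of class `spectrum`.
#' @export
new_spectrum <- function(wavenumbers, intensities) {
  wavenumbers <- as.numeric(wavenumbers)
  intensities <- as.numeric(intensities)
  if (length(wavenumbers) != length(intensities))
    stop("wavenumbers and intensities must have equal length")
  if (any(!is.finite(wavenumbers)) || any(!is.finite(intensities)))
    stop("spectrum values must be finite")
  if (length(wavenumbers) > 1 && any(diff(wavenumbers) <= 0))
    stop("wavenumbers must be strictly ascending")
  structure(list(wavenumbers = wavenumbers, intensities = intensities),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum: %d points, %.1f..%.1f cm^-1>\n",
              length(x$wavenumbers), min(x$wavenumbers), max(x$wavenumbers)))
  invisible(x)
}
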