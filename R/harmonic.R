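# Normal-mode analysis: finite-difference Hessians, mass-weighted
# eigenproblem, harmonic stick spectra and normal-mode sampling of the
# initial training set.

#' Finite-difference Hessian of a calculator
#'
#' Central differences of the analytic forces, symmetrized as
#' \eqn{(H + H^T)/2}.
#'
#' @param calc an [new_calculator()].
#' @param geom a [geometry()], ideally near a stationary point.
#' @param h displacement step, Angstrom (> 0).
#' @return symmetric 3N x 3N matrix, eV/Angstrom^2. Attribute `asymmetry`
#'   holds the max abs asymmetry before symmetrization.
#' @export
hessian <- function(calc, geom, h = 1e-3) {
  if (!is.numeric(h) || h <= 0) stop("h must be > 0")
  pos <- geom$positions
  n <- nrow(pos)
  H <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n)) for (c in 1:3) {
    col <- 3 * (i - 1) + c
    pp <- pos; pp[i, c] <- pp[i, c] + h
    pm <- pos; pm[i, c] <- pm[i, c] - h
    fp <- calc_eval(calc, pp)$forces
    fm <- calc_eval(calc, pm)$forces
    # H = d^2 E / dx^2 = -dF/dx
    H[, col] <- -as.vector(t(fp - fm)) / (2 * h)
  }
  asym <- max(abs(H - t(H)))
  Hs <- (H + t(H)) / 2
  attr(Hs, "asymmetry") <- asym
  Hs
}

#' Normal modes from a Hessian
#'
#' Eigendecomposition of the mass-weighted Hessian
#' \eqn{M^{-1/2} H M^{-1/2}}. Frequencies are returned in cm^-1;
#' negative eigenvalues (imaginary modes) are reported as negative
#' wavenumbers \eqn{-\sqrt{-\lambda}/(2\pi c)}.
#'
#' @param hess symmetric 3N x 3N Hessian, eV/Angstrom^2.
#' @param masses per-atom masses, amu.
#' @param rigid_threshold |wavenumber| below which a mode is classified as
#'   rigid translation/rotation, cm^-1.
#' @return object of class `normal_modes`: `frequencies` (cm^-1, ascending),
#'   `modes` (columns: mass-weighted orthonormal eigenvectors),
#'   `reduced_masses` (amu; the quantum-chemistry convention
#'   \eqn{\mu_m = 1/\sum_i l_{im}^2} with Cartesian displacements
#'   \eqn{l = M^{-1/2} q} — for a homonuclear unit-mass diatomic stretch
#'   this is 1 amu, not the relative-coordinate m/2),
#'   `rigid` (logical per mode), `masses`.
#' @export
normal_modes <- function(hess, masses, rigid_threshold = 5) {
  if (any(!is.finite(hess))) stop("Hessian contains non-finite entries")
  n3 <- nrow(hess)
  stopifnot(n3 == 3 * length(masses))
  invsqm <- rep(1 / sqrt(masses), each = 3)
  Hm <- hess * outer(invsqm, invsqm)
  Hm <- (Hm + t(Hm)) / 2
  eig <- eigen(Hm, symmetric = TRUE)
  lam <- rev(eig$values)            # ascending
  vec <- eig$vectors[, rev(seq_len(n3)), drop = FALSE]
  uc <- unit_constants()
  omega <- sqrt(abs(lam) * uc$acc_ev_A_amu)       # rad/fs
  nu <- sign(lam) * omega * uc$rad_fs_to_cm1      # cm^-1, imaginary negative
  # reduced mass per mode from the Cartesian displacement pattern
  red <- vapply(seq_len(n3), function(m) {
    l <- vec[, m] * invsqm
    1 / sum(l * l)
  }, numeric(1))
  structure(list(frequencies = nu, modes = vec, reduced_masses = red,
                 rigid = abs(nu) < rigid_threshold, masses = masses),
            class = "normal_modes")
}

#' @export
print.normal_modes <- function(x, ...) {
  cat(sprintf("<normal modes: %d total, %d vibrational; %s cm^-1>\n",
              length(x$frequencies), sum(!x$rigid),
              paste(sprintf("%.1f", x$frequencies[!x$rigid]), collapse = ", ")))
  invisible(x)
}

#' Vibrational (non-rigid) frequencies
#' @param nm a [normal_modes()] object.
#' @return numeric vector, cm^-1, ascending.
#' @export
vibrational_frequencies <- function(nm) nm$frequencies[!nm$rigid]

#' Harmonic (double-harmonic) stick IR spectrum
#'
#' Intensity of mode m is proportional to \eqn{|d\mu/dQ_m|^2}, the squared
#' dipole derivative along the mass-weighted normal coordinate, evaluated by
#' central differences of the calculator's dipole. Rigid modes are excluded.
#'
#' @param calc a dipole-providing [new_calculator()].
#' @param geom the minimized [geometry()] the modes belong to.
#' @param nm [normal_modes()] at that geometry.
#' @param dq displacement step along the mass-weighted mode,
#'   Angstrom*sqrt(amu) (> 0).
#' @return object of class `stick_spectrum`: `wavenumbers`, `intensities`.
#' @export
harmonic_ir <- function(calc, geom, nm, dq = 1e-3) {
  if (!is.numeric(dq) || dq <= 0) stop("dq must be > 0")
  if (!isTRUE(calc$provides_dipole)) stop("calculator must provide dipoles")
  invsqm <- rep(1 / sqrt(geom$masses), each = 3)
  keep <- which(!nm$rigid)
  pos <- geom$positions
  wn <- abs(nm$frequencies[keep])
  inten <- vapply(keep, function(m) {
    disp <- matrix(nm$modes[, m] * invsqm * dq, ncol = 3, byrow = TRUE)
    dp <- calc_eval(calc, pos + disp)$dipole
    dm <- calc_eval(calc, pos - disp)$dipole
    dmu <- (dp - dm) / (2 * dq)
    sum(dmu * dmu)
  }, numeric(1))
  o <- order(wn)
  structure(list(wavenumbers = wn[o], intensities = inten[o]),
            class = "stick_spectrum")
}

#' Write a stick spectrum as two-column text with a "stick" flag column
#' @param sticks a [harmonic_ir()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stick_spectrum <- function(sticks, path) {
  writeLines(c("# wavenumber_cm-1 intensity kind",
               sprintf("%.8f %.10e stick", sticks$wavenumbers,
                       sticks$intensities)), path)
  invisible(path)
}

#' Sample geometries along normal modes
#'
#' For each vibrational mode, displacements follow a sinusoidal cycle of
#' `n_phases` phases whose amplitude makes the maximum harmonic potential
#' energy along the mode equal to \eqn{k_B T_{ref}}; the first
#' `frames_per_mode` phases are returned. This is the initial-dataset
#' sampler: output count = (vibrational modes) x `frames_per_mode`.
#'
#' @param geom minimized [geometry()].
#' @param nm [normal_modes()] at that geometry.
#' @param frames_per_mode number of phases kept per mode (>= 1); default 10.
#' @param T_ref amplitude-setting temperature, K; default 300.
#' @param n_phases phases per full cycle; default 31. An odd count avoids
#'   mirror-image phase pairs (sin symmetric about the quarter cycle) that
#'   would duplicate geometries within the kept frames.
#' @param check_forces optional per-atom force matrix at `geom`; a warning
#'   is raised when max|F| exceeds `force_tol` (unminimized input).
#' @param force_tol eV/Angstrom; default 1e-3.
#' @return list of displaced [geometry()] objects.
#' @export
normal_mode_sample <- function(geom, nm, frames_per_mode = 10, T_ref = 300,
                               n_phases = 31, check_forces = NULL,
                               force_tol = 1e-3) {
  if (frames_per_mode < 1) stop("frames_per_mode must be >= 1")
  if (!is.null(check_forces) && max(abs(check_forces)) > force_tol)
    warning("sampling around an unminimized geometry (max|F| = ",
            signif(max(abs(check_forces)), 3), " eV/A)")
  uc <- unit_constants()
  invsqm <- rep(1 / sqrt(geom$masses), each = 3)
  keep <- which(!nm$rigid)
  out <- list()
  for (m in keep) {
    # eigenvalue back from the wavenumber; amplitude s.t. (1/2) lam A^2 = kB T
    omega <- abs(nm$frequencies[m]) / uc$rad_fs_to_cm1
    lam <- omega^2 / uc$acc_ev_A_amu            # eV / (A^2 amu)
    A <- sqrt(2 * uc$kB_eV * T_ref / lam)       # A sqrt(amu)
    for (p in seq_len(frames_per_mode)) {
      Q <- A * sin(2 * pi * p / n_phases)
      disp <- matrix(nm$modes[, m] * invsqm * Q, ncol = 3, byrow = TRUE)
      out[[length(out) + 1]] <- geometry(geom$symbols, geom$positions + disp,
                                         masses = geom$masses)
    }
  }
  out
}
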