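#' Construct a calculator
#'
#' A calculator is the package's single contract for anything that can label
#' a configuration: the analytic oracle, a fitted surrogate model, or a model
#' committee. Its `fn` maps an n x 3 position matrix to a list with `energy`
#' (eV), `forces` (eV/Angstrom), optionally `dipole` (Debye) and optionally
#' `rel_force_error` (the committee sanity statistic).
#'
#' @param fn function(positions) -> list(energy, forces, dipole = NULL,
#'   rel_force_error = NULL).
#' @param label short description.
#' @param provides_dipole logical.
#' @return An object of class `md_calculator`.
#' @export
new_calculator <- function(fn, label = "calculator", provides_dipole = FALSE) {
  stopifnot(is.function(fn))
  structure(list(fn = fn, label = label, provides_dipole = provides_dipole),
            class = "md_calculator")
}

#' @export
print.md_calculator <- function(x, ...) {
  cat(sprintf("<calculator: %s%s>\n", x$label,
              if (x$provides_dipole) ", with dipole" else ""))
  invisible(x)
}

#' Evaluate a calculator on a geometry
#' @param calc an [new_calculator()].
#' @param geom a [geometry()] (or bare position matrix).
#' @return list with energy, forces and optional dipole / rel_force_error.
#' @export
calc_eval <- function(calc, geom) {
  stopifnot(inherits(calc, "md_calculator"))
  pos <- if (inherits(geom, "geometry")) geom$positions else as.matrix(geom)
  out <- calc$fn(pos)
  if (!is.finite(out$energy) || any(!is.finite(out$forces)))
    stop("calculator '", calc$label, "' returned non-finite values")
  out
}

# run expr with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
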