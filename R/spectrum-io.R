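#' Read a two-column spectrum file
#'
#' Plain-text spectra: wavenumber (cm^-1) and intensity per row, `#` comment
#' lines allowed. Descending files are reversed to the ascending convention;
#' duplicate wavenumbers are rejected.
#'
#' @param path file path.
#' @return a [new_spectrum()].
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) < 2) stop("spectrum needs at least 2 data points: ", path)
  toks <- strsplit(trimws(lines), "[\\s,]+", perl = TRUE)
  if (any(vapply(toks, length, integer(1)) < 2))
    stop("each data row needs at least two columns: ", path)
  w <- suppressWarnings(as.numeric(vapply(toks, `[[`, character(1), 1L)))
  y <- suppressWarnings(as.numeric(vapply(toks, `[[`, character(1), 2L)))
  if (any(is.na(w)) || any(is.na(y)))
    stop("non-numeric row in spectrum file: ", path)
  if (anyDuplicated(w)) stop("duplicate wavenumbers in ", path)
  if (all(diff(w) < 0)) { w <- rev(w); y <- rev(y) }
  o <- order(w)
  new_spectrum(w[o], y[o])
}

#' Write a spectrum as two-column text
#'
#' @param spec a [new_spectrum()].
#' @param path output path.
#' @param std optional per-point standard deviation written as a third column.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path, std = NULL) {
  stopifnot(inherits(spec, "spectrum"))
  header <- "# wavenumber_cm-1 intensity"
  rows <- sprintf("%.8f %.10e", spec$wavenumbers, spec$intensities)
  if (!is.null(std)) {
    stopifnot(length(std) == length(spec$wavenumbers))
    header <- paste(header, "std")
    rows <- paste(rows, sprintf("%.10e", std))
  }
  writeLines(c(header, rows), path)
  invisible(path)
}
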