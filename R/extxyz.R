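#' Read an extended-XYZ file
#'
#' Parses the dialect `Properties=species:S:1:pos:R:3[:forces:R:3][:vel:R:3]`
#' with optional `energy=` and `dipole="dx dy dz"` entries in the comment
#' line. Missing labels yield absent (`NULL`) fields, never zeros.
#'
#' @param path file path.
#' @return list of [labeled_sample()] objects, one per frame.
#' @export
read_extxyz <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  samples <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!grepl("^\\s*$", lines[i]) || i < length(lines)) {
      if (grepl("^\\s*$", lines[i])) { i <- i + 1L; next }
    } else break
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 1)
      stop("malformed extended-XYZ header at line ", i, ": expected atom count")
    if (i + 1L + nat > length(lines))
      stop("frame starting at line ", i, " declares ", nat,
           " atoms but the file ends early")
    comment <- lines[i + 1L]
    fields <- .parse_xyz_comment(comment, i + 1L)
    body <- lines[(i + 2L):(i + 1L + nat)]
    toks <- strsplit(trimws(body), "\\s+")
    ncol_expected <- 1L + 3L * length(fields$cols)
    nc <- vapply(toks, length, integer(1))
    if (any(nc != ncol_expected))
      stop("frame at line ", i, ": atom lines have ", paste(unique(nc), collapse = "/"),
           " columns, expected ", ncol_expected, " (declared atom count or Properties mismatch)")
    sym <- vapply(toks, `[[`, character(1), 1L)
    num <- matrix(suppressWarnings(
      as.numeric(unlist(lapply(toks, `[`, -1L)))), nrow = nat, byrow = TRUE)
    if (any(is.na(num)))
      stop("frame at line ", i, ": non-numeric coordinate data")
    off <- 0L
    pos <- forces <- vel <- NULL
    for (cname in fields$cols) {
      block <- num[, (off + 1L):(off + 3L), drop = FALSE]
      if (cname == "pos") pos <- block
      if (cname == "forces") forces <- block
      if (cname == "vel") vel <- block
      off <- off + 3L
    }
    geom <- geometry(sym, pos, velocities = vel)
    samples[[length(samples) + 1L]] <-
      labeled_sample(geom, energy = fields$energy, forces = forces,
                     dipole = fields$dipole)
    i <- i + 2L + nat
    while (i <= length(lines) && grepl("^\\s*$", lines[i])) i <- i + 1L
  }
  if (length(samples) == 0) stop("no frames found in ", path)
  samples
}

# parse the key=value comment line; returns pos/forces/vel column order,
# energy and dipole (NULL when absent)
.parse_xyz_comment <- function(comment, lineno) {
  m <- regmatches(comment, gregexpr('[A-Za-z_]+="[^"]*"|[A-Za-z_]+=[^\\s"]+',
                                    comment, perl = TRUE))[[1]]
  kv <- list()
  for (tok in m) {
    eq <- regexpr("=", tok, fixed = TRUE)
    key <- substr(tok, 1, eq - 1L)
    val <- gsub('^"|"$', "", substr(tok, eq + 1L, nchar(tok)))
    kv[[key]] <- val
  }
  props <- kv[["Properties"]]
  if (is.null(props))
    stop("malformed extended-XYZ comment at line ", lineno,
         ": missing Properties=")
  p <- strsplit(props, ":", fixed = TRUE)[[1]]
  if (length(p) %% 3 != 0)
    stop("malformed Properties= at line ", lineno)
  names_p <- p[seq(1, length(p), 3)]
  sizes_p <- as.integer(p[seq(3, length(p), 3)])
  if (names_p[1] != "species" || sizes_p[1] != 1L)
    stop("Properties must start with species:S:1 (line ", lineno, ")")
  cols <- names_p[-1]
  if (!"pos" %in% cols) stop("Properties lacks pos:R:3 (line ", lineno, ")")
  if (any(sizes_p[-1] != 3L))
    stop("only 3-component per-atom fields are supported (line ", lineno, ")")
  energy <- if (!is.null(kv[["energy"]])) as.numeric(kv[["energy"]]) else NULL
  dipole <- if (!is.null(kv[["dipole"]]))
    as.numeric(strsplit(trimws(kv[["dipole"]]), "\\s+")[[1]]) else NULL
  if (!is.null(dipole) && (length(dipole) != 3 || any(is.na(dipole))))
    stop("malformed dipole= at line ", lineno)
  list(cols = cols, energy = energy, dipole = dipole)
}

#' Write samples to an extended-XYZ file
#'
#' Inverse of [read_extxyz()]: round-trips positions and labels to better
#' than 1e-12 and is byte-stable for fixed input.
#'
#' @param samples non-empty list of [labeled_sample()] (or [geometry()],
#'   which are wrapped without labels).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_extxyz <- function(samples, path) {
  if (length(samples) == 0) stop("refusing to write an empty extended-XYZ file")
  if (inherits(samples, "labeled_sample") || inherits(samples, "geometry"))
    samples <- list(samples)
  samples <- lapply(samples, function(s)
    if (inherits(s, "geometry")) labeled_sample(s) else s)
  con <- file(path, open = "wt")
  on.exit(close(con))
  fmt <- function(x) sprintf("%.15e", x)
  for (s in samples) {
    g <- s$geometry
    n <- n_atoms(g)
    cols <- "species:S:1:pos:R:3"
    blocks <- list(g$positions)
    if (!is.null(s$forces)) { cols <- paste0(cols, ":forces:R:3"); blocks <- c(blocks, list(s$forces)) }
    if (!is.null(g$velocities)) { cols <- paste0(cols, ":vel:R:3"); blocks <- c(blocks, list(g$velocities)) }
    comment <- paste0("Properties=", cols)
    if (!is.null(s$energy)) comment <- paste0(comment, " energy=", fmt(s$energy))
    if (!is.null(s$dipole))
      comment <- paste0(comment, ' dipole="', paste(fmt(s$dipole), collapse = " "), '"')
    writeLines(c(as.character(n), comment), con)
    num <- do.call(cbind, blocks)
    writeLines(paste(g$symbols, apply(num, 1, function(r)
      paste(fmt(r), collapse = " "))), con)
  }
  invisible(path)
}

#' Write a trajectory to extended-XYZ
#'
#' Per-frame dipoles and energies go into the comment line; the final frame
#' carries velocities when present.
#'
#' @param traj a [trajectory()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_extxyz <- function(traj, path) {
  samples <- lapply(seq_along(traj$frames), function(k) {
    labeled_sample(traj$frames[[k]],
                   energy = if (!is.null(traj$energies)) traj$energies[k] else NULL,
                   dipole = if (!is.null(traj$dipoles)) traj$dipoles[k, ] else NULL)
  })
  write_extxyz(samples, path)
}
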