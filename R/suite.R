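# Generation of the bundled surrogate study set: randomized, chemically
# plausible H/C/N/O molecules with Morse bonds, harmonic angles and fixed
# partial charges, each relaxed to its reference minimum.

.VALENCE <- c(H = 1L, C = 4L, N = 3L, O = 2L)

.R0_TABLE <- c("C-C" = 1.54, "C-N" = 1.47, "C-O" = 1.43, "N-N" = 1.45,
               "N-O" = 1.40, "O-O" = 1.48, "C-H" = 1.09, "N-H" = 1.01,
               "O-H" = 0.96)

.pair_r0 <- function(e1, e2) {
  key <- paste(sort(c(e1, e2)), collapse = "-")
  r0 <- .R0_TABLE[key]
  if (is.na(r0)) 1.2 else unname(r0)
}

.BASE_CHARGE <- c(H = 0.15, C = -0.05, N = -0.25, O = -0.35)

#' Build a two-atom surrogate molecule
#'
#' Convenience constructor for the diatomic test systems used throughout:
#' a single harmonic or Morse bond with opposite point charges. With
#' `k = 1` eV/A^2 and unit masses the harmonic stretch frequency is
#' \eqn{\sqrt{k/\mu}/(2\pi c) \approx 737.5} cm^-1.
#'
#' @param style "harmonic" or "morse".
#' @param k harmonic force constant, eV/A^2.
#' @param De,a Morse well depth (eV) and range (1/Angstrom); the harmonic
#'   limit force constant is `2 * De * a^2`.
#' @param r0 equilibrium bond length, Angstrom.
#' @param q charge magnitude, e (charges +q, -q).
#' @param symbols two element symbols.
#' @param masses optional mass override, amu.
#' @return a [surrogate_molecule()].
#' @export
surrogate_diatomic <- function(style = c("harmonic", "morse"), k = 1,
                               De = 0.5, a = 1, r0 = 1, q = 0.2,
                               symbols = c("H", "H"), masses = c(1, 1)) {
  style <- match.arg(style)
  geom <- geometry(symbols, rbind(c(0, 0, 0), c(r0, 0, 0)), masses = masses)
  bond <- if (style == "harmonic")
    list(i = 1L, j = 2L, style = "harmonic", k = k, r0 = r0)
  else list(i = 1L, j = 2L, style = "morse", De = De, a = a, r0 = r0)
  surrogate_molecule(geom, list(bond), charges = c(q, -q),
                     name = paste0(style, "-diatomic"))
}

# random spatial embedding of a bond tree, clash-avoiding
.embed_geometry <- function(symbols, bonds, masses = NULL) {
  n <- length(symbols)
  pos <- matrix(NA_real_, n, 3)
  pos[1, ] <- 0
  placed <- 1L
  adj <- lapply(seq_len(n), function(i) integer(0))
  r0s <- matrix(NA_real_, n, n)
  for (b in bonds) {
    adj[[b$i]] <- c(adj[[b$i]], b$j); adj[[b$j]] <- c(adj[[b$j]], b$i)
    r0s[b$i, b$j] <- r0s[b$j, b$i] <- b$r0
  }
  queue <- 1L
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if (w %in% placed) next
      for (try in 1:80) {
        u <- stats::rnorm(3); u <- u / sqrt(sum(u * u))
        cand <- pos[v, ] + r0s[v, w] * u
        dmin <- min(sqrt(rowSums(sweep(pos[placed, , drop = FALSE], 2, cand)^2)))
        if (dmin > 0.8 * r0s[v, w] || try == 80) { pos[w, ] <- cand; break }
      }
      placed <- c(placed, w); queue <- c(queue, w)
    }
  }
  geometry(symbols, pos, masses = masses)
}

.random_molecule <- function(n_tot, name) {
  stopifnot(n_tot >= 2)
  if (n_tot == 2) {
    pairs <- list(c("C", "O"), c("N", "O"), c("C", "N"),
                  c("N", "H"), c("O", "H"), c("C", "H"))
    sym <- pairs[[sample.int(length(pairs), 1)]]
    heavy <- seq_along(sym)
    bonds_idx <- list(c(1L, 2L))
  } else {
    for (attempt in 1:40) {
      n_heavy <- sample(seq.int(1L, max(1L, min(4L, n_tot - 1L))), 1)
      heavy_sym <- sample(c("C", "N", "O"), n_heavy, replace = TRUE,
                          prob = c(0.5, 0.25, 0.25))
      n_h <- n_tot - n_heavy
      sym <- c(heavy_sym, rep("H", n_h))
      val <- .VALENCE[sym]
      deg <- integer(n_tot)
      bonds_idx <- list()
      ok <- TRUE
      # random tree over heavy atoms
      if (n_heavy > 1) for (w in 2:n_heavy) {
        cand <- which(deg[1:(w - 1)] < val[1:(w - 1)])
        if (length(cand) == 0) { ok <- FALSE; break }
        v <- cand[sample.int(length(cand), 1)]
        bonds_idx[[length(bonds_idx) + 1]] <- c(v, w)
        deg[v] <- deg[v] + 1L; deg[w] <- deg[w] + 1L
      }
      if (!ok) next
      # occasional ring closure
      if (n_heavy >= 3 && stats::runif(1) < 0.2) {
        spare <- which(deg[1:n_heavy] < val[1:n_heavy])
        if (length(spare) >= 2) {
          pr <- sample(spare, 2)
          already <- any(vapply(bonds_idx, function(b)
            setequal(b, pr), logical(1)))
          if (!already) {
            bonds_idx[[length(bonds_idx) + 1]] <- pr
            deg[pr] <- deg[pr] + 1L
          }
        }
      }
      # hydrogens onto spare heavy valence
      if (n_h > 0) {
        for (h in (n_heavy + 1):n_tot) {
          spare <- which(deg[1:n_heavy] < val[1:n_heavy])
          if (length(spare) == 0) { ok <- FALSE; break }
          v <- spare[sample.int(length(spare), 1)]
          bonds_idx[[length(bonds_idx) + 1]] <- c(v, h)
          deg[v] <- deg[v] + 1L; deg[h] <- deg[h] + 1L
        }
      }
      if (ok) break
      if (attempt == 40)
        stop("impossible valence request: cannot bond ", n_tot,
             " atoms of composition ", paste(sym, collapse = ""))
    }
  }
  bonds <- lapply(bonds_idx, function(ij) {
    e1 <- sym[ij[1]]; e2 <- sym[ij[2]]
    list(i = as.integer(ij[1]), j = as.integer(ij[2]), style = "morse",
         De = stats::runif(1, 2.5, 5),
         a = stats::runif(1, 1.6, 2.4),
         r0 = .pair_r0(e1, e2) * stats::runif(1, 0.97, 1.03))
  })
  # one harmonic angle per pair of bonds sharing a centre
  nb <- lapply(seq_along(sym), function(i) integer(0))
  for (b in bonds) { nb[[b$i]] <- c(nb[[b$i]], b$j); nb[[b$j]] <- c(nb[[b$j]], b$i) }
  angles <- list()
  for (j in seq_along(sym)) {
    ns <- nb[[j]]
    if (length(ns) < 2) next
    cmb <- utils::combn(ns, 2)
    for (cidx in seq_len(ncol(cmb))) {
      angles[[length(angles) + 1]] <- list(
        i = as.integer(cmb[1, cidx]), j = as.integer(j),
        k = as.integer(cmb[2, cidx]),
        ktheta = stats::runif(1, 2, 5),
        theta0 = (109.47 + stats::runif(1, -8, 8)) * pi / 180)
    }
  }
  charges <- .BASE_CHARGE[sym] + stats::runif(length(sym), -0.05, 0.05)
  geom <- .embed_geometry(sym, bonds)
  surrogate_molecule(geom, bonds, angles, charges, name = name)
}

#' Generate a suite of surrogate molecules
#'
#' Deterministic (for a fixed seed) generator of small randomized H/C/N/O
#' molecules: tree-plus-occasional-ring bond graphs respecting simple
#' valences, Morse bond parameters drawn from documented ranges
#' (De 2.5-5 eV, a 1.6-2.4 1/A, r0 within 3% of tabulated bond lengths),
#' harmonic angles near tetrahedral, and electronegativity-ordered partial
#' charges. Each reference geometry is relaxed to max|F| < 1e-3 eV/A.
#'
#' @param n_molecules number of molecules (>= 1).
#' @param size_range integer 2-vector, atoms per molecule, within [2, 12].
#' @param seed integer seed; fixed seed gives identical output.
#' @return list of [surrogate_molecule()] objects.
#' @export
make_surrogate_suite <- function(n_molecules, size_range = c(2, 6), seed = 1) {
  if (n_molecules < 1) stop("n_molecules must be >= 1")
  if (length(size_range) != 2 || size_range[1] < 2 || size_range[2] > 12 ||
      size_range[1] > size_range[2])
    stop("size_range must lie within [2, 12]")
  with_seed(seed, {
    used <- character(0)
    out <- vector("list", n_molecules)
    for (m in seq_len(n_molecules)) {
      # draw until the composition is new: distinct surrogates with the same
      # element composition would be indistinguishable to composition-keyed
      # surrogate models, so the bundled suite keeps compositions unique
      for (draw in 1:200) {
        n_tot <- if (size_range[1] == size_range[2]) size_range[1] else
          sample(seq.int(size_range[1], size_range[2]), 1)
        mol <- .random_molecule(n_tot, name = sprintf("surrogate-%02d", m))
        key <- paste(sort(mol$geometry$symbols), collapse = "")
        if (!key %in% used || draw == 200) break
      }
      used <- c(used, key)
      for (try in 1:5) {
        gmin <- suppressWarnings(minimize_geometry(mol))
        if (attr(gmin, "fmax") < 1e-3) break
        mol <- .random_molecule(n_tot, name = mol$name)
      }
      mol$geometry <- gmin
      out[[m]] <- mol
    }
    out
  })
}

#' Serialize a surrogate molecule to a text file
#'
#' One YAML document per molecule: symbols, reference positions, bond and
#' angle terms, charges. [read_surrogate()] restores it exactly.
#'
#' @param mol a [surrogate_molecule()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_surrogate <- function(mol, path) {
  obj <- list(name = mol$name,
              symbols = mol$geometry$symbols,
              masses = mol$geometry$masses,
              positions = apply(mol$geometry$positions, 1, identity,
                                simplify = FALSE),
              bonds = mol$bonds, angles = mol$angles,
              charges = mol$charges)
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' Read a surrogate molecule written by [write_surrogate()]
#' @param path file path.
#' @return a [surrogate_molecule()].
#' @export
read_surrogate <- function(path) {
  obj <- yaml::read_yaml(path)
  geom <- geometry(obj$symbols,
                   do.call(rbind, obj$positions),
                   masses = as.numeric(obj$masses))
  surrogate_molecule(geom, obj$bonds, obj$angles, as.numeric(obj$charges),
                     name = obj$name)
}
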