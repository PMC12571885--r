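# Clustering-based held-out test set construction: uniform trajectory
# subsampling, a 2-body MBTR-style descriptor (Gaussian-broadened histograms
# of inverse pairwise distances per element-pair channel) and k-means
# stratified random selection.

#' Descriptor configuration
#'
#' @param grid_min,grid_max inverse-distance grid bounds, 1/Angstrom.
#' @param n_bins number of grid bins (>= 8).
#' @param broadening Gaussian broadening width on the 1/r axis (> 0).
#' @param elements element channel alphabet; all unordered pairs form the
#'   descriptor channels.
#' @return list of class `descriptor_config`.
#' @export
descriptor_config <- function(grid_min = 0, grid_max = 1.6, n_bins = 32,
                              broadening = 0.05,
                              elements = c("H", "C", "N", "O")) {
  if (n_bins < 8) stop("n_bins must be >= 8")
  if (broadening <= 0) stop("broadening must be > 0")
  if (grid_max <= grid_min) stop("grid_max must exceed grid_min")
  pairs <- utils::combn(sort(elements), 2)
  channels <- c(paste(sort(elements), sort(elements), sep = "-"),
                paste(pairs[1, ], pairs[2, ], sep = "-"))
  structure(list(grid = seq(grid_min, grid_max, length.out = n_bins),
                 broadening = broadening, channels = sort(channels)),
            class = "descriptor_config")
}

#' Uniformly subsample trajectory frames
#'
#' Evenly spaced frame indices including the first and last frame.
#'
#' @param traj a [trajectory()].
#' @param n number of frames (1 <= n <= frame count).
#' @return list of [geometry()] frames; attribute `indices` holds the
#'   selected frame indices.
#' @export
subsample_uniform <- function(traj, n) {
  stopifnot(inherits(traj, "trajectory"))
  nf <- length(traj$frames)
  if (n < 1) stop("n must be >= 1")
  if (n > nf) stop("cannot subsample ", n, " frames from ", nf)
  idx <- if (n == 1) 1L else as.integer(round(seq(1, nf, length.out = n)))
  # rounding can collide adjacent indices when n is close to nf; make the
  # sequence strictly increasing (spacing >= 1 guarantees there is room)
  if (n > 1) {
    for (t in 2:n) if (idx[t] <= idx[t - 1]) idx[t] <- idx[t - 1] + 1L
    idx <- pmin(idx, nf)
    idx <- unique(idx)
  }
  out <- traj$frames[idx]
  attr(out, "indices") <- idx
  out
}

#' 2-body structural descriptor of a geometry
#'
#' Per element-pair channel, a Gaussian-broadened histogram of inverse
#' pairwise distances on the configured grid; channels are concatenated in
#' fixed alphabetical order, so the vector length is independent of the
#' molecule. Invariant to rotations, translations and permutations of
#' like atoms.
#'
#' @param geom a [geometry()].
#' @param config a [descriptor_config()].
#' @return numeric feature vector of length `n_bins * n_channels`.
#' @export
structure_descriptor <- function(geom, config = descriptor_config()) {
  stopifnot(inherits(config, "descriptor_config"))
  n <- n_atoms(geom)
  grid <- config$grid
  feat <- matrix(0, length(grid), length(config$channels),
                 dimnames = list(NULL, config$channels))
  if (n >= 2) {
    idx <- t(utils::combn(n, 2))
    d <- geom$positions[idx[, 1], , drop = FALSE] -
      geom$positions[idx[, 2], , drop = FALSE]
    r <- sqrt(rowSums(d * d))
    if (any(r < 1e-6)) stop("overlapping atoms in descriptor evaluation")
    ch <- apply(idx, 1, function(ij)
      paste(sort(geom$symbols[ij]), collapse = "-"))
    unknown <- setdiff(unique(ch), config$channels)
    if (length(unknown) > 0)
      stop("element pair(s) not covered by the descriptor config: ",
           paste(unknown, collapse = ", "))
    for (p in seq_along(r)) {
      feat[, ch[p]] <- feat[, ch[p]] +
        stats::dnorm(grid, mean = 1 / r[p], sd = config$broadening)
    }
  }
  as.vector(feat)
}

# k-means++ seeding (stats::kmeans has no built-in k-means++ option)
.kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums(sweep(X, 2, X[centers[1], ])^2)
  for (j in seq_len(k)[-1]) {
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j] <- sample.int(n, 1, prob = probs)
    d2 <- pmin(d2, rowSums(sweep(X, 2, X[centers[j], ])^2))
  }
  X[centers, , drop = FALSE]
}

#' Cluster-stratified random selection
#'
#' k-means (k-means++ initialization, fixed seed and iteration cap) in
#' feature space; `per_cluster` members are drawn uniformly without
#' replacement from each cluster (all members when a cluster is smaller,
#' flagged in the result).
#'
#' @param features numeric matrix, one row per candidate.
#' @param k number of clusters; default 5.
#' @param per_cluster structures per cluster; default 4.
#' @param seed integer seed.
#' @return integer vector of selected row indices; attributes `clusters`
#'   (full assignment) and `short_clusters` (clusters smaller than
#'   `per_cluster`).
#' @export
kmeans_select <- function(features, k = 5, per_cluster = 4, seed = 1) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < k) stop("need at least k = ", k, " candidates, got ", n)
  with_seed(seed, {
    # drop constant columns to keep kmeans stable, keep determinism
    centers <- .kmeanspp_centers(features, k)
    centers <- centers + 1e-12 * matrix(stats::rnorm(length(centers)),
                                        nrow = k)  # break exact duplicates
    km <- suppressWarnings(
      stats::kmeans(features, centers = centers, iter.max = 100))
    sel <- integer(0)
    short <- integer(0)
    for (cl in seq_len(k)) {
      members <- which(km$cluster == cl)
      if (length(members) <= per_cluster) {
        if (length(members) < per_cluster) short <- c(short, cl)
        take <- members
      } else {
        take <- members[sample.int(length(members), per_cluster)]
      }
      sel <- c(sel, take)
    }
    sel <- sort(sel)
    attr(sel, "clusters") <- km$cluster
    attr(sel, "short_clusters") <- short
    sel
  })
}

#' Build a clustering-based labelled test set
#'
#' Per molecule: a Langevin MD run at `temperature` driven by `calc_fn`'s
#' calculator, uniform subsampling of `n_sub` frames, descriptor
#' featurization, k-means-stratified selection and oracle labelling.
#' Selection provenance (frame indices and cluster ids) is recorded.
#'
#' @param molecules list of [surrogate_molecule()] (the labelling oracles).
#' @param calc_fn function(molecule) returning the MD [new_calculator()];
#'   defaults to the oracle itself. Pass a committee-backed calculator to
#'   mirror a production workflow driven by the learned potential.
#' @param md_ps MD length, ps; (protocol value 100, desk-scale runs shrink
#'   it proportionally with `n_sub`).
#' @param n_sub uniformly subsampled frames per molecule (protocol 2000).
#' @param k,per_cluster clustering parameters; defaults 5 and 4
#'   (20 structures per molecule).
#' @param temperature K; default 300.
#' @param dt timestep fs; `record_every` recording stride.
#' @param record_every record stride, steps.
#' @param seed base seed.
#' @return list with `samples` (oracle-labelled [labeled_sample()] list) and
#'   `provenance` (data.frame: molecule, frame index, cluster).
#' @export
build_test_set <- function(molecules, calc_fn = oracle_calculator,
                           md_ps = 100, n_sub = 2000, k = 5, per_cluster = 4,
                           temperature = 300, dt = 0.5, record_every = 10,
                           seed = 1) {
  config <- descriptor_config()
  samples <- list()
  prov <- list()
  for (mi in seq_along(molecules)) {
    mol <- molecules[[mi]]
    calc <- calc_fn(mol)
    n_steps <- round(md_ps * 1000 / dt)
    g0 <- init_velocities(mol$geometry, temperature, seed = seed + 7919L * mi)
    traj <- run_md(calc, g0,
                   md_settings(dt = dt, friction = 0.01,
                               temperature = temperature, n_steps = n_steps,
                               seed = seed + 104729L + mi,
                               record_every = record_every))
    frames <- subsample_uniform(traj, min(n_sub, length(traj$frames)))
    feats <- t(vapply(frames, structure_descriptor,
                      numeric(length(config$grid) * length(config$channels)),
                      config = config))
    sel <- kmeans_select(feats, k = k, per_cluster = per_cluster,
                         seed = seed + mi)
    for (s in sel) {
      samples[[length(samples) + 1]] <-
        oracle_evaluate(mol, geometry(mol$geometry$symbols,
                                      frames[[s]]$positions,
                                      masses = mol$geometry$masses))
    }
    prov[[mi]] <- data.frame(
      molecule = mol$name,
      frame = attr(frames, "indices")[sel],
      cluster = attr(sel, "clusters")[sel])
  }
  list(samples = samples, provenance = do.call(rbind, prov))
}
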