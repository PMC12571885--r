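# Pluggable surrogate-potential layer. The reference implementation is a
# Gaussian kernel ridge regression of total energy on a permutation-invariant
# descriptor (per element-pair class, sorted inverse interatomic distances),
# with forces from the analytic chain-rule gradient of the kernel. A
# committee of bootstrap-resampled members supplies force uncertainties.
# Externally trained potentials can be plugged in through the same
# calculator contract; nothing downstream depends on this implementation.

.composition_key <- function(symbols) paste(sort(symbols), collapse = "")

.descriptor_layout <- function(symbols) {
  n <- length(symbols)
  if (n < 2) stop("descriptor requires at least 2 atoms")
  idx <- t(utils::combn(n, 2))
  cls <- apply(idx, 1, function(ij) paste(sort(symbols[ij]), collapse = "-"))
  ord <- order(cls)
  list(i = idx[ord, 1], j = idx[ord, 2], n = n,
       groups = split(seq_along(ord), cls[ord]))
}

# inverse-distance descriptor, sorted descending within each element-pair
# class; optional jacobian wrt flattened coordinates (x1 y1 z1 x2 ...)
.desc_eval <- function(pos, layout, jacobian = FALSE) {
  d <- pos[layout$i, , drop = FALSE] - pos[layout$j, , drop = FALSE]
  r <- sqrt(rowSums(d * d))
  if (any(r < 1e-8)) stop("overlapping atoms in descriptor evaluation")
  invr <- 1 / r
  perm <- integer(length(invr))
  for (g in layout$groups) perm[g] <- g[order(invr[g], decreasing = TRUE)]
  out <- list(d = invr[perm])
  if (jacobian) {
    J <- matrix(0, length(invr), 3 * layout$n)
    for (s in seq_along(invr)) {
      p <- perm[s]
      i <- layout$i[p]; j <- layout$j[p]
      g <- -d[p, ] / r[p]^3                     # d(1/r_ij)/d r_i
      J[s, (3 * i - 2):(3 * i)] <- g
      J[s, (3 * j - 2):(3 * j)] <- -g
    }
    out$J <- J
  }
  out
}

# Fit the kernel weights alpha of
#   E(x) = ymean + w_prior . (d(x) - dbar) + sum_m alpha_m k(d(x), D_m)
# by weighted ridge least squares over energy labels and (when present)
# force labels. Forces are linear in alpha through the chain-rule gradient,
# so force residuals simply add design rows; fitting them is what makes the
# model's gradients (and hence MD and Hessians) reliable, mirroring
# production potentials trained on energies plus forces.
#
# w_prior is a FIXED (never fitted) random linear prior in descriptor
# space, drawn per committee member and gated by kernel support at
# prediction time: inside the training manifold the gate shuts it off, so
# the fit and the in-manifold dynamics are exactly those of a pure kernel
# regression, while far outside the kernel decays, the gate opens, and
# each member reverts to its own prior slope. This randomized-prior
# construction keeps ensemble disagreement alive off the training
# manifold, where a plain kernel committee would collapse to exact
# agreement; it plays the role weight initialization plays in
# neural-network ensembles.
.fit_kernel_block <- function(D, y, sigma, lambda, jacs = NULL,
                              forces = NULL, force_weight = 1,
                              weights = NULL, w_prior = NULL) {
  if (is.null(sigma)) {
    dd <- stats::dist(D)
    med <- stats::median(dd)
    sigma <- if (is.finite(med) && med > 0) med else 1
  }
  n <- nrow(D)
  if (is.null(weights)) weights <- rep(1, n)
  sw <- sqrt(weights)
  ym <- stats::weighted.mean(y, weights)
  K <- exp(-as.matrix(stats::dist(D))^2 / (2 * sigma^2))
  rows <- list(K * sw)
  targ <- list((y - ym) * sw)
  if (!is.null(forces) && force_weight > 0) for (s in seq_len(n)) {
    if (is.null(forces[[s]]) || weights[s] == 0) next
    diff <- sweep(D, 2, D[s, ])                # rows: D_m - d_s
    G <- t(diff * (K[s, ] / sigma^2))          # p x n: grad_d k(d_s, D_m)
    # F(s) = -J_s^T G alpha  (3N x n block)
    rows[[length(rows) + 1]] <-
      -(force_weight * sw[s]) * crossprod(jacs[[s]], G)
    targ[[length(targ) + 1]] <-
      (force_weight * sw[s]) * as.vector(t(forces[[s]]))
  }
  A <- do.call(rbind, rows)
  b <- unlist(targ)
  alpha <- tryCatch(
    solve(crossprod(A) + lambda * diag(n), crossprod(A, b)),
    error = function(e)
      stop("singular kernel system; increase the ridge parameter lambda"))
  list(D = D, alpha = as.vector(alpha), w = w_prior, sigma = sigma,
       ymean = ym, dbar = colMeans(D))
}

.predict_kernel_block <- function(block, de, forces = TRUE) {
  diff <- sweep(block$D, 2, de$d)               # rows: D_n - d
  q <- rowSums(diff^2)
  k <- exp(-q / (2 * block$sigma^2))
  energy <- block$ymean + sum(block$alpha * k)
  gdesc <- NULL
  if (forces) gdesc <- colSums((block$alpha * k) * diff) / block$sigma^2
  if (!is.null(block$w)) {
    # support gate: ~1 at/near training descriptors (and through the
    # few-sigma halo MD exploration visits, so acquisition ranking stays
    # data-driven), ->0 in the genuinely unexplored region
    sg2 <- (8 * block$sigma)^2
    nstar <- which.min(q)
    s <- exp(-q[nstar] / (2 * sg2))
    dc <- de$d - block$dbar
    energy <- energy + (1 - s) * sum(block$w * dc)
    if (forces) {
      # d/dd [(1-s) w.dc] = (1-s) w + (w.dc) s (d - D_n*) / sg2
      gdesc <- gdesc + (1 - s) * block$w +
        sum(block$w * dc) * s * (-diff[nstar, ]) / sg2
    }
  }
  out <- list(energy = energy)
  if (forces) {
    grad <- as.vector(crossprod(de$J, gdesc))
    out$forces <- -matrix(grad, ncol = 3, byrow = TRUE)
  }
  out
}

#' Fit the reference potential model
#'
#' Gaussian kernel ridge regression of total energy on sorted
#' inverse-distance pair descriptors, partitioned internally by element
#' composition (one kernel block per distinct composition in the training
#' set). Forces come from the analytic gradient of the fitted kernel
#' expansion. Deterministic for fixed inputs.
#'
#' @param samples list of energy-labelled [labeled_sample()] (>= 5); force
#'   labels, when present, enter the fit as additional linear constraints
#'   (weighted by `force_weight`) and are what make the model's gradients
#'   quantitative.
#' @param hyperparams list: `sigma` (kernel width in descriptor space; NULL
#'   selects the median pairwise descriptor distance per block), `lambda`
#'   (ridge, default 1e-6), `force_weight` (weight of force residuals
#'   relative to energy residuals, default 1; 0 fits energies only) and
#'   `prior_scale` (scale of the support-gated randomized linear prior used
#'   for committee diversity off the training manifold; 0, the default for
#'   a standalone model, disables it).
#' @param seed seeds the randomized linear prior when
#'   `hyperparams$prior_scale > 0`; the default fit (`prior_scale = 0`) is
#'   fully deterministic and ignores it.
#' @param weights optional per-sample non-negative weights (e.g. bootstrap
#'   multiplicities from [fit_committee()]); all samples remain kernel
#'   centers, weights scale their residuals in the fit.
#' @return object of class `ref_potential`.
#' @export
fit_reference_model <- function(samples, hyperparams = list(), seed = NULL,
                                weights = NULL) {
  if (length(samples) < 5) stop("need at least 5 training samples")
  if (any(vapply(samples, function(s) is.null(s$energy), logical(1))))
    stop("all training samples must carry an energy label")
  sigma <- hyperparams$sigma
  lambda <- if (is.null(hyperparams$lambda)) 1e-6 else hyperparams$lambda
  force_weight <- if (is.null(hyperparams$force_weight)) 1
                  else hyperparams$force_weight
  prior_scale <- if (is.null(hyperparams$prior_scale)) 0
                 else hyperparams$prior_scale
  if (is.null(weights)) weights <- rep(1, length(samples))
  if (length(weights) != length(samples) || any(weights < 0))
    stop("weights must be non-negative, one per sample")
  keys <- vapply(samples, function(s) .composition_key(s$geometry$symbols),
                 character(1))
  blocks <- list()
  for (key in unique(keys)) {
    sub <- samples[keys == key]
    wsub <- weights[keys == key]
    layout <- .descriptor_layout(sub[[1]]$geometry$symbols)
    p <- length(layout$i)
    des <- lapply(sub, function(s)
      .desc_eval(s$geometry$positions, layout, jacobian = force_weight > 0))
    D <- do.call(rbind, lapply(des, `[[`, "d"))
    y <- vapply(sub, `[[`, numeric(1), "energy")
    w_prior <- NULL
    if (prior_scale > 0 && !is.null(seed)) {
      # random linear prior: slope scale tied to the label spread per
      # descriptor dimension (dimensionally an energy per descriptor unit);
      # robust spread estimates so occasional high-energy outliers in the
      # dataset cannot inflate the prior and its in-manifold cancellation
      # error
      sdj <- apply(D, 2, stats::sd)
      sdj <- pmax(sdj, mean(sdj) + 1e-12)
      yspread <- stats::mad(y)
      if (yspread == 0) yspread <- stats::sd(y)
      w_prior <- with_seed(seed + match(key, unique(keys)),
                           stats::rnorm(ncol(D))) *
        prior_scale * yspread / sdj
    }
    bl <- .fit_kernel_block(D, y, sigma, lambda,
                            jacs = lapply(des, `[[`, "J"),
                            forces = lapply(sub, `[[`, "forces"),
                            force_weight = force_weight, weights = wsub,
                            w_prior = w_prior)
    bl$layout <- layout
    blocks[[key]] <- bl
  }
  structure(list(blocks = blocks, lambda = lambda), class = "ref_potential")
}

#' Predict energy and forces with a fitted potential
#' @param model a `ref_potential` from [fit_reference_model()].
#' @param geom a [geometry()] (composition must be in the training set).
#' @return list with `energy` (eV) and `forces` (eV/Angstrom).
#' @export
predict_potential <- function(model, geom) {
  stopifnot(inherits(model, "ref_potential"))
  key <- .composition_key(geom$symbols)
  block <- model$blocks[[key]]
  if (is.null(block)) stop("composition ", key, " not in the training set")
  de <- .desc_eval(geom$positions, block$layout, jacobian = TRUE)
  .predict_kernel_block(block, de)
}

#' Calculator for a fitted potential bound to a molecule's composition
#' @param model a `ref_potential`.
#' @param template a [geometry()] supplying symbols/ordering.
#' @return an [new_calculator()].
#' @export
model_calculator_for <- function(model, template) {
  key <- .composition_key(template$symbols)
  block <- model$blocks[[key]]
  if (is.null(block)) stop("composition ", key, " not in the training set")
  new_calculator(function(pos) {
    de <- .desc_eval(pos, block$layout, jacobian = TRUE)
    .predict_kernel_block(block, de)
  }, label = "ref-potential")
}

#' Fit a committee of reference models
#'
#' Each member is a [fit_reference_model()] fit under a seeded bootstrap
#' resample of the training set, realized as multiplicity weights (every
#' sample stays a kernel center; its residual weight is how often the
#' bootstrap drew it). Member seeds are `seed_base + 0 ... M-1`. The
#' resampling supplies the model diversity a deterministic kernel fit
#' otherwise lacks, while the shared basis keeps members in close agreement
#' where data is dense. Each member additionally carries a support-gated
#' randomized linear prior (`hyperparams$prior_scale`, default 2): inert
#' inside the training manifold, it makes members extrapolate along
#' different slopes outside it, so the committee force disagreement keeps
#' growing off-manifold instead of collapsing with the kernel.
#'
#' @param samples labelled training samples.
#' @param M committee size; default 3.
#' @param hyperparams passed to [fit_reference_model()].
#' @param seed_base integer.
#' @return object of class `committee` with fields `members`, `member_seeds`.
#' @export
fit_committee <- function(samples, M = 3, hyperparams = list(), seed_base = 1) {
  if (M < 1) stop("M must be >= 1")
  n <- length(samples)
  if (is.null(hyperparams$prior_scale)) hyperparams$prior_scale <- 2
  seeds <- seed_base + seq_len(M) - 1L
  members <- lapply(seeds, function(s) {
    mult <- tabulate(with_seed(s, sample.int(n, replace = TRUE)), nbins = n)
    fit_reference_model(samples, hyperparams, seed = 7919L * s,
                        weights = mult)
  })
  structure(list(members = members, member_seeds = seeds), class = "committee")
}

#' @export
print.committee <- function(x, ...) {
  cat(sprintf("<committee of %d reference models>\n", length(x$members)))
  invisible(x)
}

.pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# evaluate all members once; shared by the committee statistics
.committee_eval <- function(committee, geom) {
  pos <- if (inherits(geom, "geometry")) geom$positions else as.matrix(geom)
  key_geom <- if (inherits(geom, "geometry")) geom else NULL
  lapply(committee$members, function(m) {
    block <- if (!is.null(key_geom))
      m$blocks[[.composition_key(key_geom$symbols)]]
    else if (length(m$blocks) == 1) m$blocks[[1]] else NULL
    if (is.null(block)) stop("cannot resolve composition for committee member")
    de <- .desc_eval(pos, block$layout, jacobian = TRUE)
    .predict_kernel_block(block, de)
  })
}

#' Committee mean prediction with per-atom force uncertainty
#'
#' @param committee a [fit_committee()] result (M >= 2 for the uncertainty).
#' @param geom a [geometry()].
#' @return list: `energy` (mean, eV), `forces` (mean, eV/A), `force_std`
#'   (n x 3 component-wise standard deviation across members, eV/A).
#' @export
committee_predict <- function(committee, geom) {
  stopifnot(inherits(committee, "committee"))
  if (length(committee$members) < 2)
    stop("committee uncertainty requires at least 2 members")
  preds <- .committee_eval(committee, geom)
  fs <- lapply(preds, `[[`, "forces")
  n <- nrow(fs[[1]])
  arr <- array(unlist(fs), dim = c(n, 3, length(fs)))
  list(energy = mean(vapply(preds, `[[`, numeric(1), "energy")),
       forces = apply(arr, c(1, 2), mean),
       force_std = apply(arr, c(1, 2), .pop_sd))
}

#' Relative force error (committee sanity statistic)
#'
#' Root of the mean force variance across committee members, normalized by
#' the root-mean-square committee force magnitude plus a small
#' regularization `eps`. During committee-driven MD, a value above 0.5
#' terminates the run.
#'
#' @param committee a fitted committee (M >= 2).
#' @param geom a [geometry()].
#' @param eps regularization, eV/Angstrom (> 0); default 1e-3.
#' @return scalar statistic.
#' @export
relative_force_error <- function(committee, geom, eps = 1e-3) {
  if (eps <= 0) stop("eps must be > 0")
  cp <- committee_predict(committee, geom)
  sqrt(mean(cp$force_std^2)) / (sqrt(mean(cp$forces^2)) + eps)
}

#' Frame-level acquisition score
#'
#' Aggregates the committee force uncertainty over a configuration. The
#' default is the maximum over atoms of the Euclidean norm of the per-atom
#' force standard deviation (reacting to the worst-described atom); `"rms"`
#' averages instead.
#'
#' @param committee a fitted committee (M >= 2).
#' @param geom a [geometry()].
#' @param aggregate "max" (default) or "rms" over atoms.
#' @return scalar uncertainty, eV/Angstrom.
#' @export
frame_uncertainty <- function(committee, geom, aggregate = c("max", "rms")) {
  aggregate <- match.arg(aggregate)
  cp <- committee_predict(committee, geom)
  norms <- sqrt(rowSums(cp$force_std^2))
  if (aggregate == "max") max(norms) else sqrt(mean(norms^2))
}

#' Calculator view of a committee
#'
#' Mean energy/forces across members; attaches the relative-force-error
#' sanity statistic to every evaluation so [run_md()] can abort, and a
#' dipole when a dipole model is supplied.
#'
#' @param committee a fitted committee.
#' @param template a [geometry()] supplying symbols (composition binding).
#' @param dipole_model optional [fit_dipole_model()] result.
#' @param eps regularization for the relative force error.
#' @return an [new_calculator()].
#' @export
committee_calculator <- function(committee, template, dipole_model = NULL,
                                 eps = 1e-3) {
  key <- .composition_key(template$symbols)
  blocks <- lapply(committee$members, function(m) {
    b <- m$blocks[[key]]
    if (is.null(b)) stop("composition ", key, " not in the training set")
    b
  })
  masses <- template$masses
  M <- length(blocks)
  new_calculator(function(pos) {
    de <- .desc_eval(pos, blocks[[1]]$layout, jacobian = TRUE)
    preds <- lapply(blocks, .predict_kernel_block, de = de)
    fs <- array(unlist(lapply(preds, `[[`, "forces")),
                dim = c(nrow(pos), 3, M))
    fmean <- apply(fs, c(1, 2), mean)
    fvar <- apply(fs, c(1, 2), function(x) mean((x - mean(x))^2))
    out <- list(energy = mean(vapply(preds, `[[`, numeric(1), "energy")),
                forces = fmean,
                rel_force_error =
                  sqrt(mean(fvar)) / (sqrt(mean(fmean^2)) + eps))
    if (!is.null(dipole_model))
      out$dipole <- .predict_dipole_pos(dipole_model, pos, template$symbols)
    out
  }, label = "committee", provides_dipole = !is.null(dipole_model))
}

# ---- dipole model -----------------------------------------------------------

.atom_features <- function(pos, symbols) {
  elems <- c("H", "C", "N", "O")
  n <- nrow(pos)
  d2 <- as.matrix(stats::dist(pos))
  feats <- matrix(0, n, 4 + 2 * 4)
  for (i in seq_len(n)) {
    onehot <- as.numeric(elems == symbols[i])
    s1 <- s2 <- numeric(4)
    for (e in seq_along(elems)) {
      js <- which(symbols == elems[e]); js <- js[js != i]
      if (length(js) > 0) {
        r <- d2[i, js]
        s1[e] <- sum(1 / r)
        s2[e] <- sum(exp(-r))
      }
    }
    feats[i, ] <- c(onehot, s1, s2)
  }
  feats
}

#' Fit the reference dipole model
#'
#' Regresses per-atom effective charges from local atomic descriptors
#' (element one-hot plus per-element inverse-distance and exponential
#' neighbour sums) by ridge regression against the labelled dipole vectors.
#' Predicted charges are recentred to sum exactly to zero, so the predicted
#' dipole \eqn{\sum_i \hat q_i r_i} is translation invariant.
#'
#' @param samples dipole-labelled [labeled_sample()] list.
#' @param hyperparams list: `lambda` ridge (default 1e-6).
#' @param seed unused by the deterministic fit; kept for interface parity.
#' @return object of class `ref_dipole`.
#' @export
fit_dipole_model <- function(samples, hyperparams = list(), seed = NULL) {
  if (length(samples) < 2) stop("need at least 2 dipole-labelled samples")
  if (any(vapply(samples, function(s) is.null(s$dipole), logical(1))))
    stop("all training samples must carry a dipole label")
  lambda <- if (is.null(hyperparams$lambda)) 1e-6 else hyperparams$lambda
  uc <- unit_constants()
  rows <- list(); ys <- numeric(0)
  for (s in samples) {
    pos <- s$geometry$positions
    phi <- .atom_features(pos, s$geometry$symbols)
    phic <- sweep(phi, 2, colMeans(phi))        # charge recentring, in-design
    for (c in 1:3) {
      rows[[length(rows) + 1]] <- colSums(phic * pos[, c])
      ys <- c(ys, s$dipole[c] / uc$eA_to_debye) # fit in e*Angstrom
    }
  }
  X <- do.call(rbind, rows)
  w <- solve(crossprod(X) + lambda * diag(ncol(X)), crossprod(X, ys))
  structure(list(w = as.vector(w), lambda = lambda), class = "ref_dipole")
}

.predict_dipole_pos <- function(model, pos, symbols) {
  phi <- .atom_features(pos, symbols)
  q <- as.vector(phi %*% model$w)
  q <- q - mean(q)
  colSums(q * pos) * unit_constants()$eA_to_debye
}

#' Predict a molecular dipole
#' @param model a `ref_dipole` from [fit_dipole_model()].
#' @param geom a [geometry()].
#' @return length-3 dipole vector, Debye.
#' @export
predict_dipole <- function(model, geom) {
  stopifnot(inherits(model, "ref_dipole"))
  .predict_dipole_pos(model, geom$positions, geom$symbols)
}
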