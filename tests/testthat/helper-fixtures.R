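# Shared fixtures: analytic diatomics and small labelled datasets built in
# code at test time.

harmonic_diatomic <- function(k = 1, r0 = 1, q = 0.2)
  surrogate_diatomic("harmonic", k = k, r0 = r0, q = q)

morse_diatomic <- function(De = 0.5, a = 1, r0 = 1, q = 0.2)
  surrogate_diatomic("morse", De = De, a = a, r0 = r0, q = q)

# heteronuclear C-H diatomic (dipole-model tests need distinguishable atoms)
ch_diatomic <- function()
  surrogate_diatomic("morse", De = 3, a = 2, r0 = 1.09, q = 0.15,
                     symbols = c("C", "H"), masses = NULL)

# labelled stretch samples of a diatomic oracle
stretch_samples <- function(mol, n = 60, lo = 0.85, hi = 1.35, seed = 1) {
  sym <- mol$geometry$symbols
  masses <- mol$geometry$masses
  rs <- withr::with_seed(seed, stats::runif(n, lo, hi))
  lapply(rs, function(r)
    oracle_evaluate(mol, geometry(sym, rbind(c(0, 0, 0), c(r, 0, 0)),
                                  masses = masses)))
}

# random small perturbations of a molecule's reference geometry, labelled
perturbed_samples <- function(mol, n = 50, sd = 0.05, seed = 1) {
  g0 <- mol$geometry
  withr::with_seed(seed, lapply(seq_len(n), function(i) {
    d <- matrix(stats::rnorm(3 * length(g0$symbols), sd = sd),
                ncol = 3)
    oracle_evaluate(mol, geometry(g0$symbols, g0$positions + d,
                                  masses = g0$masses))
  }))
}

# closed-form harmonic stretch wavenumber of a diatomic, cm^-1
diatomic_wavenumber <- function(k, m1 = 1, m2 = 1) {
  uc <- unit_constants()
  mu <- m1 * m2 / (m1 + m2)
  sqrt(k * uc$acc_ev_A_amu / mu) * uc$rad_fs_to_cm1
}

# independent Wasserstein oracle: integral of |F_x - F_y| over the axis,
# evaluated exactly for step CDFs of discrete distributions
wd_cdf_integral <- function(xg, xi, yg, yi) {
  px <- xi / sum(xi); py <- yi / sum(yi)
  knots <- sort(unique(c(xg, yg)))
  Fx <- vapply(knots, function(t) sum(px[xg <= t]), numeric(1))
  Fy <- vapply(knots, function(t) sum(py[yg <= t]), numeric(1))
  sum(abs(Fx[-length(knots)] - Fy[-length(knots)]) * diff(knots))
}

random_rotation <- function(seed = 1) {
  withr::with_seed(seed, {
    A <- matrix(stats::rnorm(9), 3, 3)
    qr.Q(qr(A)) * sample(c(-1, 1), 1)
  })
}
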