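# hard-coded textbook matrices, independent of the package's ladder-
# operator construction
pauli_half <- list(x = matrix(c(0, 1, 1, 0), 2) / 2,
                   y = matrix(c(0, 1i, -1i, 0), 2) / 2,
                   z = diag(c(0.5, -0.5)))
spin1_lit <- list(
  x = matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, byrow = TRUE) / sqrt(2),
  y = matrix(c(0, -1i, 0, 1i, 0, -1i, 0, 1i, 0), 3, byrow = TRUE) / sqrt(2),
  z = diag(c(1, 0, -1)))

test_that("spin operators obey the angular-momentum algebra", {
  for (case in list(list(s = 0.5, ref = pauli_half),
                    list(s = 1, ref = spin1_lit))) {
    ops <- spin_operators(case$s)
    expect_equal(ops$x, case$ref$x + 0i, ignore_attr = TRUE)
    expect_equal(ops$y, case$ref$y + 0i, ignore_attr = TRUE)
    expect_equal(ops$z, case$ref$z + 0i, ignore_attr = TRUE)
    comm <- function(a, b) a %*% b - b %*% a
    expect_equal(comm(ops$x, ops$y), 1i * ops$z, tolerance = 1e-14)
    expect_equal(comm(ops$y, ops$z), 1i * ops$x, tolerance = 1e-14)
    expect_equal(comm(ops$z, ops$x), 1i * ops$y, tolerance = 1e-14)
    casimir <- ops$x %*% ops$x + ops$y %*% ops$y + ops$z %*% ops$z
    expect_equal(casimir,
                 diag(2 * case$s + 1) * case$s * (case$s + 1) + 0i,
                 tolerance = 1e-14, ignore_attr = TRUE)
  }
  expect_error(spin_operators(1.5), "unsupported")
})

test_that("limiting cases of the NV Hamiltonian have the known spectra", {
  # B = 0, no couplings: {0, D, D} on the electron, 3-fold nuclear degeneracy
  sys0 <- spin_system(b_t = 0, A_n_hz = matrix(0, 3, 3))
  ev0 <- sort(eigen(build_hamiltonian(sys0), symmetric = TRUE,
                    only.values = TRUE)$values)
  expect_equal(ev0, c(rep(0, 3), rep(2.87e9, 6)), tolerance = 1e-10)

  # aligned field, no couplings: 0 and D -+ g muB Bz per ms = +-1
  sysz <- spin_system(b_t = 2e-3, theta_deg = 0, A_n_hz = matrix(0, 3, 3),
                      include_nuclear_zeeman = FALSE)
  evz <- sort(unique(round(eigen(build_hamiltonian(sysz), symmetric = TRUE,
                                 only.values = TRUE)$values, 3)))
  gmb <- 2.0028 * mr_constants$bohr_magneton_hz_per_t * 2e-3
  expect_equal(evz, sort(c(0, 2.87e9 - gmb, 2.87e9 + gmb)),
               tolerance = 1e-9)
})

test_that("the full Hamiltonian matches an independent Kronecker assembly", {
  a_n <- diag(c(-2.7e6, -2.7e6, -2.16e6))
  a_c <- matrix(c(5e6, 1e6, 2e6, 1e6, 4e6, 0.5e6, 2e6, 0.5e6, 9e6), 3,
                byrow = TRUE)
  sys <- spin_system(b_t = 5.5e-3, theta_deg = 34.1, phi_deg = 20,
                     A_n_hz = a_n, A_c_hz = a_c, P_n_hz = -4.95e6)
  H <- build_hamiltonian(sys)
  expect_equal(dim(H), c(18L, 18L))

  th <- 34.1 * pi / 180; ph <- 20 * pi / 180
  B <- 5.5e-3 * c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  id3 <- diag(3); id2 <- diag(2)
  S <- lapply(spin1_lit, function(m) kronecker(kronecker(m, id3), id2))
  In <- lapply(spin1_lit, function(m) kronecker(kronecker(id3, m), id2))
  Ic <- lapply(pauli_half, function(m) kronecker(kronecker(id3, id3), m))
  muB <- 13.996244936e9
  Href <- 2.87e9 * S$z %*% S$z +
    2.0028 * muB * (B[1] * S$x + B[2] * S$y + B[3] * S$z) -
    4.95e6 * (In$z %*% In$z - diag(18) * 2 / 3) -
    3.0777e6 * (B[1] * In$x + B[2] * In$y + B[3] * In$z) -
    10.7084e6 * (B[1] * Ic$x + B[2] * Ic$y + B[3] * Ic$z)
  axes <- c("x", "y", "z")
  for (a in 1:3) for (b in 1:3) {
    Href <- Href + a_n[a, b] * S[[axes[a]]] %*% In[[axes[b]]] +
      a_c[a, b] * S[[axes[a]]] %*% Ic[[axes[b]]]
  }
  expect_lt(max(Mod(H - Href)), 1e-12 * max(Mod(Href)))
  expect_equal(eigen(H, symmetric = TRUE, only.values = TRUE)$values,
               eigen(Href, symmetric = TRUE, only.values = TRUE)$values,
               tolerance = 1e-12)
})

test_that("Hamiltonians are Hermitian and reject asymmetric tensors", {
  set.seed(99)
  for (k in 1:5) {
    a_n <- crossprod(matrix(rnorm(9, sd = 1e6), 3))
    a_c <- if (k %% 2) crossprod(matrix(rnorm(9, sd = 2e6), 3)) else NULL
    sys <- spin_system(b_t = runif(1, 0, 0.02), theta_deg = runif(1, 0, 180),
                       phi_deg = runif(1, 0, 360), A_n_hz = a_n,
                       A_c_hz = a_c)
    H <- build_hamiltonian(sys)
    expect_lt(max(Mod(H - Conj(t(H)))), 1e-12 * max(Mod(H)))
  }
  bad <- diag(c(1e6, 1e6, 2e6)); bad[1, 2] <- 1e4
  expect_error(spin_system(A_n_hz = bad), "not symmetric")
})

test_that("nuclear transition frequencies reduce to the known limits", {
  # no hyperfine: every manifold shows the bare 14N Larmor ladder
  sys <- spin_system(b_t = 10e-3, theta_deg = 0, A_n_hz = matrix(0, 3, 3))
  ntf <- nuclear_transition_frequencies(sys)
  nu_n <- 3.0777e6 * 10e-3
  for (man in ntf)
    expect_equal(man, sort(c(nu_n, nu_n, 2 * nu_n)), tolerance = 1e-6)

  # no hyperfine and no nuclear Zeeman: everything is static
  sys0 <- spin_system(b_t = 10e-3, A_n_hz = matrix(0, 3, 3),
                      include_nuclear_zeeman = FALSE)
  for (man in nuclear_transition_frequencies(sys0))
    expect_equal(man, c(0, 0, 0), tolerance = 1)

  # secular 13C coupling, aligned field: |ms * Azz - gamma B| per manifold
  azz <- 3e6
  nu_c <- 10.7084e6 * 10e-3
  sysc <- spin_system(b_t = 10e-3, theta_deg = 0,
                      A_n_hz = matrix(0, 3, 3),
                      A_c_hz = diag(c(0, 0, azz)))
  ntfc <- nuclear_transition_frequencies(sysc)
  expect_true(any(abs(ntfc$ms_0 - nu_c) < 50))
  expect_true(any(abs(ntfc$ms_minus1 - abs(-azz - nu_c)) < 50))
  expect_true(any(abs(ntfc$ms_plus1 - abs(azz - nu_c)) < 50))
})

test_that("ESEEM vanishes for an aligned field with a diagonal tensor", {
  sys <- spin_system(b_t = 3e-3, theta_deg = 0,
                     A_n_hz = diag(c(-2.7e6, -2.7e6, -2.16e6)))
  sig <- simulate_eseem(sys, pulse_sequence(12, 12, 4e-8, 4e-8))
  expect_lt(diff(range(sig$values)), 1e-9)
  # while the misaligned field switches the modulation on
  sys2 <- spin_system(b_t = 3e-3, theta_deg = 34.1,
                      A_n_hz = diag(c(-2.7e6, -2.7e6, -2.16e6)))
  sig2 <- simulate_eseem(sys2, pulse_sequence(24, 24, 4e-8, 4e-8))
  expect_gt(diff(range(sig2$values)), 0.05)
})

test_that("trivial dynamics give a constant signal", {
  sys <- spin_system(b_t = 0, A_n_hz = matrix(0, 3, 3))
  sig <- simulate_eseem(sys, pulse_sequence(6, 6, 5e-8, 5e-8))
  expect_equal(sig$values, matrix(sig$values[1, 1], 6, 6), tolerance = 1e-12)
  expect_true(all(sig$values >= 0 & sig$values <= 1))
  expect_error(simulate_eseem(sys, pulse_sequence(6, 6, 5e-8, 5e-8),
                              max_elements = 10), "max_elements")
})

test_that("the density-matrix simulation reproduces the Mims envelope", {
  sq <- pulse_sequence(32, 32, 6e-8, 6e-8)
  par <- mims_parameters(5e6, 3e6, 2e6)
  sim <- simulate_eseem_twolevel(5e6, 3e6, 2e6, sq, diagnostics = TRUE)
  ref <- mims_eseem_analytic(par$omega_alpha, par$omega_beta, par$k, sq)
  # phase-cycled population is (1 + V) / 2
  expect_lt(max(abs(2 * sim$values - 1 - ref$values)) /
              max(abs(ref$values)), 1e-6)
  d <- attr(sim, "diagnostics")
  expect_lt(d[["unitarity"]], 1e-10)
  expect_lt(d[["trace"]], 1e-10)
  expect_gt(d[["positivity"]], -1e-10)
  expect_true(all(sim$values >= 0 & sim$values <= 1))
  # without phase cycling extra pathways contribute
  raw <- simulate_eseem_twolevel(5e6, 3e6, 2e6, sq, phase_cycle = FALSE)
  expect_gt(max(abs(2 * raw$values - 1 - ref$values)), 1e-2)
})

test_that("mims_eseem_analytic trivial limits and spectral content", {
  sq <- pulse_sequence(64, 64, 5e-8, 5e-8)
  expect_equal(mims_eseem_analytic(3e6, 5e6, 0, sq)$values,
               matrix(1, 64, 64))
  expect_equal(mims_eseem_analytic(0, 0, 1, sq)$values, matrix(1, 64, 64))
  expect_error(mims_eseem_analytic(3e6, 5e6, 1.4, sq), "depth_k")

  # full-depth envelope: all spectral peaks at coordinates built from
  # {0, omega_alpha, omega_beta} and their sums/differences
  wa <- 4e6; wb <- 2.5e6
  sig <- mims_eseem_analytic(wa, wb, 1, sq)
  spec <- fourier_spectrum(sig)
  pk <- detect_peaks(spec, rel_threshold = 0.1, min_separation_bins = 1)
  expect_gt(nrow(pk), 0)
  allowed <- c(0, wa, wb, wa + wb, abs(wa - wb))
  bin <- 1 / (64 * 5e-8)
  near <- function(f) any(abs(allowed - f) <= bin)
  expect_true(all(vapply(pk$f1_hz, near, TRUE)))
  expect_true(all(vapply(pk$f2_hz, near, TRUE)))
})

test_that("simulated spectra peak at the manifold transition frequencies", {
  ps <- nv_preset("n14_misaligned")
  sq <- pulse_sequence(48, 48, 4e-8, 4e-8)
  sig <- simulate_eseem(ps$system, sq)
  spec <- fourier_spectrum(sig)
  pk <- detect_peaks(spec, rel_threshold = 0.25, min_separation_bins = 1)
  expect_gt(nrow(pk), 0)
  ntf <- nuclear_transition_frequencies(ps$system)
  base <- c(0, ntf$ms_0, ntf$ms_minus1)
  allowed <- unique(c(base, as.vector(outer(base, base, "+")),
                      abs(as.vector(outer(base, base, "-")))))
  bin <- 1 / (48 * 4e-8)
  near <- function(f) any(abs(allowed - f) <= bin)
  expect_true(all(vapply(pk$f1_hz, near, TRUE)))
  expect_true(all(vapply(pk$f2_hz, near, TRUE)))
})

test_that("synth_lowrank builds matrices of rank equal to the peak count", {
  one <- synth_lowrank(data.frame(f1 = 2e6, f2 = 3e6, amplitude = 1,
                                  decay_t1 = 5e-6, decay_t2 = 5e-6),
                       48, 48, 5e-8, 5e-8)
  sv1 <- singular_value_profile(one$values)
  expect_lt(sv1[2], 1e-10 * sv1[1])

  fp <- fourpeak_signal(96, 96, noise_sigma = 0)
  sv4 <- singular_value_profile(fp$signal$values)
  expect_equal(sum(sv4 > 1e-10 * sv4[1]), 4L)
  expect_error(synth_lowrank(data.frame(), 8, 8, 1e-6, 1e-6),
               "at least one")
})

test_that("noise adds a floor of small singular values", {
  fp <- fourpeak_signal(128, 128, noise_sigma = 0.01, seed = 7)
  sv <- singular_value_profile(fp$signal$values)
  expect_gte(mean(sv < 0.05 * sv[1]), 0.7)
})
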