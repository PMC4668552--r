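# shared fixtures, built in code at test time

seeded_matrix <- function(n1, n2, seed) {
  set.seed(seed)
  matrix(rnorm(n1 * n2), n1, n2)
}

rank_r_matrix <- function(n, r, seed) {
  set.seed(seed)
  u <- matrix(rnorm(n * r), n, r)
  v <- matrix(rnorm(n * r), n, r)
  u %*% t(v)
}

# trace-norm proximal objective (1/2)||X - Y||_F^2 + tau ||X||_*
prox_objective <- function(X, Y, tau) {
  0.5 * sum((X - Y)^2) + tau * sum(svd(X, nu = 0, nv = 0)$d)
}

# hand-constructed spectrum2d for metric unit tests
make_spectrum <- function(mag, df1 = 1, df2 = 1) {
  structure(list(magnitude = mag,
                 f1_axis = (seq_len(nrow(mag)) - 1 - floor(nrow(mag) / 2)) * df1,
                 f2_axis = (seq_len(ncol(mag)) - 1 - floor(ncol(mag) / 2)) * df2),
            class = "spectrum2d")
}

# SNR windows for the four-peak study signal: peaks live within
# |f| <= 0.85 fmax; the noise window sits beyond every peak and mirror
fourpeak_regions <- function(spec) {
  f1m <- max(spec$f1_axis); f2m <- max(spec$f2_axis)
  list(peak = region_spec(c(0, 0.85 * f1m), c(0, 0.85 * f2m)),
       noise = region_spec(c(0.88 * f1m, f1m), c(0.88 * f2m, f2m)))
}

# full recovery pipeline used by the acceptance studies: mask -> SVT ->
# FFT -> peak detection -> all planted peaks within one bin?
recovery_trial <- function(signal, peaks, fraction, seed,
                           max_iter = 500L) {
  M <- signal$values
  omega <- draw_mask(mask_spec(nrow(M), ncol(M), fraction, seed))
  obs <- apply_mask(M, omega)
  cfg <- svt_config(tau = 5 * max(dim(M)), delta = 1.2 / fraction,
                    eps0 = 1e-4, max_iter = max_iter)
  fit <- svt_complete(obs, cfg)
  spec <- fourier_spectrum(td_signal(fit$completed, signal$dt1, signal$dt2))
  pk <- detect_peaks(spec, rel_threshold = 0.2)
  peaks_recovered(pk, peaks, spec, tol_bins = 1)
}
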