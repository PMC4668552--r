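#' Generic low-rank 2D test signal: damped separable cosines
#'
#' Builds a sum of separable damped cosine products,
#' \deqn{M(t_1, t_2) = \sum_p a_p \cos(2\pi f_{1,p} t_1)
#'   \cos(2\pi f_{2,p} t_2)\,
#'   e^{-t_1/\tau_{1,p}} e^{-t_2/\tau_{2,p}} + \epsilon,}
#' optionally plus seeded white Gaussian noise.  Each term is an outer
#' product, so the noise-free matrix has rank at most the number of
#' peaks — the low-rank structure that matrix completion exploits.
#'
#' @param peaks data frame with columns `f1`, `f2` (Hz), `amplitude`,
#'   `decay_t1`, `decay_t2` (s); one row per spectral peak.
#' @param n1,n2 grid sizes.
#' @param dt1,dt2 dwell times (s).
#' @param noise_sigma standard deviation of the additive Gaussian noise
#'   (0 for a noise-free signal).
#' @param seed integer seed for the noise draw (ignored when
#'   `noise_sigma = 0`).
#' @return A [td_signal()].
#' @export
#' @examples
#' pk <- data.frame(f1 = 2e6, f2 = 3e6, amplitude = 1,
#'                  decay_t1 = 5e-6, decay_t2 = 5e-6)
#' sig <- synth_lowrank(pk, 64, 64, 5e-8, 5e-8)
#' sum(svd(sig$values)$d > 1e-10) # rank 1
synth_lowrank <- function(peaks, n1, n2, dt1, dt2,
                          noise_sigma = 0, seed = 1L) {
  peaks <- as.data.frame(peaks)
  need <- c("f1", "f2", "amplitude", "decay_t1", "decay_t2")
  if (nrow(peaks) < 1L)
    stop("at least one peak is required")
  if (!all(need %in% names(peaks)))
    stop("peaks must have columns ", paste(need, collapse = ", "))
  if (!all(vapply(peaks[need], function(x) all(is.finite(x)), TRUE)))
    stop("peak parameters must be finite")
  if (!is.finite(noise_sigma) || noise_sigma < 0)
    stop("noise_sigma must be nonnegative")
  t1 <- dt1 * (seq_len(n1) - 1L)
  t2 <- dt2 * (seq_len(n2) - 1L)
  M <- matrix(0, n1, n2)
  for (p in seq_len(nrow(peaks))) {
    u <- peaks$amplitude[p] * cos(2 * pi * peaks$f1[p] * t1) *
      exp(-t1 / peaks$decay_t1[p])
    v <- cos(2 * pi * peaks$f2[p] * t2) * exp(-t2 / peaks$decay_t2[p])
    M <- M + outer(u, v)
  }
  if (noise_sigma > 0)
    M <- M + with_local_seed(seed,
                             matrix(rnorm(n1 * n2, sd = noise_sigma), n1, n2))
  td_signal(M, dt1, dt2,
            meta = sprintf("synth_lowrank %d peaks, sigma %g",
                           nrow(peaks), noise_sigma))
}

#' Reference four-peak low-rank study signal
#'
#' The standard synthetic benchmark used throughout the package's
#' recovery studies: four separable damped cosines with distinct on-grid
#' frequency pairs, equal unit amplitudes, decay constants of half the
#' record length in each dimension, and (by default) white Gaussian noise
#' at 1% of the single-peak amplitude.  With `dt = 50` ns the spectral
#' band is +/- 10 MHz and the four peaks sit between 1.6 and 8.1 MHz.
#'
#' @param n1,n2 grid sizes (default 256).
#' @param dt dwell time (s) for both dimensions.
#' @param noise_sigma noise standard deviation (default 0.01, i.e. 1% of
#'   the peak amplitude).
#' @param seed seed for the noise draw.
#' @return A list with `signal` (a [td_signal()]) and `peaks` (the planted
#'   peak table, with on-grid frequencies in Hz).
#' @export
fourpeak_signal <- function(n1 = 256L, n2 = 256L, dt = 5e-8,
                            noise_sigma = 0.01, seed = 1L) {
  # on-grid bins (k / (n dt)), distinct pairs, away from DC and Nyquist;
  # stated for the reference 256-point grid and scaled to other sizes
  k1 <- as.integer(round(n1 * c(24, 56, 88, 104) / 256))
  k2 <- as.integer(round(n2 * c(40, 72, 104, 32) / 256))
  peaks <- data.frame(
    f1 = k1 / (n1 * dt), f2 = k2 / (n2 * dt),
    amplitude = 1,
    decay_t1 = 0.5 * n1 * dt, decay_t2 = 0.5 * n2 * dt)
  list(signal = synth_lowrank(peaks, n1, n2, dt, dt,
                              noise_sigma = noise_sigma, seed = seed),
       peaks = peaks)
}
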