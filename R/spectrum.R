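#' 2D magnitude spectrum of a time-domain signal
#'
#' Magnitude of the 2D discrete Fourier transform with the
#' zero-frequency bin moved to the centre.  Frequency axes follow from
#' the dwell times: bin `k` maps to `k / (n dt)` for
#' `k = -n/2, ..., n/2 - 1`.  By default the matrix mean is subtracted
#' before transforming, which suppresses the DC spike so that
#' signal-to-noise windows can sit anywhere off-peak.
#'
#' @param signal a [td_signal()].
#' @param remove_mean subtract the matrix mean before the transform
#'   (default TRUE).
#' @return An object of class `spectrum2d` with fields `magnitude`
#'   (nonnegative `n1 x n2` matrix), `f1_axis`, `f2_axis` (Hz, strictly
#'   increasing, centred on zero).
#' @export
fourier_spectrum <- function(signal, remove_mean = TRUE) {
  stopifnot(inherits(signal, "td_signal"))
  M <- signal$values
  if (isTRUE(remove_mean)) M <- M - mean(M)
  S <- Mod(stats::fft(M))
  structure(
    list(magnitude = fftshift2(S),
         f1_axis = centered_axis(nrow(M), signal$dt1),
         f2_axis = centered_axis(ncol(M), signal$dt2)),
    class = "spectrum2d")
}

# swap half-spaces so the zero-frequency bin lands at position
# floor(n/2) + 1, matching centered_axis
fftshift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  i1 <- c((floor(n1 / 2) + 1L):n1, seq_len(floor(n1 / 2)))
  i2 <- c((floor(n2 / 2) + 1L):n2, seq_len(floor(n2 / 2)))
  m[i1, i2, drop = FALSE]
}

centered_axis <- function(n, dt) {
  (seq_len(n) - 1L - floor(n / 2)) / (n * dt)
}

#' @export
print.spectrum2d <- function(x, ...) {
  cat(sprintf("spectrum2d: %d x %d, band [%.3g, %.3g] x [%.3g, %.3g] Hz\n",
              nrow(x$magnitude), ncol(x$magnitude),
              min(x$f1_axis), max(x$f1_axis),
              min(x$f2_axis), max(x$f2_axis)))
  invisible(x)
}

#' Detect peaks in a 2D magnitude spectrum
#'
#' Local maxima (over the 8-neighbourhood) whose magnitude exceeds
#' `rel_threshold` times the global maximum, accepted greedily in
#' descending amplitude subject to a minimum Chebyshev bin separation.
#' Restricted to the non-negative-frequency quadrant: for a real signal
#' the mirrored peaks carry no extra information.
#'
#' @param spec a [fourier_spectrum()] result.
#' @param rel_threshold relative amplitude threshold in (0, 1).
#' @param min_separation_bins minimum Chebyshev distance (bins) between
#'   accepted peaks.
#' @return A data frame of class `peak_list` with columns `f1_hz`,
#'   `f2_hz`, `amplitude`, sorted by descending amplitude; the threshold
#'   used is kept in attribute `rel_threshold`.
#' @export
detect_peaks <- function(spec, rel_threshold = 0.2,
                         min_separation_bins = 2L) {
  stopifnot(inherits(spec, "spectrum2d"))
  if (!is.finite(rel_threshold) || rel_threshold <= 0 || rel_threshold >= 1)
    stop("rel_threshold must lie in (0, 1)")
  m <- spec$magnitude
  n1 <- nrow(m); n2 <- ncol(m)
  thr <- rel_threshold * max(m)
  empty <- data.frame(f1_hz = numeric(0), f2_hz = numeric(0),
                      amplitude = numeric(0))
  if (max(m) == 0)
    return(structure(empty, rel_threshold = rel_threshold,
                     class = c("peak_list", "data.frame")))
  i0 <- which(spec$f1_axis >= 0)[1L]
  j0 <- which(spec$f2_axis >= 0)[1L]
  # vectorized 8-neighbourhood maximum via shifts of a padded copy
  pad <- matrix(-Inf, n1 + 2L, n2 + 2L)
  pad[2:(n1 + 1L), 2:(n2 + 1L)] <- m
  nbmax <- matrix(-Inf, n1, n2)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    nbmax <- pmax(nbmax, pad[(2:(n1 + 1L)) + di, (2:(n2 + 1L)) + dj])
  }
  quad <- matrix(FALSE, n1, n2)
  quad[i0:n1, j0:n2] <- TRUE
  hits <- which(quad & m >= thr & m >= nbmax, arr.ind = TRUE)
  if (!nrow(hits))
    return(structure(empty, rel_threshold = rel_threshold,
                     class = c("peak_list", "data.frame")))
  cand <- cbind(hits[, 1L], hits[, 2L], m[hits])
  cand <- cand[order(-cand[, 3L]), , drop = FALSE]
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (any(keep)) {
      prev <- cand[keep, , drop = FALSE]
      cheb <- pmax(abs(prev[, 1L] - cand[k, 1L]),
                   abs(prev[, 2L] - cand[k, 2L]))
      if (any(cheb < min_separation_bins)) next
    }
    keep[k] <- TRUE
  }
  cand <- cand[keep, , drop = FALSE]
  structure(
    data.frame(f1_hz = spec$f1_axis[cand[, 1L]],
               f2_hz = spec$f2_axis[cand[, 2L]],
               amplitude = cand[, 3L]),
    rel_threshold = rel_threshold,
    class = c("peak_list", "data.frame"))
}

#' Rectangular frequency region of a 2D spectrum
#'
#' @param f1_hz,f2_hz length-2 numeric intervals (Hz), `c(lo, hi)`.
#' @return An object of class `region_spec`.
#' @export
region_spec <- function(f1_hz, f2_hz) {
  f1_hz <- sort(as.numeric(f1_hz)); f2_hz <- sort(as.numeric(f2_hz))
  if (length(f1_hz) != 2L || length(f2_hz) != 2L ||
      !all(is.finite(c(f1_hz, f2_hz))))
    stop("regions are given as two finite length-2 intervals")
  structure(list(f1_hz = f1_hz, f2_hz = f2_hz), class = "region_spec")
}

region_mask <- function(spec, region) {
  outer(spec$f1_axis >= region$f1_hz[1L] & spec$f1_axis <= region$f1_hz[2L],
        spec$f2_axis >= region$f2_hz[1L] & spec$f2_axis <= region$f2_hz[2L],
        FUN = "&")
}

#' Spectral signal-to-noise ratio
#'
#' The maximal magnitude inside a designated peak region divided by the
#' mean magnitude of a region containing only noise.
#'
#' @param spec a [fourier_spectrum()] result.
#' @param peak_region,noise_region disjoint [region_spec()]s; both must
#'   contain at least one spectral bin.
#' @return A positive number.
#' @export
snr <- function(spec, peak_region, noise_region) {
  stopifnot(inherits(spec, "spectrum2d"),
            inherits(peak_region, "region_spec"),
            inherits(noise_region, "region_spec"))
  pm <- region_mask(spec, peak_region)
  nm <- region_mask(spec, noise_region)
  if (!any(pm) || !any(nm))
    stop("peak and noise regions must contain at least one bin")
  if (any(pm & nm))
    stop("peak and noise regions must be disjoint")
  noise_mean <- mean(spec$magnitude[nm])
  if (noise_mean == 0)
    stop("noise region has zero mean magnitude; SNR undefined")
  max(spec$magnitude[pm]) / noise_mean
}

#' Recovery fidelity between two matrices
#'
#' Normalized Frobenius inner product (cosine similarity) of the fully
#' sampled reference matrix and a reconstruction, computed in the time
#' domain:
#' \deqn{F = \frac{\langle M, X \rangle_F}{\|M\|_F \, \|X\|_F} \in [-1, 1].}
#' `F = 1` at perfect recovery (up to positive scaling); a zero candidate
#' returns 0 by convention.
#'
#' @param reference full (nonzero) reference matrix `M`.
#' @param candidate reconstruction `X`, same shape.
#' @return A number in \[-1, 1\].
#' @export
fidelity <- function(reference, candidate) {
  if (!is.matrix(reference) || !is.matrix(candidate) ||
      !all(dim(reference) == dim(candidate)))
    stop("reference and candidate must be matrices of identical shape")
  nr <- sqrt(sum(reference^2))
  if (nr == 0) stop("reference matrix is zero")
  nc_ <- sqrt(sum(candidate^2))
  if (nc_ == 0) return(0)
  sum(reference * candidate) / (nr * nc_)
}

#' Singular value profile of a matrix
#'
#' All singular values in descending order — the diagnostic used to judge
#' how low-rank a measured 2D signal is (for an ESEEM-like signal, the
#' number of significant values matches the number of spectral peaks,
#' with the remainder at the noise floor).
#'
#' @param matrix numeric matrix with finite entries.
#' @return Nonnegative numeric vector of length `min(dim(matrix))`.
#' @export
singular_value_profile <- function(matrix) {
  if (!is.matrix(matrix) || !all(is.finite(matrix)))
    stop("matrix must be finite")
  svd(matrix, nu = 0, nv = 0)$d
}

#' Do detected peaks cover a set of planted positions?
#'
#' Checks that every expected peak position has a detected peak within
#' `tol_bins` frequency bins in both dimensions.
#'
#' @param peaks a [detect_peaks()] result.
#' @param expected data frame with columns `f1` and `f2` (Hz).
#' @param spec the [fourier_spectrum()] the peaks came from (supplies the
#'   bin widths).
#' @param tol_bins tolerance in bins (default 1).
#' @return TRUE if all expected peaks are matched.
#' @export
peaks_recovered <- function(peaks, expected, spec, tol_bins = 1) {
  stopifnot(inherits(spec, "spectrum2d"))
  if (nrow(peaks) == 0L) return(FALSE)
  df1 <- diff(spec$f1_axis[1:2])
  df2 <- diff(spec$f2_axis[1:2])
  all(vapply(seq_len(nrow(expected)), function(p) {
    any(abs(peaks$f1_hz - expected$f1[p]) <= tol_bins * df1 + 1e-9 * df1 &
        abs(peaks$f2_hz - expected$f2[p]) <= tol_bins * df2 + 1e-9 * df2)
  }, TRUE))
}
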