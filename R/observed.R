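#' Observed (sampled) matrix entries
#'
#' Container for the constraint set of a matrix-completion problem: the
#' shape of the underlying matrix, the set of sampled index pairs
#' \eqn{\Omega}, and the measured values \eqn{M_{ij}} for
#' \eqn{(i,j) \in \Omega}.
#'
#' @param n_rows,n_cols positive integers, the shape of the full matrix.
#' @param omega integer matrix with two columns of 0-based (row, col)
#'   indices; rows must be unique and within bounds.
#' @param values numeric vector of measured entries, one per row of
#'   `omega`.
#'
#' @return An object of class `observed_matrix` with fields `n_rows`,
#'   `n_cols`, `omega` (0-based index pairs, sorted row-major) and
#'   `values` (aligned with `omega`).
#' @seealso [apply_mask()], [zero_fill()], [svt_complete()]
#' @export
#' @examples
#' m <- matrix(1:4, 2, 2)
#' obs <- observed_matrix(2, 2, rbind(c(0, 0), c(1, 1)), c(1, 4))
#' zero_fill(obs)
observed_matrix <- function(n_rows, n_cols, omega, values) {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (length(n_rows) != 1L || length(n_cols) != 1L ||
      is.na(n_rows) || is.na(n_cols) || n_rows < 1L || n_cols < 1L)
    stop("n_rows and n_cols must be positive integers")
  omega <- as.matrix(omega)
  if (ncol(omega) != 2L)
    stop("omega must be a two-column matrix of (row, col) index pairs")
  storage.mode(omega) <- "integer"
  if (anyNA(omega))
    stop("omega contains missing indices")
  if (nrow(omega) < 1L)
    stop("omega must contain at least one index pair")
  if (any(omega[, 1L] < 0L) || any(omega[, 1L] >= n_rows) ||
      any(omega[, 2L] < 0L) || any(omega[, 2L] >= n_cols))
    stop("omega indices out of bounds for ", n_rows, "x", n_cols, " matrix")
  values <- as.numeric(values)
  if (length(values) != nrow(omega))
    stop("length(values) must equal nrow(omega)")
  if (!all(is.finite(values)))
    stop("observed values must be finite")
  # linear (column-major, 1-based) positions; also detects duplicates
  lin <- omega[, 1L] + n_rows * omega[, 2L] + 1L
  if (anyDuplicated(lin))
    stop("omega contains duplicate index pairs")
  ord <- order(omega[, 1L], omega[, 2L]) # row-major order
  structure(
    list(n_rows = n_rows, n_cols = n_cols,
         omega = omega[ord, , drop = FALSE],
         values = values[ord],
         lin_idx = lin[ord]),
    class = "observed_matrix")
}

#' @export
print.observed_matrix <- function(x, ...) {
  cat(sprintf("observed_matrix: %d x %d, |omega| = %d (%.1f%% sampled)\n",
              x$n_rows, x$n_cols, length(x$values),
              100 * sampling_fraction(x)))
  invisible(x)
}

#' Fraction of matrix entries that were sampled
#'
#' @param obs an [observed_matrix()].
#' @return `|omega| / (n_rows * n_cols)`, a number in (0, 1].
#' @export
sampling_fraction <- function(obs) {
  stopifnot(inherits(obs, "observed_matrix"))
  length(obs$values) / (obs$n_rows * obs$n_cols)
}

#' Embed observed entries in a zero matrix
#'
#' Returns the "subsampled" matrix: observed values at their positions and
#' zero everywhere else.  Its Fourier transform is the baseline that
#' completed spectra are compared against.
#'
#' @param obs an [observed_matrix()].
#' @return A numeric `n_rows x n_cols` matrix.
#' @export
zero_fill <- function(obs) {
  stopifnot(inherits(obs, "observed_matrix"))
  out <- matrix(0, obs$n_rows, obs$n_cols)
  out[obs$lin_idx] <- obs$values
  out
}
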