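#' Specification of a uniform random sampling mask
#'
#' @param n_rows,n_cols shape of the matrix to be sampled.
#' @param fraction fraction of entries to keep, in (0, 1].  The number of
#'   sampled entries is `round(fraction * n_rows * n_cols)` (round half to
#'   even), clamped to at least 1.
#' @param seed integer seed; identical specs draw identical masks.
#' @return An object of class `mask_spec`.
#' @export
mask_spec <- function(n_rows, n_cols, fraction, seed = 1L) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (anyNA(c(n_rows, n_cols)) || n_rows < 1L || n_cols < 1L)
    stop("n_rows and n_cols must be positive integers")
  fraction <- as.numeric(fraction)
  if (length(fraction) != 1L || !is.finite(fraction) ||
      fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1]")
  seed <- as.integer(seed)
  if (length(seed) != 1L || is.na(seed)) stop("seed must be an integer")
  structure(list(n_rows = n_rows, n_cols = n_cols,
                 fraction = fraction, seed = seed),
            class = "mask_spec")
}

# run expr with a private, seeded RNG stream, leaving the caller's
# .Random.seed untouched
with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed) # Mersenne-Twister, R default
  expr
}

#' Draw a uniform random observation mask
#'
#' Samples `round(fraction * n_rows * n_cols)` distinct cells uniformly
#' without replacement (R's default Mersenne-Twister generator seeded with
#' `spec$seed`, so masks are portable across machines and sessions).
#'
#' @param spec a [mask_spec()].
#' @return An integer matrix with columns `row`, `col` of 0-based index
#'   pairs in sorted row-major order.
#' @export
draw_mask <- function(spec) {
  stopifnot(inherits(spec, "mask_spec"))
  total <- spec$n_rows * spec$n_cols
  count <- min(max(1L, as.integer(round(spec$fraction * total))), total)
  lin <- with_local_seed(spec$seed, sort(sample.int(total, count)))
  lin0 <- lin - 1L # row-major 0-based decode
  omega <- cbind(row = lin0 %/% spec$n_cols, col = lin0 %% spec$n_cols)
  storage.mode(omega) <- "integer"
  omega
}

#' Restrict a matrix to an observation mask
#'
#' @param matrix full numeric matrix.
#' @param omega two-column matrix of 0-based (row, col) pairs, e.g. from
#'   [draw_mask()].
#' @return An [observed_matrix()] carrying the values of `matrix` at
#'   `omega`.
#' @export
apply_mask <- function(matrix, omega) {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop("matrix must be a numeric matrix")
  omega <- as.matrix(omega)
  storage.mode(omega) <- "integer"
  if (ncol(omega) != 2L || anyNA(omega) ||
      any(omega[, 1L] < 0L) || any(omega[, 1L] >= nrow(matrix)) ||
      any(omega[, 2L] < 0L) || any(omega[, 2L] >= ncol(matrix)))
    stop("omega indices out of bounds for the given matrix")
  vals <- matrix[omega[, 1L] + nrow(matrix) * omega[, 2L] + 1L]
  observed_matrix(nrow(matrix), ncol(matrix), omega, vals)
}
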