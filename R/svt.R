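#' Configuration of the singular value thresholding solver
#'
#' Bundles the free parameters of the SVT iteration.  `tau` and `delta`
#' may be left `NULL`, in which case [svt_complete()] resolves them from
#' the problem at hand: `tau = 5 * max(n_rows, n_cols)` (the empirically
#' suggested threshold rule) and `delta = 1.2 / sampling_fraction`
#' (equivalently `1.2 * n * m / |omega|`, the step size with provable
#' convergence for step sizes below `2`-times the inverse fraction).
#'
#' @param tau nonnegative singular-value threshold, or `NULL` for the
#'   size-based default.
#' @param delta positive gradient step size, or `NULL` for the
#'   sampling-fraction-based default.
#' @param eps0 relative termination tolerance in (0, 1): the iteration
#'   stops once the Frobenius misfit on the observed entries, relative to
#'   the Frobenius norm of the observed data, drops to `eps0` or below.
#' @param max_iter iteration cap (the solver returns a non-converged
#'   result rather than erroring when it is reached).
#' @param record_history keep the per-iteration residual trace?
#' @param warm_start start from `k0 * delta * P_Omega(M)` (the standard
#'   SVT kick-start) instead of the zero matrix.  Off by default.
#' @return An object of class `svt_config`.
#' @export
svt_config <- function(tau = NULL, delta = NULL, eps0 = 1e-4,
                       max_iter = 1000L, record_history = FALSE,
                       warm_start = FALSE) {
  if (!is.null(tau)) {
    tau <- as.numeric(tau)
    if (length(tau) != 1L || !is.finite(tau) || tau < 0)
      stop("tau must be a single nonnegative number")
  }
  if (!is.null(delta)) {
    delta <- as.numeric(delta)
    if (length(delta) != 1L || !is.finite(delta) || delta <= 0)
      stop("delta must be a single positive number")
  }
  eps0 <- as.numeric(eps0)
  if (length(eps0) != 1L || !is.finite(eps0) || eps0 <= 0 || eps0 >= 1)
    stop("eps0 must lie strictly between 0 and 1")
  max_iter <- as.integer(max_iter)
  if (length(max_iter) != 1L || is.na(max_iter) || max_iter < 1L)
    stop("max_iter must be a positive integer")
  structure(
    list(tau = tau, delta = delta, eps0 = eps0, max_iter = max_iter,
         record_history = isTRUE(record_history),
         warm_start = isTRUE(warm_start)),
    class = "svt_config")
}

#' @export
print.svt_config <- function(x, ...) {
  cat(sprintf(
    "svt_config: tau = %s, delta = %s, eps0 = %g, max_iter = %d\n",
    if (is.null(x$tau)) "auto (5 max(n1,n2))" else format(x$tau),
    if (is.null(x$delta)) "auto (1.2 / fraction)" else format(x$delta),
    x$eps0, x$max_iter))
  invisible(x)
}

#' Soft-threshold the singular values of a matrix
#'
#' The proximal operator of the trace (nuclear) norm: with
#' \eqn{Y = U S V^T} a singular value decomposition, returns
#' \eqn{U \max(S - \tau, 0) V^T}.  This matrix is the unique minimizer of
#' \eqn{\frac12 \|X - Y\|_F^2 + \tau \|X\|_*}.
#'
#' @param matrix numeric matrix with finite entries.
#' @param tau nonnegative threshold subtracted from every singular value.
#' @return A matrix of the same shape whose singular values are
#'   `pmax(sv(matrix) - tau, 0)`.
#' @export
soft_threshold <- function(matrix, tau) {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop("matrix must be a numeric matrix")
  if (!all(is.finite(matrix)))
    stop("matrix must have finite entries")
  tau <- as.numeric(tau)
  if (length(tau) != 1L || !is.finite(tau) || tau < 0)
    stop("tau must be a single nonnegative number")
  if (tau == 0) return(matrix)
  s <- svd(matrix)
  d <- pmax(s$d - tau, 0)
  r <- sum(d > 0)
  if (r == 0L) return(array(0, dim(matrix)))
  s$u[, seq_len(r), drop = FALSE] %*%
    (d[seq_len(r)] * t(s$v[, seq_len(r), drop = FALSE]))
}

#' Residual of a candidate matrix on the observed entries
#'
#' Returns \eqn{P_\Omega(M - X)}: the matrix equal to
#' `obs$values - matrix[i, j]` on the observed positions and zero
#' elsewhere.  This is the (sign convention included) gradient direction
#' `dY` of the SVT update.
#'
#' @param matrix candidate matrix `X`, same shape as the observations.
#' @param obs an [observed_matrix()].
#' @return A matrix supported on omega only.
#' @export
project_observed <- function(matrix, obs) {
  stopifnot(inherits(obs, "observed_matrix"))
  if (!is.matrix(matrix) ||
      nrow(matrix) != obs$n_rows || ncol(matrix) != obs$n_cols)
    stop("matrix shape does not match the observations")
  out <- array(0, dim(matrix))
  out[obs$lin_idx] <- obs$values - matrix[obs$lin_idx]
  out
}

#' Relative Frobenius misfit on the observed entries
#'
#' The termination criterion of the SVT iteration:
#' \deqn{\|P_\Omega(X - M)\|_F / \|P_\Omega(M)\|_F.}
#'
#' @param candidate candidate matrix `X`, same shape as the observations.
#' @param obs an [observed_matrix()]; its values must not all be zero.
#' @return A nonnegative number; 0 iff the candidate matches every
#'   observation exactly.
#' @export
relative_residual <- function(candidate, obs) {
  stopifnot(inherits(obs, "observed_matrix"))
  if (!is.matrix(candidate) ||
      nrow(candidate) != obs$n_rows || ncol(candidate) != obs$n_cols)
    stop("candidate shape does not match the observations")
  denom <- sqrt(sum(obs$values^2))
  if (denom == 0)
    stop("all observed values are zero; relative residual is undefined")
  sqrt(sum((candidate[obs$lin_idx] - obs$values)^2)) / denom
}

#' Complete a low-rank matrix by singular value thresholding
#'
#' Iterative proximal solver for trace-norm-minimizing matrix completion.
#' Starting from `Y = 0` it repeats
#' \preformatted{  X  = soft_threshold(Y, tau)
#'   dY = P_Omega(M - X)
#'   Y  = Y + delta * dY}
#' until `relative_residual(X, obs) <= eps0` or `max_iter` iterations have
#' been spent.  The iterate `Y` follows a gradient ascent on the dual, so
#' `X` is a low-rank matrix that progressively agrees with the sampled
#' entries.  With noisy observations the residual plateaus at the noise
#' level; in that regime the solver runs to the iteration cap and still
#' returns the (useful) low-rank approximant with `converged = FALSE`.
#'
#' @param obs an [observed_matrix()].
#' @param config an [svt_config()].
#' @return An object of class `completion_result` with fields
#'   `completed` (the recovered matrix `X`), `iterations`,
#'   `final_residual`, `residual_history` (if recorded), `singular_values`
#'   of the completed matrix (descending), `converged`, and the resolved
#'   `tau` and `delta`.
#' @export
#' @examples
#' truth <- outer(sin(1:20), cos(1:20)) # rank 1
#' msk <- draw_mask(mask_spec(20, 20, fraction = 0.6, seed = 1))
#' fit <- svt_complete(apply_mask(truth, msk), svt_config(eps0 = 1e-4))
#' norm(fit$completed - truth, "F") / norm(truth, "F")
svt_complete <- function(obs, config = svt_config()) {
  stopifnot(inherits(obs, "observed_matrix"))
  if (!inherits(config, "svt_config"))
    stop("config must be an svt_config object")
  n1 <- obs$n_rows; n2 <- obs$n_cols
  tau <- if (is.null(config$tau)) 5 * max(n1, n2) else config$tau
  delta <- if (is.null(config$delta)) 1.2 / sampling_fraction(obs) else
    config$delta
  lin <- obs$lin_idx
  vals <- obs$values
  if (all(vals == 0))
    stop("all observed values are zero; nothing to complete")
  obs_norm <- sqrt(sum(vals^2))

  Y <- matrix(0, n1, n2)
  if (config$warm_start) {
    # standard SVT kick-start: k0 steps of the initial gradient at once
    pm <- zero_fill(obs)
    k0 <- ceiling(tau / (delta * svd(pm, nu = 0, nv = 0)$d[1]))
    Y <- k0 * delta * pm
  }
  history <- if (config$record_history) numeric(config$max_iter) else NULL
  X <- Y
  sv_thr <- numeric(min(n1, n2))
  res <- Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(config$max_iter)) {
    s <- svd(Y)
    d <- pmax(s$d - tau, 0)
    r <- sum(d > 0)
    X <- if (r == 0L) matrix(0, n1, n2) else
      s$u[, seq_len(r), drop = FALSE] %*%
        (d[seq_len(r)] * t(s$v[, seq_len(r), drop = FALSE]))
    sv_thr <- d
    res <- sqrt(sum((X[lin] - vals)^2)) / obs_norm
    if (config$record_history) history[iter] <- res
    if (!is.finite(res)) break          # diverged (step size too large)
    if (res <= config$eps0) { converged <- TRUE; break }
    Y[lin] <- Y[lin] + delta * (vals - X[lin])
  }
  structure(
    list(completed = X,
         iterations = iter,
         final_residual = res,
         residual_history = if (config$record_history) history[seq_len(iter)],
         singular_values = sort(sv_thr, decreasing = TRUE),
         converged = converged,
         tau = tau, delta = delta, eps0 = config$eps0),
    class = "completion_result")
}

#' @export
print.completion_result <- function(x, ...) {
  cat(sprintf(
    "completion_result: %d x %d, %d iterations, residual %.3g (%s), rank %d\n",
    nrow(x$completed), ncol(x$completed), x$iterations, x$final_residual,
    if (x$converged) "converged" else "iteration cap reached",
    sum(x$singular_values > 0)))
  invisible(x)
}
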