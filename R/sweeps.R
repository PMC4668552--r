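# Seeded sweep experiments: the package's reusable versions of the
# sampling-fraction and threshold studies.

#' Stable per-cell seed derivation for sweep experiments
#'
#' A linear congruential mix of the base seed and the cell coordinates,
#' reduced mod 2^31 - 1 (all intermediates stay below 2^53, so the
#' arithmetic is exact in doubles).  Used by the sweep functions so that
#' every (setting, repetition) cell is reproducible in isolation.
#'
#' @param base_seed integer master seed.
#' @param i,j nonnegative integers identifying the cell.
#' @return A positive integer seed below 2^31.
#' @export
derive_seed <- function(base_seed, i, j) {
  h <- (as.numeric(base_seed) %% 2147483647) * 48271 + i * 69621 + j * 16807
  as.integer(h %% 2147483647 + 1)
}

sweep_row <- function(setting_name, setting, rep, seed, method, metric,
                      value, iterations, converged) {
  data.frame(setting_name = setting_name, setting = setting, rep = rep,
             seed = seed, method = method, metric = metric, value = value,
             iterations = iterations, converged = converged)
}

#' Sampling-fraction sweep: SNR and fidelity vs fraction of kept entries
#'
#' For every sampling fraction and repetition, draws a fresh uniform
#' random mask, reconstructs the matrix by SVT, and records spectral SNR
#' and time-domain fidelity for both the completed matrix (`"mc"`) and
#' the zero-filled subsampled matrix (`"zerofill"`).  Repetition seeds
#' are derived from `base_seed` with a stable hash, so the sweep is fully
#' reproducible and individual cells can be re-run in isolation.
#'
#' @param signal the fully sampled reference [td_signal()].
#' @param fractions sampling fractions in (0, 1].
#' @param n_reps repetitions (independent masks) per fraction.
#' @param config an [svt_config()] template.
#' @param peak_region,noise_region [region_spec()]s for the SNR.
#' @param base_seed integer master seed.
#' @return A data frame of class `sweep_result` with columns
#'   `setting_name` (`"fraction"`), `setting`, `rep`, `seed`, `method`,
#'   `metric`, `value`, `iterations`, `converged`.  A solver failure is
#'   recorded as a row with `value = NA`, not an error.
#' @seealso [aggregate_sweep()], [sweep_threshold()]
#' @export
sweep_fraction <- function(signal, fractions, n_reps, config = svt_config(),
                           peak_region, noise_region, base_seed = 1L) {
  stopifnot(inherits(signal, "td_signal"))
  if (any(fractions <= 0 | fractions > 1))
    stop("fractions must lie in (0, 1]")
  M <- signal$values
  rows <- list()
  for (fi in seq_along(fractions)) {
    frac <- fractions[fi]
    for (r in seq_len(n_reps)) {
      seed <- derive_seed(base_seed, fi, r)
      omega <- draw_mask(mask_spec(nrow(M), ncol(M), frac, seed))
      obs <- apply_mask(M, omega)
      zf <- zero_fill(obs)
      fit <- tryCatch(svt_complete(obs, config), error = function(e) NULL)
      for (method in c("mc", "zerofill")) {
        X <- if (method == "mc") {
          if (is.null(fit)) NULL else fit$completed
        } else zf
        iters <- if (method == "mc" && !is.null(fit)) fit$iterations else 0L
        conv <- if (method == "mc")
          !is.null(fit) && fit$converged else TRUE
        sval <- if (is.null(X)) NA_real_ else
          snr(fourier_spectrum(td_signal(X, signal$dt1, signal$dt2)),
              peak_region, noise_region)
        fval <- if (is.null(X)) NA_real_ else fidelity(M, X)
        rows[[length(rows) + 1L]] <-
          rbind(sweep_row("fraction", frac, r, seed, method, "snr",
                          sval, iters, conv),
                sweep_row("fraction", frac, r, seed, method, "fidelity",
                          fval, iters, conv))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Threshold sweep: fidelity and iteration count vs tau and fraction
#'
#' Runs SVT completion over a grid of thresholds `tau` and sampling
#' fractions, recording the recovery fidelity and the number of
#' iterations spent — the study that shows small thresholds degrading
#' fidelity at low sampling fractions while large thresholds inflate the
#' iteration count.
#'
#' @param signal the fully sampled reference [td_signal()].
#' @param taus singular-value thresholds to test.
#' @param fractions sampling fractions in (0, 1].
#' @param n_reps repetitions per (tau, fraction) cell.
#' @param config an [svt_config()] template (its `tau` is overridden).
#' @param base_seed integer master seed.
#' @return A `sweep_result` data frame as in [sweep_fraction()], with
#'   `setting_name` `"tau"` and an extra column `fraction`.
#' @export
sweep_threshold <- function(signal, taus, fractions, n_reps = 1L,
                            config = svt_config(), base_seed = 1L) {
  stopifnot(inherits(signal, "td_signal"))
  M <- signal$values
  rows <- list()
  for (ti in seq_along(taus)) {
    for (fi in seq_along(fractions)) {
      frac <- fractions[fi]
      for (r in seq_len(n_reps)) {
        seed <- derive_seed(base_seed, fi, (ti - 1L) * n_reps + r)
        omega <- draw_mask(mask_spec(nrow(M), ncol(M), frac, seed))
        obs <- apply_mask(M, omega)
        cfg <- config
        cfg$tau <- taus[ti]
        fit <- tryCatch(svt_complete(obs, cfg), error = function(e) NULL)
        row <- sweep_row("tau", taus[ti], r, seed, "mc", "fidelity",
                         if (is.null(fit)) NA_real_ else
                           fidelity(M, fit$completed),
                         if (is.null(fit)) 0L else fit$iterations,
                         !is.null(fit) && fit$converged)
        row$fraction <- frac
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Aggregate a sweep: mean and standard deviation per setting
#'
#' @param sweep a `sweep_result` data frame.
#' @return A data frame with one row per (setting \[, fraction\], method,
#'   metric) combination and columns `mean`, `sd`, `n`, `mean_iterations`.
#' @export
aggregate_sweep <- function(sweep) {
  stopifnot(inherits(sweep, "sweep_result"))
  by_cols <- intersect(c("setting_name", "setting", "fraction", "method",
                         "metric"), names(sweep))
  agg <- aggregate(sweep[c("value", "iterations")], sweep[by_cols],
                   function(x) c(mean = mean(x, na.rm = TRUE),
                                 sd = sd(x, na.rm = TRUE),
                                 n = sum(!is.na(x))))
  out <- agg[by_cols]
  out$mean <- agg$value[, "mean"]
  out$sd <- agg$value[, "sd"]
  out$n <- agg$value[, "n"]
  out$mean_iterations <- agg$iterations[, "mean"]
  out[order(out$metric, out$setting), ]
}
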