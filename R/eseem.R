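#' Two-delay pulse sequence grids for stimulated-echo ESEEM
#'
#' The three-pulse (stimulated-echo) ESEEM experiment applies four ideal
#' pi/2 microwave pulses at times `0`, `t1`, `t1 + t2` and
#' `2 t1 + t2`; the last pulse converts the refocused electron coherence
#' into a population that is read out optically.  The signal is recorded
#' on a regular grid of the two inter-pulse delays.
#'
#' @param n1,n2 number of samples along `t1` and `t2` (at least 2).
#' @param dt1,dt2 dwell times (s).
#' @param t1_start,t2_start first delay values (s), default 0.
#' @param addressed_transition which electron two-level transition the
#'   microwave pulses drive: `"ms0_to_minus1"` (default) or
#'   `"ms0_to_plus1"`.
#' @return An object of class `pulse_sequence` with fields `t1`, `t2`
#'   (delay grids, s), `dt1`, `dt2` and `addressed_transition`.
#' @export
pulse_sequence <- function(n1, n2, dt1, dt2, t1_start = 0, t2_start = 0,
                           addressed_transition = c("ms0_to_minus1",
                                                    "ms0_to_plus1")) {
  n1 <- as.integer(n1); n2 <- as.integer(n2)
  if (anyNA(c(n1, n2)) || n1 < 2L || n2 < 2L)
    stop("n1 and n2 must be integers >= 2")
  if (!is.finite(dt1) || dt1 <= 0 || !is.finite(dt2) || dt2 <= 0)
    stop("dwell times must be positive")
  if (t1_start < 0 || t2_start < 0)
    stop("delays must be nonnegative")
  structure(
    list(t1 = t1_start + dt1 * (seq_len(n1) - 1L),
         t2 = t2_start + dt2 * (seq_len(n2) - 1L),
         dt1 = dt1, dt2 = dt2,
         addressed_transition = match.arg(addressed_transition)),
    class = "pulse_sequence")
}

#' 2D time-domain signal
#'
#' @param values real `n1 x n2` matrix of the readout observable sampled
#'   on the `(t1, t2)` delay grids (rows index `t1`).
#' @param dt1,dt2 dwell times (s).
#' @param meta free-text provenance string.
#' @return An object of class `td_signal`.
#' @export
td_signal <- function(values, dt1, dt2, meta = "") {
  if (!is.matrix(values) || !is.numeric(values) || !all(is.finite(values)))
    stop("values must be a finite numeric matrix")
  if (!is.finite(dt1) || dt1 <= 0 || !is.finite(dt2) || dt2 <= 0)
    stop("dwell times must be positive")
  structure(list(values = values, dt1 = dt1, dt2 = dt2,
                 meta = as.character(meta)[1L]),
            class = "td_signal")
}

#' @export
print.td_signal <- function(x, ...) {
  cat(sprintf("td_signal: %d x %d, dt1 = %.3g s, dt2 = %.3g s%s\n",
              nrow(x$values), ncol(x$values), x$dt1, x$dt2,
              if (nzchar(x$meta)) paste0(" (", x$meta, ")") else ""))
  invisible(x)
}

# ideal pi/2 rotation with phase phi on the two addressed electron
# levels, identity elsewhere and on the nuclei
pulse_matrix <- function(de, dn, pair, phi) {
  p <- diag(de) + 0i
  c_ <- cos(pi / 4)
  s_ <- -1i * sin(pi / 4)
  p[pair[1L], pair[1L]] <- c_
  p[pair[2L], pair[2L]] <- c_
  p[pair[1L], pair[2L]] <- s_ * exp(-1i * phi)
  p[pair[2L], pair[1L]] <- s_ * exp(1i * phi)
  kronecker(p, diag(dn) + 0i)
}

herm <- function(m) Conj(t(m))

# Core propagation shared by the NV and effective-two-level front ends.
# H is the full Hamiltonian (Hz) on electron (de) x nuclear (dn) space;
# pair gives the addressed electron levels (initial/bright level first).
# The simulation runs in the frame rotating at the addressed transition's
# mean frequency (the microwave carrier), where pulse phases are defined.
propagate_eseem <- function(H, de, dn, pair, t1, t2, phase_cycle = TRUE,
                            diagnostics = FALSE) {
  d <- de * dn
  dn_idx <- function(k) (k - 1L) * dn + seq_len(dn)
  w_mw <- Re(mean(diag(H)[dn_idx(pair[2L])]) -
             mean(diag(H)[dn_idx(pair[1L])]))
  N <- matrix(0, de, de)
  N[pair[2L], pair[2L]] <- 1
  Hrot <- H - w_mw * kronecker(N, diag(dn))
  ev <- eigen(Hrot, symmetric = TRUE)
  Vb <- ev$vectors
  prop <- function(t) Vb %*% (exp(-2i * pi * ev$values * t) * herm(Vb))

  P0 <- pulse_matrix(de, dn, pair, 0)
  phis <- c(0, pi / 2, pi, 3 * pi / 2)
  Pph <- lapply(phis, function(p) pulse_matrix(de, dn, pair, p))
  wts <- exp(-1i * phis) / 4

  rho0 <- matrix(0i, d, d)
  rho0[dn_idx(pair[1L]), dn_idx(pair[1L])] <- diag(dn) / dn
  # readout: population of the initial (bright) electron level after the
  # fourth pulse; fold the fixed last pulse into the observable
  Pop <- matrix(0i, d, d)
  Pop[cbind(dn_idx(pair[1L]), dn_idx(pair[1L]))] <- 1
  Q <- herm(P0) %*% Pop %*% P0

  # weighted conjugation sum over a pulse's phase cycle (selects the
  # stimulated-echo coherence pathway); linear, so applied once per stage
  cyc <- function(x) {
    acc <- wts[1L] * (Pph[[1L]] %*% x %*% herm(Pph[[1L]]))
    for (k in 2:4) acc <- acc + wts[k] * (Pph[[k]] %*% x %*% herm(Pph[[k]]))
    acc
  }

  U1 <- lapply(t1, prop)
  U2 <- lapply(t2, prop)
  rho1 <- P0 %*% rho0 %*% herm(P0)
  out <- matrix(0, length(t1), length(t2))
  diag_err <- c(unitarity = 0, trace = 0, positivity = 0)
  for (i in seq_along(t1)) {
    Ui <- U1[[i]]
    rho_t1 <- Ui %*% rho1 %*% herm(Ui)
    if (diagnostics) {
      diag_err["unitarity"] <- max(diag_err["unitarity"],
                                   max(Mod(Ui %*% herm(Ui) - diag(d))))
      diag_err["trace"] <- max(diag_err["trace"],
                               abs(Re(sum(diag(rho_t1))) - 1))
      diag_err["positivity"] <-
        min(diag_err["positivity"],
            min(eigen((rho_t1 + herm(rho_t1)) / 2, symmetric = TRUE,
                      only.values = TRUE)$values))
    }
    A <- if (phase_cycle) cyc(rho_t1) else
      Pph[[1L]] %*% rho_t1 %*% herm(Pph[[1L]])
    for (j in seq_along(t2)) {
      B <- U2[[j]] %*% A %*% herm(U2[[j]])
      C <- if (phase_cycle) cyc(B) else
        Pph[[1L]] %*% B %*% herm(Pph[[1L]])
      D <- Ui %*% C %*% herm(Ui)
      tr <- Re(sum(Q * t(D))) # tr(Q D), Q Hermitian
      out[i, j] <- if (phase_cycle) 0.5 + 4 * tr else tr
    }
  }
  if (diagnostics) attr(out, "diagnostics") <- diag_err
  out
}

electron_pair <- function(addressed_transition) {
  # electron basis ordered by Sz eigenvalue: +1, 0, -1
  switch(addressed_transition,
         ms0_to_minus1 = c(2L, 3L),
         ms0_to_plus1 = c(2L, 1L),
         stop("unknown addressed transition"))
}

#' Simulate a 2D stimulated-echo ESEEM experiment on an NV centre
#'
#' Density-matrix simulation with ideal, instantaneous pi/2 pulses on the
#' addressed electron two-level transition.  The spin state starts in
#' `ms = 0` (the optically polarized bright state) with the nuclei
#' maximally mixed; the sequence pulse - t1 - pulse - t2 - pulse - t1 -
#' pulse is applied and the `ms = 0` population is read out.  Free
#' evolution uses the Hamiltonian propagator in the frame rotating at
#' the addressed transition's mean frequency (the microwave carrier),
#' after the secular step that removes the electron-flip blocks in the
#' electron eigenbasis (their only physical effect is a level shift of
#' order \eqn{A^2 / D}; keeping them static in the rotating frame would
#' wrongly make them resonant).  Because the blocking is done in the
#' electron eigenbasis, a misaligned field retains its effective
#' pseudo-secular hyperfine terms — the mechanism that switches the
#' modulation on.
#'
#' By default the readout is phase cycled: the phases of the second and
#' third pulses are stepped through 0, 90, 180, 270 degrees and the 16
#' runs combined with weights \eqn{e^{-i(\phi_2+\phi_3)}}, which isolates
#' the stimulated-echo coherence pathway exactly as hardware phase
#' cycling does in the laboratory.  The cycled signal equals
#' `(1 + V) / 2` where `V` is the standard echo envelope (see
#' [mims_eseem_analytic()]); without cycling the raw single-run
#' population additionally contains free-decay and two-pulse-echo
#' pathways.
#'
#' @param sys a [spin_system()].
#' @param seq a [pulse_sequence()].
#' @param phase_cycle isolate the stimulated-echo pathway (default TRUE).
#' @param diagnostics attach propagator-unitarity / trace / positivity
#'   diagnostics to the result's `meta` attribute.
#' @param max_elements resource cap on `n1 * n2` (default `2^20`).
#' @return A [td_signal()] with values in `[0, 1]`.
#' @export
simulate_eseem <- function(sys, seq, phase_cycle = TRUE,
                           diagnostics = FALSE, max_elements = 2^20) {
  stopifnot(inherits(sys, "spin_system"), inherits(seq, "pulse_sequence"))
  if (length(seq$t1) * length(seq$t2) > max_elements)
    stop("requested grid exceeds max_elements = ", max_elements)
  bl <- blocked_hamiltonian(sys)
  vals <- propagate_eseem(bl$H, 3L, bl$dn,
                          electron_pair(seq$addressed_transition),
                          seq$t1, seq$t2, phase_cycle, diagnostics)
  sig <- td_signal(pmin(pmax(as.matrix(vals), 0), 1), seq$dt1, seq$dt2,
                   meta = sprintf("simulate_eseem NV, %s, phase_cycle=%s",
                                  seq$addressed_transition, phase_cycle))
  if (diagnostics) attr(sig, "diagnostics") <- attr(vals, "diagnostics")
  sig
}

#' Simulate ESEEM for an effective electron two-level system
#'
#' The textbook model behind the Mims envelope: an electron spin 1/2 (the
#' addressed NV transition treated as an isolated two-level system)
#' coupled to one I = 1/2 nucleus through a secular (`a_zz_hz`) and
#' pseudo-secular (`a_zx_hz`) hyperfine interaction, with nuclear Larmor
#' frequency `omega_i_hz`:
#' \deqn{H = S_z (A_{zz} I_z + A_{zx} I_x) + \omega_I I_z.}
#' Useful as a direct numerical check of [mims_eseem_analytic()].
#'
#' @param omega_i_hz nuclear Larmor frequency (Hz).
#' @param a_zz_hz,a_zx_hz secular and pseudo-secular hyperfine couplings
#'   (Hz).
#' @param seq a [pulse_sequence()] (the addressed-transition field is
#'   ignored; the two levels are the transition).
#' @inheritParams simulate_eseem
#' @return A [td_signal()] with values in `[0, 1]`.
#' @export
simulate_eseem_twolevel <- function(omega_i_hz, a_zz_hz, a_zx_hz, seq,
                                    phase_cycle = TRUE,
                                    diagnostics = FALSE) {
  stopifnot(inherits(seq, "pulse_sequence"))
  s <- spin_operators(0.5)
  H <- kronecker(s$z, a_zz_hz * s$z + a_zx_hz * s$x) +
    omega_i_hz * kronecker(diag(2) + 0i, s$z)
  H <- (H + herm(H)) / 2
  vals <- propagate_eseem(H, 2L, 2L, c(1L, 2L), seq$t1, seq$t2,
                          phase_cycle, diagnostics)
  sig <- td_signal(as.matrix(Re(vals)), seq$dt1, seq$dt2,
                   meta = "simulate_eseem two-level")
  if (diagnostics) attr(sig, "diagnostics") <- attr(vals, "diagnostics")
  sig
}

#' Parameters of the Mims envelope for the two-level ESEEM model
#'
#' Closed forms for the nuclear precession frequencies in the two
#' electron manifolds and the modulation depth of the model
#' \eqn{H = S_z (A_{zz} I_z + A_{zx} I_x) + \omega_I I_z}:
#' \deqn{\omega_{\alpha,\beta} = \sqrt{(\omega_I \pm A_{zz}/2)^2
#'       + A_{zx}^2/4}, \qquad
#'       k = \left(\frac{A_{zx}\,\omega_I}
#'                 {\omega_\alpha \omega_\beta}\right)^2.}
#'
#' @inheritParams simulate_eseem_twolevel
#' @return A list with `omega_alpha`, `omega_beta` (Hz) and `k`.
#' @export
mims_parameters <- function(omega_i_hz, a_zz_hz, a_zx_hz) {
  wa <- sqrt((omega_i_hz + a_zz_hz / 2)^2 + (a_zx_hz / 2)^2)
  wb <- sqrt((omega_i_hz - a_zz_hz / 2)^2 + (a_zx_hz / 2)^2)
  k <- if (wa == 0 || wb == 0) 0 else (a_zx_hz * omega_i_hz / (wa * wb))^2
  list(omega_alpha = wa, omega_beta = wb, k = k)
}

#' Analytic stimulated-echo (three-pulse) ESEEM envelope
#'
#' The standard closed-form envelope for one I = 1/2 nucleus with
#' manifold frequencies `omega_alpha`, `omega_beta` and modulation depth
#' `k`, evaluated with first delay `t1` and second delay `t2`:
#' \deqn{V(t_1, t_2) = 1 - \frac{k}{4}\{
#'   [1-\cos\omega_\alpha t_1][1-\cos\omega_\beta (t_1+t_2)] +
#'   [1-\cos\omega_\beta t_1][1-\cos\omega_\alpha (t_1+t_2)]\}.}
#' Serves as the independent oracle for [simulate_eseem_twolevel()]
#' (whose phase-cycled population equals `(1 + V) / 2`) and as a fast
#' generator of ESEEM-like low-rank test signals.
#'
#' @param omega_alpha,omega_beta manifold transition frequencies (Hz).
#' @param depth_k modulation depth in \[0, 1\].
#' @param seq a [pulse_sequence()].
#' @return A [td_signal()] holding `V` on the delay grids.
#' @export
mims_eseem_analytic <- function(omega_alpha, omega_beta, depth_k, seq) {
  stopifnot(inherits(seq, "pulse_sequence"))
  if (!is.finite(depth_k) || depth_k < 0 || depth_k > 1)
    stop("depth_k must lie in [0, 1]")
  if (!is.finite(omega_alpha) || !is.finite(omega_beta) ||
      omega_alpha < 0 || omega_beta < 0)
    stop("frequencies must be nonnegative")
  wa <- 2 * pi * omega_alpha
  wb <- 2 * pi * omega_beta
  t1 <- seq$t1
  tt <- outer(seq$t1, seq$t2, "+")
  V <- 1 - (depth_k / 4) *
    ((1 - cos(wa * t1)) * (1 - cos(wb * tt)) +
     (1 - cos(wb * t1)) * (1 - cos(wa * tt)))
  td_signal(V, seq$dt1, seq$dt2, meta = "mims_eseem_analytic")
}
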