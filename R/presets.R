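#' Demonstration spin systems and pulse sequences
#'
#' Two ready-made scenarios exercising the simulator:
#'
#' * `"n14_misaligned"` — an NV centre with its intrinsic \eqn{^{14}}N
#'   nuclear spin and the static field applied 34.1 degrees off the NV
#'   axis.  With an aligned field the nitrogen hyperfine tensor is
#'   diagonal in the NV frame and there is no envelope modulation;
#'   tilting the field introduces effective off-diagonal terms and
#'   switches the ESEEM effect on.
#' * `"c13"` — an NV centre additionally coupled to a single
#'   \eqn{^{13}}C nuclear spin through an anisotropic hyperfine tensor,
#'   field aligned with the NV axis.  The carbon coupling is chosen to
#'   place the dominant nuclear transition frequencies near 9 MHz.
#'
#' Field magnitudes and tensor entries are package defaults chosen to
#' give well-resolved demo spectra; they are representative values, not
#' measurements of any particular centre.  The \eqn{^{14}}N tensor uses
#' the literature-style secular couplings (A_perp = -2.7 MHz,
#' A_par = -2.16 MHz).
#'
#' @param name preset name.
#' @return A list with elements `system` (a [spin_system()]) and
#'   `sequence` (a matching [pulse_sequence()]).
#' @export
nv_preset <- function(name = c("c13", "n14_misaligned")) {
  name <- match.arg(name)
  a_n <- diag(c(-2.7e6, -2.7e6, -2.16e6))
  if (name == "n14_misaligned") {
    sys <- spin_system(b_t = 3e-3, theta_deg = 34.1, phi_deg = 0,
                       A_n_hz = a_n)
    seq <- pulse_sequence(128, 128, dt1 = 4e-8, dt2 = 4e-8)
  } else {
    a_c <- matrix(c(3.0e6, 0, 2.0e6,
                    0, 3.0e6, 0,
                    2.0e6, 0, 8.6e6), 3, 3, byrow = TRUE)
    sys <- spin_system(b_t = 4e-3, theta_deg = 0,
                       A_n_hz = a_n, A_c_hz = a_c)
    seq <- pulse_sequence(128, 128, dt1 = 4e-8, dt2 = 4e-8)
  }
  list(system = sys, sequence = seq)
}
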