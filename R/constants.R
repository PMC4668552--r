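# Physical constants used by the spin Hamiltonian, in frequency units
# (energies are expressed as E/h throughout, so Hamiltonians are in Hz).
# CODATA 2018 values.

#' Physical constants of the spin simulator
#'
#' All Hamiltonians in the package are expressed in frequency units
#' (energy divided by the Planck constant), so the relevant constants are:
#'
#' * `bohr_magneton_hz_per_t`: \eqn{\mu_B / h = 13.996244936}{mu_B/h} GHz/T,
#' * `gyromag_hz_per_t`: reduced gyromagnetic ratios \eqn{\gamma/2\pi} of
#'   the nuclei handled by the simulator (Hz/T): `c13 = 10.7084` MHz/T,
#'   `n14 = 3.0777` MHz/T, `h1 = 42.57747892` MHz/T.
#'
#' @format A named list.
#' @export
mr_constants <- list(
  bohr_magneton_hz_per_t = 13.996244936e9,
  gyromag_hz_per_t = c(c13 = 10.7084e6, n14 = 3.0777e6, h1 = 42.57747892e6)
)
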