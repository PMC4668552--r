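#' Angular-momentum operators for a single spin
#'
#' Standard matrices `Sx`, `Sy`, `Sz` (in units of hbar) for a spin-1/2 or
#' spin-1 particle, built from the ladder operators.  They satisfy the
#' cyclic commutation relations `[Sx, Sy] = i Sz` and `Sz` is diagonal
#' with entries `s, s-1, ..., -s`.
#'
#' @param s spin quantum number, 1/2 or 1.
#' @return A list of three `(2s+1) x (2s+1)` complex Hermitian matrices
#'   `x`, `y`, `z`.
#' @export
spin_operators <- function(s) {
  if (!isTRUE(all.equal(s, 0.5)) && !isTRUE(all.equal(s, 1)))
    stop("unsupported spin quantum number; use 1/2 or 1")
  m <- seq(s, -s) # Sz eigenvalues, descending
  d <- length(m)
  sz <- diag(m) + 0i
  # <m'|S+|m> = sqrt(s(s+1) - m(m+1)) for m' = m + 1
  sp <- matrix(0i, d, d)
  for (k in seq_len(d - 1L))
    sp[k, k + 1L] <- sqrt(s * (s + 1) - m[k + 1L] * (m[k + 1L] + 1))
  sm <- Conj(t(sp))
  list(x = (sp + sm) / 2, y = (sp - sm) / (2i), z = sz)
}

check_hyperfine <- function(A, name) {
  if (is.null(A)) return(NULL)
  A <- as.matrix(A)
  if (!is.numeric(A) || any(dim(A) != c(3L, 3L)) || !all(is.finite(A)))
    stop(name, " must be a finite 3x3 numeric tensor (Hz)")
  asym <- max(abs(A - t(A)))
  scale <- max(abs(A), 1)
  if (asym > 1e-9 * scale)
    stop(name, " is not symmetric (relative asymmetry ",
         format(asym / scale), " exceeds 1e-9)")
  (A + t(A)) / 2
}

#' Spin system of a nitrogen-vacancy centre
#'
#' Physical parameters of the NV ground-state spin Hamiltonian: an
#' electron spin S = 1 with zero-field splitting `D`, electron Zeeman
#' coupling to a static field `B`, hyperfine coupling to the intrinsic
#' \eqn{^{14}}N nuclear spin (I = 1), and optionally to one
#' \eqn{^{13}}C nuclear spin (I = 1/2).  The `z` axis is the NV crystal
#' axis; the magnetic field is given in spherical coordinates in that
#' frame; hyperfine tensors are 3x3 matrices in the same frame, in Hz.
#'
#' @param D_hz zero-field splitting (Hz); NV ground state: 2.87 GHz.
#' @param g electron Lande factor (NV: 2.0028).
#' @param b_t magnetic field magnitude (tesla).
#' @param theta_deg polar angle of the field from the NV axis (degrees).
#' @param phi_deg azimuth of the field (degrees).
#' @param A_n_hz 3x3 hyperfine tensor to the \eqn{^{14}}N spin (Hz); the
#'   zero matrix switches the coupling off.
#' @param A_c_hz optional 3x3 hyperfine tensor to a single \eqn{^{13}}C
#'   spin (Hz); `NULL` omits the carbon from the model.
#' @param include_nuclear_zeeman include the nuclear Zeeman terms
#'   \eqn{-\gamma_n \mathbf{B} \cdot \mathbf{I}} (on by default; without
#'   them a \eqn{^{13}}C spectrum has no Larmor-split peaks).
#' @param P_n_hz optional \eqn{^{14}}N quadrupole coupling (Hz), adding
#'   \eqn{P (I_z^2 - I(I+1)/3)}; `NULL` omits the term.
#' @return An object of class `spin_system`.
#' @seealso [build_hamiltonian()], [simulate_eseem()], [nv_preset()]
#' @export
spin_system <- function(D_hz = 2.87e9, g = 2.0028,
                        b_t = 0, theta_deg = 0, phi_deg = 0,
                        A_n_hz = matrix(0, 3, 3), A_c_hz = NULL,
                        include_nuclear_zeeman = TRUE, P_n_hz = NULL) {
  if (!is.finite(D_hz) || D_hz <= 0) stop("D_hz must be positive")
  if (!is.finite(g) || g <= 0) stop("g must be positive")
  if (!is.finite(b_t) || b_t < 0) stop("b_t must be nonnegative")
  structure(
    list(D_hz = D_hz, g = g, b_t = b_t,
         theta_deg = theta_deg, phi_deg = phi_deg,
         A_n_hz = check_hyperfine(A_n_hz, "A_n_hz"),
         A_c_hz = check_hyperfine(A_c_hz, "A_c_hz"),
         include_nuclear_zeeman = isTRUE(include_nuclear_zeeman),
         P_n_hz = P_n_hz),
    class = "spin_system")
}

#' @export
print.spin_system <- function(x, ...) {
  cat(sprintf(
    "spin_system: D = %.4g GHz, g = %.4f, B = %.3g mT (theta %.1f deg, phi %.1f deg)\n",
    x$D_hz / 1e9, x$g, x$b_t * 1e3, x$theta_deg, x$phi_deg))
  cat(sprintf("  14N hyperfine max |A| = %.3g MHz; 13C: %s; nuclear Zeeman: %s\n",
              max(abs(x$A_n_hz)) / 1e6,
              if (is.null(x$A_c_hz)) "absent" else
                sprintf("max |A| = %.3g MHz", max(abs(x$A_c_hz)) / 1e6),
              if (x$include_nuclear_zeeman) "on" else "off"))
  invisible(x)
}

# field vector (tesla) in the NV frame
b_vector <- function(sys) {
  th <- sys$theta_deg * pi / 180
  ph <- sys$phi_deg * pi / 180
  sys$b_t * c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
}

# spin structure of the Hilbert space: electron (3) x 14N (3) [x 13C (2)]
space_dims <- function(sys) if (is.null(sys$A_c_hz)) c(3L, 3L) else c(3L, 3L, 2L)

# embed an operator acting on factor k of a tensor-product space
embed_op <- function(op, dims, k) {
  out <- if (k == 1L) op else diag(dims[1L]) + 0i
  for (j in seq_along(dims)[-1L])
    out <- kronecker(out, if (j == k) op else diag(dims[j]) + 0i)
  out
}

# S . A . I summed over cartesian components, with S, I given as embedded
# operator triples
coupling_term <- function(S, I, A) {
  H <- 0
  for (a in 1:3) for (b in 1:3)
    if (A[a, b] != 0) H <- H + A[a, b] * (S[[a]] %*% I[[b]])
  H
}

#' Build the NV spin Hamiltonian matrix
#'
#' Assembles, in frequency units (Hz),
#' \deqn{H = D S_z^2 + g \mu_B \mathbf{B}\cdot\mathbf{S}
#'       + \mathbf{S} A_N \mathbf{I}_N
#'       [+ \mathbf{S} A_{13C} \mathbf{I}_C]
#'       [- \gamma_n \mathbf{B}\cdot\mathbf{I} \ \mathrm{terms}]
#'       [+ P (I_{N,z}^2 - 2/3)]}
#' on the tensor-product space electron (dimension 3) x nitrogen (3)
#' [x carbon (2)], i.e. a 9x9 or 18x18 complex Hermitian matrix.
#'
#' @param sys a [spin_system()].
#' @return A complex Hermitian matrix (Hz).
#' @export
build_hamiltonian <- function(sys) {
  stopifnot(inherits(sys, "spin_system"))
  dims <- space_dims(sys)
  se <- spin_operators(1)
  sn <- spin_operators(1)
  S <- lapply(se, embed_op, dims = dims, k = 1L)
  In <- lapply(sn, embed_op, dims = dims, k = 2L)
  B <- b_vector(sys)
  gam <- mr_constants$gyromag_hz_per_t

  H <- sys$D_hz * (S[[3L]] %*% S[[3L]]) +
    sys$g * mr_constants$bohr_magneton_hz_per_t *
      (B[1] * S[[1L]] + B[2] * S[[2L]] + B[3] * S[[3L]]) +
    coupling_term(S, In, sys$A_n_hz)
  if (sys$include_nuclear_zeeman)
    H <- H - gam[["n14"]] *
      (B[1] * In[[1L]] + B[2] * In[[2L]] + B[3] * In[[3L]])
  if (!is.null(sys$P_n_hz))
    H <- H + sys$P_n_hz * (In[[3L]] %*% In[[3L]] - diag(prod(dims)) * 2 / 3)
  if (!is.null(sys$A_c_hz)) {
    Ic <- lapply(spin_operators(0.5), embed_op, dims = dims, k = 3L)
    H <- H + coupling_term(S, Ic, sys$A_c_hz)
    if (sys$include_nuclear_zeeman)
      H <- H - gam[["c13"]] *
        (B[1] * Ic[[1L]] + B[2] * Ic[[2L]] + B[3] * Ic[[3L]])
  }
  (H + Conj(t(H))) / 2 # enforce exact Hermiticity against rounding
}

# electron-only Hamiltonian (zero-field splitting + electron Zeeman)
electron_hamiltonian <- function(sys) {
  se <- spin_operators(1)
  B <- b_vector(sys)
  H <- sys$D_hz * (se$z %*% se$z) +
    sys$g * mr_constants$bohr_magneton_hz_per_t *
      (B[1] * se$x + B[2] * se$y + B[3] * se$z)
  (H + Conj(t(H))) / 2
}

# Eigenbasis of the electron Hamiltonian with columns ordered (and, in
# degenerate clusters, rotated) to carry the ms = +1, 0, -1 labels:
# each column has maximal overlap with the corresponding Sz eigenstate.
manifold_basis <- function(sys) {
  He <- electron_hamiltonian(sys)
  ev <- eigen(He)
  V <- ev$vectors
  # align degenerate clusters with the Sz basis
  scale <- max(abs(ev$values), 1)
  grp <- cumsum(c(TRUE, diff(ev$values) > 1e-9 * scale |
                        diff(ev$values) < -1e-9 * scale))
  sz <- diag(c(1, 0, -1))
  for (g in unique(grp)) {
    cols <- which(grp == g)
    if (length(cols) > 1L) {
      sub <- Conj(t(V[, cols, drop = FALSE])) %*% sz %*%
        V[, cols, drop = FALSE]
      V[, cols] <- V[, cols, drop = FALSE] %*%
        eigen((sub + Conj(t(sub))) / 2)$vectors
    }
  }
  # order columns by dominant Sz character: +1, 0, -1
  lab <- apply(Mod(V)^2, 2L, which.max)
  if (anyDuplicated(lab))
    stop("cannot assign electron manifolds unambiguously")
  V[, order(lab)]
}

# Full Hamiltonian in the electron-eigenmanifold basis with the
# inter-manifold (electron-flip) blocks removed: the secular
# approximation that underlies ideal-pulse ESEEM modelling.  Dropping
# those blocks is what makes the microwave rotating frame exact; their
# physical effect is a level shift of order A^2 / D.  Because the
# blocking is done in the electron eigenbasis, a tilted static field
# still produces the effective pseudo-secular hyperfine terms that drive
# the modulation.
blocked_hamiltonian <- function(sys) {
  H <- build_hamiltonian(sys)
  dims <- space_dims(sys)
  dn <- prod(dims[-1L])
  Ve <- manifold_basis(sys)
  W <- kronecker(Ve, diag(dn) + 0i)
  Hp <- Conj(t(W)) %*% H %*% W
  Hb <- matrix(0i, nrow(Hp), ncol(Hp))
  for (k in 1:3) {
    sel <- (k - 1L) * dn + seq_len(dn)
    Hb[sel, sel] <- Hp[sel, sel]
  }
  list(H = (Hb + Conj(t(Hb))) / 2, basis = Ve, dn = dn)
}

#' Nuclear transition frequencies per electron manifold
#'
#' For each electron spin projection (`ms = +1, 0, -1`) the nuclear spins
#' evolve under the sub-Hamiltonian conditioned on that manifold; the
#' differences of its eigenvalues are the frequencies at which the echo
#' envelope is modulated, i.e. the expected ESEEM peak positions.
#'
#' @param sys a [spin_system()].
#' @return A named list (`ms_plus1`, `ms_0`, `ms_minus1`) of nonnegative,
#'   sorted frequency vectors (Hz), each of length `choose(d_nuc, 2)`.
#' @export
nuclear_transition_frequencies <- function(sys) {
  stopifnot(inherits(sys, "spin_system"))
  bl <- blocked_hamiltonian(sys)
  dn <- bl$dn
  out <- lapply(1:3, function(k) {
    sel <- (k - 1L) * dn + seq_len(dn)
    ev <- eigen(bl$H[sel, sel, drop = FALSE], symmetric = TRUE,
                only.values = TRUE)$values
    sort(abs(as.vector(outer(ev, ev, "-"))[lower.tri(diag(length(ev)))]))
  })
  names(out) <- c("ms_plus1", "ms_0", "ms_minus1") # Sz basis order +1, 0, -1
  out
}
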