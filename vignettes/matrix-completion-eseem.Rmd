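---
title: "Reconstructing 2D ESEEM spectra from subsampled data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing 2D ESEEM spectra from subsampled data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrcomplete)
```

Two-dimensional magnetic-resonance experiments record a signal on a grid
of two inter-pulse delays $(t_1, t_2)$ and Fourier transform both axes.
The price is acquisition time: the number of measured points grows as
the product of the grid sizes, and for single-spin detection (for
example, a nitrogen-vacancy centre in diamond read out optically) each
point is expensive. When the spectrum contains only a handful of peaks,
the time-domain matrix $M$ is close to low rank — a sum of $r$ separable
damped oscillations is exactly a rank-$r$ matrix — and low-rank matrix
completion can reconstruct $M$ from a small random subset of its
entries. This vignette describes the model and algorithm choices behind
`mrcomplete`, the assumptions they make, and what the package's tests do
and do not establish.

## The completion problem and the SVT iteration

Given observed entries $M_{ij}$ for $(i,j) \in \Omega$, the package
seeks the matrix of minimal trace (nuclear) norm that agrees with the
observations,
$$\min_X \|X\|_* \quad \text{s.t.} \quad X_{ij} = M_{ij},\ (i,j)\in\Omega,$$
approximately, via singular value thresholding (SVT). Starting from
$Y = 0$, the iteration alternates

1. $X \leftarrow \mathcal{D}_\tau(Y)$, the proximal operator of the
   nuclear norm: an SVD of $Y$ with every singular value reduced by
   $\tau$ and floored at zero;
2. $Y \leftarrow Y + \delta\, P_\Omega(M - X)$, a gradient step on the
   observed residual, supported on $\Omega$ only;

and stops when the relative misfit
$\|P_\Omega(X - M)\|_F / \|P_\Omega(M)\|_F$ drops to $\varepsilon_0$ or
an iteration cap is reached. The tunable parameters, their defaults and
the reasoning:

* **`tau`** (singular-value threshold, same units as the signal times
  grid size): default $5\max(n_1, n_2)$, the standard size-based rule.
  Larger `tau` tracks the exact trace-norm minimizer more closely but
  slows the start of the iteration (the first $\sim\tau/(\delta\sigma_1)$
  steps produce $X = 0$; the opt-in `warm_start` jumps over them).
  Thresholds far below the default let noise-rank components through
  and visibly reduce recovery fidelity at low sampling fractions — the
  behaviour the threshold sweep in `sweep_threshold()` measures.
* **`delta`** (step size, dimensionless): default $1.2/p$ where $p$ is
  the sampling fraction. Step sizes below 2 are the provably convergent
  regime; $1.2/p$ is the standard aggressive choice and can oscillate on
  hard instances, in which case the solver reports
  `converged = FALSE` rather than failing.
* **`eps0`** (relative termination tolerance): default $10^{-4}$. With
  noisy observations the misfit plateaus at the noise-to-signal level on
  $\Omega$; runs on measured data therefore typically end at the
  iteration cap while still returning the useful low-rank approximant —
  the noise, living in the discarded singular values, is suppressed
  rather than fitted.
* **`max_iter`**: default 1000 (500 in the recovery studies, where the
  plateau is reached much earlier).

The solver is deterministic: identical observations and configuration
reproduce identical iterates bitwise. A full dense SVD is computed each
iteration; at the few-hundred-point grids used in 2D ESEEM this costs
milliseconds, and truncated or randomized SVDs are deliberately out of
scope.

### What completion can and cannot do

Exact recovery of a rank-$r$ incoherent $n \times n$ matrix needs on the
order of $n^{6/5} r \log n$ random samples. At $n = 256$ and $r = 4$
this is roughly 10% of the entries, which is why the recovery studies
probe that regime. Two caveats the test suite makes explicit:

* recovery is probabilistic in the mask draw: for a small fraction of
  (matrix, mask) pairs near the information limit the ground truth is
  not the unique trace-norm minimizer, and then *no* nuclear-norm
  method can return it — the solver instead certifies a feasible matrix
  of no larger nuclear norm;
* with a finite `tau` the SVT fixed point is a regularized solution,
  not the exact minimizer; the bias shrinks as `tau` grows.

## The spin model behind the synthetic data

The simulator implements the NV ground-state Hamiltonian, in frequency
units, on the space electron $(S=1)$ $\otimes$ $^{14}$N $(I=1)$
$\otimes$ optionally one $^{13}$C $(I=1/2)$:
$$H = D S_z^2 + g\mu_B \mathbf{B}\cdot\mathbf{S}
  + \mathbf{S}\mathbf{A}_N\mathbf{I}_N
  + \mathbf{S}\mathbf{A}_{C}\mathbf{I}_C
  - \sum_n \gamma_n \mathbf{B}\cdot\mathbf{I}_n
  + P\!\left(I_{N,z}^2 - \tfrac{2}{3}\right),$$
with $z$ along the NV crystal axis and the field given in spherical
coordinates in that frame. Nuclear Zeeman terms are on by default —
without them a $^{13}$C spectrum would show no Larmor splitting — and
the $^{14}$N quadrupole term is off by default; both are switches on
`spin_system()`. Constants are CODATA values
(`mr_constants`). Hyperfine tensors are symmetrized when the relative
asymmetry is below $10^{-9}$ and rejected otherwise.

### Pulse sequence, rotating frame and readout

`simulate_eseem()` models the three-pulse (stimulated-echo) ESEEM
experiment: polarization into $m_s = 0$ with the nuclei maximally
mixed, four ideal instantaneous $\pi/2$ pulses on one electron
two-level transition (default $m_s = 0 \leftrightarrow -1$) at times
$0$, $t_1$, $t_1 + t_2$, $2t_1 + t_2$, and readout of the $m_s = 0$
population. Three modelling decisions matter:

* **Secular blocking.** Free evolution uses the Hamiltonian
  block-diagonalized over electron manifolds *in the electron
  eigenbasis*. The electron-flip hyperfine blocks oscillate at the
  carrier frequency in the microwave rotating frame; keeping them as
  static matrix elements after the frame shift would make them
  spuriously resonant (a numerically verified artifact: it produces
  order-unity modulation at twice the transverse hyperfine coupling in
  a configuration that must be modulation-free). Dropping them is the
  standard secular approximation; the neglected physics is a level
  shift of order $A^2/D \sim$ kHz. Blocking in the electron eigenbasis
  rather than the $S_z$ basis is essential: it preserves the effective
  pseudo-secular hyperfine terms created by a tilted field, which are
  exactly what switches the modulation on in the misaligned-field
  experiment.
* **Phase cycling.** The raw population after four same-phase pulses
  contains, besides the stimulated-echo pathway, free-decay and
  two-pulse-echo pathways. Laboratory ESEEM removes these by phase
  cycling, and the simulator does the same by default: the phases of
  pulses two and three are stepped through $0, 90, 180, 270^\circ$ and
  the 16 runs combined with weights $e^{-i(\phi_2+\phi_3)}$. The cycled
  signal equals $(1 + V)/2$, with $V$ the textbook stimulated-echo
  envelope; for one $I = 1/2$ nucleus with secular and pseudo-secular
  couplings,
  $$V(t_1,t_2) = 1 - \frac{k}{4}\Big\{
    [1-\cos\omega_\alpha t_1][1-\cos\omega_\beta(t_1+t_2)] +
    [1-\cos\omega_\beta t_1][1-\cos\omega_\alpha(t_1+t_2)]\Big\},$$
  which `mims_eseem_analytic()` evaluates and the test suite uses as an
  independent oracle (`simulate_eseem_twolevel()` matches it to
  $10^{-6}$). `phase_cycle = FALSE` returns the raw single-run
  population.
* **Ideal pulses and readout.** Pulses are instantaneous rotations on
  the addressed transition; relaxation, finite pulse width, laser
  dynamics and photon shot noise are out of scope. The modelled
  observable is the bright-state population in $[0,1]$; experimental
  photon counts would be an affine function of it.

Expected peak positions come from `nuclear_transition_frequencies()`:
eigenvalue differences of the nuclear sub-Hamiltonian conditioned on
each electron manifold (same secular blocking), e.g. the bare Larmor
frequency in the $m_s = 0$ manifold and hyperfine-shifted lines in
$m_s = \mp 1$.

### The generic low-rank generator

`synth_lowrank()` builds sums of separable damped cosines plus seeded
white Gaussian noise: each term is an outer product, so the noise-free
rank equals the number of peaks. `fourpeak_signal()` freezes the
reference study conditions used by the recovery experiments: a
$256\times256$ grid with 50 ns dwell (spectral band $\pm 10$ MHz), four
equal-amplitude peaks at distinct on-grid frequency pairs between 1.6
and 8.1 MHz, decay constants of half the record length, and noise at 1%
of the single-peak amplitude — values chosen once as representative of
a well-resolved, mildly noisy 2D ESEEM data set. What this emulates is
the low-rank structure plus detector noise of a real measurement; what
it does not emulate is $t_1$-noise, baseline drift, phase errors or
shot-noise statistics, so passing recovery tests demonstrate the
algorithmic claim (low-rank recovery from random subsamples), not
robustness to every laboratory artifact.

## Masks, metrics and sweeps

Masks are uniform draws without replacement of
`round(fraction * cells)` entries (round-half-to-even, clamped to at
least one), using R's default Mersenne-Twister generator under a local
seed, so masks are portable and never perturb the caller's RNG state.
No structured (Poisson-gap) schedules are provided; the subsampling
studied here is plain uniform removal.

The evaluation metrics mirror the figures such studies report:

* `fourier_spectrum()` — magnitude 2D DFT, zero-frequency centred, with
  the matrix mean removed by default so the DC spike does not leak into
  noise windows (windowing and phasing are deliberately absent);
* `detect_peaks()` — 8-neighbourhood local maxima above a relative
  threshold in the non-negative-frequency quadrant, greedily separated
  by a minimum Chebyshev bin distance;
* `snr()` — maximum magnitude in a peak window over mean magnitude in a
  pure-noise window;
* `fidelity()` — the normalized Frobenius inner product
  $\langle M, X\rangle_F / (\|M\|_F\|X\|_F)$ between the fully sampled
  matrix and a reconstruction, computed in the time domain. This
  cosine-overlap normalization is the package's choice: it is 1 exactly
  at recovery up to positive scale, falls as data are removed, and
  averages cleanly over repeated masks;
* `singular_value_profile()` — the descending singular values, the
  diagnostic that shows how many components carry signal (four peaks
  plus a noise floor at the study conditions leave more than 70% of the
  values below 5% of $\sigma_1$).

`sweep_fraction()` and `sweep_threshold()` orchestrate the repeated
experiments (fresh mask per repetition, completion and zero-filled
baselines, tidy rows of SNR/fidelity/iteration counts). Per-cell seeds
are derived from the base seed with an exact integer hash
(`derive_seed()`), so any cell can be reproduced in isolation and a
sweep re-run is bitwise identical. The laboratory-scale repetition
counts are 10 per setting for SNR studies and up to 128 for fidelity
studies; the packaged tests and the acceptance study use 10 masks per
setting on grids from $64^2$ to $256^2$, sizes chosen to keep the full
suite comfortably interactive while staying in the regime where the
sampling-theory constants are meaningful.

## Numerical choices and degenerate inputs

* Repeated singular values need no special handling: the soft threshold
  shifts the whole degenerate block, and the reconstruction is
  invariant to the basis chosen inside it (tested against the proximal
  objective).
* A diverging iterate (non-finite residual, possible when `delta` is
  far too large) terminates the loop with `converged = FALSE` instead
  of erroring, so sweep rows record the failure.
* All-zero observations are rejected (`relative_residual` would be
  undefined); a zero candidate has fidelity 0 by convention.
* At $B = 0$ the $m_s = \pm1$ electron levels are degenerate; the
  manifold basis is stabilized by re-diagonalizing $S_z$ inside each
  degenerate cluster before labelling manifolds.
* Matrices are real throughout; complex time-domain data is a
  documented extension point (the modelled NV observable is a real
  population).

## Known limitations

* The simulator's accuracy is bounded by the secular approximation
  (level shifts of order $A^2/D$ are dropped) and by the ideal-pulse
  assumption; both are excellent for NV parameters but degrade for
  couplings approaching $D$ or for realistic pulse lengths.
* SVT is the simplest adequate solver; accelerated first-order methods
  and randomized SVDs would be faster on large grids but are
  deliberately not implemented.
* Recovery guarantees are asymptotic and probabilistic; at small grid
  sizes a few percent of mask draws near the information limit fail for
  any trace-norm method, as the solver's nuclear-norm certificate makes
  visible.
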