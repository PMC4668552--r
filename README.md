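# mrcomplete

Accelerated two-dimensional magnetic-resonance spectroscopy by low-rank
matrix completion, with a spin-Hamiltonian simulator of 2D ESEEM
experiments on the nitrogen-vacancy (NV) centre in diamond.

## The problem

A 2D time-domain magnetic-resonance signal $M(t_1, t_2)$, sampled on an
$n_1 \times n_2$ delay grid, costs one measurement per grid point —
prohibitive for single-spin detection, where every point means many
optical readout repetitions. But a spectrum with $r$ peaks makes $M$
(a sum of $r$ separable damped oscillations) a rank-$r$ matrix, and a
low-rank matrix can be recovered from a small random subset of its
entries by trace-norm minimization:

$$\min_X \|X\|_* \quad \text{subject to} \quad X_{ij} = M_{ij},\ (i,j) \in \Omega .$$

`mrcomplete` implements the singular value thresholding (SVT) solver
for this problem

$$X_k = \mathcal{D}_\tau(Y_{k-1}), \qquad
  Y_k = Y_{k-1} + \delta\, P_\Omega(M - X_k),$$

where $\mathcal{D}_\tau$ soft-thresholds singular values and $P_\Omega$
projects onto the observed entries, stopping when
$\|P_\Omega(X - M)\|_F / \|P_\Omega(M)\|_F \le \varepsilon_0$. Around
the solver it provides:

* a density-matrix simulator of the three-pulse (stimulated-echo)
  ESEEM sequence for the NV ground state — Hamiltonian
  $H = D S_z^2 + g\mu_B \mathbf{B}\cdot\mathbf{S} +
  \mathbf{S}\mathbf{A}_N\mathbf{I}_N\ (+\ \mathbf{S}\mathbf{A}_C\mathbf{I}_C,\ \text{nuclear Zeeman, quadrupole})$
  — with ideal pulses, stimulated-echo phase cycling, and a closed-form
  Mims-envelope oracle (`simulate_eseem()`, `mims_eseem_analytic()`);
* a generic low-rank 2D signal generator (`synth_lowrank()`,
  `fourpeak_signal()`);
* uniform random sampling masks (`mask_spec()`, `draw_mask()`,
  `apply_mask()`);
* evaluation metrics: centred 2D magnitude spectra, peak detection,
  spectral SNR, time-domain recovery fidelity, singular-value profiles;
* seeded sweep experiments over sampling fraction and threshold
  (`sweep_fraction()`, `sweep_threshold()`), and a command-line
  interface (`run_cli()`, `inst/cli/mrcomplete`).

It is aimed at magnetic-resonance spectroscopists and signal-processing
researchers who want to prototype non-uniform-sampling reconstruction
for 2D NMR/ESR-type data, or to benchmark completion against
zero-filled subsampling on controlled synthetic signals.

## Worked example

Reconstruct a four-peak 2D signal from 20% of its entries:

```r
library(mrcomplete)

fp <- fourpeak_signal(128, 128, noise_sigma = 0.01, seed = 1)
omega <- draw_mask(mask_spec(128, 128, fraction = 0.2, seed = 42))
obs <- apply_mask(fp$signal$values, omega)
obs
#> observed_matrix: 128 x 128, |omega| = 3277 (20.0% sampled)

fit <- svt_complete(obs, svt_config(max_iter = 500))
fit
#> completion_result: 128 x 128, 500 iterations, residual 0.373 (iteration cap reached), rank 4

spec <- fourier_spectrum(td_signal(fit$completed, fp$signal$dt1, fp$signal$dt2))
detect_peaks(spec, rel_threshold = 0.2)
#>     f1_hz   f2_hz amplitude
#> 1 6875000 8125000  626.4569
#> 2 4375000 5625000  621.3539
#> 3 1875000 3125000  593.0865
#> 4 8125000 2500000  593.0421

fidelity(fp$signal$values, fit$completed)
#> [1] 0.9460893
fidelity(fp$signal$values, zero_fill(obs))
#> [1] 0.4496175
```

The four detected peaks sit exactly at the planted frequency pairs
(compare `fp$peaks`), the completed matrix has the true rank 4, and its
time-domain fidelity against the fully sampled signal is 0.95 versus
0.45 for the zero-filled baseline. The terminal residual 0.37 reflects
the 1% measurement noise the low-rank model deliberately does not fit:
on noisy data the iteration runs to its cap while the noise stays in
the discarded singular values.

The same pipeline is available from a shell:

```sh
Rscript inst/cli/mrcomplete simulate --preset lowrank --n1 128 --n2 128 --out sig.csv
Rscript inst/cli/mrcomplete mask --shape 128x128 --fraction 0.2 --seed 42 --out mask.tsv
Rscript inst/cli/mrcomplete complete --signal sig.csv --mask mask.tsv --out completed.csv
Rscript inst/cli/mrcomplete spectrum --signal completed.csv --peaks peaks.csv
```

ESEEM simulation presets (`--preset c13`, `--preset n14_misaligned`)
generate NV spectra instead of the generic low-rank signal; see
`?nv_preset` and the methods vignette
(`vignettes/matrix-completion-eseem.Rmd`) for the physics and all
modelling choices.

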