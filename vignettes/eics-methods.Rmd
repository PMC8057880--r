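---
title: "Interslice k-space interpolation for compressed-sensing MRI: models and methods"
author: "eicsmri"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interslice k-space interpolation for compressed-sensing MRI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eicsmri)
```

## The problem and the idea

A multislice MRI exam acquires hundreds of thin, contiguous 2D slices, and
acquisition time is proportional to the number of k-space samples per slice.
Compressed sensing (CS) shortens scans by sampling each slice far below
Nyquist and reconstructing with a sparsity prior, but at very aggressive
ratios (a few percent of the Nyquist budget) plain CS breaks down: too few
measurements remain for the prior to resolve.

Neighboring slices of such a volume are, however, strongly correlated —
anatomy changes slowly across a sub-millimetre slice pitch. Interpolated CS
exploits this: if neighboring slices are undersampled at *complementary*
k-space locations, each slice can import the k-space samples its neighbors
acquired at locations it skipped, and reconstruct from the pooled set. This
package implements the three-slice variant of that idea on radial
trajectories (called EiCS here), with the two-slice variant (FiCS) and plain
CS as baselines, together with the full evaluation harness.

The stages, each an exported function:

1. **Radial mask triples** (`make_mask_triple`): three radial masks with the
   same spoke count but pairwise disjoint spoke angles, cycled along the
   stack with period 3.
2. **Undersampling** (`undersample_stack`): each slice is sampled at its
   mask's k-space locations through a forward NUFFT.
3. **Interpolation** (`interpolate_stack`): for a target slice $T$ with
   neighbors $L$ and $R$, the interpolated sample set is
   $T_{\mathrm{int}} = (L \ominus T) \oplus T \oplus (R \ominus T)$, where
   $\ominus$/$\oplus$ are set difference/union over quantized sample
   locations. Values are copied verbatim, never averaged; every acquired
   target sample survives unchanged.
4. **Reconstruction** (`ncg_reconstruct`): nonlinear conjugate gradient on
   $\|F_u x - y\|_2^2 + \lambda_1\|\Psi x\|_1 + \lambda_2\,\mathrm{TV}(x)$
   with $F_u$ the undersampling NUFFT and $\Psi$ an orthogonal wavelet.
5. **Evaluation** (`evaluate_stack`): SSIM, FSIM, MSE, PSNR, correlation
   (full-reference) and sharpness index, PIQE (no-reference).

Because three disjoint masks are pooled, an interior interpolated slice
holds almost three times the acquired budget (exactly
$3nN - 2(n-1) - 2$ unique locations for $n$ spokes of $N$ samples, since all
full-diameter spokes share the DC point), with almost exactly one third of
the samples coming from the target slice itself:

```{r provenance}
N <- 128
img <- generate_phantom(phantom_spec(n_slices = 3, matrix_size = N,
                                     drift = 0, noise_sigma = 0))$data[[1]]
triple <- make_mask_triple(spokes_for_ratio(0.03, N), "golden", N)
ops <- lapply(triple, nufft_operator)
ks <- lapply(1:3, function(i) nufft_forward(ops[[i]], img + 0i, source_mask = i))
ti <- eics_interpolate(ks[[1]], ks[[2]], ks[[3]])
round(100 * table(ti$provenance) / length(ti), 2)
```

## Trajectories and sampling budgets

Spokes are full k-space diameters: $N$ samples at radii
$(-N/2, \dots, N/2 - 1)/N$ cycles/pixel, so the exact DC point lies on every
spoke. Angles live on $[0^\circ, 180^\circ)$ because diametric spokes are
equivalent. Azimuthal Nyquist for an $N \times N$ image needs about
$\lceil \pi N / 2 \rfloor$ uniform spokes (402 at $N = 256$), and a sampling
ratio $\rho$ translates to $\mathrm{round}(\rho \cdot \pi N / 2)$ spokes —
12, 20, 28, 36 spokes at 3, 5, 7, 9 % for $N = 256$. Golden-angle
acquisition increments the spoke angle by $180^\circ/\varphi \approx
111.246^\circ$ ($\varphi$ the golden ratio); the sequence never repeats an
angle and any prefix covers the half-circle near-uniformly, which is why it
is the scheme of choice when the spoke budget is decided after the fact.

Mask triples deal one generated sequence round-robin to the three masks.
For the uniform scheme this interleaves three uniform masks offset by
$60^\circ/n$; for the golden scheme round-robin preserves each mask's
temporal incoherence. The generation offset (`offset_or_start`) defaults to
a deterministic 0; nothing in the method depends on it, and the CLI exposes
a seeded random offset for users who want unaligned replicates.

**Density compensation.** Radial sampling concentrates samples near the
k-space center; gridding reconstruction weights each sample by its polar
cell area, which grows linearly in $|k|$ (a Ram-Lak ramp). The package
normalizes the ramp as $w_j = N\pi |k_j| / n_{\mathrm{spokes}}$ — $N^2$
times the polar cell area — so the density-compensated adjoint approximates
the continuous inverse Fourier integral under the operators' unitary $1/N$
scaling. The DC sample's cell is a disc rather than an annulus; it receives
a quarter of the first nonzero-radius weight, which makes the *total* DC
weight across a mask's spokes equal the ideal disc area. Verified property:
regridding a delta image at the Nyquist budget reproduces a spectrum flat to
within a few percent (relative $\ell_2$) inside the covered disc
$|k| \le 0.4$. The spectrum cannot be flat over the full square — radial
spokes never sample the corners — and the point-spread function of disc
coverage is an Airy pattern whose first sidelobe is ~13 % of the peak; both
are properties of the geometry, not of the implementation, and the tests
assert against those physical bounds.

## The gridding NUFFT

No NUFFT backend is assumed: the package ships a Kaiser-Bessel gridding
implementation. The forward (type-2) operator evaluates the centered,
unitarily scaled DFT of an $N \times N$ image at arbitrary sample locations
by apodization correction in image space, zero-padding to a $2\times$
oversampled grid, an FFT, and sparse interpolation with a width-4
Kaiser-Bessel kernel (shape parameter from the standard minimal-aliasing
choice). The interpolation table is a precomputed sparse matrix, so forward
and adjoint are two FFTs plus a sparse product per application. Design
points:

* The adjoint is the *exact* matrix adjoint of the forward (same table, same
  shifts, conjugate FFT), so the inner-product identity holds to machine
  precision — important because the solver's gradient assumes matched
  operators.
* Forward accuracy against a direct nonuniform-DFT oracle is ~$6 \times
  10^{-4}$ relative $\ell_2$ at $N \le 64$ with the default oversampling 2 /
  width 4, comfortably inside the $10^{-3}$ contract the tests enforce.
* DCF weights are stored on the operator but applied only in
  density-compensated adjoints (the gridding reconstruction and the
  solver's starting point), never in the forward model: the data term
  compares plain forward samples with the measurements.
* Operators are deterministic; identical inputs give bit-identical outputs.

## Sample identity and the set algebra

The interpolation is set algebra over *sample locations*, so location
equality must be exact and global. Keys are k-space coordinates quantized to
$10^{-6}$ cycles/pixel, applied identically everywhere. With full-diameter
spokes the only location shared between distinct spokes is DC; a mask's own
$n$ duplicate DC samples collapse at container creation (their values are
equal — they sample the same slice at the same location). Unexpected key
collisions in a union resolve in favor of the later-listed part with a
warning; `eics_interpolate` orders its union so that the target slice wins
over either donor and the left donor over the right, though with disjoint
masks no collision can actually occur.

Stack boundaries have one neighbor instead of two. The package degrades the
first and last slice to the two-slice rule with the available neighbor
(recorded in the `boundary_slices` attribute and visible in the provenance
table); interior slices are unaffected.

The interslice-gap experiment decimates the stack *first* (keeping every
$(g+1)$-th slice) and then treats the decimated stack as contiguous, so a
per-slice ratio of 3 % becomes a stack-level average of 1.5 % at gap 1 and
1 % at gap 2 — at the price of weaker neighbor correlation, which is exactly
the stress the experiment is designed to apply.

## Reconstruction

The solver minimizes
$f(x) = \|F_u x - y\|_2^2 + \lambda_1 \|\Psi x\|_1 + \lambda_2 \mathrm{TV}(x)$
over complex images by Fletcher-Reeves nonlinear conjugate gradient with a
backtracking (Armijo) line search. Numerical choices:

* **Smoothing.** Both nonsmooth terms use $\sqrt{|\cdot|^2 + \mu}$ with
  $\mu = 10^{-15}$ inside gradients; reported objective values use the
  unsmoothed terms. The analytic gradient matches central finite differences
  to $< 10^{-4}$ relative error (tested on random complex $16 \times 16$
  inputs).
* **Wavelet.** Periodized orthogonal Daubechies-4 (4-tap), 4 levels,
  implemented via orthonormal circulant analysis matrices; periodization
  keeps the transform exactly orthonormal at every even size (Parseval to
  $10^{-12}$), so $\Psi^{-1} = \Psi^\top$ and the image side must be a
  multiple of $2^{\mathrm{levels}}$.
* **TV.** Isotropic, forward differences, replicate boundary (last
  row/column difference zero); the adjoint is the matching negative
  divergence.
* **Regularization weights.** MRI magnitudes here are normalized to
  $[0, 1]$, so $\lambda_1 = \lambda_2 = 0.002 \times
  \max|\mathrm{gridding}(y)|$ by default — a data-scaled weight in the range
  customary for wavelet-TV CS on unit-normalized images. Both are plain
  `recon_params` fields.
* **Line search and caching.** The initial step comes from the data-term
  quadratic fit $t_0 = -\langle g, d\rangle / (2\|F_u d\|^2)$, then Armijo
  backtracking ($\alpha = 0.01$, $\beta = 0.6$). All transforms of the
  iterate and direction are cached, so evaluating the objective along the
  line costs no FFTs and one NCG iteration costs one forward, one adjoint
  and three wavelet applications. Fletcher-Reeves restarts every 50
  iterations or on a non-descent direction; the default budget is 60
  iterations (30 in the scaled-down comparison experiments). The recorded
  objective trace is nonincreasing over accepted steps, and a non-finite
  objective raises a solver error carrying the trace.
* **Starting point** is the density-compensated adjoint (the gridding
  reconstruction) unless `x0` is supplied.

A caveat the tests encode explicitly: full-diameter radial spokes cover only
the inscribed disc $|k| \le 0.5$, never the corners of discrete k-space. A
sharp piecewise-constant image at $N = 32$ keeps ~8 % of its energy in those
corners, which *no* method sampling on radial spokes can recover — so the
Nyquist-budget least-squares recovery check uses a disc-bandlimited target
(for which the solver reaches ~2 % relative error in 60 iterations) rather
than pretending the geometry's null space is a solver defect.

## Metrics

Full-reference metrics consume magnitudes normalized by the ground-truth
maximum over the stack; no-reference metrics normalize each image by its own
maximum. Orientation: SSIM, FSIM, PSNR, CORR, SI are higher-better; MSE and
PIQE are lower-better.

* **SSIM**: sliding Gaussian window (11 taps, $\sigma = 1.5$, valid
  support), $k_1 = 0.01$, $k_2 = 0.03$, dynamic range 1. A `global = TRUE`
  mode evaluates the single-window statistic literally, which is what the
  hand-verified unit tests use.
* **FSIM**: phase congruency from a log-Gabor bank (4 scales, 4
  orientations, minimum wavelength 6, multiplier 2, $\sigma_{\mathrm{onf}} =
  0.55$) as orientation-summed local energy over summed amplitude, combined
  with Scharr gradient magnitude; similarity constants $T_1 = 0.85$, $T_2 =
  160$ on a 0-255 scale, pixel weights $\max(\mathrm{PC}_1,
  \mathrm{PC}_2)$. The noise-compensation stage of the original phase
  congruency estimator is omitted — for relative comparisons between
  reconstructions of the same scene it rescales both maps similarly — which
  is a known simplification of this implementation.
* **Sharpness index**: how exceptional the image's total variation is among
  random-phase surrogates (Fourier modulus kept, phases randomized through a
  Hermitian all-pass). With $\mu_{TV}, \sigma_{TV}$ the Monte-Carlo mean and
  standard deviation over `n_resamples` seeded surrogates, the index is
  $-\log_{10}\bar\Phi\!\left((\mu_{TV} - TV(x))/\sigma_{TV}\right)$,
  computed in log space so very sharp images do not underflow. A surrogate
  itself scores $\approx -\log_{10} 0.5 \approx 0.30$ in median. The
  compact tail-free form $-\log_{10} z$ is available under `literal = TRUE`;
  note it is *not* monotone in sharpness once $z > 1$, which is why the
  tail form is the default.
* **PIQE**: block-based no-reference score. MSCN coefficients (7x7
  Gaussian, 0-255 scale), 16x16 blocks, spatial activity at MSCN variance
  > 0.1; an active block counts as distorted (score 100) when a 6-pixel
  boundary segment has standard deviation < 0.1 (blockiness) or its MSCN
  variance exceeds 0.35 (noise). The final score
  $(\sum D_{sk} + C_1)/(N_{SA} + C_1)$ with $C_1 = 1$ makes a flat image
  score exactly 1 (the empty-sum case) and bounds the range at 100. The
  block-level constants follow the published block-distortion estimator;
  cartoon-like phantoms score high on PIQE by construction (their uniform
  regions look "blocky"), so only relative comparisons are meaningful on
  synthetic data.

## The phantom: what it emulates, what it does not

`generate_phantom` produces the study conditions for every experiment: an
ellipse superposition (one background ellipse plus `n_ellipses = 8` interior
ellipses with randomized geometry and signed intensities) whose centers,
axes and orientations perform a Gaussian random walk across slices with
per-step standard deviation `drift` $\times N$ (default 0.004), plus
additive Gaussian pixel noise (`noise_sigma = 0.01`), clipped to $[0, 1]$.
Defaults are 24 slices of $128^2$ — a desk-scale stand-in for a
$320 \times 320 \times 256$ clinical knee volume.

The random *walk* (rather than independent jitter) matters: it makes
interslice correlation decay with slice distance (`correlation_profile`),
which is the property the gap experiment stresses — decimating by gap $g$
is equivalent to sampling the correlation profile at lag $g + 1$. The drift
default keeps adjacent-slice correlation near 0.99, consistent with the
"very strong interslice correlation" regime the method assumes.

What the phantom does **not** model: MR contrast mechanisms, coil
sensitivities and multichannel combination, k-space noise correlation,
motion, and anatomical texture. Passing tests on the phantom therefore
demonstrate the *mechanism* — complementary-mask pooling helps
reconstruction when neighbors are correlated — not clinical image quality;
absolute metric values on the phantom are not comparable to values on real
knee data.

## Experiments and problem sizes

`run_pipeline` executes the grid (method x ratio x gap), evaluates against
the retained ground-truth slices, and emits a metrics CSV, per-cell
provenance tables and a JSON manifest; everything is deterministic given the
config seed. `ordering_experiment` distills the method comparison into
orientation-corrected verdicts: with more interpolated samples, quality
should not degrade, so the slice-averaged metrics should order
EiCS $\ge$ FiCS $\ge$ CS (reversed for MSE/PIQE).

The shipped comparison runs at the clinical operating point scaled to
desk size: the default phantom (24 slices, $128^2$), golden-angle masks at a
3 % ratio (6 spokes per mask at $N = 128$), 30 NCG iterations, and the four
fast full-reference metrics (SSIM, MSE, PSNR, CORR). One seed takes about a
minute on one CPU; the acceptance workflow repeats it over five seeds and
requires each metric's ordering to hold in at least four of five — the
orderings are robust but individual seeds can produce near-ties at such
aggressive undersampling. FSIM/SI/PIQE are computed by the same harness but
are excluded from the default comparison metric set purely for runtime; the
pipeline accepts any metric subset.

## Known limitations

* Single-channel magnitude data only; no parallel imaging or coil maps.
* 2D slices; no 3D trajectories or through-plane regularization.
* The FSIM phase-congruency estimator omits noise compensation (above).
* The interpolation copies values verbatim; no weighting of donor samples
  by slice distance — faithful to the method, but a known source of residual
  inconsistency at large gaps or fast anatomy drift.
* Iteration counts, $\lambda$ values and the wavelet family are
  package-level defaults (the method's description leaves them open); all
  are exposed in `recon_params` and the CLI.
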