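---
title: "Sparse coding of V1 receptive fields: model, operators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse coding of V1 receptive fields: model, operators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(v1sparse)
```

## The generative model and its assumptions

`v1sparse` implements the linear sparse-coding account of simple cells in
primary visual cortex: an image patch $I \in \mathbb{R}^M$ is a noisy
linear combination of $N$ dictionary columns,
$I = \Phi r + \nu$, with $\nu \sim \mathcal{N}(0, \sigma^2 \mathrm{Id})$.
The columns $\phi_i$ play the role of receptive fields (RFs), the
coefficients $r_i$ of neural activations. With an overcomplete dictionary
($N > M$) the inverse problem is ill-posed, and a sparsity penalty selects
among solutions:

$$E(r, \Phi) = \tfrac12 \lVert I - \Phi r\rVert_2^2
  + \lambda \sum_{i=1}^{N} c(r_i).$$

The package fits this by alternating minimization: a **coding step**
(proximal gradient on $r$ with $\Phi$ fixed) and a **learning step** (one
batch gradient step on $\Phi$ with unit-norm column renormalization).
The model assumes zero-mean, stationary, approximately whitened inputs;
the preprocessing pipeline is responsible for making that true.

## The four penalties and their thresholding operators

Each coding iteration is a gradient step followed by the component-wise
proximal map $T(z) = \arg\min_y \lambda c(y) + (y - z)^2 / (2\mu)$, with
$\mu \in (0, 1/L]$ and $L$ the squared spectral norm of $\Phi$
(`lipschitz_bound()`). Writing $\theta = \lambda\mu$:

* **soft** ($c = |\cdot|$): shrink by $\theta$, zero on
  $[-\theta, \theta]$. The classic ISTA operator.
* **half** ($c = |\cdot|^{1/2}$): closed trigonometric form. A widely
  reproduced form of this operator writes the threshold constant as
  $(54^{1/3}/4)\,\kappa^{2/3}$ in a parameter $\kappa$ that, in our
  normalization of the prox objective, equals $2\theta$. We therefore
  implement the zero region as $|z| \le \tfrac32 \theta^{2/3}$ and the
  arccos argument as $(\theta/4)(|z|/3)^{-3/2}$. This choice is not taken
  on faith: the operator is required (in the test suite) to match a
  brute-force grid minimizer of the prox objective on thousands of random
  instances, which disambiguates the constant.
* **hard** ($c = 1\{\cdot \ne 0\}$): zero iff $|z| \le \theta$, identity
  otherwise. This is the operator as used in iterative hard thresholding
  with threshold $\theta = \lambda\mu$; note that the *exact* proximal map
  of $\lambda\lVert\cdot\rVert_0$ thresholds at $\sqrt{2\lambda\mu}$
  instead. Equivalently, the implemented operator is the exact
  $\ell_0$-prox for the effective weight
  $\lambda_{\mathrm{eff}} = \theta^2/(2\mu)$. Consequence: the objective
  the hard iteration provably descends uses $\lambda_{\mathrm{eff}}$, and
  that is what `sparse_code()` records in its `energy_trace`; the exported
  `energy()` reports the nominal $\lambda$-weighted energy. For the other
  three penalties the two coincide.
* **cel0**: the continuous exact relaxation of the counting penalty,
  $c(r_i) = \lambda - \tfrac{\lVert\phi_i\rVert^2}{2}
  \big((\sqrt{2\lambda}/\lVert\phi_i\rVert - |r_i|)_+\big)^2$, which is 0
  at the origin and saturates at the $\ell_0$ cost $\lambda$. Its weight
  lives *inside* the penalty, so the outer weight in the energy is 1.
  The proximal map, derived analytically and verified against the grid
  oracle, is (with $a = \mu\lVert\phi_i\rVert^2$): for $a < 1$,
  $\operatorname{sign}(z)\min\{|z|,
  (|z| - \sqrt{2\lambda}\,\mu\lVert\phi_i\rVert)_+/(1 - a)\}$ — zero
  below the knee $\sqrt{2\lambda}\,\mu\lVert\phi_i\rVert$, linear
  shrinkage, then identity above $\sqrt{2\lambda}/\lVert\phi_i\rVert$;
  for $a \ge 1$, a hard threshold at $\sqrt{2\lambda\mu}$.

Set-valued points (the hard boundary, the CEL0 tie) resolve to 0: the
sparser choice, and deterministic. All operators are odd and
non-expansive toward zero, and each has an exactly-zero region, so active
units can be counted without an epsilon (`active_tol = 0`).

`prox_oracle()` is the package's own referee: a dense-grid minimizer of
the scalar prox objective with local refinement, used only for testing.
For the hard penalty the oracle is called with the effective weight
above, consistent with the implemented convention.

## Preprocessing

`preprocess_image()` applies, in order: min-max rescale to $[0,1]$;
standardization (error on constant images); frequency-domain whitening
with the radial filter $W(f) = f\,e^{-(f/f_0)^4}$ and zero DC; and a
multiplicative rescale to pixel variance 0.1 exactly. Because whitening
zeroes the DC, the mean is $\approx 0$ and the variance equals the mean
squared pixel value, so the baseline reconstruction error of the all-zero
code (`mse_to_zero()`) is exactly the target variance, 0.1.

The filter form is the standard retinal-ganglion-style whitening ramp
with a quartic roll-off; the published lineage this package follows does
not print its filter, so the form and the default cutoff
$f_0 = 200$ cycles/image (appropriate for $\sim 10^3$-pixel-wide images)
are documented package choices, exposed as arguments. For the small
desk-scale images used in examples and tests we scale the cutoff
proportionally (e.g. 25 cycles/image at $128^2$); the final variance
constraint, and hence the 0.1 baseline, holds for any cutoff.

Patches are extracted at uniformly random positions with 0-based,
row-major, top-left-origin coordinates throughout.

## Synthetic data: what it emulates, and what not

Two generators make every stage testable without any image download:

* `generate_pink_noise_images()` shapes white Gaussian noise in the
  frequency domain with amplitude $1/f^{\gamma}$ (zero DC) and maps the
  result to $[0,1]$. With the default $\gamma = 1$ this reproduces the
  second-order (power-spectral) statistics of natural scenes — exactly
  the property the whitening stage is designed to undo. It does **not**
  reproduce higher-order natural-image structure (edges, occlusions,
  sparse wavelet marginals). Two practical consequences, visible in the
  examples: dictionaries trained on pink noise reconstruct well and
  reproduce the *relative* sparsity ordering of the four penalties, but
  their RFs are broadly tuned (circular variance mostly > 0.5) and
  rarely pass the Gabor $r^2 \ge 0.6$ filter. Passing tests on pink
  noise therefore validate the machinery and the method-level orderings,
  not the headline RF-shape statistics of natural-image training. The
  generator accepts exponents in $[0, 2]$; 0 (white noise) is allowed
  specifically as a degenerate test case.
* `sample_planted_patches()` draws from a ground-truth model
  $I = \Phi^* r + \nu$ with exactly $k$ active coefficients per patch at
  uniform positions. Amplitudes are Laplace(0, scale): heavy-tailed and
  symmetric about zero, matching the empirical activity distributions of
  trained sparse-coding models; the scale is configurable. Recovery is
  scored by `dictionary_match()`, a greedy one-to-one assignment on
  absolute inner products (sign and permutation invariant).

Both generators are bit-reproducible given their seed, and restore the
caller's RNG state.

## Training defaults and numerical choices

* **Step size** $\mu$: `NULL` (default) uses $1/L$ recomputed from the
  current dictionary each batch, which keeps the descent guarantee as
  $\Phi$ changes. A fixed $\mu$ can be supplied; the published settings
  this package mirrors use a fixed $\mu = 0.05$ for CEL0, and that value
  is markedly more reliable for CEL0 dictionary recovery than $1/L$ (the
  gentler shrinkage avoids the early hard-thresholding local minima).
* **Coding budget**: a fixed 200 iterations, no early stopping. The
  source lineage states no iteration count; a fixed budget makes batch
  training deterministic and auditable via the exposed energy trace,
  which is asserted non-increasing in the tests.
* **Learning rate**: $\eta = 10^{-2}$ constant by default;
  $\eta = 5\times10^{-3}$ with a time-based decay
  $\eta_t = \eta_0/(1 + (\eta_0/50)t)$ for CEL0, mirroring the published
  schedules. Batch size defaults to 250.
* **Dictionary initialization**: unit-norm Gaussian columns, seeded (the
  initialization distribution is unstated in the lineage; this is the
  obvious neutral choice).
* **Batch aggregation**: the per-patch learning update is applied as the
  batch mean of residual–code outer products — the standard batch
  gradient reading of a per-sample rule.
* **Degenerate units**: a column whose norm collapses is re-randomized at
  the update; additionally, a unit never active over a 50-batch audit
  window is re-randomized (with a message), so $N$ keeps meaning "units
  participating in the code". Both draws consume the seeded training RNG
  stream, so determinism is preserved.
* **Divergence**: non-finite energies or codes abort with an error that
  names the $\mu \le 1/L$ contract rather than returning garbage.

## Receptive-field analysis conventions

* **Grating bank**: 36 equidistant orientations over $[0, \pi)$, 8
  equidistant phases, and 16 log-spaced spatial frequencies from 0.5 to
  $P/4$ cycles/patch (frequency and phase resolution are package
  choices; the orientation count is the standard 36). Gratings are
  unit-normalized so inner products are comparable across frequencies.
* **Tuning curve**: stage 1 picks the optimal spatial frequency by the
  single best-matching grating; stage 2 takes, per orientation, the max
  inner product over phases at that frequency. With 8 phases spanning
  $[0, 2\pi)$ the responses are nonnegative in practice (a $\pi$ phase
  flip negates an inner product).
* **Orientation convention**: $\theta$ is the angle of the grating's
  carrier (normal) direction, counterclockwise from horizontal, with y
  upward and patches flattened row-major; "vertical preference" reads as
  $\theta = \pi/2$.
* **Circular variance**: $V = 1 - |R|$ with the doubled-angle resultant
  $R = \sum_k \alpha_k e^{i2\theta_k} / \sum_k \alpha_k$; the preferred
  orientation is $\arg(R)/2 \bmod \pi$. An all-zero curve is an error
  (undefined ratio), not a silent NaN. Note that under a square aperture
  the resultant of a bare grating is slightly biased away from oblique
  orientations; the equivariance test therefore uses isotropic-envelope
  units.
* **Gabor fits**: 8 parameters (center, orientation, period, phase, two
  envelope sds, amplitude), least squares via Levenberg–Marquardt with
  multi-start over an orientation grid plus data-driven center/period
  starts. Parameters are canonicalized (amplitude > 0, orientation in
  $[0,\pi)$ with the phase negated when reducing by $\pi$, phase in
  $[0,2\pi)$, sds positive) so recovery tests are well-posed.
  $\sigma_\parallel$ is the envelope sd along the stripe axis,
  $\sigma_\perp$ across it; `shape_table()` reports both normalized by
  the period, plus their ratio. The $r^2 \ge 0.6$ goodness filter is
  applied to model units as well (the lineage applied it to biological
  subunits), for comparability.

## Experiment drivers and calibration

The figure-level comparisons all reduce to "hold one quantity fixed,
compare the other". `calibrate_lambda()` bisects on $\log\lambda$
against the monotone response of either the mean active count
(decreasing in $\lambda$) or the mean MSE (increasing), with an explicit
bracketing check. `run_overcompleteness_sweep()` retunes $\lambda$ per
(method, $N$) until the normalized active proportion lands in a window
(default the published 0.0105–0.0132 band), then reports
trailing-segment MSE. `run_matched_instances()` equalizes mean active
counts between two methods (5% tolerance) and compares MSEs and RF shape
tables. Every emitted table carries its full configuration and seed as
an attribute, and identical configurations reproduce identical tables.

## Problem sizes

The package's examples and test suite run at desk scale, chosen so the
full suite completes in a few minutes while each claim remains
informative: pink-noise images of $96^2$–$128^2$ pixels, patches of
$8\times8$–$10\times10$, dictionaries of 24–128 units trained for tens
to hundreds of 100–250-patch batches; the planted-recovery benchmark
uses $M = 64$, $N = 32$, $k = 3$, $\sigma = 0.01$ with 500 (soft) and
800 (CEL0) batches; the matched-MSE comparison codes 400 patches against
a 128-unit dictionary at a target MSE of 0.04 against the 0.1 baseline.
Full-scale runs (500–5000 units, 16×16 patches, 4000×250 patches) use
the same code paths with larger arguments.

## Known limitations

* Pink noise is a second-order stand-in for natural images; RF-shape and
  orientation-anisotropy results at full fidelity require a natural
  image corpus (e.g. 16-bit raw images via `read_iml()`).
* The hard operator follows the $\theta = \lambda\mu$ convention as
  printed in its lineage; whether those experiments effectively used
  $\sqrt{2\lambda\mu}$ cannot be determined from the text. The two differ
  only in how $\lambda$ is interpreted, and the effective-weight
  relationship above makes the mapping explicit.
* Accelerated solvers (FISTA), LCA-style circuit dynamics, and
  alternative dictionary normalizations are out of scope.
* Serialization is plain text (CSV for dictionaries, traces and analysis
  tables; PNG for images).
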