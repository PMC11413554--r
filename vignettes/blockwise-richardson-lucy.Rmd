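---
title: "Block-wise Richardson-Lucy deconvolution: model, numerics and design"
author: "RLDeconv authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Block-wise Richardson-Lucy deconvolution: model, numerics and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RLDeconv)
```

## The imaging model and the RL update

A fluorescence z-stack is modelled as the true object convolved with the
instrument's point spread function plus shot noise,

$$ MI = OI \ast PSF + N, \qquad N \sim \mathrm{Poisson}. $$

Richardson-Lucy deconvolution is the multiplicative
expectation-maximization scheme for this Poisson likelihood,

$$ EI_{n+1} = EI_n \times \Big[ FSP \ast \frac{MI}{PSF \ast EI_n} \Big], $$

with $FSP$ the PSF reversed along every axis. `rlIteration()` implements
one update; `rlDeconvolve()` drives it for a configured number of
iterations, starting from $EI_0 = MI$. That initialization is the
conventional choice — it keeps the iterates on the intensity scale of the
data and makes zero iterations an exact identity — and the package keeps
it fixed rather than exposing yet another knob. There is no reliable
stopping rule for RL iteration counts in general, so `iterations` is an
explicit parameter (default 10) rather than something the package
guesses.

Two structural properties of the update are worth stating because the
test suite leans on them:

* **Fixed point.** If $MI = PSF \ast E$ exactly, the bracketed ratio is
  identically one and $E$ is unchanged.
* **Flux conservation.** With a unit-sum PSF and circular convolution,
  the total intensity of the estimate equals that of $MI$ after every
  iteration — an algebraic identity obtained by swapping the summation
  order in the correction term. (See "Numerical choices" for a caveat on
  even-sized PSFs.)

## Convolution: boundary and centering conventions

All convolutions are *circular* (periodic boundary), the native boundary
of FFT convolution: the volume's opposite edge supplies the data that a
kernel overhanging one edge needs. No zero or reflective padding is
performed anywhere — padding with values that do not share the data's
noise statistics injects artifacts that RL then amplifies over
iterations, while circular wrap at least reuses real data.

The kernel is centred at its geometric centre index
$\lfloor \text{size}/2 \rfloor$ per axis (0-based), for odd and even
sizes alike, and `flipPSF()` is full index reversal. One convention is
shared by the FFT path (`circularConvolve()`), the direct-summation
reference path (`directCircularConvolve()`), and the analytic oracles,
so the two implementations can be compared at $10^{-5}$ relative
tolerance on random instances.

`inverseFilter()` is deliberately included as the flawed baseline:
direct spectral division with the PSF spectrum clamped (in magnitude, at
$10^{-6}$ of its maximum, phase preserved) so the division cannot
overflow. The clamp prevents infinities, not noise amplification; the
test suite demonstrates that on Poisson-noisy data its error exceeds
RL's by orders of magnitude.

## Block-iterative processing

`blockRLDeconvolve()` bounds memory by partitioning the volume into
*core* regions that tile it exactly, extracting each core padded by
`round(paddingFract * psf_size)` voxels per face (clipped at the volume
bounds), running the full RL iteration count on every padded block
independently, and hard-cropping each result back to its core before
merging. No feathering or weighted blending is applied: the padding
exists precisely so that the retained core is the most valid part of
each block's result. At the volume faces no padding is applied, so those
edges behave as in the unsplit volume.

Block counts are chosen deterministically from the voxel budget
(`maxBlockVoxels`): starting from one block, the count is incremented on
the axis whose worst-case padded extent is largest (ties broken in z, y,
x order), skipping axes whose further splitting would make a padded
block smaller than the PSF, until every padded block fits the budget.
This greedy rule is reproducible, makes the block count monotone
non-increasing in the budget, and fails loudly when the budget cannot
hold even one padded PSF-sized block. Remainder voxels on an axis that
does not divide evenly go to the earliest blocks, so core widths differ
by at most one voxel.

Two facts govern what block processing can and cannot promise:

* A budget admitting a single block reproduces the non-block result
  bit-for-bit (the degenerate split is the identity).
* A genuine split changes the data each block's circular wrap reuses, so
  block and non-block outputs differ near *core boundaries* — both the
  seams between cores and the volume faces, where the non-block path
  wraps the whole volume while a face block wraps onto its own opposite
  edge. In the benchmark used by the tests (64³ bead phantom, 9³
  Gaussian PSF, 10 iterations, 2×2×2 split) the two outputs agree to
  well under 2 % of the peak intensity at every voxel farther than one
  PSF width from any core boundary, while face voxels next to a bright
  bead can differ by tens of percent — which is why comparisons mask one
  PSF width around all core boundaries.

## The valid-region calculus

A "valid"-mode convolution with a $w_{PSF}$-wide kernel shrinks the
region whose values depend only on real data by $w_{PSF}-1$ samples
per side in total; each RL iteration performs two convolutions, so the
valid width of a $w_{data}$-sample block after $n$ iterations is

$$ w_{valid} = w_{data} - n\,(2 w_{PSF} - 2). $$

`validWidth()` implements this rule; the test suite checks it against a
mechanical NaN-propagation oracle (convolve a NaN-bordered signal
repeatedly and count survivors) over all $w \le 64$, $w_{PSF} \le 9$,
$n \le 5$. The rule's message is sobering: at 512 samples, a 32-wide
PSF and 10 iterations the valid width is $-108$ — formally nothing
survives. Practical deconvolution works anyway because realistic PSFs
decay to near zero at their edges, so the dependence on out-of-block
data fades with distance; the padding fraction exists to push the
residual edge effects into the discarded crop.

## The Gaussian variance recursion

For 1-D Gaussian data the RL update maps Gaussians to Gaussians, which
provides a rare exact oracle. Take the measured image equal to the PSF
(a point-like object), both centred Gaussians of variance $r^2$, and an
estimate of variance $b^2$. One update consists of: a ratio of two
Gaussians (variance $r^2(r^2+b^2)/b^2$), a convolution with the PSF
(adds $r^2$), and a product with the estimate (combines inverse
variances). The resulting variance is

$$ b^2_{\text{next}} =
   \Big( \frac{1}{b^2} + \frac{b^2}{r^2 (r^2 + 2 b^2)} \Big)^{-1}, $$

independent of the estimate's amplitude. `gaussianVarianceStep()`
implements this; at $b^2 = r^2 = 1$ it gives exactly $0.75$, i.e. one
iteration sharpens a matched Gaussian to 75 % relative variance, and
iterating yields a strictly decreasing positive sequence (0.75, 0.612,
...). The recursion was derived in the continuous infinite-domain limit,
so the package treats a discrete 1-D RL run on finely sampled Gaussians
(grid step 0.01 over ±10, variance measured by second central moment via
`fitGaussianProfile()`) as the authoritative cross-check; the two agree
to well under 1 % across estimate variances 0.5–2.

## Synthetic data: what it emulates, what it does not

The generators supply every fixture the tests need:

* `makeBeadPhantom()` — uniform spheres at seeded random non-overlapping
  integer positions (a voxel belongs to a bead iff its centre is within
  the radius, so bead mass is countable); emulates fluorescent-bead
  calibration samples.
* `makeFilamentPhantom()` — persistent random-walk polylines at constant
  intensity; emulates microtubule-like structures.
* `makeGaussianPSF()` / `makeAstigmaticPSF()` — a separable Gaussian,
  and an "hourglass" PSF whose lateral sigma grows linearly with defocus
  and whose elongation axis rotates 90° across the waist, as produced by
  instrumental astigmatism.
* `forwardModel()` — circular blur plus optional Poisson noise.
  Intensities are converted to expected counts by `photonScale`, drawn,
  and scaled back, so SNR is dialled independently of the intensity
  scale. The restoration benchmarks use bead intensity 100 with
  `photonScale = 10` (peak blurred signal of order 100–300 counts), a
  typical fluorescence regime.

These phantoms deliberately omit much of real data: spatially varying
PSFs, background autofluorescence, detector read noise and offset,
saturation, and sample motion. Passing tests show the algorithmic core
is correct under the stated model — not that any particular microscope's
stack will restore equally well.

## Numerical choices

* **Arithmetic.** All computation is in R doubles. The contracts
  (conservation at $10^{-4}$, oracle agreement at $10^{-5}$) were set
  for single-precision-class arithmetic and hold with large margin.
* **Division guard.** The re-blurred denominator is floored at
  $\varepsilon = 10^{-12} \max(MI)$ (overridable). The guard only
  engages where the denominator is vanishingly small, and is chosen so
  it cannot disturb flux conservation at the stated tolerance.
* **Clamping.** Negative values arising from FFT round-off are clamped
  to zero at the end of each convolution and iteration, keeping the
  non-negativity invariant exact.
* **Even-sized PSFs.** With the fixed $\lfloor \text{size}/2 \rfloor$
  centering, flipping an even-sized kernel shifts its effective centre
  by one voxel, so the correction convolution is the exact adjoint of
  the blur only for odd-sized PSFs; with even sizes flux conservation
  holds only approximately. Realistic sampled PSFs are odd-sized;
  prefer them.
* **PSF FFT caching.** The FFTs of the PSF and flipped PSF are computed
  once per run and reused by all iterations (each iteration needs two
  convolutions).
* **Determinism.** Generators take explicit seeds and restore the
  caller's RNG state; block split and merge order is z-major, so float
  summation order is reproducible.
* **Backend.** The `backend` selector accepts `"cpu"` (the reference
  implementation) and `"auto"`; no accelerated backend is compiled into
  this package, so `"auto"` falls back to the CPU path. The contract
  that any future accelerated backend must match the reference within
  $10^{-4}$ on volumes up to 64³ stands.

## Problem sizes used by the tests

The suite validates the FFT path against the direct triple-sum oracle on
volumes up to 16³ with kernels up to 5³ (100 random instances), flux
conservation on 32³ volumes, the block/non-block comparison on a 64³
phantom with a 9³ PSF and 10 iterations (2×2×2 split), and the Gaussian
calculus on 2001-sample 1-D grids. These sizes give sub-minute runs
while exercising every code path at meaningful scale; the engine itself
is size-agnostic and the block path exists precisely to take volumes
that do not fit comfortably in memory.

## Known limitations

* Circular boundary handling is a modelling choice, not a fidelity
  claim: objects touching a volume face wrap around, and block
  processing changes what they wrap onto (see the masking discussion
  above).
* No regularized RL variants (total-variation, damped) and no automatic
  iteration selection.
* The valid-region rule and variance recursion are 1-D calculi applied
  axis-wise; no anisotropic 2-D/3-D closed forms are provided.
* TIFF support is restricted to single-channel grayscale volumes
  (8/16-bit unsigned or 32-bit float samples); MRC support is mode 2
  (float32) only.
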