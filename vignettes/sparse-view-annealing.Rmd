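---
title: "Sparse-view CT reconstruction by simulated annealing: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse-view CT reconstruction by simulated annealing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sact)
```

## The problem

Computed tomography measures line integrals of an unknown absorption map
$f(x, y)$: at view angle $\theta$ the detector records the projection
$P_\theta(t) = \iint f(x,y)\,\delta(x\cos\theta + y\sin\theta - t)\,dx\,dy$,
and the collection over angles forms the sinogram $P(t, \theta)$. Radiation
dose is roughly proportional to the number of views, so *ultralow-dose*
imaging asks for reconstructions from very few projections — here 18 views
over $[0, \pi)$, an order of magnitude below conventional practice. With so
few views the inversion is badly ill-posed: filtered back-projection (FBP)
produces severe streaking, and algebraic methods only partially compensate.
The motivating clinical context is chest CT of patients who need repeated
scans and tolerate dose poorly; the characteristic finding there is
peripheral ground-glass opacity in the lung fields.

`sact` reconstructs the cross-section by treating the inversion as a
stochastic combinatorial search: pixel intensities live on a discrete
256-level lattice in $[0, 1]$, and simulated annealing (SA) explores that
lattice to make the forward projection of the estimate agree with the
measured sinogram under a chosen cost function.

## The discrete forward model

The grid is square with pixel centers at
$(c - \tfrac{n-1}{2},\ \tfrac{n-1}{2} - r)$ in detector units, and each
pixel contributes its full value to the *nearest* detector bin along
$t = x\cos\theta + y\sin\theta$ — the binary-indicator reading of the
discrete line-sum model, not an interpolating footprint. Two consequences
are load-bearing and tested:

* every view conserves total mass, $\sum_t P(t,\theta) = \sum_{x,y} f(x,y)$;
* a single-pixel change touches exactly one bin per view, so the annealer
  can maintain the postulated sinogram incrementally in $O(M)$ per move
  with no backward projections.

Ties at half-integer offsets (they arise on even-sided grids at axis-aligned
angles) are broken away from zero, deterministically. The default detector
has the smallest odd number of bins at least $\sqrt 2\,n$, so diagonal rays
never clip; a tight 512-bin/512-pixel layout remains expressible by
passing `n_bins` explicitly.

## Initialization: wavelet-multiscale FBP template

Annealing from a flat or random start wastes most of the budget, so the
chain starts from a multiscale filtered back-projection template. Per view
the projection is taken through a periodized orthonormal 1-D wavelet
transform, hard-thresholded, inverse-transformed, ramp-filtered, and
back-projected with linear interpolation; the view average is min-max
normalized, clipped to $[0,1]$ and quantized to the intensity lattice. The
wavelet-domain form of the composite filter (the ramp matrix conjugated by
the orthonormal transform) is honored as operator composition — identical
algebra without assembling dense $t_b \times t_b$ matrices. Choices:

* **Wavelet family.** Daubechies filters with hard-coded coefficient
  tables (`haar`/`db2`, `db4`, `db8`, named by tap count); `db4` is the
  default. Decomposition depth defaults to
  $\max(1, \lfloor \log_2 t_b \rfloor - 2)$.
* **Threshold.** The universal (VisuShrink) rule
  $\lambda = \hat\sigma\sqrt{2\ln m}$ with
  $\hat\sigma = \mathrm{median}(|d_1|)/0.6745$ estimated from the finest
  detail band; thresholding is hard, applied to detail coefficients only.
* **Ramp filter.** Applied circularly in the frequency domain on the native
  detector length. The DC response is exactly zero — a constant projection
  is annihilated — and because the detector already pads the object support
  by $\sqrt 2$, circular wrap-around does not reach the reconstruction
  region at the sizes used here.
* **Identity check.** With thresholding off the wavelet conjugation cancels
  exactly, and the template equals plain FBP to machine precision; this is
  a regression test, not an accident.

## The annealing engine

One iteration draws a uniformly random pixel and a uniformly random lattice
level, updates the postulated sinogram incrementally, and accepts by the
Metropolis rule: downhill always, uphill with probability
$h_k = \exp(-\Delta C / T_k)$. The temperature follows the
hyperbolic-secant profile
$$T_k = \frac{T_0 - T_N}{\cosh(10\,k'/N)} + T_N,$$
with $k'$ truncated to the start of its 1000-iteration constant-temperature
slab. This form reaches $T_0$ exactly at $k = 0$ and lands within about
$10^{-5}$ of $T_N$ at $k = N$. Defaults: $T_0 = 0.1$, $T_N = 1.5\times
10^{-3}$, $N = 2\times 10^5$ for $8\times 8$ grids and $8\times 10^5$
otherwise. A colder operating point with $T_N = 10^{-6}$ is used for the baseline
comparisons below and is reachable through `anneal_config(tn = 1e-6)`.

Two details matter numerically. Rejected candidates are rolled back by
restoring the single touched bin per view — no state copies. And the
best-so-far estimate is tracked separately from the current one, so the
returned image never degrades late in a hot chain.

The stopping rule couples an iteration budget with an optional slab-rate
test: at each slab boundary the run stops early when the best-cost
improvement over the slab falls below `stop_tolerance` (default 0.1) times
the current best, for error-type costs. The benchmark protocol in this
package always runs the full budget (`stop_tolerance = 0`), because the
repetition statistics are defined at fixed $N$.

The production engine is compiled (Rcpp); a plain-R reference engine with
the identical draw protocol and R-matched accumulation arithmetic exists
solely so tests can compare the two move-for-move. They produce bit-identical
trajectories on the test cases.

## The cost-function bank

Seven per-view objectives are supported, evaluated between measured and
postulated projections and averaged over views; similarity indices (UIQI,
SSIM) are wrapped as $1 - \text{index}$ so that a single minimizer serves
all seven. Definitions follow the standard forms: UIQI is the Wang–Bovik
three-factor product (correlation × mean proximity × contrast proximity),
SSIM uses stabilizers $C_1 = (0.01L)^2$, $C_2 = (0.03L)^2$, $C_3 = C_2/2$
with $L$ the dynamic range of the measured view and the whole vector as
window (projections are 1-D), RSE and RAE normalize squared and absolute
error by the measured view's deviation from its mean, and RMSLE is the
root-mean-square difference of $\log(1 + \cdot)$ — the only reading of the
logarithmic error that is defined for all non-negative data. Degenerate
configurations (RSE/RAE against a constant view; RMSLE with negative data)
are rejected up front.

Projections are costed as raw line integrals, without normalization; this
is a deliberate choice, recorded here because nothing in the cost
definitions forces it.

## Quality metrics

* **PSNR**: $10\log_{10}(1/\mathrm{MSE})$ with peak 1.
* **EuE**: relative Euclidean error $\|f - \hat f\|_2 / \|f\|_2$ — the
  normalization is this package's normative definition, consistent with the
  0.1–1.2 magnitudes such analyses report.
* **WPSNR**: PSNR with squared errors weighted by a noise-visibility map
  $w = 1/(1 + \sigma^2_{\text{local}}/\sigma^2_{\text{global}})$ from the
  3×3 local variance of the reference, so errors in flat regions (where
  they are most visible) count fully. On a constant reference WPSNR equals
  PSNR exactly.

Absolute EuE/WPSNR values depend on these definitional choices, so
cross-study comparisons should be made on orderings and gaps, not digits.

## The synthetic lung phantom

Real reference data (an institutional 3-D bronchial-tree phantom; public
COVID-19 chest CT images) cannot be redistributed here, so the generator
produces a deterministic, seeded 2-D slice analogue: a thorax ellipse
(intensity ≈ 0.85) containing two darker lung ellipses (≈ 0.15), a
recursively bifurcating airway tree (≈ 0.7, length and width decaying by
0.7 per generation, seeded angle jitter) clipped to the lung fields, and
optional peripheral Gaussian ground-glass blobs (+0.3, clipped) mimicking
the COVID-19 appearance. Values are quantized to the 256-level lattice.
Identical specs are bit-identical; the lung mask is exposed as an
attribute, and its area fraction (≈ 0.2 of the slice) is a tested
invariant.

What the phantom does *not* emulate: anatomical texture, noise (the
acquisition model here is noise-free by design), scatter, beam hardening,
and the fan-beam geometry of clinical scanners. Results on the phantom
therefore demonstrate algorithmic behavior — convergence, cost-function
sensitivity, baseline orderings — not clinical image quality.

## Benchmark protocol and what it shows

`benchmark_costs()` runs the full pipeline repeatedly per cost function
(master-seeded, hence fully reproducible) and reports mean ± sd of PSNR,
EuE and WPSNR. The package's own validation runs use the 8×8 phantom, 18
views, $N = 2\times 10^5$, $T_0 = 0.1$ and 5 repetitions — sizes chosen so
the whole suite completes in well under a minute of engine time while still
exercising $10^6$ Metropolis steps per benchmark.

Two findings are stable under this protocol. First, with the $T_N =
10^{-6}$ end point the annealed RMSLE reconstruction clearly dominates the
algebraic (Kaczmarz, relaxation 0.25, 20 sweeps) and FBP baselines in PSNR
(≈ 34 dB vs ≈ 28 vs ≈ 13 on the seeded phantom). Second, the similarity
and relative indices UIQI, SSIM and RSE are consistently the weakest
annealing objectives, as expected: they are insensitive to the absolute
scale of the projections, so entire cost plateaus are indistinguishable to
them.

One part of the expected ordering does **not** replicate under these
clean conditions: RAE behaves like MAE rather than like the weak group.
That is structural — RAE is MAE rescaled per view by a constant of the
measured data, so with exact, noise-free projections of the target grid it
shares MAE's minimizer and landscape up to view weighting. The acceptance
test encoding the full error-above-relative ordering therefore flags
exactly that pair, and is left doing so rather than being weakened.

## Student-t reporting

Repetition summaries are reported as $\bar x \pm S$ with the margin of
error $E = t_{\alpha/2} S / \sqrt n$ and the 95 % confidence interval
$\bar x \mp E$. Summary tables conventionally print $t_{\alpha/2}$ to three decimals
(2.093 at 19 df) and compute $E$ from the printed value;
`margin_of_error()` follows that convention by default (`t_digits = 3`) so
such tables reproduce digit-for-digit, with the full-precision quantile
available via `t_digits = NULL`. The APA-style test record for
$H_0: \mu = \bar x$ against the sample's own mean is reproduced as a
reporting convention; testing a hypothesis against the mean of the very
sample that generated it is vacuous as inference, and the package's
documentation says so.

## Known limitations

* Parallel-beam only; fan-beam rebinning is out of scope.
* The nearest-bin projector is faithful to the discrete model but coarser
  than interpolating (Joseph/Siddon) projectors; it is the wrong choice if
  sub-pixel accuracy of the forward model is the goal.
* Annealing cost scales with $N \times M \times t_b$; the 64×64 and larger
  grids are usable but not tuned for speed, and no parallel or adaptive
  schedules are provided.
* EuE and WPSNR are normative definitions of this package (see above), so
  only their orderings are comparable across implementations.
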