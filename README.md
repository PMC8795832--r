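# sact — sparse-view CT reconstruction by simulated annealing

`sact` reconstructs tomographic cross-sections from *very few* X-ray
projections (18 views over $[0, \pi)$, roughly a 10-fold dose reduction
against conventional practice) by simulated annealing, and provides the
surrounding apparatus needed to study the method: a discrete Radon forward
projector, a wavelet-multiscale filtered back-projection initialization
template, a bank of seven projection-domain cost functions, FBP and
algebraic (Kaczmarz) baselines, image quality metrics, Student-t repetition
statistics, and a seeded procedural lung phantom generator. The intended
audience is researchers in low-dose medical image reconstruction who want a
reproducible, fully inspectable reference implementation of the annealing
approach.

## The method in brief

The measured sinogram collects line sums
$P_M(t, \theta) = \sum_{x,y} f(x,y)\,\mu(x,y)$, where the indicator $\mu$
assigns each pixel to the nearest detector bin along
$t = x\cos\theta + y\sin\theta$. Reconstruction minimizes a cost
$C(P_M, P_P)$ between the measured sinogram and the forward projection
$P_P$ of the current estimate $\hat f_k$, whose pixels live on a 256-level
intensity lattice in $[0,1]$:

1. start from the wavelet-multiscale FBP template $\hat f^{WT}$
   (per view: 1-D wavelet transform, hard universal threshold, ramp filter,
   linear-interpolation back-projection);
2. at iteration $k$, redraw one uniformly random pixel to a uniformly
   random lattice level, updating $P_P$ incrementally (one bin per view,
   no backward projections);
3. accept downhill moves always, uphill moves with the Metropolis
   probability $h_k = \exp(-\Delta C / T_k)$ under the cooling profile
   $T_k = (T_0 - T_N)/\cosh(10k/N) + T_N$, held constant over
   1000-iteration slabs;
4. stop at the iteration budget $N$ (or optionally when the best cost
   stalls slab-over-slab), returning the best estimate seen.

Cost functions: UIQI, SSIM (similarity indices, annealed as
$1-\text{index}$), MAE, RMSE, RMSLE, RSE, RAE (error measures). Quality is
reported as PSNR, relative Euclidean error (EuE) and noise-visibility
weighted PSNR (WPSNR). The methods vignette
(`vignettes/sparse-view-annealing.Rmd`) documents every definition and
design decision.

## Worked example

```r
library(sact)

ph   <- generate_lung_phantom(phantom_spec(side = 8, seed = 1))
geom <- projection_geometry(side = 8, n_views = 18)
sino <- radon_forward(ph, geom)          # 13 bins x 18 views

cfg <- anneal_config(cost = "RMSLE", tn = 1e-6, n_iter = 2e5,
                     stop_tolerance = 0, seed = 1)
rec <- run_sa(sino, cfg)
rec
#> Simulated-annealing reconstruction (8 x 8, cost RMSLE)
#>   iterations: 200000 of 200000 (41.8% accepted)
#>   best cost:  0.0015217

quality_report(ph, rec$estimate)
#> PSNR 42.16 dB | EuE 0.0145 | WPSNR 42.29 dB

quality_report(ph, build_template(sino, 8)$image)   # the starting template
#> PSNR 10.85 dB | EuE 0.5325 | WPSNR 11.37 dB
```

The anneal lifts the reconstruction from the template's 10.9 dB to
42.2 dB PSNR from only 18 projections; `plot(rec)` draws the per-slab
normalized best-cost trace, and `residuals(rec)` returns the remaining
sinogram misfit. Repetition summaries are reported with Student-t margins:

```r
confidence_interval(sample_summary(64.33, sd = 1.98, n = 20))
#> 95% CI: 63.40 < mu < 65.26  (E = 0.926658)
```

A thin command-line front end over the same functions lives at
`inst/cli/sact.R`:

```sh
Rscript inst/cli/sact.R phantom --side 64 --seed 1 --ggo 3 --out ph.pgm
Rscript inst/cli/sact.R project --image ph.pgm --views 18 --out sino.csv
Rscript inst/cli/sact.R reconstruct --sinogram sino.csv --side 64 \
    --method sa --cost rmsle --seed 1 --out recon.pgm
```

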