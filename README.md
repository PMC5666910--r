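# segpower

Power and sample size calculations for studies that compare the voxel-wise
accuracy of two image segmentation algorithms against a common reference
standard, analysed with a paired Student's t-test on per-image accuracy
differences.

Standard power calculators do not fit this setting: the observations inside
an image are correlated voxels, images differ in difficulty, and the
reference standard itself may be imperfect. `segpower` implements a variance
model built for it. Writing `D = |B - L| - |A - L| ∈ {-1, 0, 1}` for the
per-voxel accuracy difference of algorithms A and B against reference L, the
population is summarised by the accuracy difference `δ = p₁ - p₋₁`, the
disagreement probability `ψ = p₁ + p₋₁`, and a *design factor*

    f = (1 + ω·ρ̄) / (ω + 1)

combining the Dirichlet precision `ω` of the per-image prior (inter-image
variability) with the average inter-voxel correlation `ρ̄` — the analogue of
the design effect in cluster-randomized trials. The per-image variance is
`σ²_D̄ = f·(ψ - δ²)` and the sample size solves

    n = ( t_{α{2}}·σ₀ + t_{β{1}}·σ_alt )² / δ²_MDD

with t critical values at `n - 1` degrees of freedom (fixed-point iteration;
the headline `n` is the ceiling of the converged continuous solution).

The package also:

* translates a minimum detectable difference specified against a
  high-quality reference standard H into the one observable with a cheaper
  standard L:
  `δ_MDD = δ_MDD,H + 2(p(a) - p(b))(p(l) - p(h)) + 2·cov(A - B, L - H)`;
* estimates every model parameter from pilot segmentations (NIfTI/MetaImage
  masks or CSV label tables), including a conservative variance bound by a
  calibrated double bootstrap and a Dirichlet-multinomial precision
  estimator on sparsely spaced voxels;
* validates the formulas with a built-in Monte Carlo simulator of spatially
  correlated voxel differences (Gaussian copula with calibrated latent
  correlations, exponential spatial kernel `ρ_ij = exp(-Dist_ij/σ_ρ²)`).

## Worked example

A pilot of prostate MRI segmentations gives `ψ̂ = 0.134`, `δ̂ = 0.0402` and a
per-image variance `σ̂²_D̄ = 0.00231`. How many images does a study need to
detect a 5% accuracy difference at α = 0.05 with 80% power?

```r
library(segpower)

f_hat <- estimate_design_factor(psi_hat = 0.134, delta_hat = 0.0402,
                                sigma2_hat = 0.00231)
round(f_hat, 5)
#> [1] 0.01745

sample_size_dirichlet(psi = 0.134,
                      study_design(alpha = 0.05, beta = 0.20,
                                   delta_mdd = 0.05),
                      f = f_hat)
#> Required sample size: n = 10 images (continuous 9.377)
#>   critical values t_alpha{2} = 2.2881, t_beta{1} = 0.8867
#>   achieved power at n: 0.8322
```

The design factor 0.017 says a 36-fold variance reduction relative to
perfectly correlated voxels; ten images suffice because the algorithms
disagree on 13.4% of voxels while the difference to detect is 5%.

If the study must use a lower-quality reference standard L while the 5%
requirement was set against a high-quality standard H, correct the
detectable difference first:

```r
params <- reference_quality_params(0.05, pa = 0.246, pb = 0.195,
                                   pl = 0.210, ph = 0.214,
                                   cov_ab_lh = -0.0029)
adjust_mdd(params)
#> [1] 0.043792
bias_decomposition(params)
#> contouring covariance
#>  -0.000408  -0.005800
```

The correction is dominated by the covariance term: L's errors are slightly
biased against the better algorithm, so the difference observable with L is
4.38% rather than 5%, and the study must be sized for the smaller value.

The simulator reports the spatial summary used throughout the validation:

```r
build_spatial_model(c(6, 6), 0.7)
#> Spatial model: 6 x 6 lattice (v = 36), sigma_rho = 0.7
#>   average inter-voxel correlation rho_bar = 0.04716
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/segpower` (verbs: `samplesize`, `power`, `adjust-mdd`, `estimate`,
`simulate`, `make-fixtures`, `grid`).

See `vignettes/segmentation-study-design.Rmd` for the model, its
assumptions, the estimation details and known limitations.

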