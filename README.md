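# asdlmri

Reconstruction of magnetic-resonance images from undersampled k-space data by
**adaptive-size dictionary learning**. The package is aimed at people working
on compressed-sensing reconstruction for low-field MRI, where acquiring fewer
k-space samples shortens scan time but the naive zero-filled inverse FFT is
badly aliased.

## The method

The estimate `x` minimises the patch-sparsity + data-fidelity objective

    min_{x, D, Γ}  Σ_ij || R_ij x − D α_ij ||₂² + v || F_u x − y ||₂²
                   s.t. || α_ij ||₀ ≤ T0,

where `R_ij` extracts the overlapping √m×√m patches of `x`, `D ∈ C^{m×n}` is
a dictionary of unit-norm atoms learned from the image itself, `Γ = {α_ij}`
are sparse patch codes, `F_u` is the Fourier transform restricted to the
sampled set Ω, and `y` are the measurements. Alternating minimisation
iterates three steps:

1. **Dictionary learning** — orthogonal matching pursuit codes every patch;
   an approximate-K-SVD sweep updates each atom from the residual of the
   patches using it (with standard clearing of duplicated or starved atoms).
2. **Size adaptation** — atoms are ranked by *power* `P(d_j) = ||x_jᵀ||₂`
   (the norm of their code row); candidate sub-dictionary sizes are scored
   with the extended Bayesian information criterion

       EBIC = 2 log RMSE + (log Q / Q) P + (2N/Q) log C(n, s),

   with `RMSE = ||Y − DX||_F / √Q`, `Q = mN` and complexity
   `P = sN + (m−1)n` (an extended renormalized-maximum-likelihood criterion
   is also available). The dictionary shrinks or grows toward the winning
   size `n_ITC` and freezes there after the search phase, so the number of
   atoms matches the content of the image instead of being fixed a priori.
3. **Data consistency** — the patch approximations are averaged into an
   image whose spectrum `M` is corrected by the closed form
   `M` off Ω and `(M + v·M0)/(1+v)` on Ω, `M0` being the zero-filled
   measured spectrum.

Quality is tracked with PSNR, SNR and the high-frequency error norm (HFEN,
the norm of the Laplacian-of-Gaussian-filtered difference to the reference).

## Worked example

```r
library(asdlmri)

sim <- simulate_and_reconstruct(128, 4, config = recon_config(seed = 7))
sim$result$per_iteration[c(1, 5, 10), ]
#>    iteration psnr_db snr_db hfen n_atoms
#> 1          1   23.11  11.01 0.77     123
#> 5          5   24.64  12.54 0.49     111
#> 10        10   25.04  12.94 0.44     114
round(sim$zero_filled_psnr, 2)
#> [1] 21.85
```

A 128×128 Shepp-Logan phantom is rendered, 4-fold undersampled with a
variable-density k-space mask, and reconstructed for 10 outer iterations.
PSNR climbs from the 21.85 dB zero-filled baseline to 25.04 dB while HFEN
drops from ~1.08 to 0.44 (edges recover), and the dictionary — started at
128 atoms — settles around 114 atoms for this image. `run_experiment()`
produces the same metrics as a tidy table over grids of undersampling
factors and seeds.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/asdlmri.R simulate --size 128 --factor 4 --seed 7 \
    --out y.csv --phantom-out ref.nii
Rscript inst/cli/asdlmri.R recon --kspace y.csv --ref ref.nii \
    --out recon.nii --log metrics.csv
Rscript inst/cli/asdlmri.R metrics --ref ref.nii --recon recon.nii
```

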