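# graintex

Quantitative microstructure, texture and milling analysis of cereal grain.

Grain hardness and milling behaviour are rooted in the microstructure of the
starchy endosperm: how starch granules of the A (> 15 µm diameter), B
(5–15 µm) and C (< 5 µm) size classes pack into the protein matrix, how much
void and interphase boundary the tissue carries, and how rough and oriented
its fracture surfaces are. `graintex` implements the full analysis chain used
in cultivar-comparison studies of spelt and common wheat, for anyone working
from SEM micrographs of endosperm, kernel silhouettes, milling logs and
laser-diffraction flour data:

* **Endosperm morphometry** — watershed segmentation of starch granules,
  A/B/C typing by cross-sectional area (cutoffs 177 and 20 µm², the circle
  areas at the 15 and 5 µm diameters), and Minkowski functionals of the
  binary map: solid-phase share *V = N_w/N·100%*, boundary share
  *S = N_bound/N·100%*, Euler–Poincaré characteristic *χ = (C_w − C_b)/N*.
* **Fractal surface texture** — structure function
  *S(τ) = K τ^α* with surface fractal dimension *D = 3 − α/2*, corner scale
  length τ_c at the *2S_q²* plateau, and the autocorrelation surface
  anisotropy ratio Str (decay to *R = 0.2*; 1 = isotropic).
* **Kernel morphometrics** — mean diameter *D_m = (LWT)^{1/3}*, thinness
  ratio *R_s = P_b²/(4πA_b)*, circularity *R_c = 2√(πA_b)/P_b*, from tables
  or directly from silhouette images.
* **Milling and flour** — specific milling energy *E_r = (E_c − E_s)/m_g*,
  particle-size percentiles d(0.1)/d(0.5)/d(0.9), volume-weighted mean,
  *SPAN = (d(0.9) − d(0.1))/d(0.5)*, gelatinization range *ΔT = T_e − T_o*.
* **Statistics** — descriptive stats with CV, one-way ANOVA with Duncan's
  multiple range test and letter grouping, Kruskal–Wallis fallback behind a
  Shapiro–Wilk gate, Pearson correlations.
* **Synthetic ground truth** — self-affine surfaces with prescribed Hurst
  exponent, anisotropic Gaussian fields with prescribed correlation-length
  ratio, granule packings with exact per-type counts, elliptical kernel
  silhouettes, lognormal particle-size mixtures: every estimator is
  validated against analytic truth.

## Worked example

Generate a packing with known composition (2 A, 10 B, 50 C granules at
0.5 µm/px), run the morphology chain, and measure a self-affine texture:

```r
library(graintex)

pk <- granule_packing(c(A = 2, B = 10, C = 50), size_px = 512,
                      pixel_scale = 0.5, seed = 42)
endosperm_morphology(pk$image)
#> Endosperm morphology: 62 granules, coverage 0.0009 um^-2
#>   granule area mean 36.524 um^2 (min 5.250, max 427.000)
#>   type A: 2 (3.23%)
#>   type B: 10 (16.13%)
#>   type C: 50 (80.65%)
#> Minkowski functionals
#>   solid phase V           3.455 %
#>   void share             96.545 %
#>   boundary share S        0.975 %
#>   Euler-Poincare chi      0.233 x 10^-3  (C_w=62, C_b=1)

hf <- fbm_surface(512, hurst = 0.5, pixel_scale = 0.5, seed = 42)
texture_metrics(hf)
#> Texture metrics
#>   Str    0.807
#>   D      2.505
#>   K      0.02714
#>   tau_c  64 um
#>   Sq     1
#>   R^2    0.9996
#>   monofractal: TRUE
```

The recovered counts equal the requested composition exactly (the generator
keeps disc boundaries ≥ 2 px apart and radii ≥ 1 px inside the class bands,
so segmentation and typing are deterministic), and the fitted fractal
dimension 2.505 recovers the true `3 − H = 2.5` of the synthetic surface.

Tabulated worked examples behave the same way:

```r
thinness_ratio(20.46, 20.48)   # 1.6266  -> printed 1.63
circularity(20.46, 20.48)      # 0.7841  -> printed 0.78
mean_diameter(8.35, 3.36, 2.89)  # 4.3282 -> printed 4.32
span_width(13.7, 85.0, 204.1)  # 2.24
dsc_delta(61.0, 69.8)          # 8.8
```

A config-driven pipeline ties the stages together:

```r
cfg <- default_config()
cfg$out_dir <- "demo"
run_simulate(cfg)   # synthetic dataset + ground-truth sidecars + manifest
run_analyze(cfg)    # per-stage CSVs under demo/results/
```

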