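---
title: "Quantifying cereal endosperm microstructure: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cereal endosperm microstructure: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graintex)
```

## The scientific problem

The milling behaviour of wheat-family grain — how much energy a mill draws,
how fine and how uniform the flour comes out, how much starch gets damaged —
is rooted in the microstructure of the starchy endosperm: how starch granules
of different size classes are packed into the protein matrix, how much void
space and interphase boundary the tissue contains, and how rough and oriented
the fracture surfaces are. `graintex` implements the quantitative toolchain
for this kind of study: binary-micrograph morphometry, fractal surface-texture
analysis, kernel shape descriptors, milling-energy and particle-size
bookkeeping, and the statistical battery used to compare cultivars.

Because micrograph archives of this kind are rarely deposited, the package
pairs every analysis stage with a synthetic generator whose ground truth is
analytic. The test suite exercises the full chain against that ground truth,
and against the arithmetic worked examples that published cultivar tables
provide.

## Minkowski functionals of a binary micrograph

A segmented micrograph is a two-phase image: white = solid (starch + protein),
black = void. `minkowski_functionals()` reports

* solid-phase share $V = N_w / N \cdot 100\%$,
* interphase boundary share $S = N_{bound} / N \cdot 100\%$, and
* Euler–Poincaré characteristic $\chi = (C_w - C_b)/N$,

with $N$ the pixel count, $N_w$ the white pixels, $N_{bound}$ the unordered
4-adjacent white–black pixel pairs, and $C_w$, $C_b$ the numbers of white and
black connected areas. All counts are exact integers; the only divisions
happen at the end. Two conventions had to be fixed because the field often
leaves them implicit:

* **Connectivity.** White components are 8-connected and black components
  4-connected — the standard complementary pair that avoids the connectivity
  paradoxes of the digital plane. Using the same connectivity for both phases
  makes $\chi$ inconsistent under complementation.
* **Boundary counting.** $N_{bound}$ counts adjacent pixel *pairs*, not
  boundary pixels. On adversarial inputs (a checkerboard) $S$ can then exceed
  100%; the value is reported unclamped because clamping would silently
  change the definition. Real micrographs are nowhere near this regime.

A brute-force pixel-loop oracle recomputes all three functionals on hundreds
of small random images in the test suite; the implementation must agree
exactly, not approximately.

## Granule segmentation and A/B/C typing

Touching granules are split by the watershed transform on the Euclidean
distance map of the mask (`watershed_segment()`, EBImage backend). The
seeding uses distance-map maxima with a minimum peak separation of 3 px by
default; the method name is standard in this literature but its parameters
never are, so the separation is exposed as `min_distance_px`.

Granules are typed by cross-sectional area: type A above 177 µm² (circle
diameter > 15 µm), type C below 20 µm² (< 5 µm), type B in the closed band
[20, 177] µm². The thresholds are the circle areas at the 15 µm and 5 µm
diameter cutoffs rounded to integers (`granule_area_cutoffs()`). The strict
inequalities of the usual verbal definition leave the band endpoints
unassigned; we assign both endpoints to B, which only matters for areas
landing exactly on the integer cutoffs.

The synthetic packing generator (`granule_packing()`) makes the
watershed + classifier chain exactly testable: discs are placed by rejection
sampling with boundaries at least 2 px apart (so segmentation can never merge
neighbours) and radii at least 1 px inside the class band (so pixel
discretization can never flip a label). Under those two margins the pipeline
must recover the requested per-type counts *exactly*, and the tests assert
that on dozens of random packings. What this does **not** emulate: real
endosperm shows touching and partially embedded granules, a protein matrix
with its own texture, and segmentation noise — exact-count recovery on
packings validates the machinery, not the biology.

## Fractal texture from the structure function

For a height field $z(x, y)$ (a grayscale micrograph treated as a surface)
the structure function is the mean squared height difference at lag $\tau$:
$S(\tau) = \langle (z(p + \tau) - z(p))^2 \rangle$. Squared differences are
accumulated along rows and columns at integer offsets and binned by lag —
the axis-aligned profile convention, chosen because it is exactly
reproducible by a brute-force double loop (a property the tests use on small
fields).

A self-affine (monofractal) surface obeys $S(\tau) = K \tau^{\alpha}$ with
$\alpha = 2H$; the fit is a least-squares line on $(\log_{10}\tau,
\log_{10}S)$. Two conventions are worth spelling out:

* **Which fractal dimension.** The slope gives the *profile* dimension
  $D_p = 2 - \alpha/2 \in (1, 2)$. We report the *surface* dimension
  $D = D_p + 1 = 3 - \alpha/2 \in (2, 3)$, the convention under which
  published endosperm values (2.45–2.59) are quoted. The raw slope
  $\alpha$ is stored alongside so either convention can be audited.
* **Fit range.** $\tau$ from 2 px up to $\min(\tau_c, \tau_{max})/2$:
  single-pixel lags carry discretization noise, and the shoulder of the
  plateau biases the slope down. The corner scale length $\tau_c$
  (`scale_length()`) is the first lag where $S(\tau)$ reaches the plateau
  level $2S_q^2$ ($S_q$ = RMS height), found by linear interpolation.

`fbm_surface()` synthesizes the validation target: spectral synthesis with
amplitude $\propto f^{-(H+1)}$ on a periodic grid, no windowing at
generation, so the true surface dimension is exactly $3 - H$. Recovery within
±0.1 of $3 - H$ for $H \in \{0.3, 0.5, 0.7\}$ at $512^2$, averaged over five
seeds, is asserted in the acceptance tests. The problem sizes (512² for
recovery bounds, 128–256² for unit tests) were chosen as the smallest at
which the estimators are in their asymptotic regime.

**Monofractality.** A texture is declared monofractal when the log–log
residuals show no systematic curvature: max |residual| ≤ 0.1 decades and the
slopes of the lower and upper halves of the fit range differing by ≤ 0.5.
The residual tolerance is conventional; the slope tolerance was calibrated
on the generators. A finite periodic self-affine field genuinely bends as
$S(\tau)$ approaches saturation (measured split-slope differences reach
≈0.31 over 30 fields), while a composite of two scaling regimes with
exponents 0.4/1.6 shows ≈0.86 and residuals above 0.1. The default
separates these two populations cleanly; a tolerance as tight as 0.1 would
brand ordinary single-exponent surfaces multifractal.

## Surface anisotropy ratio

The autocorrelation map (`autocorrelation()`) is the FFT-based circular
autocorrelation of the mean-subtracted field, normalized to $R(0) = 1$.
Periodic (unwindowed) correlation is exact for the periodic synthetic
generators; for real, non-periodic micrographs a Hann window option
suppresses edge leakage.

`anisotropy_ratio()` marches 72 rays (5° steps) from the zero-lag centre and
records where each first decays to $R = 0.2$, interpolating bilinearly in
the map and linearly at the crossing. The anisotropy ratio Str is the
fastest decay length over the slowest, so $Str \in (0, 1]$ with 1 =
isotropic. (Published formulations sometimes write the inverse ratio while
printing values ≤ 1; we follow the printed convention.)

On a single realization the raw min/max over 72 noisy directional lengths is
biased low — the extremes of ~tens of correlated estimates. Because the
threshold contour of a Gaussian-correlated texture is an ellipse, the
default estimator fits an origin-centred ellipse to all 72 crossing radii
and takes its axis ratio; measured against `anisotropic_field()` ground
truth this recovers ratios {1.0, 0.5, 0.25} to within ±0.1 (means ≈ 0.95 /
0.53 / 0.27 over five seeds at 256²) where raw min/max gives ≈ 0.75 on a
truly isotropic field. `method = "minmax"` retains the raw ratio.

`anisotropic_field()` provides the ground truth: separable
squared-exponential covariance $\exp(-(d_x/l_x)^2 - (d_y/l_y)^2)$, true
$Str = \min(l_x, l_y)/\max(l_x, l_y)$. When correlation lengths approach the
field size the ACF never reaches 0.2 inside the map and the ratio is
undefined; `anisotropy_ratio()` errors, and the batch wrapper
`texture_metrics()` converts that (and the analogous "no scaling regime"
failure of smooth short-correlation fields) to `NA` with a warning, since
both are legitimate outcomes for some textures.

## Kernel shape descriptors

From tabulated kernel dimensions: mean diameter $D_m = (LWT)^{1/3}$,
thinness ratio $R_s = P_b^2 / (4\pi A_b)$ and circularity
$R_c = 2\sqrt{\pi A_b}/P_b$ (furrow-down projection *b*). $R_s R_c^2 = 1$
identically; both are reported because the field quotes both. Descriptors
computed from cultivar-*mean* dimensions approximate but do not equal means
of per-kernel descriptors — the worked-example checks therefore use ±0.01–0.02
absolute tolerances, the rounding scale of the printed inputs.

The image route (`silhouette_measure()`) re-implements what is usually done
in ImageJ: area from pixel count, perimeter by Moore-neighbour contour
tracing with Kulpa step weights (0.948 axial, 1.340 diagonal — naive
pixel-edge counting overestimates smooth perimeters by ~11%, which would
corrupt $R_s$ by ~23%), and axis lengths from the second-moment ellipse.
Against analytic ellipse ground truth (`kernel_silhouette()`, Ramanujan
perimeter) the estimators land within 1–2%. A digitized circle's corrected
perimeter can fall marginally below the isoperimetric bound, so the
silhouette route computes the ratios directly instead of applying the strict
consistency check used for tabulated measurements.

## Milling energy, particle size, gelatinization range

* `specific_milling_energy()`: $E_r = (E_c - E_s)/m_g$, the net energy per
  unit grain mass; idle energy either given or `idle_power_kW × time_s`.
  Records with $E_c < E_s$ are rejected as inconsistent rather than clipped.
* `psd_summary()`: volume percentiles d(0.1), d(0.5), d(0.9) by linear
  interpolation of the midpoint cumulative curve against **log** size (the
  laser-diffraction convention; a linear axis is a flag away),
  volume-weighted mean $d_{avg} = \sum \varphi_i d_i$, and
  $SPAN = (d(0.9) - d(0.1))/d(0.5)$. `psd_mixture()` generates lognormal
  mixtures with analytically solved percentiles for validation; bimodal
  mixtures with modes near 25 and 130 µm emulate soft-wheat flour.
* `dsc_delta()`: gelatinization range $\Delta T = T_e - T_o$ (the end
  temperature, sometimes written $T_c$, is canonicalized to $T_e$).

## Statistics

The battery mirrors standard grain-quality practice: descriptive statistics
with $CV = 100\,SD/\bar{x}$ (sample SD), one-way ANOVA with Duncan's
multiple range test, Kruskal–Wallis as the non-normal fallback, and Pearson
correlation with two-sided t-test p-values.

Duncan's test (`anova_duncan()`) uses least significant ranges
$R_p = q_{(1-\alpha)^{p-1},\,p,\,df} \sqrt{MSE/n_h}$ — the studentized-range
quantile at Duncan's protection level, harmonic-mean $n$ for unbalanced
designs — with the classic sweep over ascending means in which a
non-significant span protects its sub-ranges, and minimal-letter assignment.
Two deliberate choices:

* **Fisher protection.** Ranges are only tested when the ANOVA F is
  significant at $\alpha$; otherwise all groups share a letter. Unprotected
  three-group null familywise error under Duncan's levels is ≈ 0.10, which
  no practitioner reporting "significant at p ≤ 0.05" intends; the protected
  procedure holds the simulated null letter-separation rate at ≈ 0.05
  (asserted in the tests with 1000 null replicates).
* **Normality gate.** `compare_groups()` routes to Kruskal–Wallis when any
  group fails Shapiro–Wilk at $\alpha$ — the usual published phrasing
  ("when data were not normally distributed") without naming a test, so the
  gate is explicit here.

No multiple-testing correction is applied across correlation matrices,
matching field practice; interpret wide correlation scans accordingly.

## Pipeline and reproducibility

`run_simulate()` writes a synthetic dataset (texture fields as 16-bit TIFF,
packings as PNG masks, ground-truth sidecars in YAML, tables as CSV) with a
manifest of checksums; `run_analyze()` runs morphology → fractal →
geometry → flour → stats over it and writes per-stage CSVs. Every CSV
carries the seed and a hash of the scientific configuration; identical
configs reproduce identical checksums, and all generators take explicit
seeds and restore the caller's RNG stream.

## Known limitations

* Published per-cultivar microstructure tables (solid-phase shares, χ, Str,
  D, τ_c of real endosperm) are not recomputable without the original
  micrographs and pixel scales; they serve as plausibility ranges here, and
  the quantitative validation rests on synthetic ground truth plus the
  printed worked examples.
* The binarization rule and pixel scale of archival SEM images are user
  inputs (Otsu default, brighter-equals-solid polarity), not recovered from
  vendor metadata.
* Granule typing is 2-D cross-sectional; no stereological correction to 3-D
  size distributions is attempted.
* The fractal estimator assumes a single scaling regime below the corner
  scale; strongly multifractal or layered textures should be flagged by
  `monofractal_check()` and interpreted with care.
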