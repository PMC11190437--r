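---
title: "Methods: synthetic-scene metrology for a transition-fibre protein screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic-scene metrology for a transition-fibre protein screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfscreen)
```

## The measurement problem

Transition fibres sit at the distal end of a mature basal body, a few
hundred nanometres from the proximal cartwheel marker (SAS-6) and below
the conventional diffraction limit in lateral extent. A widefield screen
for their components therefore rests on two sub-resolution measurements
per tagged candidate: the axial **distance** between the candidate's
fluorescence centre and the nearest basal-body marker focus, and a
lateral width proxy, the **pseudo-diameter**. This vignette documents the
models, parameter choices and numerical behaviour of the package's
implementation, and what its synthetic validation does and does not
establish.

## Image formation model

`render_scene()` renders each channel's noiseless expectation as

$$E(p) = B + \sum_k A_k \int_p \mathcal{N}_2(x - x_k, \sigma_\text{PSF}^2 I)\,dx,$$

background $B$ plus every object's photon total $A_k$ spread by an
isotropic 2D Gaussian PSF and *integrated analytically over each pixel
area* (products of normal CDF differences). Point sampling would make
sub-pixel ground truth meaningless at 65 nm pixels; analytic integration
keeps photon totals exact (interior objects conserve photons to well
under 0.5%). Noise is Poisson on the expectation plus additive Gaussian
read noise. Annular structures are discretised as 180 point sources on
the circle (plus concentric rings weighted by radius for the filled-disc
component), each convolved analytically.

Defaults, with reasons:

| parameter | default | rationale |
|---|---|---|
| `pixel_size_nm` | 65 | 6.5 µm camera pixel / 100× magnification |
| `psf_sigma_nm` | 73 | 0.21 λ/NA with λ = 510 nm (green emission), NA = 1.46 |
| `background_level` | 5 photons/px | sparse, extracted-cytoskeleton-like background |
| `read_noise_sd` | 2 photons | sCMOS-class camera |
| object `amplitude` | 2×10⁴ photons | bright endogenous tag; high-SNR regime |

No exposure or SNR calibration data exist for the original acquisitions,
so these are plausibility choices, made once; the localisation accuracy
the tests report is specific to this regime (accuracy degrades as
amplitude falls, which the amplitude-sweep test demonstrates
qualitatively).

Coordinates: origin at the centre of the first pixel, x rightward along
columns, y downward along rows, everything in nm. Each scene draws its
noise from an RNG stream derived from `(seed, scene_index)`, so any scene
is reproducible in isolation and reruns are bit-identical.

One physical point worth recording: the radial intensity maximum of a
PSF-blurred ring lies *inside* the true radius — for a circle of radius
$R$ blurred by $\sigma$, the blurred profile is
$\propto e^{-(r^2+R^2)/2\sigma^2} I_0(rR/\sigma^2)$, whose peak solves
$r = R\, I_1(rR/\sigma^2)/I_0(rR/\sigma^2)$, always below $R$. The test
suite uses this closed form as the rendering oracle. It is also why a
width statistic taken directly from a blurred image underestimates the
physical diameter (see *Calibration* below).

## Focus detection and sub-pixel centring

`detect_maxima()` scores every local maximum by **topographic
prominence** — peak height minus the highest saddle connecting it to a
higher peak — computed exactly by flooding the image in order of
decreasing intensity with union-find merging (8-connectivity). The global
maximum's prominence is its height above the image minimum. Plateaus
collapse to one peak; all ties break to the lower (y, x) position, so
detection is fully deterministic. Prominence is a better noise gate than
raw height because it is invariant to the local background pedestal. The
default pipeline threshold (50 photons) sits far above the shot-noise
floor of the default background and far below true peak heights in the
default amplitude regime.

`fit_centre()` reproduces the screen's centring step: within a window
(default 15×15 px ≈ 1 µm, wide enough for the largest structures plus
margin), the column sums give an x-profile and the row sums a y-profile;
each is fitted with a four-parameter 1D Gaussian. Fits use raw
Levenberg–Marquardt (`minpack.lm::nls.lm`, ≤200 iterations, tolerances
1e−8) initialised from background-subtracted moments. A degenerate fit —
non-convergence, escape from the window, non-finite or non-positive
width — flags the focus invalid, and invalid foci are excluded
downstream with a logged count. Manual point selection is supported by
passing an explicit `c(row, col)` seed instead of a detected peak.

Two properties characterise the estimator on noiseless input: integer-
pixel translation equivariance (exact), and per-axis width agreement
within 2% on isotropic emitters. Column/row summation is optimal for
separable Gaussians and degrades gracefully for rings, whose projected
profiles are symmetric about the centre (the fitted mean stays unbiased
even where a single Gaussian is a poor shape model for the double-humped
projection).

## Distance and pseudo-diameter

`pair_to_nearest()` assigns each green focus to its Euclidean-nearest
red focus and drops pairs beyond 500 nm — foci farther than that are not
plausibly the same basal-body apparatus. Equidistant reds break to the
brighter focus, then lower (y, x). On small scenes the implementation is
verified against an exhaustive search oracle.

`pseudo_diameter()` samples 45 line profiles through the fitted centre at
0°–176° in 4° steps — 45 distinct orientations; a 180° line would
duplicate 0°. Profiles extend ±600 nm at quarter-pixel steps (16.25 nm)
by bilinear interpolation. Each profile gets a Gaussian fit; the fitted
standard deviation times `diameter_scale` is that line's **effective
diameter**; lines failing the fit or exceeding 500 nm are excluded as
outliers; the maximum over valid lines (ties to the smallest angle) is
the pseudo-diameter, with its angle reported. If all 45 lines fail the
structure is flagged unmeasurable rather than given a fabricated value.

### Calibration

`diameter_scale` defaults to 1 — the fitted SD is read directly as the
effective diameter, the literal form of the original macro's definition.
This is a *relative* width statistic: a PSF-blurred profile's SD is not
the physical diameter, and two blur-dependent biases act in opposite
directions (PSF convolution widens; the annulus-projection geometry and
Gaussian shape mismatch compress). The package therefore ships
`calibrate_diameter_scale()`, which renders noiseless rings of known
diameter under the user's optical configuration and regresses true on
measured diameter. What the screen's gate needs is only monotonicity —
wider structures must measure wider — and that is what the tests assert
(strict growth over true diameters 220, 280, 340, 400 nm, and every ring
≥200 nm measuring wider than a point source, the basis of the
barrel-control gate). Bilinear interpolation also broadens fitted widths
slightly (about 1–2% at σ = 150 nm on 65 nm pixels, shrinking as σ/px
grows) and makes the 45 effective diameters of a perfectly isotropic spot
agree only within a fraction of a percent rather than exactly; both
effects are orientation-generic and cancel out of the within-
configuration comparisons the screen makes.

## The inclusion gate and classification

`apply_inclusion_gate()` works on protein-level means (the form in which
the control baselines are defined) with **strict** inequalities: a
candidate exactly at a control baseline is excluded, the conservative
reading of "distal to" / "more proximal than" / "greater than".
Per-cell-distribution gating was deliberately left out of scope — the
controls are summarised as means, and a distributional gate would need a
criterion the source analysis never states.

`classify_recruitment()` reduces per-cell observations (2 vs 4 red marker
foci; green focus count; green signal on probasal bodies) to a timing
class. `min_fraction` defaults to 0.25: probasal recruitment is visible
in only about a third of early-S cells (arrival is progressive), so a
detection fraction above ~1/3 would misclassify genuine probasal
recruiters, while early/late recruitment patterns are near-universal in
their stage and sit far above any sensible threshold. Classes are
checked probasal → before → after; the call is order-free in the
observations (a set statistic, verified by shuffling).

`reciprocal_best_hits()` takes precomputed 12-column tabular alignment
hits and emits (a, b) iff each is the other's best hit (lowest E-value,
ties by higher bitscore then lexicographic subject id) and both E-values
are ≤ 1e−5. Running the sequence search itself is out of scope. The
implementation is tested against a brute-force scan over all id pairs.

`helix_length()` is the ideal-helix arithmetic (5.4 Å pitch, 3.6
residues/turn): a 1000-residue helix spans 150 nm — the scale argument
for how α-helix-rich proteins can span a transition-fibre blade.

## Morphometrics and statistics

`measure_trace_length()` offers segmented (chord-sum) and spline modes.
The spline is a natural cubic through the clicked points with
chord-length parameterisation — the standard choice when the original
tool's spline variant is unspecified — with arc length accumulated over
100 subdivisions per segment (error well below 0.01 µm for flagellum-like
curvature; a 9-point semicircle of radius 5 µm measures within 0.05 µm of
πr). Duplicate consecutive points collapse with a warning.

`mann_whitney_u()` wraps `stats::wilcox.test`: exact p-values whenever
n₁·n₂ ≤ 400 with no ties (verified against full enumeration of all 252
assignments at n = 5/5), otherwise the normal approximation with tie and
continuity correction. The exact two-sided test at n = 20/20 has
closed-form size 0.0491 at α = 0.05; the calibration test estimates it by
2000 null simulations. `classify_flagellum_bias()` applies the two-sided
test to paired new/old-flagellum net densities (≥20 cells), calling
enrichment only when the median difference and significance agree;
α = 0 degenerates to "equal" by construction.

ROI photometry is deliberately minimal: integrated density is the pixel
sum over a rectangle, background subtraction requires equal-area regions
(unequal areas are an error, not a scaling), and net density is invariant
to a constant offset on the whole image.

## The end-to-end screen and reproducibility

`run_screen()` chains simulate → detect → measure → gate → stats over a
configured cohort; any stage failure aborts with the stage's name. The
demo cohort — a 340 nm ring-like candidate at 300 nm offset, a point-like
barrel control, and a point-like transition-zone control at 480 nm — is
constructed so the gate's three exclusion modes are all exercised and
exactly the ring passes. The configuration round-trips through JSON with
schema-style validation (bad optics are rejected before any compute), and
a single master seed expands into per-scene streams, so outputs are
byte-identical across reruns; each output table carries the md5 hash of
the scientific configuration (output location excluded) as a manifest id.

Problem sizes in the shipped tests and acceptance script — 200 recovery
scenes of 32×32 px, 6 cells per demo protein, 2000 null simulations,
4 calibration rings — were chosen as the smallest sizes at which the
estimates are stable (Monte-Carlo SE of the type-I estimate ≈ 0.005;
median localisation error stable to two decimals), keeping a full run in
tens of seconds.

## What synthetic validation does not show

The generator emulates flat 2D fields of well-separated bright objects
with an isotropic Gaussian PSF and pixel-uniform noise. Real screen data
add: 3D structure projected through defocus, spectral bleed-through,
chromatic offsets between channels, autofluorescent background texture,
variable expression level, and clustered basal bodies in dividing cells.
Passing the recovery tests therefore certifies the *algorithms* —
unbiasedness and precision of the centring, correctness of the pairing,
monotonicity of the width proxy, calibration of the rank test — not
instrument-level accuracy on real images. The classification fixtures
encode published per-protein outcomes and validate the bookkeeping, not
the microscopy that produced them; where a published family-level count
(conservation of the CEP164 family) did not resolve to individual
proteins, the fixture assigns the family's canonical member.
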