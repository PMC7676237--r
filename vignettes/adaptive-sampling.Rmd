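---
title: "Voronoi-regularized leave-one-out adaptive sampling for scanning hyperspectral microscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voronoi-regularized leave-one-out adaptive sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(livsampler)
```

## The problem

A scanning FTIR microscope measures one absorbance spectrum at a time at a
stage position chosen by the operator. Raster maps at full spatial resolution
are slow — often prohibitively so for live or drift-prone specimens — and most
of the measurement time is spent on chemically uninteresting regions. An
autonomous adaptive data-acquisition loop instead decides, after every
measurement, where the next spectrum is most worth taking, aiming to resolve
spatiochemical "hot spots" (regions of steep physico-chemical gradients) with
a fraction of the points a uniform raster needs.

`livsampler` implements such a loop, called **LIV** (Linear Interpolation +
Voronoi), together with the non-adaptive baselines it is compared against
(uniform grid **UG**, uniform random **UR**, largest-unexplored-region
**LUR**), the preprocessing used inside the loop, simulation benchmarks
against full-resolution "ground truth" maps, and seeded generators of
synthetic maps so the entire system is testable without a beamline.

## The surrogate model and the LIV score

After $N_s$ measurements at positions $X_i \in \mathbb{R}^2$ with (reduced)
spectra $Y_i$, the surrogate $U_0$ is a piecewise-linear interpolant:
barycentric interpolation on the Delaunay triangulation of the $X_i$, applied
to each value dimension independently. Queries outside the convex hull take
the value of the nearest support point — some rule is required there, and the
nearest-support fallback keeps every later quantity finite and well defined.

The sensitivity of the model to point $i$ is its leave-one-out (LOO)
cross-validation error
$$\epsilon_{\mathrm{LOO},i} = \lVert U_0(X_i) - U_{-i}(X_i)\rVert_2
 = \lVert Y_i - U_{-i}(X_i)\rVert_2,$$
where $U_{-i}$ is the surrogate rebuilt without point $i$ (the first equality
uses the interpolation identity $U_0(X_i) = Y_i$). Linear interpolation gives
no intrinsic uncertainty estimate, so the Voronoi cell area of each point acts
as an ad hoc regularizer: interpolation error tends to grow with distance from
the support. Each cell
$$V_i = \{u : \lVert u - X_i \rVert_2 < \lVert u - X_j \rVert_2 \;\forall j \ne i\}$$
is clipped to the map rectangle so its area $\mathcal{V}_i$ is finite. Both
quantities are min–max normalized,
$\sigma(x_i) = (x_i - \min x)/(\max x - \min x)$, and combined with equal
weight:
$$\epsilon^{(\mathrm{LIV})}_{\mathrm{LOO},i} =
  \sigma(\epsilon_{\mathrm{LOO},i}) + \sigma(\mathcal{V}_i) \in [0, 2].$$
The next measurement is a uniform random draw from the Voronoi cell of the
point maximizing this score (ties broken by lowest index). Run-level model
accuracy is summarized by the Voronoi-weighted mean LOO error
$$\langle \epsilon_{\mathrm{LOO}} \rangle_V =
  \frac{\sum_i \mathcal{V}_i\,\epsilon_{\mathrm{LOO},i}}{\sum_i \mathcal{V}_i},$$
which corrects the plain mean for the irregular point distribution adaptive
sampling produces.

The acquisition loop is: measure `n_init` random points (default 10 — the
loop needs a buildable support before the score is meaningful); then
repeatedly preprocess all spectra, rebuild the surrogate, compute the error
table, pick the next point, and measure, until the point budget (default 500)
is reached. Every iteration is appended to an audit log that serializes the
full error table; reruns with the same configuration and seed are
bit-identical.

## Preprocessing inside the loop

Raw spectra pass through three steps before the error calculation:

* **Band restriction** to a configurable wavenumber window (e.g.
  900–3700 cm⁻¹ in the synchrotron workflow, to avoid detector-limit noise
  and morphology-driven baseline effects at the band edges).
* **Rubber-band baseline correction**: subtraction of the lower convex-hull
  envelope of the (wavenumber, absorbance) points, linearly interpolated
  between hull vertices. The result is non-negative up to numerical
  tolerance, exactly zero at both endpoints, and the operation is idempotent.
* **PCA** to at most five components (configurable), refit on all acquired
  spectra at every iteration — early iterations have too few spectra to fix a
  basis once. Scores are raw rather than whitened, so the L2 LOO error
  weights components by the spectral variance they carry. A deterministic
  sign convention (largest-magnitude loading element positive) keeps audit
  logs reproducible. The effective number of components is
  $\min(n_c, N_s - 1, N_f)$.

Order of operations is restrict → baseline → PCA. Band restriction and
baseline correction are per-spectrum and therefore cached per point; PCA is
the only step refit globally each iteration.

## Baselines

UG measures a cell-centred $r \times c$ grid in raster order, with $r c$
maximal within the budget and the grid aspect ratio closest to the domain's.
UR measures uniformly random positions. LUR operationalizes "measure the most
sparsely sampled region" as a uniform draw from the largest clipped Voronoi
cell — exactly the LIV rule with the LOO term removed, which makes the
pairwise comparison interpretable.

## Benchmarks against ground truth

Simulated acquisition serves spectra by nearest-grid lookup from a
full-resolution reference map (ties broken by lowest row-major index). A
strategy's quality at a point count is the ground-truth error of its
interpolation evaluated at every reference grid point,
$$\epsilon_{\mathrm{GT}} = \sqrt{\tfrac{1}{N_0}\textstyle\sum_{i=1}^{N_0}
  \lVert U(X^{(0)}_i) - Y^{(0)}_i \rVert_2^2},$$
with a `sum` variant that omits the $1/N_0$ (the two differ exactly by
$\sqrt{N_0}$ and rank strategies identically on a fixed map).
$\epsilon_{\mathrm{GT}}$ is always computed on the full (band-restricted)
spectra for every strategy; LIV's internal PCA affects only where it samples.
This keeps the comparison representation-identical across strategies.

The headline comparison mirrors the histogram-of-ratios design: for each map,
UG's target is its $\epsilon_{\mathrm{GT}}$ at the budget of a $k$-fold
offset subgrid, averaged over all $k^2$ subgrids (the aggregation is
configurable; the mean is the default). Every other strategy then grows its
own acquisition sequence one point at a time until it first reaches the
target, and reports $N_s(\text{strategy})/N_s(\text{UG})$. UG against itself
is identically 1.

The **on-target ratio** (OTR) scores an acquired set spectrally rather than
geometrically: the fraction of spectra whose intensity meets the mean-peak
threshold at *any* criterion wavenumber (inclusive OR). Criteria are derived
from a noise-filtered reference set — spectra whose signal-band mean over
quiet-band standard deviation (the package's concrete SNR definition; the
bands and threshold are configuration) falls below a minimum are removed, and
the threshold at each chosen band is the mean intensity of the survivors.

## The synthetic map generators

Maps are built as $Y(x, y) = \sum_c \mathrm{conc}_c(x, y)\, S_c + \eta$,
where each component standard $S_c$ is a sum of Gaussian/Lorentzian peaks and
each concentration field is a sum of anisotropic Gaussian blobs — the
simplest structure with tunable gradients and mixing zones. The default axis
is 650–4000 cm⁻¹ at 4 cm⁻¹, the native spectral resolution of the emulated
instrument; $\eta$ is i.i.d. Gaussian with default sd 0.001 a.u.

The noise default deserves explanation. Simulated sampling draws spectra from
the map itself, so map noise is a *shared realization*: it behaves as
fine-scale spatial texture that no interpolant can predict, not as
independent measurement noise. At 0.001 a.u. (≈1 mOD, the noise floor of a
well-averaged high-brightness measurement) this texture contributes little to
$\epsilon_{\mathrm{GT}}$; at several mOD it would dominate the benchmark and
mask every structural difference between strategies.

Two presets emulate the experimental regimes:

* **`two_component`** — an abiotic sample of two compact deposits on a bare
  substrate: an elongated marker stroke (major band 1580 cm⁻¹, aromatic C–H
  near 3050 cm⁻¹) and a roundish grease smear (silica band 798 cm⁻¹, CH
  stretches near 2963 cm⁻¹), their tails meeting in a mixing zone. The
  deposits occupy roughly a fifth of the mapped area — chosen so that a
  uniform grid's on-target fraction lands near the ~0.19 such samples show —
  and carry seeded fine-scale thickness texture, because lightly applied
  smears are internally uneven. The texture matters: perfectly smooth
  deposits become exactly interpolable after a handful of samples, after
  which an adaptive sampler has nothing left to exploit, a behaviour real
  deposits do not show.
* **`wormlike`** — an elongated, gently curved body with three overlapping
  compartments (protein-rich anterior, lipid-rich mid-body, hydrated matrix
  throughout), emulating a whole-organism map with smooth multi-compartment
  gradients.

What the generator does **not** emulate: scattering/Mie baseline artifacts,
detector drift, atmospheric vapour lines, absorbance saturation, and —
importantly — the open-ended information content of a real instrument. With
nearest-grid lookup, revisiting a grid cell returns a duplicate spectrum, so
once an adaptive run has visited most cells of a deposit its LOO errors there
collapse and exploitation saturates. Experimentally measured on-target ratios
near 0.95 at budgets comparable to the map size are therefore not reachable
in simulation (the simulated LIV OTR is bounded well below that); the
simulated OTR comparison is meaningful only as UG-vs-LIV direction, not in
absolute level. Passing benchmarks on these maps shows the selection logic
works under the stated conditions; it does not certify performance on real
tissue.

## Numerical choices

* **Geometry engine.** The Delaunay/Voronoi/LOO core is compiled (Rcpp).
  Incremental Bowyer–Watson triangulation with long-double predicates and
  scale-relative tolerances; exactly cocircular configurations (ubiquitous on
  subgrids) are resolved deterministically by insertion order. Voronoi cells
  are built by half-plane clipping of the domain rectangle, so areas are
  exact polygon areas and sum to the domain area to ~10⁻¹² relative error.
* **Domains** are half-open rectangles $[x_{\min}, x_{\max}) \times
  [y_{\min}, y_{\max})$ extending half a step beyond the outermost grid
  points; grid points are cell centres. The adaptive sampler proposes
  continuous positions; queries outside the domain are errors.
* **Degenerate cases.** Fewer than 3 or collinear support points are a
  "degenerate support" error at build time; inside the LOO loop, a degenerate
  reduced support falls back to the nearest-support value so every
  $\epsilon_{\mathrm{LOO},i}$ is defined. $\sigma$ of a constant vector is
  all zeros (a constant carries no ranking information). Duplicate points are
  rejected.
* **Cell sampling** is rejection sampling from the cell's bounding box with a
  nearest-owner membership test, capped at 10⁴ trials with the cell centroid
  as a deterministic fallback — this avoids explicit point-in-polygon tests
  and guarantees termination.
* **Exact reproducibility.** All randomness flows through R's RNG seeded from
  the configuration; the LOO engine accumulates in long double to match R's
  `sum()`, so independent reimplementations of the rebuild loop agree
  bit-for-bit with the compiled path.

## Problem sizes used in tests and the acceptance script

Desk-scale runs use 30 × 30 maps (N₀ = 900) at 1.5 µm step with the axis
coarsened to 50 cm⁻¹ (68 channels), ten seeded `two_component` maps with 20
replicates per strategy, and a subsampling factor of k = 4 for the UG target
(56 points, a 6% sampling fraction). k was fixed at 4 because the nearest-grid
simulation approximation requires $N_s \ll N_0$; at k = 2 a quarter of all
grid points would be sampled and the approximation degrades. These sizes are
the package's choice of a configuration that exercises the full loop while
keeping the whole suite runnable on a laptop; the generator and benchmark
accept larger maps, finer axes and more replicates unchanged.

At this scale the LIV-vs-UG median ratio sits only modestly below 1 (with a
wide spread), while LIV's fraction of runs beating UG far exceeds UR's. The
margin is structural: on a 30 × 30 map no admissible UG subgrid is badly
aliased relative to deposits a few steps wide, so the regime in which adaptive
sampling shines — large maps whose structures a uniform grid oversamples
around and undersamples within — is only partially entered. Larger maps widen
the gap; the desk-scale direction is the honest miniature.

## Known limitations

* Single-point acquisition only; no batching, no multi-objective scores.
* The surrogate is piecewise linear: no gradient estimation (LOLA-style) and
  no kriging-style uncertainty; the Voronoi area is a proxy, not a variance.
* Preprocessing covers band restriction, rubber-band baseline and PCA only —
  no vector normalization, deconvolution or vapour correction.
* The instrument abstraction is a pure function position → spectrum; stage
  motion cost, drift and acquisition-time modelling are out of scope.
* File I/O covers the documented long-format delimited text; proprietary
  spectrometer formats are not read.
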