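---
title: "Phase-contrast CT morphometry of thymic compartments: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-contrast CT morphometry of thymic compartments: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcctomo)
```

## What the package models

`pcctomo` is a simulation and analysis pipeline for propagation-based
(free-space propagation) phase-contrast computed tomography of the
developing human thymus. The organ's three epithelial compartments —
outer cortex, inner medulla, and the keratin-rich Hassall's bodies (HBs)
unique to the medulla — differ in density, and in phase-contrast CT denser
tissue reconstructs brighter. The pipeline generates a labelled 3D phantom
with known compartment fractions, simulates the imaging experiment,
recovers the compartments from the reconstruction, and checks that the
normalised volumetric measures used for inter-sample comparisons are
returned faithfully:

* **medulla content**: $100 \cdot V_\mathrm{med} / (V_\mathrm{med} + V_\mathrm{cx})$,
  the volumetric percentage of medulla over the core thymic tissue;
* **HB content**: $100 \cdot V_\mathrm{HB} / (V_\mathrm{med} + V_\mathrm{HB})$,
  the percentage of the (HB-inclusive) medulla occupied by HBs;
* 2D (histology-style) and flow-cytometry analogues of the first ratio.

Because these are pure count ratios they are invariant to voxel pitch and
to any per-sample size differences, which is what makes them usable for
group comparisons across samples spanning an order of magnitude in size.

## The synthetic thymus phantom

`generate_thymus_phantom()` builds an integer-labelled voxel grid
(codes: 0 background, 1 interlobular gap, 2 cortex, 3 medulla, 4 HB).
The construction emulates the developmental anatomy:

1. an ellipsoidal organ with a smoothly perturbed outline (a coarse
   Gaussian random field modulates the radius by up to 10 %);
2. a seeded, noise-perturbed Voronoi partition into `n_lobules` lobules
   (`n_lobules = 1` reproduces the pre-lobulation stage with one central
   medulla); boundaries can be eroded into interlobular gaps of a given
   width, and `interlobular_gap = 0` gives the compact postnatal packing;
3. a per-voxel *centrality score* $u = d_\mathrm{seed} / (d_\mathrm{seed} +
   d_\mathrm{edge})$ (0 at a lobule centre, 1 at the lobule edge) plus a
   smooth noise term; the medulla is the set of tissue voxels below the
   score quantile that realises `target_medulla_frac`;
4. HBs as irregular blobs: distance to a few random medullary sites plus
   smooth noise, thresholded at the quantile realising `target_hb_frac`.

Two properties follow directly from this construction rather than from
iterative adjustment: realised fractions sit within a voxel-discreteness
sliver of their targets (far inside the documented ±0.03), and raising a
target can only enlarge the selected set because the score field is fixed
before any threshold is applied (all random draws happen up front,
independent of the targets). Tissue voxels that touch background or gap
are cortex by construction, so every medulla — and therefore every HB —
is wrapped in cortex, as in the real organ.

The medulla fraction is accounted HB-inclusively,
$(V_\mathrm{med}+V_\mathrm{HB})/(V_\mathrm{cx}+V_\mathrm{med}+V_\mathrm{HB})$:
HBs are carved out of medulla, and excluding them would silently move a
phantom away from its generating target.

**Tall-organ windows.** Real scans of larger samples cover a window of a
sample that extends beyond the field of view, and quantification uses a
fixed budget of 300 central slices so that small and large samples are
compared on equal footing. `elongation > 1` reproduces this situation:
the organ's z semi-axis extends past the grid and the medulla quantile is
taken slice-wise, making the composition stationary along z. That is the
regime in which a central-300-slice measure is representative of the full
volume; a compact organ (`elongation = 1`) keeps its genuine
pole-to-centre variation.

## Materials

The refractive index is $n = 1 - \delta + i\beta$. No measured
$\delta/\beta$ values exist for critically-point-dried thymic tissue, so
`material_table()` ships plausible synthetic defaults at 35 keV chosen on
two grounds: (i) critical-point drying leaves a porous matrix with
effective density well below 1 g/cm³, so $\delta \sim 10^{-7}$ rather
than the full-density soft-tissue $\sim 4\times10^{-7}$; and (ii) the
resulting phase excursions (a few radians across the organ) keep a
single-distance experiment at 3.45 m inside the near-field regime where
single-material retrieval is meaningful — at full density a hard-edged
specimen-in-air phantom produces fringe nonlinearities that no
single-distance method can invert. Densities are ordered
HB > cortex > medulla so that reconstructed brightness matches the
observed contrast; all values scale as $\delta \propto E^{-2}$,
$\beta \propto E^{-3}$ from the 35 keV anchor and can be overridden
per label. These are documented stand-ins, not measurements.

## Forward model

`acquire()` implements a parallel-beam geometry (a synchrotron source at
~150 m is quasi-parallel): per-slice Radon line integrals of $\delta$ and
$\beta$ (ray-driven, bilinear sampling on a t-grid symmetric about the
axis so opposing views are exact mirrors), then Fresnel free-space
propagation of the complex transmission
$\exp\!\big(-\tfrac{2\pi}{\lambda}\!\int\!\beta\,dl + i\,\varphi\big)$,
$\varphi = -\tfrac{2\pi}{\lambda}\!\int\!\delta\,dl$, via the Fourier
transfer function $\exp(-i\pi\lambda z f^2)$ on a reflect-padded grid
(padding at least half the image extent per axis, to suppress
wrap-around fringes). Wavelength follows $\lambda = 12.398/E$ Å. At
$z = 0$ the Beer–Lambert contact image is returned exactly. Propagation
is simulated on a symmetric extended detector lattice and then cropped to
the requested window: diffraction happens in free space over the whole
wavefield, and the detector only samples part of it — this matters for
the edge-of-field geometry of half-acquisition scans. A guard refuses
propagation when the per-pixel Fresnel number $\Delta^2/\lambda z$ falls
below a configurable floor. Poisson noise at a stated photon count is
optional and seeded; defaults are noiseless, as the validation suite
targets method bias rather than noise response.

The default geometry is 35 keV, 3.45 m propagation, 3.5 µm pixels, and
equally spaced, endpoint-exclusive angles over 180° (or 360° with the
rotation axis offset towards the detector edge for the extended
field-of-view mode).

## Phase retrieval

Single-material, single-distance retrieval applies the low-pass kernel
$H(f) = 1/(1 + \pi\lambda z (\delta/\beta) |f|^2)$ to the normalised
intensity and takes $-\tfrac{1}{\mu}\ln(\cdot)$, $\mu = 4\pi\beta/\lambda$.
With `beta = NULL` the result is the dimensionless attenuation line
integral, the natural input to reconstruction; with a reference `beta` it
is projected thickness in µm. Padding is symmetric (reflect), appropriate
for specimen-in-air projections. $\delta/\beta = 0$ reduces exactly to
Beer–Lambert inversion.

**Automated $\delta/\beta$ selection.** The practice this replaces is
manual: adjust the ratio until the image "looks right".
`adaptive_delta_beta()` scores each candidate and returns a full score
table. The default criterion is *non-negativity of the retrieved
projected density*: an under-retrieved map carries oscillatory fringe
undershoot below zero, which no physical projected thickness can have,
while matched and over-retrieved maps are non-negative and tie at zero —
and the documented tie rule (lowest ratio wins, i.e. the least smoothing
consistent with a physical map) then rejects the over-smoothed
candidates. Two alternatives are provided with their caveats stated: an
edge contrast-to-noise (CNR) score between two user-marked regions, and
residual fringe energy above a frequency cutoff. Numerical experiments on
slab and cylinder objects, with and without Poisson noise, show both to
be monotone in the ratio under the Lorentzian kernel (the within-region
spread falls at least as fast as the contrast it normalises), so neither
can select a matched ratio from a bracketing set on its own; they remain
useful for comparing moderate candidates. This is why the default is the
positivity criterion rather than CNR.

## Reconstruction and stitching

`fbp_slice()` is standard parallel-beam filtered backprojection: each
detector row is filtered with the **discrete band-limited Ram-Lak
kernel** (the DFT of the sampled spatial kernel, $h[0]=1/4\Delta^2$,
$h[m]=-1/(\pi m\Delta)^2$ for odd $m$), zero-padded to twice the row
length, and backprojected with linear interpolation. Sampling $|f|$
directly would bias the interior of a uniform disk several percent low;
the discrete kernel recovers it to 0.05 %. Shepp-Logan filtering and
Hann/Hamming apodisation are options. Angular spans below 180° are
refused — limited-angle reconstruction is out of scope.

`halfacq_stitch()` implements the extended field-of-view scheme: a 360°
scan with the rotation axis at the detector edge is folded into a 180°
scan of roughly double width by mirroring each projection's partner at
$\theta+180°$ and joining at the axis column; any overlap is blended with
a linear ramp, and with the axis exactly on the last column the shared
axis column is counted once (output width $2W-1$). `vertical_stitch()`
merges sub-volumes acquired at different heights, averaging overlaps with
ramp weights, with an optional integer-slice offset refinement that
minimises the mean squared mismatch over the overlap.

## Segmentation

`propagate_annotations()` reproduces the sparse-annotation workflow:
label images on every *k*-th slice (default `k = 10`; the interval used in
practice is not standardised, so it is a parameter) train a random-forest
pixel classifier on handcrafted features — intensity, Gaussian-smoothed
intensity at σ = 1, 2, 4 px, and gradient magnitudes at those scales —
which then labels every unannotated slice; annotated slices pass through
unchanged, so annotating every slice reproduces the annotation exactly.
The volume is z-scored first, making the output invariant to global
affine intensity rescaling. An optional 3×3 modal filter cleans
salt-and-pepper on predicted slices. Labels with fewer than 50 annotated
pixels are dropped from training with a warning. In the pipeline the
annotations are taken from the phantom's ground-truth labels — the
synthetic stand-in for the expert's manual slices.

`segment_hbs()` is the rule-based surrogate for manual HB segmentation:
inside a medulla support mask, voxels beyond robust intensity bounds
(above the 0.99 or below the 0.01 quantile of a reference medullary
intensity) are grouped into 6-connected 3D components, components under
50 voxels are discarded, and both bright (dense) and dark (cystic) parts
of a component are kept. The quantile *reference* matters: when HBs
occupy a sizeable share of the medulla (they reach ~25 % postnatally),
quantiles taken over the HB-inclusive support land inside the HB
intensity cluster and under-segment; the pipeline therefore passes the
classifier's medulla-only mask as the reference while searching the full
support. All thresholds are exposed.

## Statistics

`wilcoxon_rank_sum()` is the two-sided rank-sum test with mid-ranks for
ties. For pooled sizes up to 12 the p-value is exact: the null
distribution of the rank sum is enumerated by dynamic programming over
the pooled (doubled) mid-rank multiset, and
$p = P(|W - \mu| \ge |w_\mathrm{obs} - \mu|)$. Larger samples use the
tie-corrected normal approximation with continuity correction. Because
the groups compared in this field sit right at that boundary (e.g. 7 vs
6), both values are computed and reported whenever the pooled size allows
(≤ 20), so the two routes can be compared; significance is flagged at
p ≤ 0.05. Group descriptives are mean ± SD with the n−1 divisor by
default (divisor exposed, since conventions differ), rounded to integer
percent in the report string. `compare_groups()` plus `tidy()`,
`glance()` and `autoplot()` give the tabular interface.

## Reproducibility plumbing

`run_pipeline()` executes the whole chain per sample and writes every
artefact (uint8 label TIFFs, 32-bit image TIFFs with offset/scale
sidecars, the quantification CSV, comparison JSON) together with the
fully-resolved configuration and a manifest of MD5 checksums. One global
seed fans out as `seed × 97 + stage offset (mod 2³¹)` to per-stage seeds,
so stages are individually reproducible without seed reuse; identical
configuration and seed give bit-identical artefacts (verified in the test
suite). TIFF float storage is quantised at 2⁻³² of the value range — the
one knowingly non-exact round-trip, far below any tolerance used here.

## Problem sizes and what the validation shows

The validation suite runs phantoms at 64³ voxels with 180 projection
angles (and a 900 × 64 × 64 phantom for the central-slice protocol),
sizes at which the full chain recovers generating medulla fractions of
0.38 and 0.22 and an HB fraction of 0.25 to within ±3 percentage points,
with cortex/medulla Dice above 0.9 from annotations every 10th slice.
These are the package's chosen study conditions: compartment contrasts
come from the synthetic material table, projections are noiseless by
default, and annotations are ground-truth slices. Passing therefore
demonstrates correctness of the *methods* — projector, propagator,
retrieval, reconstruction, stitching, measure arithmetic and test
statistics — under a faithful but idealised forward model. It does not
by itself establish performance on beamline data, where partial
coherence, detector blur and PSF, ring artefacts, annotation error and
genuinely textured tissue intervene; none of those effects are modelled
(deliberately — they are properties of instruments and annotators, not of
the measures under test).

## Known limitations

* Parallel-beam only; no cone-beam, source-size blur, or detector PSF.
* Single-material retrieval only; no multi-distance or hybrid schemes.
* `segment_hbs()` is a declared surrogate for expert manual HB
  segmentation, not a claim of equivalence with it.
* Published per-sample source tables are distributed as supplementary
  spreadsheets; the readers (`read_quant_csv()` with `col_map`) ingest
  them once exported to CSV, but the package cannot fabricate them, so
  the corresponding reproduction check remains inert until the files are
  supplied.
* The adaptive $\delta/\beta$ criterion selects within a candidate set;
  it does not estimate the ratio continuously.
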