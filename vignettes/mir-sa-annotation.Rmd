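---
title: "Spatial-autocorrelation tissue-type annotation for MIR imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial-autocorrelation tissue-type annotation for MIR imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Spatial multi-omics studies of heterogeneous cancer resections need per-pixel
tissue-type labels — which pixels are viable tumour, which are stroma,
necrosis, or normal parenchyma — before any molecular signal can be
attributed to a tissue compartment. Mid-infrared (MIR) hyperspectral
microscopy records an absorbance/transmittance spectrum (750–4000 cm⁻¹) at
every pixel of a tissue section and carries enough biochemical contrast to
annotate tissue types computationally, without staining. `mirsa` implements
an annotation workflow built on *local spatial autocorrelation* rather than
per-pixel classification: a pixel is annotated as a tissue type when it lies
inside a statistically significant spatial cluster of high intensity in that
tissue's *projection image*, not merely because its own spectrum crosses a
threshold. This buys three things: spatial context is part of the decision,
uncertainty is explicit (pixels can be claimed by several tissue types or by
none), and no large training corpus or GPU is needed.

The workflow has three phases:

1. **Discriminant wavenumber selection** — on one annotated training
   section, rank bands by random-forest permutation importance for the
   one-vs-rest task of each tissue type of interest (TTOI), then keep only
   bands that pass a specificity *error test*.
2. **Projection and hotspot mapping** — fuse the selected band images into
   one projection image per tissue type and map significant clusters of
   high intensity with the local Moran's I statistic under conditional
   permutation inference.
3. **Interdependent processing** — run the statistic cohort-wide on a
   stitched "super image" so all samples share one reference distribution,
   or calibrate a new sample against two reference samples drawn from a
   previously processed database.

## Preprocessing

Spectra are preprocessed per pixel: optional division by a background
reference spectrum, a Savitzky–Golay second derivative along the spectral
axis, and standard normal variate (SNV) scaling (subtract the per-pixel
spectral mean, divide by the per-pixel spectral standard deviation).
Second-derivative spectra are reported unit-less, as is conventional.
The derivative method is a smoothing-polynomial filter (window 9 bands,
polynomial order 3 by default) because plain finite differences amplify
noise at 4 cm⁻¹ sampling; the differentiation step is taken from the cube's
wavenumber spacing, so a pure quadratic `a·ν²` maps to the constant `2a`
(this is a unit test). Pixels whose derivative spectrum is constant have no
SNV scale; they are zeroed, flagged, and should be dropped from the tissue
mask — `preprocess_cube()` returns the flag matrix for exactly that purpose.

On-tissue masks come from 2-means clustering of a single raw band image
(default 1552 cm⁻¹, an amide-region band with strong tissue/background
contrast). Polarity is configurable: with absorbance-like data tissue is the
high-intensity cluster (the default); for transmittance data use
`polarity = "low"`.

## Feature selection

`rank_wavenumbers()` repeats, ten times by default: draw a fresh balanced
sample of 500 labelled pixels per tissue type, fit a 200-tree random forest
to TTOI-vs-rest, record each band's permutation importance. Any band ranking
in the top ten of at least one repeat becomes a candidate. The forest size
and depth are deliberately unremarkable — the ranking, not the classifier,
is the product — and ties are broken by ascending wavenumber so runs are
reproducible.

The *error test* (`error_test()`) then scans, for every candidate band, 512
cutoffs across the band's observed intensity range. For each non-TTOI tissue
type the error at a cutoff is the balanced mean of the two misassignment
fractions (non-TTOI pixels on the TTOI side, and TTOI pixels on the wrong
side) — identical class distributions score 0.5, perfect separation 0. A
band is kept iff the cutoff minimising the *worst* per-class error reaches
25% or less. The balanced-mean form was chosen over summing the two
fractions because it is the quantity the 25% threshold is naturally stated
for (one minus the balanced accuracy of the single-cutoff classifier) and it
reproduces the expected behaviour in the degenerate cases. The deterministic
grid scan replaces an unspecified iterative optimiser: it is auditable
(tests compare against brute force over every observed value) and invariant
under affine rescaling of a band, since the grid follows the data range. A
tissue type for which no band survives is reported as an explicit error —
some tissue types genuinely lack specific wavenumber features, and silence
would be the wrong behaviour.

Directions: a kept band is *ppf* (positive predictive) when the TTOI mean
exceeds the mean of all other types at that band, *npf* otherwise. Note that
the second derivative flips peaks: a band that is a distinctive absorbance
*peak* of a tissue becomes a *negative* feature after preprocessing. The
synthetic generator's truth tables record directions in preprocessed space
for this reason.

## Projection images

For each tissue type, `project_image()` computes per on-mask pixel

$$P_k = 10 + \sum_i T_k^i - \sum_j T_k^j$$

with `i` over ppf bands and `j` over npf bands of that tissue's feature set.
The +10 baseline keeps typical values positive; values are deliberately not
clipped — the spatial statistic works on relative intensities and clipping
would distort the distribution it permutes. Off-mask pixels are written as
0, which doubles as the zero-padding value during cohort stitching.

## Local Moran's I and conditional permutation

For on-mask pixels the statistic is the standard LISA form

$$I_i = \frac{z_i}{m_2} \sum_j W_{ij}\, z_j,\qquad z_i = x_i - \bar x,
\quad m_2 = \tfrac1n \sum_k z_k^2,$$

with queen contiguity (up to eight neighbours), off-mask neighbours removed
and the remainder row-standardized. Significance comes from conditional
permutation: hold the focal value fixed, draw its neighbourhood from all
other on-mask observations without replacement, 999 times by default, and
report the one-sided pseudo p-value `(count + 1)/(n_perm + 1)` — never zero,
with floor `1/(n_perm+1)`. A **hotspot** is a pixel that is significant at
the confidence level (1% by default) *and* in the high-high quadrant;
significant low-low pixels are exposed as coldspots but unused by the
annotation workflow. Isolated pixels (no on-mask neighbour) stay in the
global moments — they are observations — but receive no statistic and are
never hotspots.

Two numerical choices deserve note:

* the permutation engine (C++) keys each pixel's random stream on the master
  seed, the focal deviation's bit pattern and its neighbour count, and draws
  indices into the *sorted* pool of the other deviations. This makes pseudo
  p-values independent of traversal order, exactly invariant when image and
  mask are translated together, and exactly equal for identical samples
  stitched at different positions of a super image — properties a
  position-keyed stream cannot have. The stream is exposed internally so the
  test suite can replay the exact draws through an independent loop
  implementation and demand bit-identical p-values.
* re-thresholding at a different confidence level never recomputes
  permutations: results store the full p-value grid.

## Cohort-wide and reference-based processing

`cohort_sa()` zero-pads all projections to a common tile size and stitches
them into a near-square super image with a one-pixel padding gutter between
tiles, so queen neighbourhoods never cross samples (cross-sample adjacency
would be artefactual). Padding is off-mask: it is excluded from the mean,
the variance and the permutation pool, while the pool spans the on-tissue
pixels of *all* samples. The consequence that motivates the whole module: a
homogeneous low-intensity control processed alone produces spurious
within-sample hotspots (every sample has a relative maximum), but processed
cohort-wide its pixels sit below the cohort mean and receive essentially
none.

`build_database()` stores, per sample, the full Moran result, the hotspot
map at the database confidence level, the projection, and the
hotspot-to-total-tissue-area ratio. `reference_sa()` annotates a new sample
without recomputing the cohort: the new sample is stitched with the two
database samples of lowest and highest ratio (the low–high pair), SA runs
once on that group of three — the database's global moments are *not*
injected — and the confidence level is swept over 0.0005…0.5 in 0.0005
steps. The calibrated level

$$\alpha^* = \arg\max_\alpha \frac1m \sum_{i=1}^m IoU\!\left(R_i,
\hat R_i(\alpha)\right)$$

maximises the mean intersection-over-union between the references' group-run
maps and their database maps; ties resolve to the smallest α, and the
variant that averages the two per-reference optima is available as
`mode = "mean_argmax"`. The calibration default of 1999 permutations makes
the pseudo-p granularity (1/2000) match the α grid step. A practical
limitation worth knowing: near its optimum the IoU curve is flat, and a
permutation p-value at p ≈ 0.01 with 2000 draws has a Monte-Carlo sd of
about 0.002, so α\* is only localised to a few grid steps — the resulting
*maps*, however, are insensitive to this (self-consistency IoU ≥ 0.98 in the
package's benchmarks, which the acceptance script recomputes).

## Evaluation

`confusion_counts()` compares a binary annotation with a pathology label map
inside an evaluation rectangle intersected with the tissue mask; unlabelled
pixels are excluded. Pixels the SA stage assigned to no tissue count as
negative predictions by default (an exclusion flag exists, since the
treatment of unassigned pixels in the denominators is a genuine design
choice). Overlay pixels claimed by several tissues count as positive for
each tissue evaluated independently. Metrics are standard accuracy
`(TP+TN)/total`, balanced accuracy `(TPR+TNR)/2` and PPV `TP/(TP+FP)`;
`cohort_report()` averages standard accuracy over a sample's rectangles,
summarises across samples by median and linearly interpolated quartiles, and
pools balanced accuracy from *summed* counts rather than averaging
per-rectangle values (the two differ, and a test demonstrates it).

## The synthetic cohort generator

Real MIR cohorts are large and subject to access control, so validation runs
on seeded phantoms with known ground truth, at two levels.

`generate_cohort()` builds full spectral cubes: 64 × 64 pixels at 25 µm,
263 bands (750–1798 cm⁻¹ at 4 cm⁻¹ — the fingerprint region where
discriminant features live, kept small enough for minute-scale tests). Tissue
regions are organic blobs (argmax over smoothed Gaussian random fields) that
tile the on-tissue area, so every on-tissue pixel has exactly one true label;
a configurable fraction of samples (default 1/7) are homogeneous controls
carrying a single non-tumour tissue. Spectra are sums of shared structural
bands (amplitudes 1.5–3), one tissue-specific marker band and the other
tissues' anti-marker bands (amplitude 1), Gaussian bandwidth 8 cm⁻¹, plus
smooth baseline drift (amplitude 0.3) and iid noise (sd 0.1 — band-level
SNR ≈ 10, a realistic regime for FT-IR imaging of tissue). A per-sample
gain/offset knob exercises batch robustness qualitatively.
`punch_cores()` crops circular "digitally punched" cores (825 µm at 25 µm/px
→ 33 px diameter) to emulate needle-biopsy geometry.

`simulate_projection_cohort()` generates projection-level phantoms directly —
N(0,1) background, correlated spatial texture (sd 0.5; tissue has texture,
and texture is what makes single-sample SA err on homogeneous controls), and
organic blobs planted at +4 sd contrast — so the SA stage can be benchmarked
independently of feature selection.

What the phantoms do *not* emulate: Mie scattering and dispersion artefacts,
instrument drift within a section, co-registration error against the label
maps, and the long-tailed intensity distributions of real projections.
Passing benchmarks on phantoms therefore validates the statistical machinery
and its implementation, not clinical performance; the clinical numbers in
the literature require the corresponding raw cohorts.

## Problem sizes and determinism

The test-suite and acceptance benchmarks use 64 × 64 phantoms (6–7 samples
per cohort, 999 database / 1999 calibration permutations), 20 seeded
feature-selection runs, 50 noise fields for the false-positive benchmark and
10 cohorts for the held-out comparison — sizes chosen so a full validation
run completes in a few minutes on one core while keeping every estimate's
Monte-Carlo error well inside the asserted margins. All randomness flows
through named seeds (simulation, sampling, forests, permutations); two runs
with equal configuration and seeds produce byte-identical hotspot maps and
reports, which is itself an acceptance check.

## Known limitations

* Bands are selected per tissue type independently; no joint multivariate
  selection or multi-section training.
* α\* calibration localises the confidence level only to the Monte-Carlo
  resolution of the permutation p-values (see above).
* The ENVI reader covers the plain ASCII-header + BSQ float32 subset used
  for interchange, not vendor binary formats; atmospheric/scatter correction
  (e.g. EMSC) is out of scope.
* Co-registration of label maps to cubes is upstream: inputs are assumed
  aligned.
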