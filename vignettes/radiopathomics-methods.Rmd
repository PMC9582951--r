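---
title: "Methods: cross-scale radiomic–pathomic association analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-scale radiomic-pathomic association analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models, defaults and
numerical conventions: what each stage assumes, which knobs matter, what the
synthetic cohort generator does and does not emulate, and where genuinely
open design choices were settled.

## 1. The scientific setting

Tumours such as glioblastoma are heterogeneous at every imaging scale.
Diffusion MRI summarises microstructure indirectly — the apparent diffusion
coefficient (ADC, ~10⁻⁶ mm²/s) falls where cellularity rises, because
tightly packed cells restrict extracellular water motion — while digitised
H&E sections resolve individual nuclei. Radiomics and pathomics extract
quantitative descriptors at these two scales; the analysis implemented here
asks whether the descriptors co-vary across patients, feature by feature and
after factor-analytic compression. No predictive or survival modelling is
attempted: the target estimand is the set of cross-scale Spearman
correlations that survive false-discovery-rate control, with Bayes factors
as a complementary evidence scale.

## 2. The texture engine

`extract_features()` computes a fixed, ordered vector of 91 features:
18 first-order statistics and five gray-level matrix families (co-occurrence,
run length, size zone, dependence, neighbouring gray-tone difference) under
IBSI-style nomenclature. The GLCM family is fixed at 22 features — the
common 24-feature list minus `SumAverage` and `Dissimilarity`, which are
deterministic duplicates of `JointAverage` (×2) and `DifferenceAverage` and
would only inflate the redundancy filter's work.

Conventions that matter for reproducibility:

* **Discretization.** Fixed bin width `floor((x − min)/w) + 1` for
  quantitative maps (default w = 25 ADC units), fixed bin count (default 32
  equal-width bins, maximum assigned to the top bin) for count images. A
  constant image yields a single level under either scheme; it is not an
  error.
* **Directions and aggregation.** Chebyshev-distance-1 neighbourhoods:
  4 unique directions in 2D, 13 in 3D. GLCM matrices are symmetrised and
  normalised per direction; GLCM/GLRLM features are the arithmetic mean of
  per-direction values (not merged matrices). Directions that produce no
  valid voxel pair (e.g. a one-voxel-thick mask) are skipped; if none
  remain, the single-level conventions apply.
* **Degenerate values.** With one gray level: GLCM contrast 0, joint energy
  1, correlation 1, both information measures of correlation 0; NGTDM
  contrast/busyness/complexity/strength 0 and coarseness capped at 10⁶.
  A single-voxel mask puts all mass in the zero-neighbour dependence bucket
  (dependence variance 0). First-order skewness and kurtosis are defined as
  0 for constant input.
* **Connectivity.** Size zones use full 8-/26-connectivity — diagonal
  same-level neighbours belong to one zone. GLDM dependence size is the
  count of equal-valued neighbours plus one, so emphasis weights are
  positive.
* **First-order details.** Percentiles use the standard linear-interpolation
  definition (R type 7); variance, skewness and kurtosis are population
  moments (kurtosis not excess); entropy and uniformity use the discretized
  histogram; `TotalEnergy` scales by the voxel volume from the image
  spacing.

Every texture class is verified against an independent brute-force
enumeration oracle (naive loops over voxels, runs, flood-filled zones,
neighbourhoods) on random small 2D/3D instances to 10⁻⁹, and all features
are checked to be translation invariant and — for first-order — functions of
the in-mask value multiset only.

## 3. Radiomic and pathomic blocks

**Radiomics.** One 91-feature row per patient per modality, extracted inside
the volume-of-interest mask. ADC maps are quantitative and enter unchanged;
T1C-like images are first z-normalised over *all* voxels of the volume
(population SD), which makes the downstream features exactly invariant to
positive affine intensity transforms of the scan — binning happens after
normalization, so the T1C default bin width is 0.1 on the unit-variance
scale (the quantitative-map default of 25 would collapse a z-scored image
into one bin). Whether a quantitative map should also be normalised is a
genuine choice; here only T1C is, because normalising ADC would discard its
physical scale and the mean-ADC preliminary analysis depends on it.

**Pathomics.** Per-cell detection rows carry a 65-column schema: 7 nuclear
shape descriptors; 36 staining-intensity statistics ({nucleus, cytoplasm,
cell} × {hematoxylin, eosin, optical-density sum} × {mean, SD, min, max});
13 intranuclear Haralick features on the optical-density sum; and 9
Delaunay measurements computed from the centroids (incident-edge distance
statistics, incident-triangle areas, and cluster size / distance-to-centroid
on the Delaunay graph pruned at 50 µm — the pruning threshold is a
convention, configurable in `delaunay_features()`). Aggregation is a
two-level unweighted mean — cells to slide, slides to patient — so a slide
with many cells does not dominate a patient's value; this also makes the
aggregate invariant to duplicating cells within a slide only through the
slide mean.

**Cell-density maps.** A square tile grid (50/100/150/200 µm) is anchored at
the ROI bounding-box origin with half-open tiles `[i·r, (i+1)·r)`; the tile
count is the number of centroids inside, and a tile is *valid* when its
centre lies inside the ROI (centre rule: no double counting, no partial-tile
bias at the boundary; with ROI extents that are not close to a multiple of
the resolution, nuclei in an invalid boundary tile are deliberately
excluded). The raw integer counts are the gray values — no remapping — and
the 2D engine runs on the valid tiles with fixed-bin-count 32. The patient
block is 65 + 4 × 91 = 429 columns; density-map features are computed per
slide and averaged across slides at the feature level.

**Annotation measurements.** Per slide: nuclei count, extracellular area
(ROI minus summed cell areas, cell area reconstructed as nucleus area /
nucleus-to-cell ratio), extracellular + cytoplasm area (ROI minus summed
nucleus areas), and each normalised by ROI area. Overlapping segmentations
can push summed areas past the ROI; the remainder is clamped at zero with a
log message.

## 4. The association screen

* **Redundancy filter.** While any retained pair exceeds |Spearman ρ| > 0.9
  (the conventional threshold for pre-factor-analysis redundancy removal),
  the pair with the *largest* absolute correlation is resolved by removing
  the member with the larger mean absolute correlation against all currently
  retained features, recomputing after each removal. Which pair to resolve
  first is underdetermined by that description; largest-first plus a
  lexicographic tie-break makes the result deterministic. Constant features
  are removed up front. An explicit correlation matrix can be filtered
  directly — useful because some textbook triples (e.g. 0.95/0.6/0.3) are
  not realisable as data.
* **Spearman ρ** uses average ranks and the t-approximation for p-values
  (n − 2 df). Exact permutation p-values are deliberately not the default at
  cohort scale; at n ≈ 50 the approximation error is far below the FDR
  resolution.
* **FDR** is Benjamini–Hochberg, applied *within* each screen (ADC–pathomic
  and T1C–pathomic are separate tasks, each adjusted over all of its pairs
  jointly); q < 0.05 is called significant.
* **Bayes factor.** BF₁₀ = ∫ p(r | ρ, n) π(ρ) dρ / p(r | 0, n) with the
  exact sampling density of the correlation coefficient under bivariate
  normality (its hypergeometric term summed as a series) and a stretched-beta
  prior with κ = 1, i.e. uniform on (−1, 1). The integral is evaluated in
  log space with a max-shift before quadrature so that extreme |r| at large
  n cannot overflow; |r| within 10⁻¹² of 1 short-circuits to an infinite
  Bayes factor. Applying an r-scale Bayes factor to a rank correlation is a
  documented convention of this package, self-consistent across the screen
  rather than a claim about any particular historical implementation.
  Reported on the log₁₀ scale alongside the raw ratio.
* **Heatmap reduction.** For plotting, rows and columns without a single
  significant pair are dropped and surviving non-significant cells set to 0.

## 5. Factor-analytic compression

Blocks are z-normalised (sample SD), the correlation matrix is shrunk toward
the identity, R(λ) = (1 − λ)R + λI rescaled to unit diagonal, and λ is
chosen on a 25-point log-spaced grid in [10⁻³, 1] by 5-fold cross-validated
held-out Gaussian log-likelihood with a seeded, unstratified fold
assignment. The convex identity-target form was chosen over closed-form
eigenvalue shrinkage because its endpoints are exactly testable (λ → 0
returns the sample matrix, λ = 1 the identity) and it guarantees positive
definiteness for any λ > 0 — which in turn guarantees invertibility for the
Thomson scores. Features constant within a small training fold would make
the fold correlation undefined; they are treated as uncorrelated in that
fold.

The factor count is the first Guttman lower bound (eigenvalues of the
regularized correlation matrix strictly greater than 1) — the conservative,
assumption-free member of the Guttman family — floored at one factor and
capped at the Ledermann identifiability bound (the floor wins for p = 2,
where the bound is 0 but a single factor is still the only sensible
answer). The maximum-likelihood fit minimises
F = log|Σ| + tr(RΣ⁻¹) − log|R| − p with Σ = ΛΛᵀ + diag(ψ) by profiling Λ
out through the eigendecomposition of ψ^{-1/2}Rψ^{-1/2} and optimising ψ
quasi-Newton (L-BFGS-B) with the analytic gradient; uniquenesses are floored
at 0.005 as a Heywood guard, and convergence is declared on a gradient norm
below 10⁻⁶ (the fit is cross-checked in the test suite against an
independent ML implementation). Varimax rotation (orthogonal, Kaiser row
normalization with zero-communality rows guarded) preserves communalities
to 10⁻⁹; a deterministic sign convention (largest-|loading| entry positive)
and explained-variance column ordering make the rotated solution unique.
"Proportion of covariation retained" is defined as the mean communality
Σ(1 − ψⱼ)/p. Scores are Thomson regression scores F = Z R⁻¹ Λ using the
regularized R. Factor scores of different blocks are then screened exactly
like features.

## 6. The synthetic cohort generator

The generator replaces restricted patient data with a cohort whose
cross-scale structure is known, so calibration and power are provable rather
than asserted. Per patient, a latent tissue vector z is drawn; channel 1 is
the *shared* channel, scaled by `coupling` ∈ [0, 1], and the remaining
channels alternate radiology-only / pathology-only. All feature-generating
parameters are linear-Gaussian in z — baseline + coupling·(loading·z) +
noise — matching the factor model assumed downstream so that recovery tests
are meaningful.

* **Radiology.** An ellipsoidal VOI inside a 32 × 32 × 16 volume
  (1 × 1 × 2 mm spacing). ADC: background 800, VOI 1100 + 150·(shared
  signal), plus spatially correlated texture (Gaussian-smoothed noise,
  σ = 1.5 voxels) whose amplitude is modulated by the radiology channel, and
  white noise. T1C is built the same way and then pushed through a random
  per-patient affine intensity transform (scale e^U(−0.7, 0.7), shift
  U(−50, 200)) — so T1C analysis *must* normalise, and the test suite checks
  the features are unchanged by a second random affine.
* **Pathology.** 1–3 slides per patient. Nuclei are an inhomogeneous Poisson
  pattern: a smooth log-density clump field (25 µm grid, amplitude modulated
  by the pathology channel) around a per-patient density
  `nuclei_intensity · exp(−0.5·shared − var/2)` (mean-one multiplier), drawn
  by thinning a homogeneous pattern — simple, exact and seedable. The
  shared channel therefore *lowers* cell density as it *raises* ADC,
  reproducing the inverse ADC–cellularity relationship. Marks are sampled
  per cell: two intranuclear Haralick columns carry the shared channel
  (opposite signs), the optical-density-sum intensity columns carry a weaker
  version, nuclear circularity/eccentricity follow the pathology channel,
  and the twelve eosin columns carry *no* latent loading at all — they
  certify ground-truth null pairs even in coupled cohorts. Delaunay columns
  are computed from the generated centroids, not sampled.
* **Ground truth.** The planted pairs are the mean-level channels (ADC/T1C
  first-order mean × density-map first-order means and the two Haralick
  marks, 12 pairs with signs); `coupling = 0` makes every cross-block pair
  null and is flagged as such.
* **Seeding.** One master seed; patient k uses a fixed-offset substream, so
  growing the cohort leaves earlier patients bit-identical.

Defaults — 48 patients, coupling 0.6, noise 0.3, 1 mm² ROI at 1200
nuclei/mm² — are a desk-scale stand-in for a single-site glioblastoma
cohort: the patient count and slide multiplicity match that setting, while
the ROI area and nuclear density sit at the low end of the plausible range
so that a full study runs in seconds. What the generator does **not**
emulate: H&E pixel data (per-cell intensity/Haralick marks are sampled, not
measured from rendered nuclei), registration error between modalities,
scanner/site effects, spatial correspondence between the VOI and the
sampled tissue, and survival outcomes. Passing calibration tests on these
cohorts therefore demonstrates the *statistical machinery* is sound — not
that real ADC–histology couplings have any particular strength.

## 7. Problem sizes and runtime choices in the test suite

The calibration tests run two 200-patient cohorts (a null cohort pooling
>1000 cross-scale pairs for the realized false-discovery proportion, and a
coupling-0.9 / noise-0.1 cohort in which every planted pair must reach
q < 0.05 at |ρ| ≥ 0.4); factor recovery uses 100 replicates of a planted
three-factor model with p = 30, n = 500; the oracle-equivalence sweep uses
2D instances up to 5 × 5 and 3D instances up to 4 × 4 × 3 with at most four
gray levels; end-to-end determinism compares every output file of two
6-patient pipeline runs byte for byte. These sizes were chosen so the full
suite completes in a few minutes while keeping each statistical check
adequately powered; the calibration conditions (n = 200) are part of the
test design, not tuned to outcomes.

## 8. Known limitations

* The filter's iterative removal rule is order-dependent by construction;
  the largest-|ρ|-first rule with a name tie-break is one deterministic
  member of the family the verbal description allows.
* Bayes factors assume bivariate normality of the latent scale underlying
  the rank correlation; they are reported as evidence summaries, not used
  for any decision in the pipeline (decisions use q-values).
* The density-map centre rule can exclude nuclei falling in boundary tiles
  whose centre lies outside the ROI; with the default 1 mm ROI and the four
  standard resolutions no tile is excluded.
* At very small n (≲ 6 patients) the cross-validated penalty often selects
  full shrinkage, factor loadings collapse to zero and the factor-level
  screen degrades to an (explicitly logged) empty table.
* The run log deliberately contains no wall-clock timings — timings go to
  console messages — so that identical seeds yield byte-identical output
  trees.
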