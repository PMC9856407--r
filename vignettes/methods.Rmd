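---
title: "Methods: generative model, gating, zonal statistics and hotspot detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: generative model, gating, zonal statistics and hotspot detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mimaspat` analyzes the spatial single-cell readout of intratumoral
microdose drug-delivery assays: a microdevice reservoir releases a drug into
the tumor, the tissue is sectioned, stained by cyclic multiplex
immunohistochemistry, and every segmented cell carries an XY position (µm)
and a 0–1 mean intensity per marker. This vignette documents the model
behind each stage, the parameters that matter, and the design decisions
taken where the underlying assay leaves the choice open.

## 1. The synthetic scene generator

No public dataset accompanies this assay class, so the package ships a
generator whose defaults are the study conditions everything downstream is
tested against.

**Geometry.** The drug source sits at `source_xy` (default the origin) and
releases along `release_direction` (default `+y`). Cells occupy the *assay
band*: the rectangle ahead of the source with cross-axis half-width
`assay_band_halfwidth`, clipped to the outermost zone radius. Zones are
radial distance intervals: immediate 0–100 µm, proximal 100–400 µm, border
400–600 µm, distal 600–1000 µm, remote 1000–2000 µm. These boundaries are a
modeling choice — the assay literature describes the zones qualitatively but
never publishes numeric boundaries — chosen so that a cell ~1500 µm from the
source is remote. The half-width default is 400 µm with a density of 11,000
cells/mm²: together these land ~17,500 cells in the assay area (inside the
8,000–18,000 range typical for this assay class) while keeping ~2,100 cells in the narrow
border zone, enough to estimate border-zone fractions with useful precision.
A matched control region of equal area and expected count is placed
perpendicular to the release direction, beyond every zone (gap 200 µm), so
no control cell lies in any assay zone.

**Placement and composition.** Within the band, cells follow a homogeneous
Poisson point process; placement statistics are not available for this
assay class, so the simplest process consistent with per-ROI counts (200–500
cells per 110–220 µm circle) is used. Each cell draws its planted type from
its zone's multinomial composition. The shipped composition encodes the
panobinostat-type response: cytotoxic N1 neutrophils at 13.3% of proximal
cells; a border zone where cancer stem cells (21.1%) outnumber ICAM-1+
dendritic cells 13.2-fold (DCs at 4% with 40% ICAM-1 positivity);
galectin-3-positive non-proliferating tumor dominating the distal zone; and
sparse PD-L1 confined to the remote zone. The planted percentages for those
populations are the assay class's reported quantities; every other fraction
is an assumption and is marked as such in
`inst/extdata/panobinostat_scenario.yaml`.

**Expression model.** Marker intensities are Beta-distributed on [0, 1]:
positives from Beta(12, 4) (mode ≈ 0.79), negatives from Beta(1.5, 20)
(mode near 0). Against the default gating threshold of 0.35 each side
misclassifies with probability ≈ 5×10⁻⁴, so per-marker flags agree with the
planted truth at ≥ 99.9% and full cell types are recovered at ≥ 98% through
an 8-marker gating path. Each (cell type, marker) pair has a positive
fraction, optionally overridden per zone — the zone overrides are what make
PD-L1 peak remotely and galectin-3 peak distally, as the assay's spatial
readout requires; a purely type-level model cannot express that structure.
Remote-zone rates for clustering markers (galectin-3 in particular) are set
low enough that the remote ε-graph stays far below the continuum-percolation
threshold (mean degree ≈ 0.4 at 50 µm), which is what "no remote hotspots"
means generatively.

**What the generator does not emulate.** Staining chemistry, cycle-to-cycle
registration error, tissue folding and border effects, anisotropic or
clustered cell placement, and marker correlations beyond the planted
type/zone structure. Passing recovery tests therefore demonstrates that the
pipeline's estimators are correct under the stated model, not that the
model captures every property of real tissue.

## 2. Image quantification

Rendered fixtures follow a Beer–Lambert model with published absorbance
vectors (hematoxylin ≈ (0.65, 0.70, 0.29), AEC ≈ (0.27, 0.68, 0.68)).
Nuclei are compact discs (radius 4 µm at 0.5 µm/px); the AEC deposit spreads
1.6× wider, mirroring perinuclear chromogen diffusion — without that spread
the yellow channel censors weak signals to zero wherever the counterstain
dominates the blue channel.

AEC extraction is the standard RGB→CMYK yellow component with `Y = 0` where
`K = 1`. The nuclear channel for fixtures is a closed-form two-stain solve
of the red and blue optical densities rather than a full deconvolution.
Segmentation is Otsu thresholding, morphological opening (disc radius 2 px),
then a distance-transform-seeded watershed (tolerance 1) with objects under
50 px discarded; a blank image yields an empty mask without error. Per-object
means are plain pixel averages — tested against a per-pixel loop at 1e-12 —
and are invariant to mask relabeling.

## 3. Hierarchical gating

Positivity is strict (`intensity > threshold`; equality is negative). The
gating tree is a binary hierarchy over flags, shipped as YAML and validated
on load (unknown markers and repeated tests on one path are configuration
errors). CD45 is gated at the root so leukocytes classify independently of
their Epcam status. Assignment is fully deterministic — gate order is the
tie-break — and unmatched cells fall through to `unclassified`. The shipped
tree implements twelve standard cell types; complete type rosters vary by
antibody panel, so the tree is deliberately user-extensible and no fixed
combination count is assumed.

## 4. Zonal rates and enrichment

Rates are counts over a denominator: the group total (for combination-level
rates) or the cells of the type (for conditional questions such as
"fraction of CSCs that are calreticulin-high"). Reporting uses the
conventional strict >1% clinical threshold.

ROIs are circles with diameters uniform in 110–220 µm (capped at the zone
width), placed uniformly while remaining fully inside their zone, and
pairwise disjoint where the zone allows: overlapping ROIs share cells,
correlate the replicate rates, and measurably inflate the paired test's
type-I error (≈0.09 at nominal 0.05 in the package's own null simulation;
0.046 once disjoint). In zones too crowded for the requested count the
sampler keeps the last candidate and warns. Enrichment is a paired *t* on
per-ROI rate differences, one-tailed (assay > control) by default —
two-tailed is available for whole-assay contrasts, both exposed as flags
since the assay literature uses both. Fewer than two pairs is an error;
zero-variance differences return p = 1 with a warning rather than a
spurious rejection. No multiplicity correction is applied by default
(mirroring practice); Benjamini–Hochberg is available behind a flag.
Calibration is verified by 1,000 null simulations in which assay and
control share the background composition, at a reduced problem size
(~2,900 cells per simulated dataset on an 800 µm field) chosen so the full
generate→gate→ROI→test path runs inside each simulation.

## 5. Hotspot clustering

The cluster function takes a population's points and returns the connected
components of the graph joining pairs at Euclidean distance strictly below
`d_max` (ties at exactly `d_max` do not link); components smaller than
`min_cells` dissolve to non-clustering. `d_max` is interpreted as the
pairwise link distance — the assay description is worded both as "distance"
and "diameter" in different places; the algorithmic description ("each cell
clusters with the closest neighboring cell if the distance between the two
cells is shorter than the defined threshold") fixes the link reading, and
the defaults 30/50/75 µm with `min_cells = 10` follow that source.
Implementation is a uniform grid (cell size `d_max`) plus union-find, so
only 3×3 neighborhoods are scanned; correctness is contracted by
equivalence with a brute-force ε-graph oracle up to 2,000 points over 100
random instances. Cluster ids are a seeded random permutation (mirroring
randomized display colors); the partition itself never depends on the label
seed, and it is invariant to point order, translation and rotation.

**Treatment specificity.** A cluster is *present* in a zone when at least
`min_cells` of its members lie there; a population is treatment-specific
when some cluster is present in proximal or border and none in remote. The
alternative — classifying each cluster by its centroid — is equivalent for
compact clusters but fails descriptively for extended ones: under the
planted gradient the galectin-3+ population forms a single connected
component spanning proximal through distal whose centroid lands distally,
even though the cluster plainly occupies the proximal and border zones.
Presence semantics state what the cluster occupies; the majority zone per
cluster is still reported.

## 6. Pipeline and reproducibility

`run_pipeline()` chains generation (control matched to the realized assay
count), gating, zoning, reportable-combination selection, per-zone paired
enrichment, and multi-scale clustering with specificity verdicts. All
randomness derives from one master seed via fixed per-stage offsets; the
same configuration yields byte-identical reports, and no stage mutates an
earlier stage's table. Reports serialize to JSON/CSV without timestamps
precisely so reruns compare equal.

## 7. Known limitations

- The generator's spatial process is homogeneous within zones; real tumors
  show vasculature-driven anisotropy the hotspot statistics would pick up.
- Thresholded gating assumes the bimodal, well-separated intensity
  distributions the generator plants; real mIHC requires per-marker
  threshold calibration on control tissue and can violate separation.
- Image quantification assumes pixel-aligned channels; cycle registration
  is out of scope.
- The paired design treats ROIs as exchangeable replicates; in crowded
  zones where disjoint placement fails, residual overlap makes the test
  slightly anticonservative.
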