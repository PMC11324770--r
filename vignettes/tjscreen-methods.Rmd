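---
title: "tjscreen: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tjscreen: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The assay being modelled

Inhaled small molecules can injure the airway epithelium, and the earliest
common lesion is loss of the epithelial barrier. The barrier is held
together by tight-junction proteins; occludin in particular forms the
familiar "cobblestone" staining pattern at cell-cell contacts in confluent
alveolar epithelial (A549-like) monolayers. A high-content imaging assay
quantifies the *area of occludin staining at the cell membrane*, normalised
to cell number and to vehicle (DMSO) controls, across a 9-point
concentration series (100 µM down to 15 nM, 3-fold steps). Compounds that
erode the junctional signal in a concentration-dependent way are flagged as
respiratory irritancy risks and ranked by IC50; coupling the IC50 with a
physiologically based model of where an inhaled dose actually lands in the
lung turns the hazard call into a quantitative risk assessment.

`tjscreen` implements that whole chain as testable software: a seeded
synthetic-image generator standing in for the microscope, the membrane /
junction quantification algorithm, dose-response fitting with Cooper
predictivity statistics, and a generation-resolved lung PBPK simulator.

## Synthetic monolayer fields

`generate_field()` renders one three-channel field (nuclei, whole-cell
"cell mask", junction) plus pixel-level ground truth:

* **Geometry.** Cell bodies are the Voronoi tessellation of
  rejection-sampled nucleus centers with a minimum separation of twice the
  nucleus radius — the cheapest construction that produces the cobblestone
  geometry. The 1-px inter-cell boundary ("membrane skeleton") uses a
  right/down half-boundary convention so boundaries are single-pixel
  curves; boundary tests use 4-connectivity and components 8-connectivity
  throughout the package, which keeps the geometry tests bit-exact.
* **Channels.** Nuclei are Gaussian blobs; the whole-cell channel is
  uniform cytoplasm with the membrane rendered as a *dim 1-px ridge*
  (`membrane_dip` below `cytoplasm_level`), which is what makes the
  analysis pipeline's inversion step meaningful. The ridge is deliberately
  not widened: a wider dim band leaves the seeded watershed boundary
  ambiguous inside the ridge and costs the 1-px outline agreement.
* **Junction degradation.** The junction channel carries signal on a
  subset of membrane *segments* (one segment per shared cell-cell edge)
  totalling `junction_integrity` of the skeleton length, dilated by 1 px.
  Selection is spatially clustered: the retained set grows as contiguous
  patches over the edge-adjacency graph. Junction loss in a degrading
  epithelium is patchy rather than salt-and-pepper, and the clustered
  geometry also keeps the measured staining area proportional to the true
  retained length (independently scattered short segments would inflate
  the area measurement through the end-caps of each dilated piece).
* **Cytotoxicity and noise.** Cell loss removes whole cells before
  tessellation (`round(n_cells * (1 - cell_loss_fraction))`). Additive
  Gaussian noise is applied last and clipped at zero. No Poisson shot
  noise, point-spread function, illumination gradients or 3D growth are
  modelled; the segmentation tests showed the additive model is already
  sufficient to exercise every failure mode the quantifier guards against,
  and those optics effects are irrelevant to the algorithm contracts.

**Default scale.** No instrument pixel size or bit depth is prescribed
anywhere, so both are generator configuration. The defaults emulate a 40×
objective on a fine camera grid: 0.16 µm/px, 16-bit intensities, 256×256 px
fields containing ~5 cells of ~18 µm diameter. The important ratio is cell
size to analysis band width: the quantification grows a ±10 px band around
every membrane, and if cells are only a few band-widths across, the bands
from opposite edges of one cell overlap and the measured area saturates,
decoupling it from the true junction length. At the default scale cells are
~7 band-widths across and the measured junction area tracks ground-truth
integrity to within a few percent (the integrity-0.5 field measures
0.52 ± 0.04 of its full-integrity sibling).

**Seeding.** Every stochastic step derives from one master seed through a
counter-based splitting scheme (`derive_seed(master, well, field)`), so
a single field is regenerable in isolation and a whole plate is
bit-reproducible. Generation saves and restores the caller's RNG state.

Plates follow the screening layout: 9-point 3-fold series from 100 µM,
duplicate or triplicate treated wells, vehicle wells on every plate, 16
fields per well. `simulate_plate()` drives per-well ground truth from Hill
curves: junction integrity `1/(1+(c/IC50)^h)` and cell survival
`1/(1+(c/EC50)^h)`.

## The quantification algorithm

`field_metrics()` chains four steps, mirroring a high-content module
pipeline:

1. **Nuclei** (`count_nuclei`): Gaussian smooth (σ = 2 px) → global Otsu
   threshold → drop components outside [20, 2000] px → split touching
   blobs by a distance-transform watershed (neighbourhood radius =
   `min_separation_px`). A constant image counts zero nuclei, it is not an
   error.
2. **Membranes** (`segment_membranes`): the whole-cell channel is
   *inverted* (max − value) so dim membranes become bright ridges, then
   flooded from the nuclei labels by marker-controlled region growing
   (EBImage's `propagate`, λ = 1e-4, i.e. intensity-driven with a distance
   tie-break). Inter-label boundary pixels give the 1-px outline; a
   Euclidean disk of radius 10 ("10 pixels on either side") grows it into
   the analysis band. Boundaries with the image frame are *not* outlines by
   default — only membrane shared between two cells carries tight
   junctions — with a configuration flag to include them.
3. **Junctions** (`junction_band`): the junction channel is specific
   enough that no inversion is needed: Otsu threshold → remove specks
   < 10 px → skeletonize (Zhang–Suen thinning) → dilate by the same disk.
   A threshold-then-dilate variant sits behind
   `quantify_params(junction_mode = "dilate")` since either reading of
   "assessed in a similar manner" is defensible. The Otsu threshold is
   additionally required to clear a robust background floor
   (median + 8·MAD of the channel): a global two-class threshold collapses
   into the noise on fields with little or no junction signal, and the
   floor — scale-invariant like the threshold itself — is what keeps
   high-concentration wells from reporting spurious staining.
4. **Metrics**: membrane area = stained pixels (Otsu on the whole-cell
   channel) inside the band; junction-at-membrane area = junction-band
   pixels inside the membrane band; both × pixel-area in µm², totalled
   over the image.

All thresholds operate on max-normalised intensities, so every mask — and
hence every area — is invariant to rescaling all intensities by a positive
constant. Halving the pixel size (same pixel content) divides µm² areas by
4 and leaves per-cell fold changes unchanged.

**Well aggregation.** Per-cell values are the ratio of means over the
well's fields (mean area / mean nuclei count), not the mean of per-field
ratios: the ratio of means stays stable when an individual field has few
cells. The mean-of-ratios convention is available via
`quantify_params(normalization = "mean_of_ratios")`. A well with zero mean
nuclei count has undefined per-cell metrics — flagged, never silently NaN.

## Dose-response and predictivity

`normalize_to_vehicle()` expresses treated wells as fold change over the
plate's vehicle mean (junction area per cell for the barrier endpoint,
nuclei count for viability — reported in parallel, never mixed).

`fit_ic50()` implements two methods:

* **loglinear** (default, matching the linear-regression convention of
  screening IC50s): responses regressed on log10 concentration over the
  points bracketing the 0.5 crossing (minimum 3 points, one extra point on
  each side of the bracketing pair), solved for response = 0.5.
* **fourpl**: bounded least squares (L-BFGS-B, multi-start over the slope)
  of a four-parameter logistic with top near 1 and bottom ≥ 0; the
  reported IC50 is the concentration where the fitted curve crosses an
  absolute response of 0.5, for consistency with the loglinear rule.

**Establishment rule.** No published rule exists for when an IC50 "could be
established", so the package adopts the simplest one that reproduces the
observed pattern — including compounds with only minor effects at the top
concentration yielding no curve: an IC50 is established iff the mean
normalized response reaches ≤ 0.5 somewhere within the tested range.
`classify_compound()` is POSITIVE exactly when an IC50 is established
(a crossing exactly at the highest tested concentration is in range, hence
POSITIVE). Degenerate shapes are handled explicitly: multiple crossings
take the lowest-concentration crossing (flagged); a response already below
0.5 at the lowest concentration pins the IC50 to the range minimum
(flagged); estimates outside the tested range are clamped to it (flagged).

`cooper_statistics()` computes sensitivity, specificity and accuracy from
the binary calls against a truth annotation; an empty truth class flags the
corresponding ratio as undefined rather than dividing by zero.
`per_concentration_test()` is the pooled-variance two-sided Student's t per
concentration, computed from the textbook formula (cross-checked against
`stats::t.test` in the test suite); p-values are deliberately left
unadjusted across the 9 concentrations, and the output records that.

The package ships `validation_compounds()`: 19 inhaled small molecules with
respiratory-risk annotation (10 risk / 9 clean) and the assay IC50 where a
curve could be established. On that table the calls give 90% sensitivity,
100% specificity, accuracy 18/19, with established IC50s spanning
2.1–46.7 µM.

## Lung PBPK

`simulate_lung()` integrates a generation-resolved disposition model:
24 airway generations (1 = trachea; 1–16 tracheobronchial, 17–24 alveolar),
each with an epithelial-lining-fluid (ELF), epithelium and sub-epithelium
compartment, and a volume-less "deep" binding compartment (first-order
`k_in`/`k_out`) inside each tissue. Fluxes, in amount units (nmol, mL, h):

* **Dissolution** (solid formulations): Nernst–Brunner,
  `(D/h)·A·(Cs − C_elf)`, with A the surface of `n` monodisperse shrinking
  spheres fixed at dosing. Supersaturation clips the rate at zero — no
  precipitation modelling — and the run records that it happened.
* **Mucociliary clearance** (tracheobronchial only): first-order transfer
  of dissolved *and* undissolved ELF content one generation up; the
  trachea empties into a swallowed sink that is removed, not reabsorbed —
  conservative for lung exposure.
* **Permeability**: bidirectional `P·SA·(C_elf − Cu_epi)` with no
  non-specific binding in the ELF (ELF unbound = total); alveolar
  permeability is 10× the tracheobronchial value by default.
* **Tissue exchange**: epithelium ↔ sub-epithelium via the same
  permeability (configurable factor); tissue unbound concentrations use
  `Kpu = Kp/fu_plasma`.
* **Perfusion-limited systemic exchange**: the tracheobronchial wall is
  perfused by the bronchial blood flow (default 1% of cardiac output), the
  alveolar region by the entire cardiac output, each distributed across
  generations at constant flow per tissue volume; plasma is a
  one-compartment model with CL and Vss.

Deposition defaults to 70% tracheobronchial / 30% alveolar, split within
each region proportionally to surface area; the remainder of the dose is
swallowed immediately (extra-thoracic). Deposition physics (MMAD →
fractions) is out of scope — fractions are inputs, as is parameter
estimation against in vivo PK: the simulator consumes given parameters.

**Numerics.** `deSolve::lsoda` at relative tolerance 1e-8; mass balance
(lung + plasma + cleared + swallowed vs dose) is asserted at every output
time to 1e-6 relative; materially negative states abort with an error
rather than being clipped. In the single-generation permeability-only
limit the ELF profile matches `C0·exp(−P·SA/V·t)` to better than 1e-6.

**Default morphometry.** The shipped table
(`default_airway_morphometry()`) is a scalable Weibel-like dichotomous
tree — 2^(g−1) airways per generation with geometrically shrinking
dimensions, ELF/epithelium thicknesses tapering down the tree, mucus
velocity over generation length as the mucociliary rate (zero in the
alveolar region), alveolar surface area two orders of magnitude above
tracheobronchial. It is a structurally plausible default, not a measured
morphometry, and every value is overridable. Consequently the simulator's
regional Cmax values are *qualitatively* meaningful (upper-airway peak
exposure well above alveolar at default deposition) but are not a
reproduction of any particular published animal study, which would require
the fitted compound- and species-specific parameters.

`elf_region_summary()` reduces profiles to regional Cmax using
ELF-volume-weighted means over member generations (upper TB = generations
1–6, lower TB = 7–16, alveolar = 17–24), and `map_exposure_to_ic50()`
joins them to the in vitro curve: exposure ratio Cmax/IC50, predicted
response at Cmax, and an at-risk flag at Cmax ≥ 0.5·IC50 — the fraction at
which airway pathology co-occurred with ELF exposure in the motivating use
case (regional Cmax ≈ 14 µM against an IC50 of ~28 µM).

## Problem sizes and what the tests show

The suite validates the pipeline at deliberately miniature scale so it
runs on one CPU in minutes:

* Unit tests use 128 px fields with ~4 cells.
* The IC50 recovery study simulates one plate per condition over a grid of
  true IC50 ∈ {2, 10, 30} µM × Hill ∈ {1, 2}, triplicate wells per
  concentration, 16 fields/well at 256×256 px (plus a flat plate with the
  true IC50 far above the range, which must return no established curve).
  Median recovered-IC50 relative error is ~12%, within the 15% the
  package commits to; steep (Hill 2) curves recover within a few percent,
  shallow ones are noisier.
* Segmentation is compared exhaustively to generator ground truth on
  noiseless fields of 10–50 cells: ≥99% label agreement outside a 2-px
  boundary collar, and the detected 1-px outline sits within 1 px
  (8-neighbour) of the true skeleton. The grown band of an isolated pixel
  equals the brute-force enumerated 317-point digital disk of radius 10.

Passing on synthetic fields shows the algorithm implements its contracts
and recovers known ground truth under additive noise; it does not certify
performance on real micrographs, whose illumination artifacts, focus
variation and staining heterogeneity the generator intentionally omits.

## Known limitations

* The generator's phenotype is geometric; it does not emulate cytoplasmic
  occludin relocalisation, which in real images dims rather than removes
  junction signal.
* The loglinear IC50 inherits the local-window sensitivity of any
  piecewise method; for steep curves the 4PL route is preferable and both
  are reported with diagnostics.
* The PBPK default morphometry is human-like in scale and shape; regional
  quantitative predictions require measured morphometry and fitted
  compound parameters supplied by the user.
* Solubility in the ELF is a single constant; no mucus binding, surfactant
  solubilisation or pH dependence.
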