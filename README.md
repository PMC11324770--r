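# tjscreen

Tight-junction high-content screening, simulated end to end: synthetic
epithelial monolayer imaging with ground truth, membrane/junction
quantification, dose–response IC50 estimation with Cooper predictivity
statistics, and a generation-resolved lung PBPK simulator that maps
epithelial-lining-fluid (ELF) exposure onto the in vitro dose–response
curve.

## Who this is for

Discovery-safety and imaging-informatics groups who quantify epithelial
barrier integrity by the **area of occludin staining at the cell membrane**
in confluent alveolar epithelial monolayers, and who want the whole chain —
image → per-well metric → IC50 → lung-exposure risk call — as seeded,
testable software. Because no public image set accompanies this kind of
assay, the package includes a first-class synthetic-plate generator whose
ground truth makes every stage of the analysis verifiable.

## The science in brief

**Quantification.** Per field: nuclei are segmented and enumerated
(smooth → Otsu → area filter → distance-transform watershed split); the
whole-cell channel is *inverted* so dim membranes become bright ridges and
flooded from the nuclei seeds (marker-controlled watershed), giving a 1-px
outline of all cell membranes, grown by a Euclidean disk of radius 10 px
("10 pixels on either side"); the junction channel is thresholded,
skeletonized and grown the same way; the junction area inside the membrane
band, `A_junc∩mem` (µm², total per image), is the barrier readout. Per
well (16 fields): fold change over vehicle of

```
junction area per cell = mean_fields(A_junc∩mem) / mean_fields(nuclei count)
```

**Dose–response.** Response r(c) vs the 9-point series (100 µM → 15 nM,
3-fold); an IC50 is *established* iff r reaches ≤ 0.5 in range, solved from
a local regression of r on log10 c around the crossing (or a bounded 4PL);
POSITIVE call ⇔ established. Cooper statistics (sensitivity, specificity,
accuracy) score the calls against a bundled 19-compound validation
annotation.

**Lung PBPK.** 24 airway generations (1–16 tracheobronchial, 17–24
alveolar) × {ELF, epithelium, sub-epithelium (+ deep binding)}:
Nernst–Brunner particle dissolution `(D/h)·A·(Cs − C_elf)`, mucociliary
transport toward the trachea (swallowed sink), permeability flux
`P·SA·(C_elf − Cu_epi)` (alveolar P = 10× TB), perfusion-limited systemic
exchange (bronchial flow for TB, cardiac output for alveoli), plasma CL/Vss.
Regional ELF Cmax (upper TB 1–6, lower TB 7–16, alveolar 17–24) is mapped
onto the fitted curve as exposure ratio Cmax/IC50.

## Worked example

Simulate one screening plate for a compound with true junction IC50
10 µM, quantify it field by field, fit the curve, then ask whether an
inhaled 100 µmol dry-powder dose would expose any lung region near the
IC50:

```r
library(tjscreen)

layout <- plate_layout(compound_id = "CPD1", replicates = 2, n_vehicle = 2)
res <- simulate_and_analyze_plate(
  layout,
  pharmacology = list(junction_ic50_um = 10, junction_hill = 1,
                      viability_ec50_um = 400, viability_hill = 1),
  base_spec = monolayer_spec(), fields_per_well = 8, seed = 1)

responses <- normalize_to_vehicle(res$well_table)
fit <- fit_ic50(responses$concentration_um, responses$response,
                compound_id = "CPD1")
fit
#> ic50_fit [CPD1] (loglinear): IC50 = 10.9 uM
#>   9 concentrations, 0.0152 - 100 uM; response range 0.0619 - 1.02
classify_compound(fit)
#> [1] "POSITIVE"

sim <- simulate_lung(build_lung_model(compound = compound_params()),
                     dose_event(1e5), t_end_h = 24)
regions <- elf_region_summary(sim)
regions
#>     region   cmax_um tmax_h
#> 1 upper_tb 49.782671    5.9
#> 2 lower_tb 49.504219    0.5
#> 3 alveolar  3.472288    0.1
map_exposure_to_ic50(regions, fit)
#>     region   cmax_um  ic50_um exposure_ratio predicted_response at_risk note
#> 1 upper_tb 49.782671 10.85834      4.5847390          0.1940853    TRUE
#> 2 lower_tb 49.504219 10.85834      4.5590950          0.1951480    TRUE
#> 3 alveolar  3.472288 10.85834      0.3197806          0.7352382   FALSE
```

Reading: the recovered IC50 (10.9 µM) is within ~9% of the generator's
truth; at this dose both tracheobronchial regions peak well above the
IC50 (exposure ratio ≈ 4.6, predicted junction signal down to ~0.2 of
control) and are flagged at risk, while the alveolar region stays below
half the IC50. The default morphometry is a scalable Weibel-like tree —
regional numbers are qualitative until you supply measured morphometry and
fitted compound parameters.

A command-line interface over the same functions ships at
`system.file("cli", "tjscreen", package = "tjscreen")` with subcommands
`simulate-plate`, `analyze-plate`, `fit-dose-response`, `cooper`,
`pbpk-simulate`, `risk-map`, `run-all` (`--seed`, `--version`,
`--log-level` on each; exit codes 0/2/3 for ok/validation/runtime).

The bundled validation table (`validation_compounds()`,
`inst/extdata/validation_compounds.csv`) lists 19 inhaled compounds with
respiratory-risk annotation and, where a curve could be established, the
assay IC50; on it the binary calls score 90% sensitivity / 100%
specificity (accuracy 18/19).

See `vignettes/tjscreen-methods.Rmd` for the model assumptions, parameter
meanings and numerical choices.

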