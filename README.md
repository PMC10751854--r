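# lafat

Quantification of left atrial (LA) intramyocardial fat infiltration from
contrast-enhanced cardiac CT, for imaging researchers studying the substrate
of atrial fibrillation.

Fat attenuates X-rays less than myocardium, so adipose tissue infiltrating
the thin LA wall appears as voxels of reduced radiodensity between the
endocardial and epicardial shells. Given a HU-calibrated CT volume and the
two triangulated shells, `lafat` computes:

* **LAWT maps** — wall thickness at each endocardial vertex as the distance
  to its projection on the epicardial shell, binned with the standard colour
  scale (red < 1 mm, 1 ≤ yellow < 2, 2 ≤ green < 3, 3 ≤ blue < 4,
  purple ≥ 4 mm);
* **inFAT maps** — threshold segmentation of the inter-shell wall
  compartment: inFAT = HU ∈ [−194, −5], split into dense inFAT
  [−194, −50] and fat–myocardium admixture (−50, −5], after excluding the
  appendage, the mitral valve and pulmonary veins > 5 mm from their ostia;
  volumes (mL), per-class mean HU, and six normalized metrics (per LA cavity
  volume and per segmented wall volume);
* **19-segment regional analysis** — anatomical parcellation of the shell
  (posterior wall 1–4, floor 5–6, septum 7, anterior wall 8–11, left lateral
  wall 12, carinae 13–14, PV antra 15/16/18/19, ridge 17), with each
  segment's relative inFAT percentage (segment fat / total fat) and regional
  volume percentage (segment wall / total wall);
* **cohort statistics** — mean±SD or median (IQR) summaries gated by
  Shapiro–Wilk, ANOVA / Kruskal–Wallis / chi-squared omnibus tests,
  Bonferroni-corrected pairwise post-hoc tests, and BMI-adjusted ANCOVA
  (type-II), for three-arm control / paroxysmal AF / persistent AF designs.

Because patient scans cannot be redistributed, the package ships a synthetic
phantom generator (`phantom_spec()`, `make_phantom()`, `plant_fat()`,
`make_cohort()`) producing CT volumes with analytic two-shell LA-like
geometry, planted fat deposits of known volume/HU/location, and seeded
cohort tables — every downstream number has ground truth.

## Worked example

Generate an LA-like phantom (1 mm voxels, 10 HU noise), plant 0.20 mL of
dense fat in the LSPV antrum (segment 16) and 0.25 mL of admixture in the
anterior wall (segment 9), then run the mapping stages:

```r
library(lafat)

spec    <- phantom_spec("la_like", spacing = 1.0, noise_sd = 10, seed = 42)
phantom <- make_phantom(spec)
phantom <- plant_fat(phantom, 0.20, "dense",     segment = 16)
phantom <- plant_fat(phantom, 0.25, "admixture", segment = 9)

wall    <- build_wall_mask(phantom$ct, phantom$truth$endo, phantom$truth$epi,
                           landmarks = phantom$truth$landmarks)
tm      <- compute_lawt(phantom$truth$endo, phantom$truth$epi)
classes <- classify_fat(phantom$ct, wall)           # default HU thresholds
metrics <- compute_metrics(classes, phantom$ct, wall, endo = phantom$truth$endo)
seg     <- parcellate(phantom$truth$epi, phantom$truth$landmarks)
labels  <- label_wall_voxels(seg, wall, phantom$ct)
reg     <- regional_distribution(classes, labels, wall)
```

Output (this exact run):

```
wall mask: 22312 voxels between shells (22.31 mL)
exclusions: removed 3570 voxels (appendage/MV/distal PV); 18742 remain

  infat_ml dense_ml admix_ml dense_hu admix_hu la_vol_ml wall_vol_ml infat_lavol_au
1    0.447    0.202    0.245 -77.4209 -25.8747  101.9013      18.742         0.0044

   label                           name infat_ml rel_infat_pct regional_vol_pct
9      9 anterior wall (superior-right)    0.247      55.25727         9.774837
16    16                    LSPV antrum    0.200      44.74273         4.268488
```

The planted 0.20 / 0.25 mL deposits are recovered as 0.202 / 0.245 mL
(classification leakage across the −5 HU bound at 10 HU noise accounts for
the admixture deficit), the per-class mean radiodensities reflect the
planted HU ranges, and the regional distribution localises 44.7% / 55.3% of
the fat to the two planted segments (truth: 44.4% / 55.6%). `run_patient()`
wraps these stages and writes `patient_metrics.csv`, the 19-row
`segments.csv`, `thickness.csv` and a `config_echo.json` audit of the
thresholds; `run_cohort()` writes the three-group comparison tables. A thin
command-line front end with `phantom` / `map` / `cohort` subcommands is
installed at `inst/cli/lafat`.

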