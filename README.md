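# dualphasepet

Simulation and analysis toolkit for **dual-phase dynamic SV2A PET**
alongside static FDG PET, aimed at methods work on lesion detection in
unilateral focal epilepsy.

Dynamic PET with a synaptic vesicle glycoprotein 2A (SV2A) tracer carries
two signals: the first minutes after bolus injection reflect tracer
delivery (a perfusion-like image, spatially similar to FDG hypometabolism),
while the 30–60 min frames reflect specific SV2A binding and hence synaptic
density. This package implements the full computational workflow for
studying that duality — and, because no patient data ship with it, a
synthetic cohort generator with known ground truth drives every analysis:

- **Phantom simulation** — a left–right symmetric digital brain phantom
  (multi-sector cortex, subcortical structures, centrum semiovale, pons,
  blood pool), one-tissue-compartment kinetics
  (dC_T/dt = K1·Cp − k2·C_T, V_T = K1/k2) with a parametric bolus-plus-tail
  input function, pharmacologic target blockade (occupancy scales V_T via
  k2 inflation, leaving the first pass untouched), unilateral lesions with
  a broad perfusion/metabolic extent and a tighter synaptic core, Gaussian
  PSF blur at the intrinsic scanner resolution (6.6 × 6.6 × 5.1 mm), and
  frame-duration-scaled noise.
- **Imaging core** — frame-schedule arithmetic, SUV conversion, windowed
  averaging, SUVR with selectable reference regions, NIfTI-1 I/O.
- **TAC analysis** — regional time–activity curves, peak characterisation,
  blocked-vs-unblocked group comparison (Welch t tests, Holm–Šidák).
- **Cross-tracer correlation** — framewise Pearson correlation of the
  dynamic signal against static FDG, with imaging-window selection.
- **Asymmetry mapping** — smooth, flip across the midline, voxelwise
  percent difference Δ% = 100·(I − I_mirror)/I_mirror, cortical masking,
  −8 % thresholding, most-affected-90 % retention, lesion severity (mean
  Δ%) and volume (mL), kernel sweeps, and quadrature resolution arithmetic
  (√(intrinsic² + kernel²)).
- **Kinetics** — Logan graphical V_T from an (image-derived) input
  function, reference-tissue Logan DVR, and static-vs-kinetic agreement.
- **Reporting** — one-way ANOVA + Tukey HSD across modalities, pairwise
  cross-modality correlations, CSV/markdown reports, and a deterministic
  `run_pipeline()` orchestrating simulate → windows → stats → asymmetry →
  kinetics → report with an MD5 manifest.

## Worked example

Generate a 29-subject cohort (21 unblocked, 8 on SV2A-binding medication)
at desk scale and compare the groups per region and analysis window:

```r
library(dualphasepet)

sched <- parse_frame_spec("12x5,6x10,3x20,7x60,4x300,3x600")
sched
#> <frame_schedule> 35 frames, 3600 s total (60.0 min)

cfg <- cohort_config(n_unblocked = 21, n_blocked = 8,
                     grid_shape = c(48, 48, 40), voxel_size_mm = 4)
coh <- generate_cohort(cfg, seed = 1, render = "tac")
coh
#> <cohort> 29 subjects (8 blocked), 32 regions, 35 frames

tacs <- collapse_tissue(cohort_tac_table(coh), coh$atlas)
blocked <- setNames(coh$truth$blocked, coh$truth$subject)
cmp <- compare_groups(tacs[tacs$region != "blood", ], blocked)
subset(cmp, window == "late", c(region, percent_change, raw_p, adjusted_p))
#>               region percent_change  raw_p adjusted_p
#> 8      basal_ganglia          -51.9 0.0049      0.024
#> 9  centrum_semiovale            9.4 0.6247      0.625
#> 10        cerebellum          -53.5 0.0038      0.023
#> 11            cortex          -51.6 0.0096      0.029
#> 12              pons          -25.5 0.1958      0.353
#> 13     temporal_lobe          -54.6 0.0030      0.021
#> 14          thalamus          -52.2 0.0060      0.024
```

Target blockade halves the late-window signal in gray matter (−52 % in
cortex here, significant after Holm–Šidák adjustment), while the
centrum semiovale — modelled as 90 % nondisplaceable — is untouched, which
is what qualifies it as the late-phase reference region. The early window
(not shown) has no significant group differences: the first pass is
delivery-dominated.

Resolution arithmetic and correlation inference behave like the field
expects:

```r
effective_resolution(c(6.6, 6.6, 5.1), 8)   # 8-mm filter on intrinsic PSF
#> [1] 10.37111 10.37111  9.48736
pearson_p(0.70, 21)
#> [1] 0.0004112939
pearson_p(0.14, 21)
#> [1] 0.5450003
```

The full pipeline — rendered NIfTI volumes, TAC extraction, framewise
correlation with window selection, per-subject asymmetry maps and lesion
metrics for FDG / early / late, Logan kinetics from the image-derived input
function, and the cross-modality report — runs from one configuration:

```r
config <- pipeline_config(cohort = cfg, seed = 1)
run_pipeline(config, "out/")        # writes a manifest of all artifacts
```

A thin command-line front end is installed at
`inst/cli/dualphase-pet.R`
(`dualphase-pet.R all --config cfg.yaml --out DIR --seed 1`, plus
`simulate`, `window`, `suvr`, `asymmetry` subcommands).

## Documentation

The methods vignette (`vignettes/dual-phase-sv2a-pet.Rmd`) describes the
kinetic model and its calibration, the lesion model, all tunable
parameters with units and defaults, the numerical choices, and what the
synthetic cohorts do and do not emulate about real data.
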