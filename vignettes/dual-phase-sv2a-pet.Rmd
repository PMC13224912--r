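---
title: "Simulating and analysing dual-phase SV2A PET"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing dual-phase SV2A PET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualphasepet)
```

## The problem

Dynamic PET with an SV2A (synaptic vesicle glycoprotein 2A) tracer carries
two distinct biological signals: the first minutes after bolus injection are
dominated by tracer delivery and behave like a perfusion image, while the
late frames reflect specific binding to SV2A and hence synaptic density. In
focal epilepsy this duality is attractive — the early phase resembles the
hypometabolic/hypoperfused pattern that interictal FDG PET shows around an
epileptogenic zone, while the late phase delineates the synaptic lesion core
with higher contrast. `dualphasepet` implements the computational workflow
for this kind of study: framewise cross-tracer correlation to select the two
imaging windows, reference-region scaling, mirrored-subtraction asymmetry
mapping with smoothing optimisation to detect unilateral lesions, and
graphical kinetic modelling to validate the static late-phase measures — all
driven by a synthetic cohort generator with known ground truth, so every
step is testable without patient data.

## The phantom and its kinetics

The digital phantom (`build_phantom()`, `default_phantom_spec()`) is a
left–right symmetric label volume on a 96 × 96 × 80 grid of 2-mm voxels
(desk-scale: under a minute per rendered subject, while still supporting
8-mm smoothing). It contains a cortical shell split into 10 angular sectors
per hemisphere (emulating a multi-region cortical atlas), paired temporal
lobe, basal ganglia, thalamus, cerebellum and centrum semiovale, a midline
pons, and a midline venous blood pool used for image-derived input
functions. Paired structures are painted on the right and mirrored exactly,
so flipping the volume along the first axis and swapping left/right labels
is an identity — the property the asymmetry analysis relies on.

Tissue kinetics follow the one-tissue compartment model

$$\frac{dC_T}{dt} = K_1 C_p(t) - k_2 C_T(t), \qquad V_T = K_1/k_2 ,$$

which is sufficient to reproduce all of the qualitative dynamic-phase
phenomenology (rapid influx, single peak, continuous washout) while keeping
the Logan estimates exactly interpretable in the noise-free limit. The
plasma input \(C_p\) is a gamma-variate bolus (peak at 0.75 min) plus a
biexponential tail (fractions 0.04/0.015 of the bolus peak, half-lives 5
and 45 min) that switches on over the bolus rise, so \(C_p(0) = 0\) and the
tail decays monotonically. The tail fractions were fixed once, at design
time, so that the three group-level phenomena the emulated study reports
are jointly realisable under one parameterisation: an unblocked cortical
peak near 4 min, a blocked peak near 2.7 min, and a late-window (30–60 min)
cortical signal reduction of roughly one half under blockade.

Pharmacologic blockade with occupancy \(o\) removes a fraction \(o\) of the
available binding: it is applied as \(k_2 \to k_2/(1-o)\), which scales
\(V_T\) by \(1-o\) while leaving the first-pass influx \(K_1 C_p\)
unchanged — early-phase signal is preserved by construction, matching the
observation that treated patients show no early-phase group difference.
Each region carries a *specific fraction* that scales its effective
occupancy; the centrum semiovale is modelled as 90 % nondisplaceable
signal, which makes it nearly blockade-insensitive and therefore suitable
as the late-phase reference region.

### Subject-level parameter draws

Each subject draws a cortical peak SUV and peak time from the arm-specific
normal distributions (unblocked 7.4 ± 1.6 SUV at 4.0 ± 0.7 min; blocked
6.4 ± 2.3 at 2.7 ± 0.8 min), and the generator inverts the noise-free
model: \(k_2\) is solved so the simulated curve peaks at the drawn time,
then \(K_1\) is scaled to the drawn peak SUV. Peak-time draws are truncated
at roughly ±2.25 SD (blocked 1.5–4.5 min, unblocked 2.0–7.0 min) because
the peak-time-to-washout inversion is steep near the bolus: unconstrained
tails would imply washout half-lives of about two minutes and a nearly
empty late image, which the uniformly strong late-phase statistics of the
emulated study rule out. Blocked subjects additionally draw a pre-blockade
baseline peak time from the unblocked distribution; the occupancy is the
value implied by the two calibrated washout rates, rejection-sampled into
0.30–0.85 (regional blocking of roughly 40–75 % is the plausible range
under SV2A medication). Injected dose (185.1 ± 13.6 MBq dynamic,
146.7 ± 10.5 MBq FDG) and body weight (75 ± 12 kg) are drawn per subject;
curves are simulated in SUV units and converted to kBq/mL via dose/weight.

Regional kinetics are scaled relative to cortex by per-tissue multipliers
(`default_regional_table()`): delivery (\(K_1\)), total binding (\(V_T\))
and specific fraction, plus absolute FDG uptake values. No regional table
exists to emulate, so these are free parameters of the phantom, chosen as
plausible gray/white contrasts and documented here; changing them is a
configuration edit, not a code change. Per-subject regional variability
(log-normal, CV 0.08) is drawn once per left/right region *pair*: baseline
anatomy is mirror-symmetric, so lesions and noise are the only sources of
hemispheric asymmetry, which is the premise of the mirrored-subtraction
method. The delivery variability is shared with the FDG pattern (metabolism
tracks delivery), while binding variability is independent — this is what
makes early frames correlate with FDG across subjects while late frames
carry independent synaptic information.

### Lesions

Every subject carries one unilateral temporal lesion with two nested
extents. The broad component (radius 14 ± 2.5 mm) reduces delivery: \(K_1\)
and \(k_2\) are scaled together by \(1-\text{perfusion}\), preserving
binding potential, and the same draw scales the FDG uptake — so FDG and
early-phase lesion volumes co-vary across subjects while the late phase
does not, emulating the reported dissociation of volume correlations. The
synaptic core (radius 8 ± 1.5 mm, drawn independently) additionally carries
a binding reduction: the washout rate is inflated until the late-window
(30–60 min) signal is reduced by exactly `severity_frac` relative to the
unlesioned curve. Calibrating to the late-window *signal* (rather than to
\(V_T\)) makes the severity parameter mean exactly what the asymmetry map
measures; a pure \(V_T\) scaling would overshoot the late-window contrast
for slow kinetics, where 30–60 min is far from equilibrium.

The default severities (synaptic 0.45 ± 0.06; metabolic/perfusion
0.22 ± 0.05) encode the study-level condition that *measured* lesion
severity is comparable across the three modalities after the 8-mm filter
and the most-affected-90 % restriction: a small core is diluted more by
smoothing than a broad lesion, so its underlying contrast must be higher
for the measured values to coincide. This calibration was performed once on
a rendered probe and frozen.

### Rendering

`render_dynamic_image()` paints each frame from the regional curves,
convolves with a Gaussian point-spread function at the intrinsic scanner
resolution (6.6 × 6.6 × 5.1 mm FWHM), and adds zero-mean Gaussian noise
with
\(\sigma = \text{noise\_scale}\sqrt{\max(v,\epsilon)/\Delta t}\) — a cheap
surrogate for reconstructed-PET Poisson noise whose variance grows with
activity and shrinks with frame duration. The default `noise_scale = 2`
gives roughly 40 % voxel noise in a 5-s early frame and 2–3 % in a 600-s
late frame at cortical activity levels, which is the regime in which an
8-mm filter halves asymmetry-map background noise. Smoothing uses
separable per-axis convolution matrices with kernels truncated at 4σ and
renormalised at the array boundaries: constants are preserved exactly and
the operator commutes with the mirror flip, so a symmetric noise-free
phantom has an identically zero asymmetry map.

## The analysis workflow

**Windows and scaling.** The standard acquisition is
`"12x5,6x10,3x20,7x60,4x300,3x600"` — 35 contiguous frames over 60 min.
A frame belongs to a window iff fully contained (the 0–10 and 30–60 min
analysis windows align with frame boundaries, so partial-frame weighting is
unnecessary); window averages are duration-weighted. SUVR division uses the
cerebellum for the early phase and the centrum semiovale for the late phase
by default, with pons and whole-brain global mean as alternates; percent
difference maps are invariant to this scaling, so reference choice matters
for cross-tracer correlation, not for lesion mapping.

**Cross-tracer correlation.** `framewise_correlation()` computes one
Pearson r (and exact two-sided t-based p) per frame across subjects between
the dynamic signal and the static FDG value; `select_windows()` reports
maximal runs of at least `min_run = 3` consecutive frames with p < 0.05
(uncorrected along frames; a 3-frame minimum suppresses single-frame
noise). Within-subject agreement across atlas regions of the unaffected
hemisphere is available via `intrasubject_region_correlation()`.

**Asymmetry mapping.** `percent_difference_map()` smooths first (stage
order: smooth, then flip), mirrors across the midline, and computes
\(\Delta\% = 100\,(I - I_{mirror})/I_{mirror}\) with the contralateral
value as denominator (the contralateral hemisphere is the internal
reference; a symmetric-mean denominator is available as an option and makes
side-swapping an exact sign flip). Voxels whose mirrored value falls below
1 % of the robust (99th-percentile) image maximum are excluded and counted.
`lesion_mask()` keeps hypo-signal voxels at Δ% ≤ −8 by default, then
retains the 90 % of suprathreshold voxels with largest |Δ%| (rank by
magnitude, ties by voxel index; retention by count was chosen over a
cumulative-severity quantile as the simpler reading of "most affected").
`kernel_sweep()` reports lesion signal, lesion volume and background noise
— the SD of Δ% over the contralateral cortical mask, the only lesion-free
cortical compartment by construction — across kernels, and
`effective_resolution()` gives the quadrature-combined resolution
(e.g. 6.6 mm intrinsic with an 8-mm kernel → 10.4 mm).

**Kinetics.** `logan_vt()` regresses \(\int C_T/C_T\) on
\(\int C_p/C_T\) for frames with midpoint ≥ `t_star` (default 15 min, well
past the ~4-min cortical peak; configurable), estimating \(V_T\);
`logan_dvr()` is the reference-tissue variant with the \(C_{ref}/k_2'\)
correction term, estimating DVR. All running integrals are trapezoidal on
frame midpoints (plasma on its fine grid). `idif_extract()` interpolates
the blood-pool curve to a fine grid anchored at zero; it applies no
partial-volume correction, so with the default 5-mm blood pool and the
intrinsic PSF the image-derived input is diluted and slightly delayed —
adequate for the agreement analyses here, not for absolute quantification.
`static_vs_kinetic_agreement()` correlates late-window SUVR with
\(V_T\)-ratio and DVR across subjects per region; on one-tissue synthetic
data DVR equals the \(V_T\) ratio up to fit tolerance, and the reference
region's own ratios are near-constant (their correlation is noise and is
excluded from summaries). `k2_ref` comes from generator truth in tests and
from configuration in runs.

**Statistics.** Group comparisons use Welch's two-sided unpaired t test by
default (arms of 21 vs 8 with unequal variances; a pooled-variance flag
exists), with Holm–Šidák step-down adjustment across regions within each
window: sort ascending, \(\tilde p_{(i)} = 1-(1-p_{(i)})^{m-i+1}\), enforce
the running maximum, restore order. Modality comparisons (severity and
volume across FDG / early / late) use a one-way ANOVA with Tukey HSD,
treating the paired-by-subject lists as independent groups as the emulated
analysis does (a repeated-measures variant would gain power but is not the
default), plus pairwise Pearson correlations against FDG.

## Numerical choices

- The one-tissue ODE is integrated with an exact-decay trapezoidal
  recursion on the input-function grid (≤ 1 s, default 0.5 s; at least 5×
  finer than the shortest frame is enforced). It agrees with a brute-force
  0.1-s Riemann evaluation of the convolution integral to well under 0.5 %
  on all 35 frames.
- Peak inversion (`k2` from peak time) uses `uniroot` on
  \(k_2 \in [0.004, 3]\,\text{min}^{-1}\) with the peak located on the fine
  grid; lesion calibration solves a washout multiplier in [1, 200].
- Gaussian kernels: σ = FWHM/(2√(2 ln 2)), truncation at 4σ,
  boundary renormalisation; FWHM 0 is the identity.
- Degenerate inputs are errors, not warnings: empty masks, non-positive
  dose/weight, reference means ≤ 0, zero-variance correlation inputs,
  overlapping phantom regions (the error names both labels), missing label
  TACs (the error names the label), fewer than 3 frames past `t_star`.
- Empty lesion masks yield `NA` severity and zero volume rather than an
  error, since threshold sweeps legitimately produce them.
- Determinism: the master seed derives one RNG stream per subject from the
  subject index, so truth tables are stable under cohort-size changes, and
  `run_pipeline()` reruns are bit-identical (MD5-verified manifest).

## What the generator does and does not emulate

The phantom reproduces the *computational* conditions of a dual-phase
study: symmetric anatomy with a multi-region cortical parcellation,
arm-specific peak kinetics, blockade with a nondisplaceable reference
region, nested lesion extents with dissociated volume correlations,
intrinsic-resolution blur and frame-duration-scaled noise. It does not
attempt realistic anatomy (no template deformation), scatter or attenuation
effects, arterial sampling beyond the parametric input, metabolite
correction, head motion, or asymmetric normal anatomy. Passing tests
therefore demonstrate that the analysis code measures what it claims on
data obeying its assumptions — not that the method is robust to
misregistration or anatomical asymmetry in real images.

Test problem sizes: most checks run on a 48 × 48 × 40 grid of 4-mm voxels
(the same geometry in mm), with a 29-subject curve-level cohort and a
6-subject rendered cohort; the background-noise acceptance computation uses
the full 2-mm grid. These sizes were chosen so the whole suite exercises
every stage, including full renders, in about a minute.

## Known limitations

- Severity semantics are tied to the 30–60 min window; changing the late
  window changes what `severity_frac` calibrates to.
- The IDIF is uncorrected for partial volume; Logan VT from the rendered
  blood pool is biased even noise-free, which is why the kinetic module's
  accuracy tests use the true input function and the IDIF is validated for
  shape and agreement analyses only.
- The Gaussian noise surrogate has no positivity constraint; near-zero
  late-frame activity can dip below zero, and the Logan fit treats
  non-positive fit-range activity as an error rather than clamping it.
- With a lesion present, the "background noise" region (contralateral
  cortex) contains the mirrored lesion; for lesion-free noise
  quantification use a lesion-free render, as the acceptance computation
  does.
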