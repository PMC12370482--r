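---
title: "Models, parameters and design choices in laserlesion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, parameters and design choices in laserlesion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laserlesion)
```

This vignette documents the scientific model behind each pipeline stage, the
tunable parameters with their units and defaults, the choices made where the
experimental literature leaves the design open, and — importantly — what a
green test against the synthetic world does and does not establish.

## The experimental setting being modelled

Cultured RPE cells (artificially pigmented with melanosome particles) are
exposed to flat-top laser beams while an infrared camera records the
temperature field. Cell death is read out an hour later with calcein (live,
green cytoplasm) and ethidium homodimer (dead, red nuclei). Two damage modes
matter: *photothermal* (heating; a contiguous central dead core surrounded by
a sublethal halo of contracted, hyperfluorescent cells) and *photochemical*
(blue-light oxidative chemistry; dead cells scattered inside the beam
footprint with no halo). The package automates mask construction, thermal
fusion, lesion scoring, probit thresholding, and the reciprocity /
damage-frequency / interaction statistics that distinguish the two modes.

## Thermal model

Steady-state temperature rise is linear in irradiance:
`dT_ss(E) = k_slope * E + intercept`, and the temporal response is first-order,
`1 − exp(−t/τ)` with `τ = rise_time_constant`.

* `k_slope`, `intercept` — defaults are the line through the two printed
  calibration anchors of the 2-µm standard curve, (7.3 W cm⁻² → 44.5 °C) and
  (12.22 W cm⁻² → 50.0 °C) at 35.5 °C ambient, i.e. `k = 1.118 °C/(W cm⁻²)`,
  `intercept = 0.84 °C`. A two-point line is exact at its anchors, which is
  what the worked-number tests rely on.
* `rise_time_constant = 0.4 s` — chosen so the response exceeds 99% of steady
  state by 2 s, matching the observed "steady state after about 2 s". Nothing
  downstream is sensitive to the exact value provided steady state is reached
  well before the read-out window.
* `diffusion_sigma = 150 µm` — the spatial profile is the flat-top indicator
  convolved with an isotropic Gaussian, normalised to 1 at the centre. The
  experiments report no spatial temperature profiles, only centre
  temperatures, so lateral heat spread is a modelling choice exposed in
  configuration. The generator's ground truth carries its own closed form
  (`truth$temp_at(r)`), so profile-dependent tests validate the pipeline
  against the generator's stated world, not against measured physics.
* `camera_noise_sd = 0.1 °C` — typical cooled MWIR camera NETD.

The read-out window for "peak" (steady-state) values is the final 10% of the
exposure frames; the experiments name no averaging window, and the first-order
model is within 0.2% of steady state there.

## Fluorescence image model

Cells are placed by a Poisson point process (`cell_density = 2500 mm⁻²`,
about the density of a confluent RPE monolayer). Live cells are rendered as
overlapping cytoplasm territories of radius `cyto_radius = 20 µm`; at the
default density the union covers ≈96% of the substrate, emulating confluency.
(A first draft used 14 µm, which left a fifth of the substrate bare — a world
that the monolayer-integrity QC rules themselves would exclude.) Dead cells
show a red nucleus (`nucleus_radius = 5 µm`) and no green. Halo cells render
at 1.3× green intensity and 0.7× radius — a rendering stand-in for
"contracted, hyperfluorescent", not a biological claim. The observed green
channel adds `bleedthrough_coeff = 0.1` of the red signal; both channels get a
2-µm PSF blur, camera offset/noise, and 16-bit quantisation.

Phenotypes:

* photothermal — cells die where the steady-state temperature exceeds
  `T_crit` (death isotherm); cells within `halo_width` (default 1.5 °C) below
  it become halo cells. Ground truth is the filled isotherm disk whose radius
  solves `s(r)·dT_ss = T_crit − ambient`.
* photochemical — cells inside the footprint die independently with
  `p_death_max`; outside, with `background_death_rate = 0.5%` (healthy
  monolayers show <1% spontaneous death). Ground truth is the footprint disk.

## Mask construction

The damage signal is `D = max(L) − L` with `L = clamp(green − red, 0)`:
red is subtracted to cancel bleed-through, and the lesion is the hole in the
live carpet. (The alternative of thresholding red directly is available to
callers but is not the default: `D` reproduces both phenotypes' morphologies.)
Contrast enhancement clips 0.35% of pixels per tail (the common ImageJ
default; the protocol names no value).

RATS thresholding: Sobel gradient `g`, weights `w = g²` gated at
`λσ` (`lambda_factor = 3`; `noise_sd` estimated as 1.4826·MAD of the border
gradient when not supplied), quadtree to `min_leaf`, leaf threshold
`Σwf/Σw` where leaf weight exceeds the significance floor `(λσ)²·min_leaf`,
unpropagated leaves inherit their deepest significant ancestor, and the
per-pixel surface is bilinear between leaf centres. The four-mask stringency
schedule doubles the leaf (8/16/32/64 px): the first mask has the most edge
detail, later masks a larger minimum feature size. The floor constant is a
documented default — the reference implementation's exact parameter values are not published.

Cleaning is 10 erosions + 10 dilations with the 3×3 square element (the
ImageJ default), which removes structure thinner than ~20 px without moving
the boundary of a large region. Finalisation keeps the principal 8-connected
component (largest; centre-proximity breaks near-ties) and fills holes; a
discarded component above 25% of the principal area sets `needs_review` — an
explicit flag replacing the original manual-inspection step.

Degenerate inputs fail loudly: flat images raise a no-edges error, masks
emptied by cleaning raise an error that callers (and `build_mask_set`) treat
as a per-stringency failure, and only the failure of all four stringencies
aborts the pipeline.

## Thermal fusion

Registration is restricted to flips, quarter-turn rotations, uniform scaling
by the pixel-pitch ratio (nearest neighbour), and translation of the mask
centroid to the hotspot — the transform vocabulary the instrument geometry
actually needs. The hotspot is the argmax of the frame averaged over the last
10% of the exposure (averaging suppresses single-frame noise; ties break to
the smallest (row, col)).

The "single-pixel ROI" at the damage boundary is read as a one-pixel-wide
ring (`mask XOR erode(mask, 1)`), whose mean is reported; a ring is far more
noise-robust than one literal pixel, and the alternative reading remains
available via the `roi` configuration flag. Mask selection computes the ring
temperature SD on the end-of-exposure averaged frame: a ring lying on an
isotherm has SD near camera noise, so the minimum-SD mask is the
best-registered one. Whether the original analysis used a single frame or a
temporal average is unstated; the average is the lower-variance choice.

Note one geometric fact the tests encode: the 8-connected ring of a digital
circle carries up to 4/π times `2πr` pixels (stair-stepping), so ring length
is not a clean perimeter estimate; ring *means* are unaffected.

## Lesion scoring

Dead-cell detection thresholds the red channel at `median + 5·MAD`, then
refines each component at 30% of its own peak — without this, the PSF skirt
merges touching nuclei and the nucleus-scale area filter (20–400 µm²) would
silently drop them. Components above the filter (merged nuclei, contiguous
dead sheets in maximal lesions) are preserved with an area-based count
estimate, so counting rules remain monotone in lesion severity.

Photochemical positive: ≥5 dead cells within the central 50% of the footprint
radius, an identifiably circular in-footprint hull (circularity ≥ 0.6 — any
fixed cutoff is a proxy for the original two-scorer consensus and is
configurable), and damage confined to the footprint. The confinement rule is
implemented as an outside-density check (dead cells in the 1.05–2 footprint
radius annulus must stay below max(3, 20% of the in-footprint count)): a
literal hull-diameter test on in-footprint cells is vacuous, and a hull over
all detections would be tripped by the <1% spontaneous background deaths.

Photothermal positive: a contiguous red region reaching within 50 µm of the
beam centre with at least 10 nucleus-areas of stain; halo-only images (no
central red) are negative by construction.

QC exclusion is explicitly best-effort automation of the manual rules:
live coverage below 60% outside the footprint flags monolayer disruption;
bright objects larger than 10 nucleus areas outside the footprint flag
foreign material.

## Dose-response statistics

The dose metameter is log₁₀(irradiance) and the reported slope is the probit
regression coefficient β₁ in probits per decade. The source material calls
the slope a "first derivative at 50%", but its printed magnitudes (~8 and
~16) match the β₁ convention of the laser-damage literature, so β₁ feeds the
slope > 5 gate. Fiducial limits use Fieller's theorem on
`(Φ⁻¹(p) − β₀)/β₁`, with Finney's heterogeneity correction (variance scaled
by Pearson χ²/df over dose groups and a t quantile) when χ²/df > 1; `g ≥ 1`
raises an unbounded-limits error rather than returning a misleading interval.
Complete separation raises a separation error that points the caller to
`detect_deterministic()`.

Determinism: the crossover range is [min positive dose, max negative dose]
(sorted); the response is deterministic when the range width is below the
relative dose uncertainty (3.2%, the stated irradiance uncertainty) or when
no probit fit is possible, and the threshold is the range midpoint — which
reproduces 12.22 W cm⁻² from the reconstructed 93-exposure table. On that
table a probit GLM happens to converge numerically (slope ≈ 125); the
deterministic call rests on the narrow-range rule, not on convergence
failure.

## Interaction and reciprocity

Reciprocity compares threshold radiant exposures `H = ED50·τ` at two
durations; the default 10% tolerance quantifies the qualitative "nearly
identical", and fiducial-limit disjointness on the irradiance scale is
reported separately as the significance check. Interaction classification
generalises the 25%/50% guideposts to arbitrary planned probabilities with
exact binomial acceptance bands; when one agent is inactive the additive and
independent expectations coincide, the additive class is empty, and anything
above the band is synergistic (which is how 22/22 at a planned 25% classifies).
Percent frequencies round half away from zero (5/11 renders 45%; some prior
reports round it to 46%) — raw ratios are always retained.

## What the synthetic world does not establish

The generator emulates the *statistical and morphological structure* the
analysis assumes — not instrument physics. In particular: the radial
temperature profile is a smoothed indicator, not a conduction solution; cell
geometry is a disk-based rendering, not segmentable cytology; staining,
washing and focus artefacts are absent (QC heuristics are therefore only
smoke-tested); and dose-response draws are exactly probit, so probit recovery
tests measure estimator correctness, not model adequacy. Green tests
establish that the pipeline recovers the truth of its stated world at the
stated tolerances; they cannot validate the diffusion width, the scoring
cutoffs (circularity 0.6, central 50%, footprint 1.05×), or the RATS
significance floor against real instrument data.

## Scaled-down defaults in tests

Thermal stacks are simulated at tens of fps over ~3-s exposures (the model is
frame-rate agnostic and at steady state by 1.5 s), images at 3 µm/px over
~1.8 beam diameters, and stochastic properties run at the replication stated
in the acceptance criteria (20 seeds, 100 seeds, 200 simulations) or, in the
module suites, smaller — each test says so where it matters.
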