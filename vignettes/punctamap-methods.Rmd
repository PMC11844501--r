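---
title: "Methods: quantifying punctate neuropeptide innervation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying punctate neuropeptide innervation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

punctamap quantifies sparse, punctate immunoreactive processes —
neuropeptide-containing axons and their varicosities — in multichannel
fluorescence images of layered tissue, modelled on coronal sections of
the mouse olfactory bulb (OB). This vignette documents the models and
procedures, the tunable parameters and their defaults, the design
choices made where the methodology was genuinely open, and what the
synthetic benchmarks do and do not demonstrate about real data.

## The measurement problem

A neuropeptide channel (orexin-A- or MCH-like immunolabel) shows two
kinds of objects: thin *fibers of passage* and bulbous *varicosities*
(putative axon terminals). Three quantities are of interest:

* per-layer density of labeled processes (processes/mm², per OB layer:
  GL, EPL, MCL, GCL), from tiled low-magnification stacks;
* the cross-sectional area of each process and the size at which the
  population transitions from fibers to terminals, from
  high-magnification stacks;
* the fraction of terminals whose signal co-localizes with VGLUT1
  and/or VGLUT2, i.e. terminals capable of glutamate co-release.

## Pipeline stages

### Segmentation and the minimum-size filter

Segmentation is a *contract*: any per-pixel classifier that yields a
foreground mask can be swapped in. Three methods are built in:

* `otsu` (default): Otsu's threshold on the image histogram (2048
  bins over the observed range). Deterministic, and invariant to
  constant intensity offsets on well-separated two-mode histograms.
* `fixed`: explicit threshold, foreground strictly above it.
* `trainable`: a random-forest on per-pixel features (raw intensity,
  Gaussian-smoothed intensity at two scales, local standard deviation)
  fitted to a handful of foreground/background scribbles — the manual
  training protocol (5–10 marks per class) used with interactive pixel
  classifiers. It exists to honour that protocol; the pipeline never
  depends on it, and no automatic retraining trigger is defined.

Particles are 8-connected components in-plane (26-connected for
volumetric masks), and a component is kept only when its pixel count is
*strictly greater than* `min_size_px = 2`. At the tiled pixel edge of
0.65 µm this is the 0.845 µm² floor (2 × 0.65² = 0.845); the strict
reading (≥ 3 px survive) follows the filter's printed definition.

### Layer maps and density

Layer contours are closed polygons in micrometres (GeoJSON on disk).
Containment uses the even-odd rule with boundary points counted inside;
a centroid exactly on the shared boundary of two adjacent layers is
assigned to the earlier layer in map order — an explicit, deterministic
tie-break. Density is defined as particle count over contour area;
particles outside every layer are tallied separately and never enter a
density. Anterior–posterior profiles are ordered by descending bregma
and summarised as mean ± SEM across preparations, after averaging each
preparation's sections, matching how per-preparation summary figures
are usually drawn. Whole-section density is reported both ways (pooled
over sections and averaged over preparations) since the aggregation
convention is not fixed by the field.

### Nucleator morphometry

For each volumetric particle the *largest cross-section within a
z-window* is found by scanning every contiguous window of slices
spanning at most `z_window_um = 2` and taking the maximum-projection
footprint with the largest area (ties: smallest starting slice). The
footprint is then measured with the nucleator probe:

* centre = footprint centroid;
* `ray_count = 6` rays at 60° spacing from a start angle drawn from the
  seeded generator (classical nucleator isotropy; fixable for tests);
* `r_i` = distance from the centre to the last foreground pixel along
  ray *i*, sampled at a tenth of a pixel with a half-step correction so
  the measured radius is centred on the mask boundary;
* area `A = π r̄²` with `r̄ = mean(r_i)`.

Two interpretation choices were open. "6 equally spaced lines" is read
as 6 rays with the mean of 6 centre-to-edge distances (the quantity
that formula averages); a 12-ray reading can be emulated by doubling
`ray_count`. And each distance is centre-to-edge along one direction,
not a full chord. Note that `π r̄²` squares the *mean* distance and is
therefore biased low for non-circular profiles (Jensen's inequality):
on a 2:1 ellipse its exact expectation is 5.923 against a true area of
2π ≈ 6.283, about −5.7%. The package implements the published formula
as printed; the unit tests check the implementation against the exact
expectation of that estimator, not against the raw shape area. Concave
footprints whose centroid falls outside the mask are flagged
(`center_inside = FALSE`) but still measured.

### The size-transition rule

Within each image, measured areas are sorted ascending and adjacent
differences taken. A difference at least `k = 3` times the mean
difference marks a sharp jump; the transition point is the midpoint of
the two areas flanking the selected jump, and processes strictly above
it are putative terminals (an area exactly at the threshold is a
fiber). Per-image thresholds are the primary quantity; a study-level
threshold is their mean (the aggregation rule is not otherwise
specified in the field, and the mean is the simplest defensible
choice).

The selection rule deserves a note. Read literally, "the maximum value
in the derivative plot" would pick the globally largest spacing. But
with realistic right-tailed terminal sizes, the largest spacing
regularly falls between the few largest processes rather than at the
fiber/terminal boundary — at 100 fiber + 150 terminal draws from
disjoint uniform supports this happens in roughly one seed in six, and
per-image thresholds would then scatter far above the class gap, which
is not how reported per-image thresholds behave (they concentrate in a
narrow band just above the fiber mode). The default rule is therefore
the *first* difference reaching `k` times the mean — the first sharp
jump, where the fiber mode ends — with the literal global-maximum
reading available as `rule = "max"`. Under the default, detection on
separable mixtures returns the class-gap midpoint essentially always.

### Object-based VGLUT co-localization

"Spatially overlapping signal with similar morphology" is
operationalised with two explicit dials, because the original criterion
is human judgment:

* overlap fraction = |footprint ∩ marker mask| / |footprint|, positive
  when ≥ `theta = 0.5` (inclusive);
* similarity = intersection-over-union between the footprint and the
  single marker connected component with maximal intersection, positive
  when ≥ `s_min = 0.3` (inclusive).

A channel is called positive only when *both* conditions hold; the two
channels give the four categories `1-/2-`, `1+/2-`, `1-/2+`, `1+/2+`.
Overlap is computed on the same ≤ 2 µm max-projection window used for
the terminal's area. Raising `theta` can only move records from
positive to negative (monotone classification; property-tested).
Summaries report per-image percentages (summing to 100 within each
image), their mean ± SEM across images, and pooled percentages over all
terminals. For MCH-like runs, dual-positive records are excluded when
at most 2 occur in the whole pool (`drop_dual_max_n = 2`), mirroring
the analysis convention for that marker; orexin-A-like runs keep all
four categories.

### Statistics

Group comparisons use N-way ANOVA with type-II sums of squares (the
design can be unbalanced; the convention is stated in the output),
full-factorial by default, with rank-deficient designs rejected by
name. The degenerate all-equal-response case is reported as F = 0,
p = 1 rather than 0/0. Post-hoc contrasts use Tukey's HSD with
studentized-range adjusted p-values and stars at p < 0.05 / 0.01 /
0.001. SEM is the sample standard deviation (n − 1) over √n, undefined
(NA) at n = 1. Reports are assembled as markdown with a configuration
echo and no timestamps, so identical inputs give byte-identical output.

## The synthetic-scene generator

The generator exists so that every stage has a known answer. A
`scene_spec` fixes the image shape and calibration, the layer
geometry, per-layer object intensities, the fiber/terminal size
mixture, the VGLUT category mixture, the noise model and a seed; *all*
randomness flows from that one seed, and identical specs render
bit-identical stacks.

**Study conditions (defaults).** Per-layer intensities default to an
MCH-like pattern: GL 38, EPL 84.4, MCL 161.4, GCL 306.4 objects/mm².
The orexin-A-like size mixture draws fibers from Uniform(0.18, 0.80)
and terminals from Uniform(0.96, 4.76) µm² — spanning the 0.18–4.76 µm²
process range with a gap whose midpoint is 0.88 µm²; the MCH-like
mixture is the same geometry scaled by 0.73/0.88 so its midpoint is
0.73 µm². Category mixtures: orexin-A-like
(0.366, 0.063, 0.394, 0.177) for (1-/2-, 1+/2-, 1-/2+, 1+/2+) — the
three VGLUT-positive probabilities follow the reported per-image means
and the remainder is assigned to 1-/2-, which is introduced as "the
remaining" fraction (the reported means do not sum to 100 because the
per-image averaging convention behind them is underdetermined; pinning
the positive categories and absorbing the slack into the negative one
is the least-committal completion). MCH-like:
(0.719, 0.026, 0.252, 0.003), whose pooled post-exclusion shares
reproduce 72 / 2.6 / 25.2. Fiber weights are 0.45 (orexin-like) and
0.6 (MCH-like), consistent with per-image process counts dominated by
fibers. Noise: Poisson photon noise on a background of 100 AU plus
Gaussian read noise (sd 10), 16-bit quantisation — an SNR at which
segmentation recall exceeds 0.95 by design.

**Rendering.** Terminals are 3-D Gaussian blobs whose in-plane σ
satisfies `area above the half-maximum isophote = drawn area`
(`A = 2π ln 2 · σ²`), which makes "true area" operationally
measurable. Fibers are short, slightly wavy constant-intensity
segments of width 0.3 µm whose stamped footprint equals the drawn area
(length = area/width); rendering them instead as long (tens of µm)
fibers of passage would detach the drawn size-mixture value from
anything the nucleator can measure and break the generator's own
ground-truth contract, so the short-segment reading was adopted. Each
VGLUT-positive terminal receives a co-localized blob (slightly
jittered centre and scaled σ) in the corresponding channel, plus each
VGLUT channel receives independent background puncta
(0.005 puncta/µm²). The DAPI channel carries a flat tissue fill inside
the section contour.

**Calibration choices.** Three rendering details were set during
development so the generator's stated conditions are actually realised
at the implemented calibrations:

* objects are placed with a minimum centre separation of 4 µm
  (dart-throwing; counts are drawn first and stay exactly Poisson).
  Without it, fused doublets create area outliers whose tail spacings
  hijack the derivative peak; the separation mirrors the "clearly
  labeled process" inclusion criterion of manual annotation, which
  would not fuse two distinct varicosities;
* in-plane rendering floors (blob σ ≥ 1 px, fiber stamp radius
  ≥ 1.05 px) guarantee every object's footprint survives the > 2 px
  filter at the 0.65 µm tiled calibration, emulating PSF blur at low
  magnification;
* fiber curvature (heading sd 0.35 rad per 0.1 µm step) keeps
  near-axial nucleator rays short, so measured fiber areas stay below
  the terminal mode.

**What the generator does not emulate.** Real VGLUT neuropil is far
denser than the sparse resolvable puncta rendered here; tissue
autofluorescence, lipofuscin, anisotropic PSFs and depth-dependent
attenuation are absent; terminal size is drawn independently of VGLUT
category (real data show category–size associations); and overlapping
varicosities, which manual annotation would split but automated
segmentation fuses, are excluded by the separation rule. Passing the
synthetic benchmarks therefore demonstrates that the *pipeline
arithmetic* — filtering, density, the transition rule, the category
classifier, the statistics — is correct and recovers known truth at
realistic SNR and density; it does not certify segmentation or
similarity thresholds against the full messiness of real tissue, where
the two explicit dials (`theta`, `s_min`) should be swept.

**Measured vs drawn areas.** Segmented footprints depend on the
segmentation threshold: for a Gaussian blob thresholded at *t*, the
footprint is `2π σ² ln(peak/t)`, a multiplicative factor relative to
the half-maximum area. Measured terminal areas are therefore scaled
(typically ~2× at default amplitudes) relative to drawn areas, while
the fiber/terminal *gap* is preserved — the transition rule, the
classification and the category proportions are all invariant to this
common scale, which is why the benchmarks target category recovery and
gap-midpoint behaviour rather than absolute measured areas.

## Problem sizes

The test suite and the acceptance script use: 20 seeds × (100 + 150)
draws for the transition rule; 26 MCH-like scenes of ~25 terminals and
30 orexin-A-like scenes of ~40 terminals (fields sized to keep terminal
density near 0.006/µm²) for end-to-end category recovery; and 3
simulated preparations × 3 tiled sections on a scaled-down
(0.8 × 0.6 mm) four-layer section, with between-preparation log-normal
variability (CV 0.25, matching the reported spread of layer densities),
for density recovery and the GCL–GL contrast. These sizes are the
package's chosen benchmark conditions; they keep a full run in the
range of a few minutes on one CPU while leaving the statistical margins
(binomial sampling error ~1.5–2 percentage points on pooled category
percentages) comfortably inside the tested tolerances.

## Known limitations

* The nucleator estimator is the published `π r̄²`, biased low on
  elongated profiles (about −6% at 2:1 aspect); use `π·mean(r²)`-style
  estimators if unbiased areas of anisotropic profiles matter.
* Per-image transition detection needs both classes present and at
  least three measured processes; images without a detectable jump
  contribute no terminals (reported as "no transition" diagnostics).
* The trainable segmentation mode predicts over every pixel with a
  random forest and is slow on large tiled images; it is a protocol
  stand-in, not the default path.
* Stack I/O uses plain multi-page TIFF with a YAML calibration sidecar;
  reading vendor OME metadata is out of scope, and a stack without its
  sidecar is an error by design (calibration is never silently
  defaulted).
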