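---
title: "Methods: cyclic chromogenic multiplex IHC analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cyclic chromogenic multiplex IHC analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameters and design decisions behind
the package, in the order the pipeline runs.

## Stain model

Brightfield chromogenic staining follows Beer–Lambert absorption: a pixel
with transmitted intensity $I$ against blank-glass intensity $I_0$ has
optical density $\mathrm{OD} = -\log_{10}(I/I_0)$ per RGB sample, and the
OD 3-vector of a pixel is (to good approximation) a *linear* mix of the
constituent stains' unit OD vectors weighted by their local densities.
`rgb_to_od()` guards saturated-dark pixels by clamping intensities at one
intensity level before the log; the clamp (rather than an additive guard)
leaves every pixel at or above one level exactly on the Beer–Lambert curve,
so blank glass maps to OD 0 and a tenfold attenuation to OD 1 with no bias.

`deconvolve()` solves the per-pixel least-squares projection of the OD
vector onto the stain basis via the pseudo-inverse; a two-stain basis is
completed with its cross-product third vector, which leaves the two stain
coefficients unchanged. Negative coefficients — noise projected outside the
cone of physical mixtures — are clipped to zero and the clipped fraction is
reported per stain as QC (`attr(, "clip_fraction")`). Clipping, not
re-balancing, keeps the contract simple and the statistic visible.

No published OD vectors exist for the AMEC red chromogen, so
`default_stain_matrix()` ships an AEC-like red, `(0.274, 0.680, 0.680)`,
with a standard hematoxylin, `(0.650, 0.704, 0.286)` — the same vectors the
synthetic renderer uses. For real slides the vectors should be measured:
`estimate_stain_vector()` returns the first principal direction (through
the origin, since OD mixtures are conical) of the OD vectors in a
user-selected single-stain region.

## Registration

The hematoxylin counterstain is re-applied every round and is therefore the
only structure common to all rounds; registration is anchored on it.
`estimate_transform()` searches a coarse rotation grid (default ±5° in 1°
steps), initializes translation by integer-peak phase correlation at each
angle, and refines the rigid parameters by Nelder–Mead on normalized
cross-correlation (NCC) over mutually valid pixels. On the synthetic study
conditions (shifts ≤ 10 px, rotations ≤ 2°) the estimator recovers
translations to well under 0.1 px and rotations to under 0.01°; the test
suite asserts the looser 0.5 px / 0.2° bounds.

Rigid is the default because the same physical section is re-imaged each
round — there is no cutting deformation between rounds, only stage
placement. `mode = "affine"` refines all six parameters; `mode =
"deformable"` adds a block-wise phase-correlation displacement field
(default 128 px blocks, bilinearly interpolated between block centres,
displacements clamped to a quarter block). A final NCC below
`min_similarity` raises a typed `registration_failure` error; falling back
to the identity is deliberately left to the caller.

`warp()` resamples by pull-back bilinear interpolation; out-of-field pixels
are zeroed and flagged in a validity mask that every downstream area
statistic respects, so border strips never inflate area fractions.
Coordinates are 0-based pixel centres, x rightward, y downward; all
user-facing geometry is in microns.

## De-stain QC

`area_fraction()` is the plain thresholded-pixel percentage over a tissue
mask. `residual_stain()` registers the post-de-staining scan onto the pre
scan, thresholds *both in their native frames* with the same threshold, and
maps the post-positive markup through the transform at the 0.5 level. The
markup-then-warp order matters: warping densities first smears
partial-amplitude pixels (thin processes, soft edges) below threshold and
biases the residual low, while warping the binary markup is
area-preserving. The residual percentage is computed on the pre-positive
region (blocked re-development of the *same* structures), and the
whole-tissue post area fraction is reported alongside, since the two answer
different questions and it is not obvious from a printed percentage which
of the two a given workflow used; we emit both.

The default threshold is Otsu on the pre image's density histogram with a
floor of 0.1 OD (`otsu_threshold()`): Otsu always splits a histogram, so on
a channel with no stain it would land inside the acquisition noise; the
floor sits ~10 standard deviations above the default noise and ~9× below
the rendered chromogen density. One caveat is documented by a test: when
heavy multi-round contamination is present, Otsu adapts to the contaminated
pre histogram, so cross-retention comparisons should fix the threshold (or
use round 1, which has no prior rounds).

## Objects and phenotypes

`detect_objects()` thresholds a channel, labels 4-connected components
(EBImage's `bwlabel`), converts geometry to microns, and applies the
minimum-area exclusion — 40 µm² for cell candidates, which removes
obliquely cut process fragments while keeping somata. Touching cells are
not split: the synthetic study conditions space cells at microglia-like
territorial separation (30 µm default) so separability is guaranteed, and
a watershed would add a behaviour the measurement chain does not need.

The pathology size exclusion is stated in the field as "100 µm". We read
it as a minimum **area** in µm² by default (`pathology_min_size = 100`,
`pathology_size_metric = "area"`): tangle-bearing neuronal somata are
15–25 µm across, so a 100 µm *diameter* floor would exclude every tangle
body while the workflow plainly keeps them, and the companion cell
exclusion in the same workflow is an area (40 µm²). The diameter reading
remains available via `pathology_size_metric = "diameter"`.

Marker positivity per object uses an overlap-fraction rule: marker $m$ is
TRUE when ≥ 25% of the object's pixels exceed that channel's threshold
(`overlap_fraction`, configurable); mean densities and fractions are stored
so a mean-density rule can be audited against it. The gate
(`default_phenotype_gate()`) is an ordered rule table — IBA1− →
`non_microglia`; GFAP+ → `gfap_conflict`; P2Y12+ → homeostatic;
Ferritin+CD68+ → triple-positive; Ferritin+; CD68+; else `IBA1-only` —
evaluated first-match, so totality and disjointness hold by construction
and are additionally asserted over all $2^7$ vectors in the tests. TMEM119
and CD45 are captured but not gated.

## Proximity

Distance is measured from the cell centroid to the pathology object's
boundary polygon (exact point-to-segment geometry), zero inside the object
— the convention typical of proximity modules and robust for small cells;
boundary-to-boundary distance is what the association summary uses for
"touching". Profiles bin each cell by its nearest pathology object within
a 100 µm radius in 20 µm bins (a round divisor of the radius; widths are
configurable), and both normalizations are emitted: per-bin percentages
over phenotypes and per-phenotype percentages over bins. Cells within the
radius of both a plaque and a tangle are assigned to the nearer kind
(`exclude_nearer`), and counted for each kind separately in the
association summary. With `touch_tolerance = 0` "touching" reduces to mask
overlap/contact; when no vessel masks are supplied the vessel column is
`NA` (not computed), never 0.

## The synthetic scene generator

`generate_scene()` emulates what the wet-lab protocol hands the analysis:
per-round misaligned brightfield RGB scans of one tissue field. Cells are
soma disks (radius 3.6–4.8 µm, area ≈ 40–70 µm²) with 2–4 thin processes
(7–12 µm long, ~1 px wide), so the 40 µm² exclusion and process-fragment
artifacts are exercisable; plaques are unions of jittered disks
(nominal radius 12–22 µm) with deliberate sub-exclusion diffuse speckles;
tangle bodies are 6–8 µm-radius disks with thin neurites; vessels are
capsule masks supplied as truth, never a stained channel. Hematoxylin
renders all nuclei plus a light tissue background (0.06 OD); chromogen
densities are 0.9 OD (cells) and 1.1 OD (plaque cores). Phenotypes are
drawn i.i.d. from the configured proportions — default (0.45, 0.25, 0.10,
0.12, 0.08) over homeostatic, IBA1-only, Ferritin+, Ferritin+CD68+,
CD68+ — and each cell's marker vector is sampled consistently with its
label (TMEM119 only on P2Y12+ cells, CD45 probabilistic, reactive markers
exact), so gate round-trip consistency holds by construction and is tested
over seeds.

Placement is sequential rejection with a minimum centre separation
(default 30 µm, matching microglial territorial tiling and guaranteeing
non-touching objects at default geometry); an infeasible packing is a
config error, not a silent densification. Reactive phenotypes can be drawn
toward plaques by a placement weight $1 + a\,e^{-d/25\,\mu m}$ (default
$a = 8$ for triple-positives), or placed in *direct contact* with plaques
at an exact per-phenotype fraction (`contact_fraction`), with non-contact
cells kept clear — the knob used to validate touching-fraction recovery.

Misalignment is rigid per round (round 1 is the reference): shifts up to
±8 px and rotations up to ±2° by default, ±10 px in the multiplex-vs-single
comparisons. Rendering is analytic at transformed coordinates — no
resampling — so the generator shares no code path with `warp()` and can
serve as its oracle. Noise is additive Gaussian in OD space (default
σ = 0.01 per RGB sample) before 8-bit quantization.

Residual staining is modelled as a *retained-pixel fraction*: a smooth
Gaussian random survival field (correlation ~2.5 µm, fixed by the seed) is
cut at the exact `retention_fraction^k` quantile over the stained region
for stain that has survived $k$ de-stainings. Patchy retention matches the
observed spatial non-uniformity of blocking failures; the quantile cut
makes the retained fraction of stained pixels exact, and the shared field
makes the retained sets nested in the fraction, so residual monotonicity
is deterministic. Retention recovery is validated on aligned pre/post
pairs; across a misaligned pair, any pixel-level intersection measurement
loses roughly half a boundary ring of each retained patch to rasterization
decorrelation (a known-sign bias of ~2–3 percentage points at the default
patch scale), which is a property of this class of measurement, not of the
generator.

What the generator does *not* emulate: real tissue texture, lipofuscin or
other autofluorescence-analogue artifacts (brightfield scope), scanner
illumination fields beyond a single white point, antibody-specific stain
intensity variation, or cutting deformation between rounds. Passing tests
therefore demonstrate the computational chain's correctness on controlled
input, not robustness to every property of real slides — stain-vector
mis-specification and genuinely deformable tissue must be handled via
`estimate_stain_vector()` and `mode = "deformable"` on real data.

## Problem sizes and numerical choices

The test suite and the acceptance script use 224–320 µm fields with 24–30
cells for rendered scenes (a 288 µm field renders and analyses in well
under a minute), 1 250–1 400 µm truth-only scenes with 700–1 000 cells for
statistical recovery, and 10 seeds for the de-stain average; these sizes
put every statistical check comfortably inside its binomial bounds while
keeping a full run on one CPU in minutes. Statistical recovery tests use
joint 95% binomial bounds (Bonferroni over the five phenotype classes).
Ties and degenerate inputs are pinned by tests: blank channels yield empty
object sets (threshold `Inf`), a zero-cell scene runs to completion with
empty tables, an empty pathology set returns an empty profile with a
warning, and all-identical pre/post pairs give exactly 100% residual.

## Known limitations

- Exact numeric parity with proprietary slide-analysis suites is not
  attempted: their stain vectors and thresholding rules are unpublished.
  The contracts here (least-squares deconvolution, NCC rigid registration,
  Otsu defaults) are reproducible replacements, not re-implementations.
- Whole-slide pyramidal tiling is out of scope; the package processes
  single fields/regions.
- The deformable mode is a local-translation refinement, not a full
  free-form deformation; it is adequate for the small non-rigid residuals
  of re-imaged sections but not for serial-section (adjacent-slide)
  registration, which is out of scope.
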