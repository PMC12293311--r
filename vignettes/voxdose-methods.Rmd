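---
title: "Methods: voxel-phantom photon dosimetry with voxdose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voxel-phantom photon dosimetry with voxdose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxdose)
```

## Scope

`voxdose` is a desk-scale toolkit for photon dosimetry on voxel
anthropomorphic phantoms. It covers the full chain from a voxel organ-ID
lattice to an anterior–posterior (AP) effective-dose curve: phantom
construction and fill-card I/O, material data, a deterministic
collision-kerma engine plus an analog Monte Carlo engine, radiograph
projection through mesh tallies, organ-dose and effective-dose
calculation per unit fluence, model-comparison statistics for published
effective-dose tables, and XML input-deck export for external
lattice-based Monte Carlo codes. It is intended for method development,
teaching and consistency checking — not as a replacement for a
production Monte Carlo code with evaluated nuclear data.

## The phantom data model

A `voxel_phantom` is a 3D integer lattice of organ IDs (1–254) with a
cubic voxel pitch in cm and an attached organ registry (ID, name,
density, elemental mass fractions, effective-dose weighting class). ID
255 is reserved for the exterior (air) and may not appear in a
registry. The lattice is stored with x fastest in memory, then y, then
z, which is also the fill-card order: a linear fill array populates the
lattice from the bottom slice upward, and `populate_lattice()` /
`flatten_phantom()` are exact inverses. The physical frame is centered
on the origin; voxel `(i, j, k)` has its center at
`((i - nx/2 - 0.5) * pitch, ...)` cm. Fill cards are plain text:
whitespace-separated IDs with optional `value r count` run-length
tokens and a `# dims nx ny nz pitch` header; the writer emits a
canonical run-length-compressed form, the reader accepts both.

Organ masses are `count * pitch^3 * density` grams. Since every voxel
belongs to exactly one registry organ or to air, total phantom mass is
exactly the sum of the per-organ masses.

## The material data and its construction

All photon physics rests on a bundled table of elemental mass
attenuation (μ/ρ) and mass energy-absorption (μen/ρ) coefficients for
13 biologically relevant elements (H through I) on an 18-point grid
covering 0.01–1.25 MeV. Mixtures use Bragg additivity (mass-fraction
weighted sums), with log–log linear interpolation between grid nodes;
energies outside the table range raise an error rather than
extrapolate.

The table is generated once by `tools/make_coefficient_table.R` and
shipped as CSV. It is an approximate, self-contained construction
rather than a transcription of a reference library:

* the incoherent part is the free-electron Klein–Nishina cross section
  (total, and its energy-transfer moment by numerical quadrature),
* the photoelectric part is a two-parameter power law,
  τ/ρ ∝ Z^4.6 / A · E^−3.28, calibrated against standard water
  reference values at 50 keV,
* coherent (Rayleigh) scattering is excluded, and there is no
  absorption-edge structure (iodine's 33 keV K-edge is smoothed over;
  iodine appears only as a 0.1% thyroid trace),
* photoelectric energy is treated as locally absorbed (fluorescence
  escape neglected), so μen ≤ μ holds identically.

For low-Z tissue elements this reproduces standard water values to a
few percent across the diagnostic range (e.g. μ/ρ at 1 MeV of 0.0706
vs the familiar 0.0707 cm²/g). That accuracy is adequate for every
property the package asserts — closed-form agreement, orderings,
trends — but absolute organ doses computed with this table should not
be quoted against evaluated-data calculations without that caveat.

## Transport engines

Both engines assume the kerma approximation: energy transferred to
electrons is deposited at the interaction site, with no electron
transport. This is a good approximation at diagnostic energies; above
roughly 1 MeV electron ranges approach voxel dimensions and the
approximation degrades, which is the main reason the table stops at
1.25 MeV.

**Deterministic kerma engine.** For the monodirectional AP plane
source, `deposit_kerma()` sweeps each (y, z) voxel column along x. The
primary fluence entering a voxel is the product of upstream voxel
transmissions `exp(-mu * pitch)`; the voxel's deposit is
`E * F_in * (1 - exp(-mu * pitch)) * (muen/mu)`. Scattered energy is
booked as escaping, so per ray the deposited, transmitted and
scattered-escape energies sum to the source energy exactly (this
bookkeeping is exposed via `detail = TRUE` and tested to 1e-9). The
engine is noise-free and reports zero uncertainty.

**Analog Monte Carlo.** `mc_transport()` runs an analog history loop
with delta (Woodcock) tracking against the per-energy majorant of the
organ attenuation coefficients. At a real collision the Compton
probability is `n_e * sigma_KN(E) / mu`, consistent with how the
coefficient table was built; Compton events sample the Klein–Nishina
scattered-energy fraction by rejection (uniform proposal on the allowed
fraction range, which is efficient below a few MeV), deposit the
transferred energy locally, and continue the photon with the sampled
polar angle and a uniform azimuth. The non-Compton remainder is local
photoabsorption; Rayleigh scattering is not modeled. Photons terminate
on absorption, on leaving the lattice, or on falling below the 10 keV
table floor, where the residual energy is deposited locally (a
conservative, documented bias of order the cutoff energy). With
`scatter = FALSE` a history deposits the expected collision kerma
`E * muen/mu` at its first collision and stops, which makes the
estimator exactly unbiased against the deterministic engine — the basis
of the cross-validation test.

Uncertainties use batch statistics: the standard deviation of the mean
over batch means, mirroring the batch structure of production MC codes.
The batch count matters: with B batches the uncertainty estimate itself
carries relative noise of about `1/sqrt(2B)`, so tests that compare
uncertainty magnitudes (the 1/√n scaling check) use 400 batches to make
the estimator stable; routine dose runs default to 10.

**Ray traversal.** General rays use an Amanatides–Woo voxel traversal
(`siddon_traverse()`) returning visited voxels with exact chord
lengths; chord sums match the analytic ray–box intersection to 1e-9
over random rays. Rays starting exactly on voxel faces are nudged by
1e-12 of the box scale; this tie-break only affects measure-zero rays.

**Radiography.** `project_radiograph()` casts one primary ray through
the center of every mesh cell (parallel beam), so the image is the
noise-free primary-transmission map; there is no scatter fog, which
exaggerates contrast relative to a full simulation but preserves the
energy ordering of contrast. Grayscale exports apply logarithmic
normalization. Contrast statements use the Michelson definition on
region-mean fluxes.

## Dosimetry

Organ absorbed dose per source particle converts the heating tally via
`D_T = heating[eV] * C1 / mass[kg] * C2` with `C1 = 1.602176634e-19`
J/eV and `C2 = 1e12` pGy/Gy. Division by the fluence per particle on
the normalization plane — analytically `1/area` for the plane source,
which is also the default normalization plane — gives the
fluence-to-dose conversion coefficient in pGy·cm². For a beam fully
covering the phantom the DCC is independent of the source area and of
the particle count.

Effective dose applies the ICRP-103 tissue weighting factors
(w_R = 1 for photons, so pGy and pSv coincide numerically): 0.12 for
red marrow, colon, lung, stomach, breast and the remainder; 0.08 for
gonads; 0.04 for bladder, oesophagus, liver, thyroid; 0.01 for bone
surface, brain, salivary glands, skin. The weights sum to exactly 1,
enforced at construction. The remainder term is the arithmetic mean of
the remainder organs' equivalent doses times 0.12 — the ICRP-103
convention; a mass-weighted mean is a defensible alternative but the
arithmetic mean is the published rule and is what the package uses.
The upper and lower colon are combined into the single colon target by
mass-weighted mean dose, which is the physically correct organ-average
of a tissue segmented in two pieces. Uncertainties propagate in
quadrature with the same weights, treating organ tallies as
independent; correlations induced by shared histories are neglected.

## The synthetic body phantom

`default_body_recipe()` builds a deterministic, stylized 30-organ body
on a 64 × 64 × 160 lattice at 0.5 cm pitch (a 32 × 32 × 80 cm frame
that rescales linearly with other dims/pitch choices): an adipose body
volume with muscle bulk, a skeleton (spine, skull, ribcage band,
pelvis) with red-marrow core and bone-surface lining, head organs
(brain, eye lenses, salivary glands), thoracic and abdominal organs,
pelvic organs, and a one-voxel skin shell computed from the body/air
boundary so the skin always encloses the body. A seeded jitter of
±0.2 cm on organ centers provides controlled variability; geometry is
otherwise deterministic, and the same seed reproduces the same lattice
bit for bit.

The generator emulates the features downstream code depends on — a
complete weighted-organ inventory including both colon halves and a
remainder set, superficial vs deep organs, bone/soft-tissue contrast,
disjoint IDs with an air exterior — at roughly half scale (≈47 kg). It
does not emulate anatomical realism, true organ masses, postures, or
population-specific anatomy. Consequently, tests passing on this
phantom validate the *mechanics* (bookkeeping, weighting, transport,
trends) and qualitative physics; they do not certify absolute dose
coefficients for any real body, whose values depend on the segmented
anatomy and evaluated cross-section data.

## Comparison statistics

Published multi-model effective-dose tables are compared with three
conventions, chosen because together they exactly reproduce the
published derived columns of the bundled 20-energy AP table:

* **pairwise-complete RMSE** — each pair of models is compared over the
  energies where both report a value (the sparse MCNPX column
  contributes 7 of 20 energies);
* **available-model averages** — the multi-model mean at each energy is
  taken over the models defined there;
* **full-precision internals** — averages feed statistics unrounded;
  display rounding (4 significant figures for doses, two decimals for
  percents) is applied only at output. Computing the RMSE from the
  *printed* (rounded) averages instead changes the reference-vs-average
  RMSE in the fifth decimal (0.052673 vs 0.052687); the package uses
  full precision.

Percent differences are `(value - reference)/reference * 100`; in
pairwise reports the later-listed model is compared against the
earlier-listed one as reference, matching the usual "X vs. Y" table
convention.

## Input-deck export

`export_deck()` writes four XML cards (materials, geometry, settings,
tallies) in the style of modern lattice-based MC codes: materials
numbered by organ ID plus air as 255; a rectangular lattice with
lower-left corner at minus half the physical extent (consistent with
the centered frame), pitch, and the full universe map; two bounding
spheres (defaults 750 and 800 cm, the outer a vacuum boundary); a
fixed-source run with a monodirectional +x plane source and a single
discrete energy line (eV in the card); heating tallies filtered by the
universe list and/or a flux mesh tally. Fidelity is structural, not
byte-exact for any particular external code version: every export
round-trips through the package's own parsers back to the originating
objects, which is what the tests assert, and the decks are not executed
here.

## Problem sizes and numerical choices

The test and acceptance workloads use the 64 × 64 × 160 synthetic body
(655,360 voxels), slab phantoms of a few thousand voxels, Monte Carlo
runs of 10⁴–1.6 × 10⁵ histories, and 128 × 256 radiograph meshes —
sizes chosen so the full suite runs in well under a minute while every
statistical check retains comfortable power. Key numerical choices,
collected: log–log interpolation exact at nodes with hard range errors;
composition sums enforced to 1e-6; weight sums enforced exactly;
delta-tracking majorants recomputed at every energy change; 10 keV
termination cutoff; voxel-face tie-breaks by interior nudge;
mass-weighted combination for split organs; quadrature propagation of
independent organ uncertainties.

## Known limitations

No electron transport (kerma approximation), no Rayleigh scattering, no
bound-electron (incoherent scattering function) corrections, no
absorption edges, approximate photoelectric scaling, primary-only
radiographs, and a stylized rather than anatomical default body. Each
is deliberate for a desk-scale engine and flagged where it matters
above.
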