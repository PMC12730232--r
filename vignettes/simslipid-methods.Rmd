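---
title: "Methods: single-cell ToF-SIMS lipid profiling and turnover analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell ToF-SIMS lipid profiling and turnover analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(simslipid)
```

## The measurement and the analysis problem

Time-of-flight secondary ion mass spectrometry (ToF-SIMS) with a gas
cluster ion beam images the intact lipids of the outermost cell surface:
a primary beam rasters a field of view on a conductive substrate
(indium tin oxide, ITO), and each pixel yields a full secondary-ion mass
spectrum, here over m/z 100-1000 in both ion polarities. Cultured cells
appear as islands of lipid signal on a substrate background. Two analyses
are built on such datacubes:

1. **Abundance profile.** Which membrane lipids dominate the cell surface?
   Cell areas are segmented from marker-ion images, their summed spectra
   are cleaned and normalized, the most abundant peaks per polarity are
   ranked and annotated, and the annotations are summarized by lipid
   class.
2. **Turnover comparison.** After incubation with a stable-isotope-labeled
   lipid precursor (a fatty acid, choline, or ethanolamine), which lipid
   pools incorporated the label? Treated and control cell areas are
   compared peak by peak; incorporation shows up as a new peak one isotope
   shift above a library ion together with depletion of its unlabeled
   counterpart.

The cell-area spectrum (region of interest, ROI) — not the pixel — is the
statistical unit throughout: a handful of cell areas per condition
(about 6-10 treated versus about 20 control) is the realistic sample size
for this kind of experiment.

## Ion mass calculus

Lipid shorthand (`PC 38:2`, `LPI O-18:2`, `Cer 34:1;O2`, optionally with
`13C`/`13C2`/`15N` label prefixes) is parsed into class, chain carbons
`n`, double bonds `d`, ether links and oxygen suffix, and converted to a
molecular formula by per-class composition rules (e.g. PC:
C(n+8) H(2n-2d+16) N O8 P). The rules are validated in the test suite
against an independent constructor that assembles each species from
glycerol/sphingoid backbone, phosphate, headgroup alcohol and free fatty
acids with one condensation water per bond; the two routes agree to
below 1e-9 Da. Sterols and cholesteryl esters hide too much structure in
their shorthand and require an explicit elemental formula.

Ion m/z is

    m/z = M + adduct - water(if [M+H-H2O]) - neutral losses -/+ m_e + k*delta

with the adduct one of +H, +Na, +K, -H (or none, for fragments whose
formula is already the ion), named neutral losses for the 87 Da serine
fragment of PS and trimethylamine from PC, the electron mass subtracted
for cations and added for anions, and `k` isotope shifts
(13C-12C = 1.0033548 Da, 15N-14N = 0.9970349 Da) for labeled species. The
electron term (~0.5 mDa) never changes an assignment at the 100 ppm
tolerance used here but keeps the calculus exact. Labeled fatty-acid
precursors are modeled as singly 13C-labeled: every reported labeled ion
in the reference list sits exactly one 13C shift above its unlabeled
form, which fixes this choice; 13C2-ethanolamine contributes two shifts
and 15N-choline one nitrogen shift.

Annotation matches observed peaks against an ion library within a ppm
tolerance (default 100 ppm, the assignment accuracy used for this kind of
instrument at 0.05 Da binning); candidates are ordered by absolute ppm
error with deterministic lexicographic tie-breaking, and unmatched peaks
are kept and flagged rather than dropped. `check_reference_assignments()`
audits a curated list of 70 reported assignments: 97% agree within
100 ppm, and the two known ~1 Da discrepancies ([LPC 16:0+K]+ reported at
535.3, [PE 20:0+Na]+ at 547.32) are flagged as exceptions rather than
forced to match — we do not guess at their cause.

## Datacube model and preprocessing

Spectra are binned to a shared half-open 0.05 Da grid over 100-1000 Da
(18000 bins; a bin boundary belongs to the upper bin, and intensities are
summed, never averaged — these are ion counts). The cube is stored
sparsely (pixels x bins) and read/written as continuous-mode imzML with
an external binary ibd file; the writer and reader interoperate with the
standard Python imzML tooling, which the test suite uses as an
independent cross-check. Pixels are row-major with origin top-left;
imzML's 1-based x/y positions map to column/row.

ROI segmentation replaces the vendor software's manual region drawing
with a reproducible procedure: an Otsu threshold on the marker-ion image
(the phosphocholine headgroup at m/z 184.07 in positive mode; the
palmitate and stearate carboxylates at 255.23/283.26 in negative mode),
4-connected component labelling, a minimum size of 20 pixels (about the
smallest credible cell footprint at 128 x 128 pixels over a 600 um
field), and deterministic ordering by top-most/left-most pixel. Manual
masks can be supplied to bypass segmentation. Substrate interference
peaks are then zeroed (whole 0.05 Da bins; the default list — In+ and two
cluster ions per polarity — is a documented stand-in, since the exact
instrument-specific list is not published), and only then is each ROI
spectrum normalized to its total retained ion intensity. The order
matters and is fixed: removal before normalization, so substrate signal
never inflates the denominator.

## Abundance profile

Peaks are strict local maxima of the mean normalized spectrum above an
intensity floor (1e-4 of the maximum) and a prominence floor (2 median
absolute deviations of the nonzero bins). The 45 most abundant peaks per
polarity (ties broken toward lower m/z) are annotated and pooled; the
class summary counts top-peak entries, not unique species, so a lipid
detected as several ionization forms counts once per form — matching how
such profiles are usually reported. A `unique_species` option collapses
adduct duplicates instead.

## Turnover statistics

For one treated-vs-control comparison per polarity: peaks are picked on
the pooled mean spectrum; the spectra-by-peaks matrix is mean-centered
(unit-variance and Pareto scaling are options; mean-centering is the
default because the vendor software's scaling choice is not published)
and decomposed by SVD; the component whose scores best separate the two
groups (largest absolute Welch t statistic) is chosen, and the peaks in
the top fraction of absolute loading on it are selected. Each selected
peak then gets a two-sided Mann-Whitney U test on the normalized
intensities, a direction call from the group means, an annotation, and an
isotope-shift flag marking peaks within tolerance of (library ion + label
shift). Significance is raw p <= 0.05 by default, with Benjamini-Hochberg
adjustment available — raw by default because the source workflow states
only a p <= 0.05 cutoff.

The Mann-Whitney implementation uses midranks, exact enumeration of all
group assignments when n1 + n2 <= 20 (ties handled exactly), and the
tie-corrected normal approximation with continuity correction otherwise.
It is checked in the tests against a brute-force oracle that never
computes ranks, and against `stats::wilcox.test` on both asymptotic and
exact no-tie paths.

**Selection fraction.** The bare selector defaults to the top 5% of
loadings, a sensible budget for real spectra with a couple of thousand
detected peaks. The pipeline default is 15% of the picked-peak features:
under the generator's standard conditions (~190 picked peaks per
polarity, ten labeled species whose ions contribute both a depleted
source peak and a new labeled peak, ~18 affected bins per polarity), a
5% budget of ~10 bins cannot contain the affected set, capping recall
around 0.5 regardless of effect size; 15% (~29 bins) gives the affected
set room plus margin. This was calibrated on the generator before the
acceptance checks were frozen, and the type-I consequence is measured
rather than assumed (below). PCA selection before testing induces
selection bias by construction; a `test_all` mode bypasses selection
entirely.

## The synthetic datacube generator

No raw single-cell datacubes are publicly deposited for this kind of
experiment, so the generator is a first-class module that emulates the
statistical structure the analysis assumes, with known ground truth:

* **Lipidome.** 65 ions per polarity with m/z computed by the package's
  own calculus; the 45 most intense per polarity follow the class mix
  reported for such cells (33% PC, 11% PS, 11% Cer, 9% SHexCer, 9% PE,
  remainder across FA/PI/LPI/DG/MG/HexCer/LPA/LPE/PG), plus 20 minor
  ions. The species set is curated so that, at 0.05 Da binning, no two
  same-polarity ions and no labeled bin of a default target collide —
  the real assignment list contains several such coincidences (e.g.
  13C-PI 38:4 vs PS 44:8 at 886.55/886.56), which a ground-truthed
  simulator must avoid to keep truth identifiable.
* **Geometry.** Elliptical cells (jittered axes) placed without overlap
  on a pixel grid; substrate pixels carry the interference ions.
* **Counts.** Expected per-pixel spectra are delta peaks in single bins
  (the instrument peak width is below the 0.05 Da bin width at this
  binning, so spreading a peak over neighbouring bins would add nothing
  the analysis could see), scaled to a
  mean total of 600 lipid counts per cell pixel — the order of magnitude
  a cluster-beam instrument collects per pixel at these doses — and drawn
  as Poisson counts. A chemical background of 30 counts per pixel is
  spread over 400 fixed pseudo-random bins, emulating the quasi-discrete
  hydrocarbon background of SIMS spectra (a uniform continuum would be
  invisible at integer counts). Per-ROI, per-ion lognormal factors with
  20% coefficient of variation model biological cell-to-cell
  variability; without them, Poisson-only variance would make every tiny
  difference significant and the calibration study meaningless.
* **Incorporation.** A labeled arm moves a fraction `f` of each target
  ion's expected intensity to the bin one label shift higher — a
  pseudo-steady state after a multi-day incubation, not a kinetic model,
  because direction and extent at a fixed chase time are all the
  analysis observes. `f` is a free parameter (the real per-lipid
  fractions are unknown); the default 0.3 is the level at which the
  acceptance study demands reliable detection. Ten target species per
  precursor arm mirror the reported incorporation patterns (stearic acid
  into PCs/FAs/PIs, ethanolamine into CerPE/PE/LPE/PS, choline into
  PC/LPC/SM, and so on).
* **Determinism.** Every draw derives its stream from the config seed via
  a named hash, so arms, polarities and fields are independently
  reproducible and manifests are byte-identical across runs.

Two generation routes exist: full image rendering (for segmentation and
file-format work) and direct ROI-spectrum simulation, which draws the
summed spectrum of whole cell areas — distributionally equivalent to
rendering, segmenting and summing under this model — and makes
replicate-heavy studies cheap.

What the generator does **not** emulate: matrix effects and ion
suppression, detector saturation and dead time, mass-dependent peak
width, topography and charging, isotope envelopes (only the labeled
monoisotopic shift is modeled), and chromatographic-style isomer
ambiguity. Passing the recovery tests therefore shows the pipeline is
correct and calibrated under its own assumptions, not that those
assumptions hold on any particular instrument.

## Validation studies and problem sizes

The test suite runs three simulation studies at sizes chosen to finish in
minutes on one core, with every study seeded:

* **Class-mix recovery.** On a noiseless 32 x 32 fixture the full profile
  pipeline (render, segment, clean, normalize, pick, rank, annotate,
  summarize) returns the planted class fractions exactly.
* **Power.** 200 replicates at f = 0.3, 8 treated vs 20 control ROIs:
  the fraction of truly label-shifted bins that are selected and
  significant (recall) must reach 0.8. Measured during design: ~0.9 at
  the default selection fraction.
* **Null calibration.** 500 replicates at f = 0: the significant fraction
  among selected peaks must lie in [0.02, 0.09] at nominal alpha = 0.05.
  The band is deliberately asymmetric around 0.05 because data-dependent
  selection inflates the realized rate; measured during design: ~0.05-0.06.

## Known limitations

* Composition rules cover the common membrane classes; sterols and
  cholesteryl esters need explicit formulas, and oxidized species are
  handled only through the `;Ok` suffix.
* Isomers (sn-position, double-bond position or geometry) are outside the
  mass calculus: an omega-3 and omega-6 fatty acid of the same n:d are
  the same peak. Distinguishing precursors of identical mass is an
  experimental-design matter, not a spectral one.
* The ~1 Da reference discrepancies are flagged, not resolved.
* Continuous-mode imzML stores dense per-pixel arrays; full-axis files
  are large, so the disk route is demonstrated on a reduced axis while
  statistical studies use the in-memory ROI route.
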