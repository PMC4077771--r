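---
title: "Triangular EEM acquisition and analysis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triangular EEM acquisition and analysis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eem2d)
```

## The data model

A two-dimensional fluorescence spectrum is a matrix
$I(\lambda_{ex}, \lambda_{em})$ with excitation on the rows (Y) and
emission on the columns (X). Fluorescence is Stokes-shifted, so the region
$\lambda_{em} \le \lambda_{ex}$ carries no signal at the intensities of a
typical Xenon source; the *triangular* acquisition scheme therefore starts
each emission scan one step (or a configurable offset) above the current
excitation wavelength and skips that region entirely. Stopping the
excitation scan early, once the remaining emission range is short, gives a
*trapezoidal* plan.

`eem2d` represents the stages of the workflow with four S3 classes:

* `triangular_scans` — the per-excitation emission traces exactly as
  acquired (one row per excitation, all rows on one emission step and one
  common maximum emission wavelength).
* `eem` — the rectangular matrix after conversion, with a logical
  `acquired` mask alongside the intensities.
* `acquisition_plan` — the schedule of (excitation, emission-range) scans.
* `spectrum1d` — a 1D emission or excitation slice with its fixed
  conjugate wavelength (requested and actually used).

### Conversion and the zero-fill convention

`triangular_to_rectangular()` is a pure reshaping step. The emission axis
spans from the *first excitation wavelength* (not the first acquired
emission point) to the common maximum emission wavelength, so the Rayleigh
diagonal $\lambda_{em} = \lambda_{ex}$ is representable inside the grid and
can be drawn as the separator between the measured region and the filler.
Every measured point is placed at its exact emission wavelength — a
wavelength off the global grid (tolerance $10^{-9}$ nm) is a hard error,
and no interpolation exists anywhere in the package. Unmeasured cells are
filled with exactly 0.

Zero-filling alone cannot distinguish "not measured" from "measured zero",
so the `acquired` mask travels with the matrix and every statistic that
matters (the contour intensity scale, peak picking, slices) is computed
over acquired cells only. The interchange files do not carry the mask;
`read_matrix_files()` rebuilds it as $\lambda_{em} > \lambda_{ex}$, which
is exact for one-step-offset triangular data. Two corner cases are thereby
unrepresentable in the files and documented on the reader: a measured
value at or above the diagonal, and an unmeasured cell below it (as occurs
with an emission offset of more than one step), which re-reads as an
acquired zero.

## Acquisition economics

For a matched pair — identical excitation rows, step and final emission
wavelength, with the rectangular comparator spanning `ex_start` to
`em_end` in every row — an $N$-row triangular plan with one-step offset
ending one step below `em_end` measures $N(N+1)/2$ points against the
rectangle's $N(N+1)$: a saving ratio of exactly 2, and never more than 2
for any matched one-step-offset pair (the emission span per row always
exceeds the excitation span by at least one step). The package computes
the ratio from explicit row expansions, not the closed form, and the tests
cross-check both. Whether a practitioner's rectangular comparator starts
emission at `ex_start` or elsewhere is a convention; this matched
definition is the one that makes the two-fold bound provable, and
instrument dead time (monochromator slew, integration overhead) is
deliberately out of model — wall-clock savings on hardware are of the same
order but not identical.

## Processing

**Baseline subtraction** (`subtract_baseline()`) is elementwise on the
intersection of the two acquired masks and requires bitwise-equal axes:
sample and baseline are measured on the same programme, so resampling is
neither needed nor offered, and an axis mismatch is an error rather than a
silent regrid. Negative differences are preserved because the same
operation serves difference spectra between related samples or time
points.

**Contour levels** (`contour_levels()`): "percent of the full intensity
scale" is interpreted as percent of the maximum intensity over *acquired*
cells — contour levels must live on the intensity scale of the plot, and
the zero-filled triangle must not distort it (with all-negative
differences the acquired maximum is negative, and the signed maximum is
used as-is). Levels are evenly spaced between the two percent bounds and
scale linearly with intensity. Automatic scaling of raw 2D spectra is
impractical because the second-order reflection dominates; the intended
workflow is manual adjustment of the two percent bounds over repeated
runs.

**Scatter annotation** (`annotate_scatter()`) marks three ridges by
geometry alone: the first-order (Rayleigh) reflection
$|\lambda_{em} - \lambda_{ex}| \le w_1$, the grating second-order
reflection $|\lambda_{em} - 2\lambda_{ex}| \le w_2$, and the water Raman
ridge $|\lambda_{em} - \lambda_R(\lambda_{ex})| \le w_3$ with
$\lambda_R = (1/\lambda_{ex} - \Delta\tilde\nu)^{-1}$ in consistent units
(`raman_wavelength()`; default shift 3400 cm⁻¹, the water O–H stretch —
configurable, since the exact band position varies with temperature and
solutes). Excitations whose wavenumber falls below the shift have no
physical Raman solution and are left unmarked. Default half-widths of
10 nm are of the order of typical slit bandpasses; they are display/mask
parameters, not physical constants.

**Peak picking** (`find_peaks()`) reports strict local maxima over the
8-neighbourhood among acquired, non-masked cells above a percent threshold
of the candidate-cell maximum. Strictness means plateaus and flat matrices
yield no peaks; ties between two exactly equal adjacent maxima (measure
zero under noise) are dropped rather than arbitrated.

## Slicing semantics

Requests for a slice wavelength use the *nearest existing* grid value; the
object records both the requested and the used wavelength. Ties (a request
exactly midway between grid points) resolve deterministically to the lower
wavelength; requests outside the axis clamp to the nearest endpoint with a
warning. Slices return only acquired cells — an excitation slice stops
where the Rayleigh diagonal truncates the column — and the X-window is a
pure filter. Exported slice files embed the kind and the used wavelength
(`em_slice_ex_360nm.txt`), so re-runs at other wavelengths accumulate a
comparable family, as do 2D exports which embed the contour percents.

## The synthetic generator

`simulate_eem()` evaluates, at every planned point,

$$I = \sum_k A_k\, e^{-(\lambda_{ex}-x_k)^2/2\sigma_{x,k}^2}
             e^{-(\lambda_{em}-m_k)^2/2\sigma_{m,k}^2}
    + \sum_{r \in \{1,2,R\}} B_r\, e^{-(\lambda_{em}-c_r(\lambda_{ex}))^2/2w_r^2}
    + \varepsilon,\qquad \varepsilon \sim N(0, \sigma^2),$$

with the ridge centres $c_1 = \lambda_{ex}$, $c_2 = 2\lambda_{ex}$,
$c_R = \lambda_R(\lambda_{ex})$. Separable Gaussian peaks, Gaussian ridge
profiles and additive (rather than Poisson) noise are modeling choices
made for analytic tractability: every expectation in the tests is closed
form, and the noise-free simulator output is reproduced independently in
the test suite from this formula. The generator is seeded explicitly and
is bit-reproducible; different seeds change only the noise term.

`hras_preset()` emulates a Ras-GTPase/mant-GDP sample on the measurement
grid `hras_plan()` (200–700 nm, 5 nm step, triangular): tyrosine
fluorescence at (280, 330) nm with amplitude 1000 counts/s, the two
mant-GDP bands at (360, 440) and (260, 440) nm at 260 and 200 counts/s
(tyrosine much stronger, as when endogenous GDP is only partially
exchanged), Gaussian widths 12–20 nm chosen so each peak is several mask
widths clear of every ridge on the 5 nm grid. `buffer_preset()` carries
the identical scatter model (Rayleigh 800, second-order 300, Raman 120
counts/s) and no fluorophores, so sample-minus-buffer subtraction cancels
the ridges the way a measured baseline does. Peak widths and absolute
intensities are invented constants: the emulated experiment's instrument
counts are not published, and none of the package's checks depend on their
absolute values, only on orderings and positions.

What the generator does *not* emulate — and what passing tests therefore
do not demonstrate about real data: detector saturation (real second-order
ridges saturate), inner-filter effects, wavelength-dependent instrument
response (the raw/corrected distinction is structural only: the corrected
channel defaults to a copy of raw), Poisson photon statistics, and lamp
drift. Scatter *removal* beyond baseline subtraction (interpolation
through ridges, PARAFAC) is out of scope.

One check deserves a note: after sample-minus-buffer subtraction the
Rayleigh and Raman ridge cells are asserted to fall to the noise floor of
the difference ($6\sigma\sqrt2$, the two measurements' noise combined).
Real fluorophores legitimately overlap the ridges — the tyrosine band at
330 nm emission sits ~20 nm from the Raman centre at 280 nm excitation —
so that assertion is evaluated on ridge cells outside the fluorophores'
4-sigma support, where only cancelled scatter and noise remain. Inside the
support the persistence of the peaks is what the peak-recovery check
asserts.

## The export dialect

The group-export layout of vendor software is not publicly specified, so
the parser implements a documented stand-in dialect: a header line per
trace (`raw:ex=<nm>` or `corr:ex=<nm>`), then two-column numeric lines
(emission nm, intensity) separated by tab or comma, raw traces before
corrected ones, tolerant of CRLF and blank lines. The simulator emits the
same dialect (`write_export()`), so the parser is exercised end-to-end.
All interchange files serialize doubles with 17 significant digits, which
round-trips IEEE doubles bit-exactly. The corrected channel is the default
everywhere, matching what one normally analyses.

## Driver and graphics

`run_analysis()` mirrors a settings-file driven workflow: a plain
`key = value` text file (no GUI, deliberately — trivially scriptable and
diffable) selects the data folder, optional baseline folder, mode (`2D` or
the two 1D slice modes), contour percents, colormap (default blue-to-red)
and export switch. With `graphics_export = "off"` (trial runs while
adjusting contour levels) nothing is written; with `"on"` each figure goes
to four files: 300 dpi PNG, 72 dpi PNG, EPS, and a serialized figure-data
RDS for programmatic re-display. The baseline-corrected matrix is written
whenever subtraction is on, regardless of the graphics switch, so the
corrected data stay accessible as plain text. In non-interactive sessions
figures are composed but only rendered into files, never onto a device, so
a scripted run with export off leaves the directory untouched.

## Problem sizes and numerical choices

The test suite and the acceptance script run on the 60-row, 10 nm planning
grid (1830 triangular / 3660 rectangular points) and the 100-row, 5 nm
measurement grid (5050 acquired cells) — the sizes the workflow was
designed around, and comfortable for routine test runs. Property checks
use 10–50 randomized triangular sets or plan pairs per invariant under
fixed seeds. Grid membership uses a $10^{-9}$ nm absolute tolerance;
equality of axes for subtraction is exact; file round trips are asserted
bit-exact, not approximate.

## Known limitations

* One uniform grid per dataset; non-uniform or wavenumber axes are
  rejected at construction.
* The acquired mask is in-memory only; the file format cannot represent
  the two diagonal corner cases noted above.
* `saving_ratio()` bounds hold for one-step emission offsets; larger
  offsets can push the point ratio above 2 for short rows, which is why
  the matched-pair validator insists on shared rows, step and emission
  end rather than attempting a general bound.
* No vendor-exact parsers (binary or otherwise) and no instrument
  control; the CLI's `convert` expects the documented text dialect.
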