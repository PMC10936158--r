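---
title: "Quantifying DNA content across a foraminiferal life cycle: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying DNA content across a foraminiferal life cycle: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ploidyscope)
```

## The problem

*Allogromia laticollaris* strain CSH, an early-diverging foraminifer, runs
a life cycle in which true haploidy and diploidy are fleeting: most stages
carry massively endoreplicated genomes, up to roughly 12,000 haploid
copies in a single nucleus. Before gametogenesis the cell resets ploidy
through *Zerfall*: the nuclear envelope breaks down, chromatin is
reorganized in the cytoplasm into threads a quarter to a third of a
micrometre wide, and the threads resolve into hundreds of compact bodies
("haploid genome complements"), each carrying about one gamete's worth of
DNA.

Because the organism is uncultivable at scale and nuclear DNA content can
only be read out through fluorescence, the quantitative chain is:
Hoechst-stained confocal z-stacks, 3D segmentation, integrated
fluorescence per nucleus (in arbitrary units F), normalization to
C-values against the gamete median, and conversion to base pairs via
standards of known genome size. `ploidyscope` implements that chain as
tested, reusable R code, together with a synthetic scene generator that
provides ground truth for every stage of it.

## The synthetic scene generator

Every quantitative claim the package makes about itself is a closed loop
through the generator: simulate nuclei with known DNA content, render,
measure, compare.

**Nuclei** are ellipsoids with one of three radial intensity
architectures:

* `H` — homogeneous staining;
* `HDP` — homogeneous with a small DNA-poor centre (default: the inner
  45% of the radius at 0.35 times the shell intensity);
* `V` — "vegetative": a bright peripheral chromatin ring (outer 30% of
  the radius) around a DNA-poor core at 0.15 times the ring intensity,
  with a handful of small bright bodies (condensed chromosomes) in the
  core. The ring can be rendered `smooth` (lattice-like) or `beaded`
  (bright spheroids with dimmer gaps).

The rendered object is scaled so its integrated pre-noise intensity
equals `dna_bp * fluor_per_bp` exactly; the default `fluor_per_bp` puts a
1C (34 Mb) nucleus at 0.11 MF, the scale of the tabulated gamete median.
The PSF is a separable anisotropic Gaussian (defaults
$\sigma_{xy} = 0.1\,\mu m$, $\sigma_z = 0.3\,\mu m$) whose kernel columns
are normalized, so blur redistributes intensity but conserves it. Noise
is Poisson shot noise on a configurable photon scale plus optional
additive Gaussian read noise; both are off in unit-test scenes. Default
voxels are $0.1 \times 0.1 \times 0.13\,\mu m$ — the axial step matches the
acquisitions this generator emulates; the in-plane pitch is a declared
choice sized so gamete-scale nuclei span well over
five voxels.

The "default noise" condition used by the closed-loop recovery tests is
shot-noise-limited (`photon_scale = 1`, no read noise). Line-averaged
confocal acquisition is effectively shot-noise-limited, and additive
read noise clipped at zero would act as a spurious positive background:
on a dim yeast-sized standard nucleus it inflates integrated
fluorescence by tens of percent, which is a detector-offset artefact,
not a property of the measurement chain under study.

**Populations.** `sample_stage_population()` draws volumes and C-values
for a life stage from the packaged per-stage table of medians and
quartiles. The sampler is a two-piece log-normal: below the median the
log-sd is fitted to the lower quartile, above it to the upper quartile.
A single log-normal cannot do this — several stages have strongly
asymmetric interquartile ranges in log space (the V2 C-value row spans
0.44 to 180 around a median of 85) — whereas the two-piece form matches
the printed median and both quartiles exactly in distribution. Volumes
and C-values are drawn independently; the generator does not model the
empirical volume-fluorescence correlation, so joint statistics
(e.g. regression slopes of fluorescence on volume) should not be read
off synthetic populations.

**Zerfall scenes** partition a total DNA content across up to three
structure classes: constant-width tubes along smooth random paths
(threads), Gaussian spots of one genome complement each (puncta), and
dense homogeneous fragments (globular chromatin). Conservation of total
fluorescence through fragmentation therefore holds by construction, and
the measurement side must recover it.

**What the generator does not emulate:** optics-grade PSFs, fixation
artefacts, AT-base-composition staining bias, autofluorescent food
vacuoles, spatial gain variation within a stack, nuclear shapes beyond
ellipsoids, and the geometry of meiotic bouquets (MB is accepted as a
manual annotation only; no bouquet detector is attempted). Passing
closed-loop tests therefore demonstrates the internal consistency of the
measurement chain, not its accuracy on real micrographs.

## Segmentation and measurement

Objects are maximal connected components of above-threshold voxels
(compiled breadth-first labelling; lattice connectivity 6 or 26,
anisotropy deliberately ignored in the adjacency). Three conventions
matter and are worth stating because the original analysis software is
closed:

* **Hole filling.** A vegetative nucleus thresholds as a bright ring
  around a sub-threshold centre. Nuclear volume means the volume of the
  nucleus, not of its bright chromatin, so enclosed cavities are filled
  before labelling; this also merges the core's condensed chromosome
  bodies into their nucleus.
* **Fluorescence halo.** The PSF pushes roughly 15% of a small nucleus's
  light just outside the thresholded boundary. The fluorescence integral
  therefore runs over the mask dilated by a physical radius (default
  0.45 um, about 1.5 axial PSF sigma); a voxel claimed by two objects is
  credited to the nearer one, so the per-stack sum of object
  fluorescence can never exceed the stack total. Volume and voxel count
  always come from the undilated mask.
* **Raw intensities.** The integral sums raw, unthresholded intensities
  over the measurement region; nothing is background-subtracted inside
  nuclei. Whole-cell measurements (used for *Zerfall* cells whose signal
  is dispersed through the cytoplasm) subtract the median intensity
  outside the mask times the mask size.

Thresholds: `otsu` (pooled histogram over the full stack) reproduces the
classic bimodal split and keeps single-object volumes within a few
percent. When one stack contains nuclei differing in brightness by an
order of magnitude, Otsu splits *within* the signal and silently drops
the dim objects; `otsu_log` (Otsu on log intensities) separates signal
from background instead and is the pipeline default. The original
per-stack manual thresholds are unrecorded, so neither is a
reconstruction — they are documented, reproducible stand-ins. A degenerate
constant stack is an error; a manual value outside the intensity range is
passed through with a warning.

## Calibration

A standard is a species of known haploid genome size $G$ imaged under the
same protocol; with assumed ploidy $C_s$ of its measured nuclei and mean
nuclear fluorescence $\bar F$, its calibration constant is
$\mathrm{bp/F} = G\,C_s/\bar F$. Method 1 multiplies a nucleus's total
fluorescence by the yeast constant; method 2 uses the mean per-nucleus
ratio pooled across all standard nuclei (per-species pooling is exposed
as an option). Both estimators are exactly linear in fluorescence, so the
ratio of their standard deviations over any nucleus set equals the ratio
of the two constants — the package verifies this against brute-force sd
computation. The assumed ploidy of standard nuclei is explicit
configuration, never a constant: the staining protocol cannot reveal
whether an imaged somatic nucleus was at 1C, 2C or 4C. No GC-content
correction is applied; Hoechst's AT preference is a recognized caveat of
the whole approach, not something this package can repair.

## C-values and stage statistics

The C-value of a nucleus is its total fluorescence divided by the median
total fluorescence of gamete nuclei, pooled across cells — gametes being
the putatively haploid reference. Both numerator and denominator are
fluorescences, so gain changes cancel; C-values are invariant under
global intensity rescaling and the package tests that property. Stage
summaries report counts, medians and quartiles using linear interpolation
between closest ranks (the `type = 7` convention). Border-touching objects are excluded from summaries by
default. `fold_range()` and `median_ratio()` reproduce the headline
comparisons: a 144,000-fold volume range from the printed extremes, and
V1 nuclei at roughly 9 and 19 times the median DNA content of MB and H
nuclei.

## Architecture classification

The radius coordinate is built from the interior distance-to-boundary
transform: $r_{norm} = 1 - d/d_{max}$, 0 at the deepest interior point, 1
at the boundary. Unlike centroid distance this behaves correctly for
oblong nuclei. The peripherality index P is the mean intensity over shell
bins ($0.7 \le r_{norm} \le 0.9$) divided by the mean over core bins
($r_{norm} \le 0.5$); the outermost sliver above 0.9 is excluded because
a thresholded object's rim carries partial, PSF-decayed intensity
whatever its architecture. P is scale-invariant by construction.

The three-way call uses thresholds $t_H = 1.3$ and $t_V = 2.0$,
calibrated once on noiseless renders: homogeneous nuclei measure
$P \approx 0.9$ (the residual rim effect), HDP nuclei $\approx 1.6$–$1.8$,
vegetative nuclei $\approx 3$–$5$. On balanced synthetic sets the
classifier is exact without noise and comfortably above 85% under shot
noise. These thresholds are calibrated to this generator; transfer to
real micrographs is untested by design, since the original architecture
assignments were made by eye. The beaded/latticed distinction is reported
as a continuous shell-texture score (coefficient of variation of shell
intensities) rather than a hard class — no threshold for it is published.
Two-channel stacks (DNA plus nascent RNA) reuse the same binned radius;
the DNA/RNA profile correlation is negative for vegetative nuclei whose
transcription is concentrated in the DNA-poor centre.

## Zerfall morphometrics

Thread width is measured in-plane, per z-slice: threshold, Zhang-Suen
skeletonization, and twice the Euclidean distance from skeleton points to
the mask boundary (minus half a pixel for the centre-to-centre offset).
Axial width measurement is deliberately not attempted: a 0.13 um z-step
under a ~0.3 um axial PSF cannot support 0.3 um widths. Three refinements
make the estimator honest:

* the mask is re-thresholded at half the skeleton plateau intensity — a
  mask-based analogue of full-width-at-half-maximum — because a global
  background threshold sits far below a blurred thread's plateau and
  inflates the mask;
* skeleton points near branch points are excluded, since thread
  crossings widen the mask geometrically;
* when the lateral PSF sigma is known (as it is for synthetic scenes),
  the half-peak width is deconvolved by inverting the blurred-bar width
  function — the half-peak width of a 0.30 um bar under a 0.1 um PSF is
  0.33 um, and the inversion removes exactly that bias.

Whether the published width range is FWHM-like or mask-based is not
stated; the mask-at-half-plateau convention is this package's declared
one. Puncta are detected by multiscale difference-of-Gaussian filtering
with anisotropic kernels, non-maximum suppression at three detected
sigmas, and integration of raw intensity over an ellipsoid of three
sigmas (1.9 times elongated axially); that radius captures essentially
all of a Gaussian spot's mass, and the closed loop recovers the
one-genome-complement fluorescence per punctum within a few percent.
Structure classes are assigned by shape: skeleton length above five times
the mean width makes a thread; volume at or below 1.5 um^3 with neither
thread geometry makes a punctum; the remainder is globular.

## Life-cycle statistics

Longitudinal tables record one observation per cell per day. Sparse
(biweekly) observations are carried forward, so a stage's duration is the
number of days from its first observation to the first observation of the
next stage; the package warns on gaps above 14 days rather than
interpolating more cleverly. Emergence classes use the published
boundaries with both 25 and 35 days belonging to "middle". Transition
percentages are reported with their raw counts and rounded only for
display. The synchrony index is the mean daily fraction of cells in the
modal stage, bounded between 1/k and 1 for k observed stages. Cells
flagged as deviating (budding, reproductive arrest) are excluded from
duration summaries, the same handling the reference durations received. The cohort simulator draws stage durations per cell from truncated
normals whose type-specific totals default to 25 +/- 3 days (Type 2) and
31 +/- 10 days (Type 1), and assigns each emerger's own reproductive type
by the cross-type switch probabilities 0.72 and 0.93.

## Numerical choices and degenerate inputs

* Quantiles: linear interpolation between closest ranks, everywhere.
* Connectivity default 26; minimum object volume 0.05 um^3 (below the
  0.30 um^3 *Zerfall* sphere class, above single-voxel noise).
* Rendering is bit-reproducible under a fixed scene seed; every
  stochastic test fixes its seed.
* Degenerate inputs fail loudly: constant stacks under Otsu, empty
  masks, empty gamete references, non-positive fold-range inputs,
  zero-variance profiles in correlations, unknown stage labels (the
  error lists the valid ones).
* Problem sizes in the shipped tests are chosen so the full suite runs
  in about a minute: per-nucleus stacks of roughly 30-60 voxels per
  side, populations of 60-100 nuclei per stage, ten Zerfall scenes for
  the width loop, and classifier batches of 60 nuclei.

## Known limitations

Absolute genome-size reproduction (the 34 Mb / 64 Mb estimates) is out of
reach: the underlying per-nucleus measurements are not public, and the
package's closed loops validate the estimators, not the data. Touching
nuclei are not split by watershed (the measured nuclei were
well-separated); stages are user-supplied annotations except for the
H/HDP/V call; and everything the generator does not emulate (listed
above) bounds what synthetic validation can show.
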