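---
title: "Quantifying extrachromosomal telomere-repeat DNA from Halo-FISH images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying extrachromosomal telomere-repeat DNA from Halo-FISH images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The assay and the computational problem

Halo-FISH embeds live cells in a thin agarose layer, lyses and
deproteinizes them, and denatures the DNA with NaOH. Chromosomal DNA is too
large to move through the gel and stays in a compact, intensely DAPI-stained
"nuclear core"; extrachromosomal molecules diffuse outward and settle in a
surrounding "Halo". Strand-specific PNA probes then label the G-strand
(TTAGGG, Cy5) and C-strand (AATCCC, Rho) of telomere-repeat DNA, a
pan-centromere probe (FAM) marks chromosomal centromeres, and each nucleus
is imaged as a 4-channel widefield z-stack (40 planes at 0.2 µm).

This package implements everything downstream of the camera: deconvolution,
core/Halo segmentation, 3D spot detection, plasmid-standard calibration of
integrated probe intensity into DNA base pairs, and per-nucleus
quantification of extrachromosomal telomere-repeat (ECTR) DNA — counts,
lengths, strand biases, chromosomal-versus-extrachromosomal partitioning,
and centromere-based cell-cycle binning. Because no public image data exist
for this assay, the package also contains a first-class forward simulator
that renders ground-truthed synthetic acquisitions; every pipeline stage is
validated against that ground truth.

## The simulator

`sim_config()` describes the virtual microscope. Defaults follow the assay's
acquisition where stated (40 z-planes at 0.2 µm, 12-bit camera) and standard
widefield practice where not:

* xy pixel pitch 0.16 µm (a 40x/0.95 objective with a 1" interline CCD);
* separable Gaussian PSF, σ = 0.12 µm laterally and 0.35 µm axially;
* Poisson shot noise, Gaussian read noise (SD 2 ADU), camera offset
  100 ADU, clipping at 4095 ADU (12 bit), unit gain (1 ADU/photon);
* photon yield 1 photon per base pair of hybridized target, flat background
  of 10 photons/voxel.

The photon yield, background and read noise are package decisions, not
values inferred from the assay's hardware; they were chosen so that the
810-bp calibration standard is detected with a comfortable but not extreme
peak signal-to-noise ratio (about 10:1), which is the regime the assay's
own threshold logic implies. With unit gain, molecules beyond roughly
55 kb saturate individual voxels of the 12-bit camera; simulated length
statistics therefore compress the extreme upper tail, which is a real
property of fixed-exposure acquisition and is flagged by a saturation
warning.

### Nuclei

`build_nucleus_truth()` models the deproteinized nucleoid as an oblate
spheroid (default xy radius 7 µm, z semi-axis 2 µm) centered in the field:
lysis and deproteinization swell the nucleoid laterally while the agarose
layer keeps it flat. Chromosomal content is explicit: per chromosome
(2N = 46 by default) one centromere focus and two telomere foci are placed
uniformly inside the core. Chromosomal telomeres are duplex — they carry
both strands at one position and are rendered into both telomere channels —
which is what makes G/C colocalization inside the core near-total, and the
expected core telomere:centromere focus ratio exactly 2 in G1. G2 doubles
and S multiplies by 1.5 both centromere and telomere entries.

ECTR molecules live in the Halo. Their xy distance from the core edge is a
fixed 0.8 µm standoff plus a half-normal draw (scale 2 µm) — diffusion
clears a visible gap between core and Halo foci and keeps molecules inside
the field of view, matching the assay's tuned denaturation conditions — and
their z position is uniform within ±2 µm of the core plane. Placement
outside the field is retried and eventually errors.

### ECTR population laws

Per-nucleus molecule counts are negative binomial (size 2 by default),
reproducing the reported spread from under 20 to over 300 molecules per
nucleus around means of order 100; each molecule is independently G-strand
with probability `mean_G / (mean_G + mean_C)`. Lengths are log-normal with
σ = 1.25, giving the strong positive skew with mean 2–2.5× the median seen
in ALT cells. The packaged presets encode the three ALT lines studied with
the assay (GM847: 126/95 G/C molecules, median ~12 kb; VA13: 59/44,
~12 kb; U2OS: 21/14 but longer molecules, median ~43 kb) plus a primary
fibroblast control (WI38, < 5 molecules). Cell-cycle progression scales the
count rate (3.5× in G2 by default, within the reported 2.7–4.9× range)
much more than the length scale (1.226× median).

One known inconsistency is documented rather than hidden: with ~100
molecules of median ~12 kb against 92 chromosomal telomeres of ~15 kb, the
simulated extrachromosomal fraction of total telomere-repeat DNA comes out
near 50%, higher than the ~15–20% the assay reports for the same cells.
The per-molecule count and length laws and the reported fraction cannot all
hold simultaneously with a diploid telomere complement; the simulator
follows the per-molecule laws, which are what the downstream statistics
are validated against.

## Preprocessing

`deconvolve()` implements Richardson–Lucy iteration (default 10 iterations)
under the Gaussian PSF, operating on offset-subtracted intensities with
reflective boundaries; flux is conserved globally and per focus to well
under 1%, the estimate stays non-negative, and a uniform image is a fixed
point. Deconvolution sharpens crowded core foci and improves their
splitting; detection counts on clean, well-separated fields are invariant
to it, so large simulation batches that only need Halo statistics may skip
it (`deconvolve_iterations = 0` in `analyze_stack()`).

`estimate_background()` is a per-z-plane median. During focus measurement
the background is re-estimated from voxels outside every detection
aperture, because in crowded planes the plain median is biased upward by
focus signal.

## Segmentation

`segment_nuclear_core()` thresholds the log-intensity of the smoothed DAPI
channel (Otsu's split refined by isodata iteration — with a small bright
body Otsu's histogram criterion alone sits too low), fills 3D holes, and
takes the largest connected component as the core. The threshold sits
between the background and core intensity levels, which places the mask
boundary slightly *outside* the true core surface (about 0.9× the total
blur σ); this deliberate outward bias is what guarantees that molecules
truly inside the core are inside the mask, at the cost of a few percent of
volume overestimate. A 2-voxel guard dilation separates core from Halo so
that PSF bleed from core chromatin is never scored as Halo signal; the
Halo is the entire remaining field of view. Fields without a bright body
("no nucleus") and off-center nuclei touching more than 25% of the border
are reported explicitly.

## Spot detection and intensity integration

`detect_foci()` finds candidate spots as 3D local maxima of a
difference-of-Gaussians band-pass (a Laplacian-of-Gaussian approximation)
computed at 0.5× the PSF scale — slightly finer than matched filtering,
trading a little peak SNR (which is abundant) for better separation of
crowded core foci along z, where widefield resolution is poorest. The
detection cut is `max(2 ADU, 7 × MAD)` of the response: the MAD term adapts
to the noise level, the absolute floor keeps detection defined on noise-free
synthetic images, where deconvolution ripple (≤ ~2 ADU) would otherwise
create spurious weak maxima. True foci of even the smallest calibrated
length (810 bp) respond at ≥ ~7.5 ADU, several-fold above both terms.

Each peak owns an ellipsoidal aperture of 4.5 PSF σ per axis (capturing
99.98% of a Gaussian spot's flux); voxels in the union of apertures are
partitioned among peaks by marker-based watershed on the smoothed
intensity, so isolated foci keep their full aperture while overlapping foci
split the contested voxels. Integrated intensity is the
background-corrected sum over the assigned region; foci whose aperture
crosses the xy border are flagged and excluded from length estimation
(their flux is truncated). Compartments are assigned by centroid;
guard-zone centroids count as core.

Residual detection loss is honest physics: two same-channel foci closer
than roughly the response width (≈ 0.25 µm laterally, ≈ 0.8 µm axially)
merge into one detection. At the default geometry this costs a few percent
of the 92 chromosomal telomere foci (and less of the sparser centromeres),
so the measured core telomere:centromere ratio sits slightly below the
ideal 2.0; in the densest Halo fields (hundreds of molecules) it costs
up to ~8% of the molecule count, which bounds the accuracy of per-nucleus
counts in the highest-burden nuclei.

## Calibration

`fit_calibration()` converts integrated intensity to base pairs with a
zero-intercept model (background is subtracted upstream, so a free
intercept would double-count it). With only the 135-repeat (810 bp)
standard the slope is `mean(I_810)/810`; with both standards it is the
least-squares line through the origin, and the 1620-bp residual is kept as
a linearity diagnostic. Calibration is per channel — Cy5 and Rho cannot
share a slope. The mean 810-bp intensity doubles as the minimum detection
threshold for ECTR calling (boundary case passes), which is why molecules
longer than 1620 bp are called with essentially full sensitivity while
sizing below 1620 bp is not claimed.

`detection_limit_bp()` reports the informational limit `snr × σ_noise /
slope`, with `σ_noise` the SD of integrated intensity over randomly placed
focus-sized null apertures in the Halo (`estimate_noise_sigma()`). It is
hardware-dependent by construction: the package validates its internal
consistency (a focus built to sit at twice the noise is recovered as the
2:1 limit), not any particular instrument's numeric value.

## Per-nucleus quantification

`summarize_nucleus()` computes, per nucleus: passing-focus counts per
strand and compartment; kb content (sums of estimated lengths, border foci
excluded); the extrachromosomal fraction per strand
(`100 × halo/(halo + core)` on kb content — content, not intensity, because
the reported quantity is a percentage of telomere-repeat DNA); the core
telomere:centromere ratio per strand (flagged undefined at zero
centromeres); object-based G/C colocalization per compartment
(mutual-nearest-neighbor pairing within 0.3 µm, a distance of the order of
the PSF width; fraction = pairs / mean(nG, nC)); and percent strand biases
`100 × (G − C)/mean(G, C)` in Halo number and content. The symmetric mean
denominator keeps the bias index bounded and makes a strand swap negate it
exactly — the reported "% more G-strand" figures leave their denominator
ambiguous, and the symmetric choice is documented here as the package's.

`assign_cell_cycle_bin()` sorts nuclei into G1/S/G2-enriched fractions from
core centromere counts: ≤ 1.25× the modal (2N) count is G1, ≥ 1.75× is G2.
The margins are symmetric around the 2N and 4N expectations and
configurable; they are a package decision, as is estimating the modal count
as the most frequent per-nucleus count. `cell_cycle_fold_changes()`,
`regress_content_vs_centromeres()` (OLS with a 95% slope interval) and
`compare_groups()` (Welch's t-test — the unequal-variance form, since
per-nucleus spreads differ strongly between lines) reproduce the
population-level analyses; group summaries report median and interquartile
range throughout.

`chance_mixed_focus_probability()` carries the aggregation argument: if a
Halo focus were a chance co-deposit of k ≥ 2 independent molecules with
equal strand odds, at least `1 − 2·(1/2)^k ≥ 50%` of such foci would
contain both strands and score as colocalization events; the observed
few-percent G/C colocalization therefore rules out aggregates as the main
interpretation of Halo foci.

## Determinism, numerics, degenerate inputs

Every stochastic step takes a seed; a fixed seed and configuration
reproduce stacks bit-identically and pipeline CSVs byte-identically.
Detection order, plateau collapse (one peak per connected equal-response
component), watershed flooding (FIFO among equal intensities) and pairing
(global-minimum distance, first index on ties) are all deterministic.
Degenerate inputs error early and specifically: empty images, blank DAPI,
missing channels (named), constant regressors, zero-variance t-tests,
unknown config keys. Empty compartments and bins produce explicit NA with
a warning, not silent zeros.

## Problem sizes

The validation suite mirrors the assay's study design — 60 nuclei per cell
line (three replicate sets of 20) — at the package's default field of
40 × 160 × 160 voxels: calibration slides with 60–100 foci, 20 nuclei for
the core-ratio check, 60 null nuclei for the false-positive ceiling, 60
nuclei per ALT preset for parameter recovery, and 100 random small-field
configurations for exact oracle equivalence. Unit tests run on a reduced
24 × 72 × 72 field with the same voxel size and optics.

## What passing tests do and do not show

The simulator emulates diffraction blur, shot/read noise, quantization,
compartment geometry and the population laws of ECTR DNA; it does not
emulate hybridization chemistry or efficiency, probe off-target binding,
agarose autofluorescence, spatially varying background, optical
aberrations beyond a Gaussian PSF, chromatin fibers protruding from the
core, or molecules so long they stop being point sources (a 200-kb molecule
may be physically extended). Tests passing on synthetic data therefore
validate the measurement chain given the stated image-formation model —
they do not certify performance on real microscope data, where threshold
transfer between slides, hybridization variability and background structure
dominate.
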