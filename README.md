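# halofish

Quantitative analysis of **Halo-FISH** microscopy: counting and sizing
extrachromosomal telomere-repeat (ECTR) DNA molecules in single
deproteinized human nuclei.

In the Halo-FISH assay, cells embedded in agarose are lysed,
deproteinized and alkali-denatured. Chromosomal DNA cannot move through
the gel and remains in an intensely DAPI-stained **nuclear core**;
extrachromosomal molecules diffuse outward into a surrounding **Halo**,
where strand-specific PNA probes label G-strand (TTAGGG, Cy5) and
C-strand (AATCCC, Rho) telomere-repeat DNA, and a pan-centromere probe
(FAM) marks chromosomal centromeres. Each nucleus is imaged as a
4-channel widefield z-stack (40 planes, 0.2 µm spacing, 12-bit). This
matters for cells using the Alternative Lengthening of Telomeres (ALT)
pathway, whose abundant ECTR DNA is otherwise hard to measure per cell.

`halofish` is the computational half of that experiment, for microscopists
and telomere biologists:

* a **ground-truthed simulator** of the full acquisition (nucleoid
  geometry, ECTR population laws, Gaussian PSF, Poisson–Gaussian camera
  noise) so every stage is testable without a microscope;
* **Richardson–Lucy deconvolution** and robust background models;
* **core/Halo segmentation** from the DAPI channel (Otsu/isodata threshold,
  3D hole filling, guard dilation);
* **3D spot detection** (difference-of-Gaussians maxima, marker watershed
  flux partitioning) with background-corrected integrated intensities;
* **quantitative-FISH calibration**: plasmid standards with 135 (810 bp)
  and 270 (1620 bp) telomere repeats convert integrated intensity to base
  pairs via a zero-intercept fit; the mean 810-bp intensity is the minimum
  detection threshold, and a signal-to-noise detection limit is derived
  from Halo null apertures;
* **per-nucleus metrics**: Halo/core focus counts per strand, kb content,
  percent extrachromosomal per strand, core telomere:centromere ratio
  (expected 2 in diploid G1 nuclei), object-based G/C colocalization,
  symmetric strand-bias indices, length-distribution summaries,
  centromere-count cell-cycle binning, Welch tests, content-vs-centromere
  regression.

The core quantitative ideas, in standard notation: per-focus length
`bp = I / s` with slope `s = mean(I_810)/810` (or the zero-intercept
least-squares line through both standards); detection limit
`bp_min = SNR · σ_noise / s`; strand bias `100·(G − C)/mean(G, C)`;
extrachromosomal fraction `100 · halo_kb / (halo_kb + core_kb)`; and the
aggregation argument `P(mixed | k molecules) = 1 − p^k − (1−p)^k ≥ 1/2`
for `k ≥ 2, p = 1/2`, which rules out chance co-deposition as the source
of Halo foci given the observed few-percent G/C colocalization.

## Worked example

Simulate one GM847-like ALT nucleus, calibrate on a simulated 810-bp
plasmid slide, and run the analysis chain:

```r
library(halofish)
set.seed(1)

cfg    <- sim_config()                       # 40 x 160 x 160 voxels, 12-bit
preset <- get_preset("GM847")

cal <- simulate_and_fit_calibration(cfg, n_foci = 60, seed = 2)$calibration
print(cal)

pop   <- sample_ectr_population(preset, 1)[[1]]
truth <- build_nucleus_truth(preset, pop, "G1", cfg)
stack <- render_stack(truth, cfg)
out   <- analyze_stack(stack, cal, deconvolve_iterations = 10)

cat("truth halo G/C:", sum(pop$strand == "G"), "/",
    sum(pop$strand == "C"), "\n")
print(t(out$metrics[, c("halo_count_G", "halo_count_C", "core_count_G",
                        "centromere_count_core", "tel_cen_ratio_G",
                        "coloc_fraction_core", "coloc_fraction_halo",
                        "number_bias_pct", "length_median_kb_G")]))
```

```
TelG: slope 0.9737 ADU/bp, threshold 788.7 ADU (mean of 810-bp standard, n = 60)
  noise sigma 76.45 ADU; 2:1 SNR detection limit 157 bp
TelC: slope 1.01 ADU/bp, threshold 818.1 ADU (mean of 810-bp standard, n = 60)
  noise sigma 75.69 ADU; 2:1 SNR detection limit 150 bp
truth halo G/C: 22 / 15
                           [,1]
halo_count_G          22.000000
halo_count_C          15.000000
core_count_G          90.000000
centromere_count_core 46.000000
tel_cen_ratio_G        1.956522
coloc_fraction_core    1.000000
coloc_fraction_halo    0.000000
number_bias_pct       37.837838
length_median_kb_G    18.090748
```

Reading this: the fitted calibration slope is close to the simulator's true
1 ADU/bp and the 810-bp standard sets the detection threshold; all 22
G-strand and 15 C-strand ECTR molecules placed in the Halo were recovered
(this nucleus drew a below-average count from the over-dispersed law); 90
of the 92 chromosomal telomere foci were resolved in the crowded core over
46/46 centromeres (ratio 1.96, near the ideal 2); core G/C signals
colocalize completely (chromosomal telomeres are duplex) while no Halo
focus pair colocalizes (single-stranded molecules); this nucleus has 37.8%
more G- than C-strand molecules, with a median estimated length of ~18 kb.

The same chain runs from the shell over directories of TIFF stacks:

```sh
Rscript exec/halofish simulate  --preset GM847 --n-nuclei 20 --seed 1 --out stacks/
Rscript exec/halofish calibrate --n-foci 60 --seed 1 --out cal.json
Rscript exec/halofish analyze   --in stacks/ --cal cal.json --out results/
Rscript exec/halofish summarize --in results/nuclei.csv --out summary.csv
```

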