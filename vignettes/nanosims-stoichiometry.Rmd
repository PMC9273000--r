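---
title: "Quantifying subcellular ligand-to-metal stoichiometry from NanoSIMS ion-count images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying subcellular ligand-to-metal stoichiometry from NanoSIMS ion-count images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanostoich)
```

## The measurement problem

NanoSIMS rasters a finely focused primary ion beam over a resin-embedded
cell section and counts mass-resolved secondary ions per pixel, producing
co-registered elemental and isotopic images at sub-100 nm resolution.
When cells are exposed to a platinum drug whose ammine ligands carry a
^15^N label (cisplatin, *cis*-PtCl~2~[NH~3~]~2~, has two such ligands), two
quantities become measurable in every subcellular compartment:

* the **metal signal**: the ^194^Pt^−^ count rate, proportional (with an
  unknown sensitivity factor) to the local platinum concentration, and
* the **ligand signal**: the enrichment of ^15^N in the CN^−^ secondary
  ions (^12^C^15^N^−^ vs ^12^C^14^N^−^), which reports how much of the
  local nitrogen arrived with the drug.

Comparing the two across compartments and exposure concentrations reveals
whether the drug still carries its nitrogen ligands where it accumulates —
a flattened ligand-versus-metal curve means Pt–N bonds were cleaved during
processing. `nanostoich` implements this evaluation as a tested pipeline:
ROI count extraction with Poisson counting errors, the isotope mixing
model, a reference-normalised Pt/N index, stoichiometry-curve fitting, and
a synthetic phantom generator with exact ground truth for validation.

## The model

**Label fraction.** A region's nitrogen is a two-component mixture:
biological nitrogen at the unlabeled abundance $a_{\mathrm{ctr}}$
(measured on an untreated control, or natural abundance 0.003676) and
drug-derived nitrogen at the label purity $a_{\mathrm{CDDP}}$. With the
measured abundance $a_{\mathrm{tot}} = n_{15}/(n_{14}+n_{15})$, the
fraction of nitrogen atoms originating from the drug is the unique linear
mixing form with the right endpoints:

$$ x \;=\; \frac{N_{\mathrm{CDDP}}}{N_{\mathrm{tot}}}
   \;=\; \frac{a_{\mathrm{tot}} - a_{\mathrm{ctr}}}
              {a_{\mathrm{CDDP}} - a_{\mathrm{ctr}}}, $$

so $x(a_{\mathrm{ctr}})=0$ and $x(a_{\mathrm{CDDP}})=1$ exactly, and $x$
is affine in $a_{\mathrm{tot}}$. Counting errors propagate linearly:
$\sigma_x = \sigma_a/(a_{\mathrm{CDDP}}-a_{\mathrm{ctr}})$ with the
binomial $\sigma_a = \sqrt{a(1-a)/(n_{14}+n_{15})}$. $x$ is displayed in
per mil; at realistic exposures it stays below one per mil.

**Pt/N index.** SIMS is only semi-quantitative for elemental analysis, so
the platinum-to-nitrogen concentration ratio is only defined up to a
sensitivity factor. Using the structural ^12^C~2~^−^ signal as internal
reference cancels run-to-run instrument sensitivity:

$$ q \;=\; \frac{\left[I(^{194}\mathrm{Pt})/I(^{12}\mathrm{C}_2)\right]_{\mathrm{Pt}}}
               {\left[I(^{12}\mathrm{CN})/I(^{12}\mathrm{C}_2)\right]_{\mathrm{avg}}} $$

with $I(^{12}\mathrm{CN})$ the summed ^12^C^14^N^−^ + ^12^C^15^N^−^
intensity. The 'Pt' bracket comes from the platinum acquisition; the 'avg'
bracket is the arithmetic mean of the CN/C~2~ ratio over the acquisitions
of the same ROI that record CN. Averaging ratio-then-mean (rather than
summing counts across runs) keeps $q$ exactly invariant under independent
per-run multiplicative gains, which is the property that makes sequential
acquisition workable; with the channel sets used here only the nitrogen
run records CN, so the bracket reduces to that run's ratio. $q$ is
proportional to Pt/N~tot~.

**Stoichiometry.** Because both $x$ and $q$ are normalised to total
nitrogen, plotting $x$ against $q$ across exposure concentrations gives a
line through the origin whose slope is proportional to the N/Pt
stoichiometry of the accumulated drug: slope $= L / (s_{\mathrm{Pt}}/s_{\mathrm{N}})$,
with $L$ the retained ligand count per Pt atom and
$s_{\mathrm{Pt}}/s_{\mathrm{N}}$ the relative sensitivity factor (RSF)
ratio converting atom ratios to count ratios. On real samples the RSFs are
unknown and only slope *ratios* between compartments are interpretable
(flattening = ligand loss); on phantoms the RSFs are known by construction
and `calibrate_stoichiometry()` recovers $L$ itself — 2 for the intact
diammine drug. The label-purity span $a_{\mathrm{CDDP}}-a_{\mathrm{ctr}}$
does not re-enter the calibration because the label-fraction formula has
already divided by it.

## Counting statistics and numerical choices

Secondary-ion counts are shot-noise limited, so every error bar is
first-order Poisson propagation on **ROI-summed counts** — never on means
of per-pixel ratios, which are undefined at zero counts and biased at low
counts. For a ratio $R = n_1/n_2$,
$\sigma_R = R\sqrt{1/n_1 + 1/n_2}$; a zero numerator reports $R = 0$ with
the one-sided single-count scale $1/n_2$ and a flag. The propagation for
$q$ treats its (up to four) contributing counts as independent. These
formulas are validated in the test suite against Monte-Carlo resampling
(10^4^ replicates, agreement within 5% for counts ≥ 100).

Degenerate inputs fail loudly rather than silently: zero reference counts,
zero total CN counts, constant images in registration or colocalisation,
fewer than two distinct $q$ values in a fit, and non-integer or negative
pixel values are all structured errors. Accumulated-frame floats are
rejected, not rounded, because the error model is only valid on raw
counts.

Two choices deserve emphasis:

* **Clipping vs fitting.** Noise can push a measured abundance marginally
  below the control baseline. Per-ROI label fractions are reported clipped
  at 0 (they are physical fractions) with a `clipped` flag, but slope fits
  consume the *unclipped* estimates: regressing censored values inflates
  the low-concentration end of the curve and biases the recovered
  stoichiometry downward by a few percent. A 60-seed simulation at the
  default conditions recovers N:Pt = 2.001 ± 0.010 with unclipped fits
  versus a ≈ 2.5% deficit with clipped ones.
* **Abundances far below baseline** (more than 5 counting errors) are an
  error, not a clip — they indicate a wrong $a_{\mathrm{ctr}}$, not noise.

## Registration

The platinum and nitrogen images of one field are acquired sequentially
and can be displaced by stage drift. Alignment uses phase correlation on
the ^12^C~2~^−^ channel — present and structured in both runs, unlike the
drug channels, which are empty in controls. The model is translation-only
(successive frames of the same field differ mainly by drift), the shift is
applied by whole pixels with zero-filled borders, and the sub-pixel
residual from a parabolic peak refinement is reported but never used to
resample: interpolation would turn integer Poisson counts into
non-integers and invalidate every error formula downstream. The search is
bounded by `max_shift` (default 20 px) and the number of zero-filled
border pixels is logged.

## The phantom generator

Real NanoSIMS acquisitions of this kind have no public deposits, so
validation runs on synthetic phantoms with exact ground truth. The
generator emulates the statistical structure of the measurements, not
their biological detail:

* **Geometry**: a centred cell (default radius 9 μm in a 40 μm field,
  512 × 512 px) with nucleus (5.5 μm), an offset nucleolus (1.8 μm), a
  chromatin rim lining the inner nuclear boundary (0.6 μm), and six
  non-overlapping S-rich cytoplasmic aggregate discs (0.8 μm) placed by a
  seeded sampler — minimal shapes matching the compartments an analyst
  would outline: cytoplasm, nucleus (excluding nucleolus and rim),
  nucleolus, chromatin, aggregates.
* **Counts**: every pixel is an independent Poisson draw from its
  compartment's expected rate per channel. Default yields give ROI CN
  sums of 10^5^–10^7^ counts — the regime needed for sub-per-mil label
  precision — with the ^194^Pt^−^ rate reaching a few counts per pixel at
  the top exposure, as in the published images.
* **Drug**: accumulation is linear in exposure concentration with
  per-compartment rates; drug nitrogen enters only the CN channels, at
  the rate implied by the configured ligand number and RSF ratio
  (default 5), keeping true label fractions below 10^−3^ everywhere at
  the default settings. The isotopologue split realises
  $a = a_{\mathrm{ctr}} + x\,(a_{\mathrm{CDDP}} - a_{\mathrm{ctr}})$
  exactly, with $a_{\mathrm{CDDP}} = 0.99$ (label purity is rarely
  printed; 99% is typical of commercial ^15^N reagents).
* **Drift**: the nitrogen run is rigidly translated by a configured
  integer shift.
* **Determinism**: one global seed, split deterministically per run and
  channel; identical seeds give bit-identical stacks.

Not simulated: detector dead time, quasi-simultaneous-arrival effects,
beam drift within a frame, depth sputtering, chloride/aquation chemistry,
and partial-volume mixing at compartment boundaries (masks match rate
regions exactly). Passing phantom tests therefore demonstrates the
correctness of the estimators under Poisson statistics and rigid drift —
not robustness to segmentation error or instrument artefacts in real data.

## Exercised problem sizes

The test and acceptance suites run the full pipeline on 8-concentration
series (0–150 μM) at 256 × 256 px over ≥ 20 seeds for stoichiometry
recovery, 50-seed ligand-loss contrasts at 128 × 128, 2,000 simulated
null experiments for t-test calibration at 96 × 96, and 200 seeded
registration replicates; these sizes keep every ROI above the 10^4^-count
floor where the Gaussian error approximations hold, while completing in
minutes.

## Statistics layer

Treated-versus-control comparisons use the classic two-tailed,
pooled-variance Student's t-test on per-ROI normalised signals (a Welch
variant is exposed but off by default, mirroring how such comparisons are
conventionally reported for this assay type; no multiple-testing
correction is applied). Colocalisation between channel pairs is quantified
by Pearson correlation over in-scope pixels plus Manders M1/M2 with
per-channel Otsu thresholds computed on the in-scope count histograms (the
threshold choice is recorded in the result; fixed thresholds can be
supplied, and zero thresholds reproduce the classic co-occurrence
definition).

ROIs are kept separate through the pipeline and aggregated only at the
curve/statistics layer (across-ROI standard deviations are the error bars;
per-ROI counting errors are carried alongside and are typically smaller).

## Known limitations

* Translation-only registration; no rotation, scale, or elastic warping.
* No automatic segmentation: masks are supplied by the analyst or the
  phantom.
* Vendor raw formats are not parsed; inputs are plain-text matrices or
  multi-page TIFF with a JSON sidecar.
* Single accumulated frame per acquisition; no plane-resolved depth
  profiling.
* Absolute quantification (fg Pt per cell, molarity) is out of scope; on
  real data only RSF-relative quantities are reported.

## A worked phantom run

```{r example, eval = FALSE}
library(nanostoich)

cfg <- phantom_config(grid = c(256L, 256L), pixel_size = 40 / 256,
                      shift = c(2L, -3L), seed = 1L)
series <- nested_exposure_series(cfg, c(0, 2.5, 5, 10, 25, 50, 100, 150))

samples <- lapply(series, function(tr) list(pt_run = tr$pt_run,
                                            n_run = tr$n_run))
masks <- lapply(series, function(tr) tr$truth$mask)
names(masks) <- vapply(samples, function(s) s$pt_run$sample_id, "")

res <- analyse_experiment(samples, masks, rsf = c(pt = 5, n = 1))
res$fits_table
plot(res$curves[["nucleolus"]])
```
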