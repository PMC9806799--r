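---
title: "Simulating and quantifying cell-resealing Trim-Away at single-cell resolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and quantifying cell-resealing Trim-Away at single-cell resolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Trim-Away degrades an endogenous protein by delivering an antibody against
it into the cytosol, where the Fc receptor and E3 ligase TRIM21 routes the
antibody--target complex to the proteasome. When the antibody is delivered
by streptolysin-O (SLO) cell resealing — transient pore formation followed
by Ca^2+^-driven membrane repair — delivery is heterogeneous: each cell
receives a different amount of antibody, carries a different amount of
TRIM21 and of the target, and a small fraction of cells never permeabilize
or fail to reseal. A bulk readout (western blot) therefore underestimates
what well-delivered cells achieve. The remedy studied here is microscopic
image-based single-cell analysis with cyclic immunofluorescence (CycIF):
stain, image, bleach and re-stain the same cells over several rounds,
co-register the rounds on the nuclear channel, segment cells, and analyze
per-cell intensities — gating on the delivery marker or restricting to the
best-delivered percentiles.

Because no raw microscopy data are published for this kind of experiment,
`trimcycif` pairs the analysis pipeline with a synthetic image generator
that carries full per-cell ground truth. Every stage of the pipeline is
validated against what the generator knows to be true, and the shipped
presets are calibrated so that their population-level ground truth equals
the measured values the emulated experiments report (e.g. a 74.6%
antibody-positive fraction at the optimal SLO dose, or a 65% bulk
knockdown at 3 h).

## The generative model

Per cell $i$, with all intensities in arbitrary units (AU):

* **Permeabilization.** A membrane-cholesterol factor
  $c_i \sim \mathrm{Lognormal}(0, \sigma_c)$ modulates the effective dose;
  the cell permeabilizes with probability
  $p_i = \frac{(d\,c_i)^h}{(d\,c_i)^h + K^h}$, a Hill curve in the SLO
  dose $d$. The midpoint $K$ is calibrated (Monte-Carlo root finding,
  fixed calibration seed) so that $\mathbb{E}[p] = 0.746$ at $d = 0.2$,
  the optimal-dose operating point of the emulated titration; the same
  dose response is shared by every preset (one cell line). Delivery
  presets run at $d = 0.4$, giving $\mathbb{E}[p] \approx 0.90$.
* **Resealing failure.** Among permeabilized cells a fraction fails to
  reseal and dies (`reseal_fail_prob`, conditional on permeabilization).
  The `reseal-fail` preset calibrates the conditional rate to
  $0.01/\mathbb{E}[p]$ so that the *population* died fraction is the
  observed ~1%. Died cells are rendered with shrunken nuclei (factor 0.5)
  and are excluded from analysis, mirroring the exclusion of
  propidium-iodide-positive cells.
* **Abundances.** Delivered antibody $A_i$ (permeabilized cells only),
  TRIM21 $T_i$ and initial target $X^0_i$ are independent lognormals.
  Defaults: $A \sim \mathrm{LN}(\log 1500, 0.8)$ — delivery is the widest
  source of heterogeneity — $T \sim \mathrm{LN}(\log 1000, 0.5)$
  (overexpression; 150 for endogenous, 800 for supplemented presets), and
  $X^0 \sim \mathrm{LN}(\log 2000, 0.45)$.
* **Degradation.** No rate law is available for antibody-mediated
  degradation in this system, so the simplest form with the right
  qualitative behavior is used: first-order decay with saturating
  dependence on both antibody and TRIM21 and a degradation-resistant
  fraction,
  $$X_i = X^0_i\left[f_{res} + (1 - f_{res})\,
    e^{-k_i t}\right],\qquad
    k_i = k_{max}\frac{A_i}{A_i + K_A}\frac{T_i}{T_i + K_T}.$$
  This produces time-dependent deepening of knockdown, TRIM21-limited
  capacity, and (with $f_{res} > 0$, used for the mTOR preset where part
  of the target pool is inaccessible) incomplete degradation. $K_A = 500$
  and $K_T = 300$ are fixed; $k_{max}$ is what each preset calibrates.
  The calibrated $k_{max}$ values span roughly 0.16–2.2 h⁻¹ across
  presets, i.e. effective per-cell half-lives from tens of minutes
  upward — the time scale reported for antibody-mediated degradation. No resynthesis term is modeled;
  presets stay at incubations of 12 h or less, short of the 24 h
  recovery regime.
* **Downstream signaling.** Phospho channels follow
  $P = \beta X^{\gamma} e^{\varepsilon}$,
  $\varepsilon \sim N(0, \sigma)$: pAkt and pS6 track the remaining
  target ($\gamma = 1$), total Akt and S6 are target-independent
  ($\gamma = 0$). A cell-cycle-like subpopulation (probability 0.15)
  multiplies pS6 by 2.5, decoupling part of the pS6 signal from the
  target — the kind of secondary structure single-cell maps reveal.
* **NC condition.** The non-targeting control IgG is delivered and
  stained identically (same $A$ distribution) but degrades nothing, so
  gating behaves identically across conditions.

**Calibration is part of the study conditions.** `calibrate_knockdown()`
solves for $k_{max}$ so that the *bulk* knockdown
$1 - \mathbb{E}[X\,|\,\text{targeting}]/\mathbb{E}[X\,|\,\text{NC}]$ over
all analyzable cells — permeabilized or not, the western-blot-equivalent
readout — equals the preset's target (40%, 65%, 41%, 59%, 31%, 44%).
Calibration uses a fixed internal seed (20,000-cell Monte-Carlo
population, monotone 1D root finding), so presets are reproducible
definitions independent of the user's simulation seed. An infeasible
target (above the ceiling $\mathbb{E}[p](1 - f_{res})$) is an explicit
error.

## Rendering

Nuclei are filled ellipses (semi-major axis lognormal around 9 px at
0.65 µm/px — HEK-scale nuclei at a binned 40x confocal sampling); the
cell region is the nucleus thickened by 12 px, with contested pixels
assigned to the *nearest nucleus* (ties to the lower label), and the
cytosol is cell minus nucleus. All channels are piecewise constant per
cell and compartment: antibody over nucleus+cytosol, target over cytosol
with half intensity in the nucleus, phospho channels over the cytosol.
Piecewise-constant scenes make the central verification contract exact:
with noise off, every region mean equals its configured truth to machine
precision.

Per staining round the scene is translated by an integer stage drift
(rounded $N(0, 2\,\mathrm{px})$, recorded as the true shift), a
`bleach_carryover` fraction (default 0.02) of the previous round's
same-color-slot signal is added (the nuclear counterstain is re-imaged
fresh each round), then a background plane (12 AU) with a linear gradient
(4 AU), Poisson shot noise, Gaussian read noise (sd 5 AU) and clipping to
unsigned 16-bit. A noise-free render skips quantization so exactness is
preserved; any noisy render is integer counts.

Not modeled (out of scope): PSF blur and z-dependent optics, subcellular
texture (lysosomal puncta), cell motion between rounds (cells are fixed;
only stage drift moves), and antibody retention kinetics beyond the
incubation window. Passing tests therefore demonstrate correctness of the
measurement and inference machinery under realistic intensity statistics,
not robustness to optical aberrations or segmentation of crowded,
irregular real-world morphologies.

## The analysis pipeline

* **Registration** (`register_rounds`): translation-only phase
  correlation of each round's nuclear image against round 1, sub-pixel
  refinement by a locally upsampled DFT (default 0.1 px). A fixed plate
  re-imaged at the same position justifies the translation-only model;
  rotation would surface as a low peak score, which is reported, and
  estimates above 10% of the image width are flagged low-confidence
  rather than silently accepted. Exposed borders are zero-filled and a
  validity mask is propagated so downstream cells overlapping invalid
  pixels are flagged.
* **Segmentation** (`segment_nuclei`, `expand_cells`,
  `derive_cytosol`): Otsu binarization of the (max-projected) nuclear
  channel — the emulated commercial software's rule is unknown, and Otsu
  is the standard parameter-free default; a fixed threshold is available
  for full reproducibility — hole filling, minimum-area filtering
  (30 px), optional watershed splitting of touching nuclei (off by
  default: the generator enforces nuclear spacing), then exact
  Euclidean nearest-nucleus thickening implemented by per-label windowed
  distance transforms. Border-touching cells are flagged and excluded
  from statistics by default. Cells whose nucleus area falls below
  95 px² — between the shrunken died-nucleus distribution (≤ ~90 px²)
  and the live minimum (≥ ~130 px²) — are classified as died.
* **Measurement** (`measure_cells`): mean and sum intensity per cell
  region for every round and channel (`r{round}_{channel}_{mean|sum}`).
  Because the segmented boundary between touching cells wobbles by about
  a pixel under noise, a 2-px *spillover guard* excludes pixels along
  boundaries shared with another cell (reported as `area_measured_px`);
  without it, bright neighbors contaminate the delivery marker of
  negative cells and inflate the positive fraction by several points. No
  background subtraction is applied by default (raw means are reported);
  colocalization (`colocalize`) computes per-cell Pearson correlations
  over the cytosol region, undefined (never imputed) below 3 pixels or
  at zero variance.
* **Gating** (`gate_positive`): "antibody-positive" has no numeric
  definition in this assay; the default stand-in is the 99th percentile
  of a no-delivery control's delivery-marker distribution, recorded in
  the result together with the rule. The threshold rule and null source
  are explicit function arguments.
* **Knockdown** (`estimate_knockdown`):
  $1 - \mathrm{mean}_{treated}/\mathrm{mean}_{control}$ — ratio of means,
  matching densitometry aggregation; a median-ratio estimator is exposed
  as a robust alternative — with a seeded nonparametric bootstrap
  (default 1000 resamples, percentile CI) over cells. Modes: `bulk` (all
  analyzable cells), `gated` (delivery-positive only), `percentile` (top
  delivery percentiles, computed within condition with ties included).
* **Comparisons** (`compare_conditions`, `compare_many_to_one`): Welch's
  unequal-variance t-test; many-to-one comparisons use per-group Welch
  tests with Holm adjustment — a conservative approximation of the
  classical Dunnett procedure, whose exact multivariate-t critical values
  are deliberately not reimplemented here.
* **Embedding** (`tsne_embed`, `pairwise_summary`): features are
  z-scored over the pooled table (the natural choice when conditions are
  displayed on one map) and embedded with Barnes-Hut t-SNE (perplexity
  30, seeded). The embedding is visualization/QC only: no quantitative
  claim is attached to its geometry, and the tested contracts are
  reproducibility and preservation of well-separated groups.

## Numerical choices and degenerate inputs

* Pixel convention: 0-free R indexing internally, (row, col) with origin
  top-left; shifts are (dy, dx) applied to the moving round.
* Tie-breaks in label expansion go to the lower label; because label
  numbering is arbitrary, an equidistant boundary pixel may differ
  between two otherwise identical segmentations — at most a one-pixel
  band, excluded anyway by the spillover guard.
* Constant images cannot be registered (explicit error); blank images
  segment to zero objects with a warning, not an error.
* Quantile type 7 (R default) everywhere a percentile is taken.
* All randomness flows from a single integer seed per simulation; field
  sub-seeds are derived additively and stay far below 2³¹. Identical
  config + seed gives bit-identical ground truth, images and CSVs.

## Problem sizes

Defaults keep a full two-condition run at 2000 cells per condition (three
1024×1024 fields per condition at up to 850 cells each) in the
low-minutes range on one CPU; the acceptance script and the test suite
use those sizes. Statistical property checks that do not need images run
on truth-level tables of 5000–10,000 cells drawn directly from the
generator.

## Known limitations

* The degradation law is a modeling choice; only its qualitative
  behaviors (saturation, time dependence, TRIM21 limitation, resistant
  fraction) are supported by the emulated experiments, not its
  functional form.
* Segmentation quality targets (≥0.95 count precision/recall, median
  IoU ≥0.8) hold for the generator's ellipse morphology at default
  noise; they say nothing about crowded or irregular real nuclei.
* Bulk knockdown estimates from raw means carry a small background
  dilution bias (background ≈ 12 AU against signals in the thousands,
  well under a percentage point); per-field median background
  subtraction is available but off by default.
* The two-sided comparison machinery assumes approximately continuous
  intensity distributions; heavily censored (clipped) channels would
  need a different treatment.
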