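# trimcycif

Single-cell, image-based quantification of **Trim-Away** protein
degradation delivered by **streptolysin-O (SLO) cell resealing**, read out
with **cyclic immunofluorescence (CycIF)** — plus a synthetic microscopy
generator with full per-cell ground truth so that every stage of the
pipeline is verifiable without any external data.

## The scientific problem

Trim-Away removes an endogenous protein by delivering an antibody against
it into the cytosol; the Fc receptor/E3 ligase TRIM21 then routes the
antibody–target complex to the proteasome. Cell resealing delivers the
antibody by transient SLO pore formation followed by membrane repair, and
it is intrinsically heterogeneous: per cell, the delivered antibody amount
*A*, the TRIM21 amount *T* and the target amount *X⁰* all vary, a fraction
of cells never permeabilizes, and ~1% fail to reseal. Bulk assays
(western blots) average over all of this; single-cell imaging can gate on
the delivery marker and recover what well-delivered cells actually do.

The generator draws cells with lognormal *A*, *T*, *X⁰*, permeabilization
from a Hill dose response in SLO dose, and degrades the target with
saturating first-order kinetics

X = X⁰ · [ f_res + (1 − f_res) · exp(−k·t) ],   k = k_max · A/(A+K_A) · T/(T+K_T),

renders multi-round fields (stage drift, bleach carryover, shot/read
noise, background gradient), and the pipeline then registers rounds by
phase correlation on the nuclear channel, segments nuclei (Otsu) and
thickens them into cell regions (exact nearest-nucleus assignment),
measures per-cell mean/sum intensities, gates antibody-positive cells
against a no-delivery null (99th percentile), and estimates knockdown
1 − mean(treated)/mean(control) in bulk, gated and top-percentile modes
with bootstrap intervals. Shipped presets are calibrated (fixed
calibration seed, Monte-Carlo root finding) so their ground-truth
population values equal the measurements they emulate.

## Worked example

```r
library(trimcycif)

cfg <- preset_config("IKKa-3h", seed = 1)   # calibrated to 65% bulk knockdown
tcfg <- cfg; tcfg$condition <- "targeting"
ncfg <- cfg; ncfg$condition <- "NC"
tt <- simulate_celltable(tcfg, n_cells = 2000, seed = 42)  # render -> register
nc <- simulate_celltable(ncfg, n_cells = 2000, seed = 43)  #  -> segment -> measure
estimate_knockdown(tt$cells, nc$cells, "r1_target_mean",
                   mode = "bulk", n_boot = 200, seed = 1)
#> <knockdown_estimate> bulk: 65.6% [64.2, 67.1]  n = 1982/1981
```

The estimate is the per-cell analogue of densitometry: the population
ratio of target-channel means, here recovering the preset's calibrated
65% (the bracket is the bootstrap 95% CI; n are analyzable cells after
excluding border, registration-invalid and non-resealed cells).

The numbered scripts under `analysis/` run the full study and write their
tables under `results/`:

* `01_slo_titration.R` — SLO dose series; measured antibody-positive
  fraction vs ground-truth permeabilization (75.6% vs 75.6% at dose 0.2,
  10.0% vs 8.7% at dose 0.025).
* `02_knockdown_timecourse.R` — the five IKKα presets; measured bulk
  knockdowns 39.5 / 63.5 / 40.1 / 59.2 / 32.6 % against calibrated
  40 / 65 / 41 / 59 / 31 %.
* `03_mtor_single_cell.R` — three CycIF rounds, six markers: bulk 43.3%
  vs gated 48.0% vs top-5%-delivered 54.7% knockdown; antibody–mTOR
  correlation −0.24 in the targeting condition; condition separation
  (|SMD| of mTOR intensity) rising 1.06 → 1.63 as filtering narrows from
  100% to the top 5% by delivery; a seeded t-SNE map of all markers.
* `04_spatial_electroporation.R` — center-gradient delivery mode:
  79.1% positive at the field center vs 7.0% at the periphery.

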