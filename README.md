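# zgsync

Quantitative analysis of synchronized calcium spiking and gap-junction
coupling in the adrenal zona glomerulosa (ZG).

ZG cells fire ~1 Hz calcium spikes clustered into bursts; cells within
a rosette (glomerulus) can spike in synchrony. Whether that synchrony
runs through gap junctions is tested functionally: by blocking them
pharmacologically (carbenoxolone, CBX) during imaging, and by checking
whether a photobleached cell's cytosolic dye is replenished by its
neighbours (FRAP). `zgsync` implements the complete quantitative
pipeline for such experiments — for imaging labs analysing acute-slice
calcium recordings and for anyone who wants to reproduce or stress-test
the statistics on simulated data with known ground truth.

## The statistic at the core

For two cells with spike-frame sets $A$ and $B$ on a shared 100 ms
frame grid, synchrony is the Jaccard index

$$\mathrm{JI} = \frac{|A\cap B|}{|A\cup B|} \in [0,1],$$

the fraction of temporally synchronized spikes among all spikes across
the two cells. Connections with $\mathrm{JI} > 0.1$ count as coupled.
Three companions make the number interpretable:

* a **frame-shift surrogate null** — recompute every JI with one train
  of each pair circularly shifted by 1..10 frames; genuine synchrony
  collapses, chance frame-binning coincidences do not;
* **bootstrap confidence intervals** (percentile, 10,000 resamples) for
  every summary;
* **center-to-center distances** from rectangles fitted around each
  cell, relating coupling to rosette geometry.

Drug effects are quantified per baseline-coupled connection as the
relative JI change $100\,(\mathrm{JI}_\mathrm{drug} -
\mathrm{JI}_\mathrm{base})/\mathrm{JI}_\mathrm{base}$ (absolute
differences co-reported), and FRAP traces as the plateau recovery
$(F_\mathrm{end}-F_\mathrm{post})/(F_\mathrm{pre}-F_\mathrm{post})$
with pooled Student's t-tests between treatment groups.

A seed-deterministic synthetic-data generator (burst-modulated renewal
spiking, shared parent-train coupling within rosettes, fluorescence
forward model, FRAP traces) provides ground truth for every stage; see
`vignettes/zg-synchrony-methods.Rmd` for the model and its assumptions.

## Worked example

Simulate a two-slice session (40 cells, 45 min at 10 frames/s,
baseline / CBX / washout protocol), detect spikes, and quantify
synchrony and the drug effect:

```r
library(zgsync)

cfg <- synth_config(n_slices = 2, cells_per_slice = 20, rosette_size = 5,
                    coupling_prob = 0.4, epochs = protocol_epochs(27000),
                    seed = 7)
out    <- generate_recording(cfg)          # session + ground truth
trains <- detect_session(out$session)      # per-cell spike trains
ep     <- out$session$epochs

baseline <- pairwise_ji(
  lapply(trains, restrict_to_epoch, epoch = ep[1, ]),
  out$session$slices,
  geometry = out$session$geometry, pixel_size = out$session$pixel_size
)
baseline
#> <synchrony_result>
#>   40 cells, 380 within-slice pair(s), tolerance 0 frame(s)
#>   threshold 0.1: 34 coupled pair(s), 29 coupled cell(s)

summarize_coupled_ji(baseline, seed = 1)$ci
#> mean 0.3763, 95% CI [0.3683, 0.3839] (n = 34, 10000 resamples)

d <- coupled_distance_summary(baseline)
#> coupled distance: 6.92 um +/- 0.29 (s.e.m., n = 34)

drug <- pairwise_ji(lapply(trains, restrict_to_epoch, epoch = ep[2, ]),
                    out$session$slices)
ji_change(baseline, drug, seed = 1)
#> <epoch_comparison>
#>   34 baseline-coupled connection(s) (threshold 0.1), 0 excluded
#>   mean relative change: -14.7% (95% CI -20.4 to -8.66)

rates <- session_epoch_rates(trains, ep)
round(tapply(rates$rate_hz, rates$epoch, mean), 3)
#> baseline     drug  washout
#>    0.425    0.059    0.214
```

Reading the numbers: 29 of 40 cells have at least one connection above
the 0.1 cutoff; those connections average JI 0.38 and sit ~7 um apart
(adjacent rosette neighbours). CBX perfusion suppresses mean activity
from 0.43 to 0.06 spikes/s while reducing the JI of pre-coupled
connections by only ~15% — spiking is hit hard, synchrony barely, the
signature dissociation the analysis is built to expose. The generator's
ground truth (`out$truth`) lets you verify every one of these numbers
against the simulated coupling graph and spike times.

FRAP quantification works the same way from traces:

```r
tr <- generate_frap(mobile_fraction = 0.35, tau = 20,
                    config = synth_config(seed = 3), noise_sd = 0)
frap_recovery(tr)
#> [1] 0.3454779
two_sample_t(list(mean = 0.11, sd = 0.10, n = 12),   # control group
             list(mean = 0.07, sd = 0.03, n = 5))$t  # CBX group
#> [1] 0.8635089
```

`run_pipeline()` chains every stage (simulate -> detect -> synchrony ->
shift null -> perturbation -> FRAP) into a machine-readable report;
`inst/cli/zgsync.R` wraps it for shell use.

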