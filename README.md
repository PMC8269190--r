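# caslice

Analysis of intracellular Ca²⁺ dynamics recorded simultaneously from many
cardiomyocytes in acute cardiac tissue slices — the kind of multicellular
Ca²⁺-imaging experiment used to study stress-induced arrhythmia models
(e.g. CPVT, where a "leaky" RyR2 release channel promotes diastolic Ca²⁺
leak). The package is aimed at labs quantifying per-cell fluorescence
traces from paced slice recordings and at methodologists who want the
detection rules to be explicit, configurable and testable.

## What it computes

For a per-cell raw-fluorescence matrix with a pacing protocol:

* **F/F0 normalization** — F0 is the per-cell minimum fluorescence.
* **Paced transients** — amplitude ΔF/F0 (peak − pre-stimulus baseline)
  and decay time constant τ from a monoexponential fit
  `y(t) = baseline + A·exp(−(t − t_peak)/τ)`.
* **Spontaneous diastolic Ca²⁺ release (SCR)** — events are contiguous
  diastolic regions above basal mean + 2 SD whose amplitude is ≥ 10% of
  the cell's triggered transient amplitude; duration is the time between
  the bounding 2-SD crossings. Per-cell rates use diastolic exposure only.
* **Ca²⁺ alternans** — a cell is positive when consecutive transient
  amplitudes differ by ≥ 10% (relative, `|Aᵢ−Aᵢ₊₁|/max`) with strictly
  alternating sign for ≥ 10 consecutive transients.
* **Pace-stop latency** — time from pacing interruption to the first SCR,
  right-censored when none occurs.
* **Wave speed** — OLS slope of half-maximum front positions in line-scan
  kymographs (μm/s).
* **SCR coupling** — for each SCR, latencies of neighboring cells' next
  SCR within the source event's duration W; the observed probability
  `p_obs` of ≥ 1 secondary is compared with the independent-events Poisson
  null `p_null = 1 − exp(−n·λ̂·W)` (printed with its inputs).

A synthetic generator (`simulate_slice_recording`, `simulate_kymograph`,
fixture registry `make_fixture`) emulates the experiment — paced transient
trains, β-adrenergic modulation, genotype-dependent SCR rates (0.4 vs
0.1 events/s/cell), ~0.9 s event durations, alternans, neighbor-coupling
hazard amplification, 40–60 μm/s traveling waves — with full ground truth,
so the whole pipeline is testable offline.

## Worked example

```r
library(caslice)

fx <- make_fixture("pace_stop_basic")   # 40 cells, 2 Hz, pacing stops at 8.5 s
b  <- run_pipeline(fx$recording)
cat(b$log, sep = "\n")
#> normalize: 40 cells, F0 method min
#> transients: 640 accepted over 16 stimuli
#> scr: 114 events, 1262.0 s total diastolic exposure
#> alternans: 0/40 positive
#> pace_stop: 2/40 cells censored
#> coupling: p_obs 0.307 vs p_null 0.219 over 114 sources

b$scr_summary$mean_rate_hz      # 0.090 events/s/cell: the fixture's 0.1/s hazard
mean(b$pace_stop$latency_s[!b$pace_stop$censored])  # 10.18 s mean latency
print(b$coupling)
#> SCR coupling report (114 source events)
#>   p_obs  = 0.307 (95% CI 0.224-0.400)
#>   p_null = 0.219  [p_null = 1 - exp(-n_neighbors * lambda_hat * W); ...]
#>   mean neighbor latency = 0.411 s
```

With coupling off (this fixture), `p_obs` sits inside the binomial CI of
`p_null`; on the strongly coupled fixture (`make_fixture("coupling_strong")`,
hazard ×20 for neighbors of an active cell) the pipeline reports
`p_obs > 0.8` against a null near 0.43 — the signature of
non-independent, source–sink-coupled diastolic release.

Alternans classification on the 25-cell fixture (11 truly alternating
cells, 14 designed traps):

```r
af <- alternans_fraction(run_pipeline(make_fixture("alternans_cpvt_25")$recording)$alternans)
af$n_positive  # 11
af$percentage  # 44
```

## Command line

```sh
Rscript inst/cli/caslice.R show-config
Rscript inst/cli/caslice.R simulate --fixture pace_stop_basic --out /tmp/demo
Rscript inst/cli/caslice.R analyze  --traces /tmp/demo/rec_traces.csv --out /tmp/demo/results
Rscript inst/cli/caslice.R report   --dir /tmp/demo/results
```

## Documentation

`vignettes/caslice-methods.Rmd` describes the model, every threshold and
its provenance (published constant vs implementation default —
also `show_config()`), the synthetic world and its limits, and the
numerical edge cases.
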