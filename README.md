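# thermocol

Detecting microbial heat production in sediment microcosms from
multi-channel temperature logs.

Winogradsky columns — sealed sediment-and-water microcosms in which
microbial communities stratify along oxygen and sulfide gradients — produce
heat as a by-product of catabolism. `thermocol` implements a complete
analysis pipeline for deciding whether that heat is visible in the
temperature records of an instrumented pair of columns (a living column and
an autoclaved control), each carrying digital thermometers in its top and
bottom sediment regions inside a diurnally lit incubator.

The package covers:

* **Heat-balance theory.** For a sediment with specific heat `c_s`
  (J kg⁻¹ °C⁻¹) and a metabolic power density `P` (W kg⁻¹, per-cell heat
  rate × cell abundance), the idealized loss-free heating rate is
  `dT/dt = P / c_s` (°C s⁻¹). With per-cell rates of 0.8 pW (aerobic) and
  0.2 pW (anaerobic) and `c_s` between 2880 and 4180 J kg⁻¹ °C⁻¹, this
  bounds the attainable rates and the aerobic-vs-anaerobic vertical
  gradient (`theory_prediction_table()`).
* **Logger I/O.** Reading, writing, and merging semicolon-delimited
  multi-channel logs with plausibility filtering, gap reporting, and
  valid-day accounting (`read_temp_log()`, `merge_temp_logs()`,
  `valid_days()`).
* **Diel phase segmentation.** The 24-h light program is split into day
  quarters D1 (08:00–15:30) and D2 (15:30–00:00), night quarters
  N1 (01:00–04:00) and N2 (04:00–07:00), and excluded sunrise/sundown
  transitions (`phase_schedule()`, `summarize_phases()`).
* **Difference statistics.** Vertical gradients ΔT_TB = T_top − T_bottom
  within each column (internal probes or external wall references) and
  living-minus-control differences ΔT_Top, ΔT_Bott, aggregated
  hierarchically: raw samples → per-day phase means → boxplot/monthly
  summaries (`difference_series()`, `phase_boxplot_stats()`,
  `monthly_aggregate()`).
* **Insulation retention metrics.** For a wrapping experiment, the
  temperature retention ΔΔT (highest during-insulation per-day phase mean
  minus the preceding three-day baseline) and the steady-state retention
  ΔΔT_Steady (post- minus pre-insulation three-day means), flagged against
  the 0.0625 °C sensor quantization step (`retention_stats()`,
  `precision_flag()`).
* **Binned distribution test.** Differences binned into 0.01 °C intervals
  on [−1, +1) °C, normalized to the total dataset size, and compared with
  a two-sided Mann–Whitney U test on the frequency vectors
  (`bin_differences()`, `mwu_binned()`), plus the conventional raw-sample
  test (`mwu_raw()`) as a diagnostic.
* **A calibrated simulator.** A seeded lumped-capacitance thermal model of
  both columns (two nodes each) under 22–30 °C diurnal forcing with
  light-modulated microbial sources, insulation events, per-channel sensor
  offsets, Gaussian noise, 0.0625 °C quantization, and logging gaps
  (`simulate_columns()`, `scenario_default()`), so the whole pipeline is
  testable without any deposited data.

## Worked example

Theory first — the prediction table computes power densities and heating
rates and flags bounds that disagree with the commonly quoted reference
values at printed precision:

```r
library(thermocol)
theory_prediction_table()
#> # A tibble: 2 x 8
#>   condition power_density rate_low rate_high ref_low ref_high low_consistent
#>   <chr>             <dbl>    <dbl>     <dbl>   <dbl>    <dbl> <lgl>
#> 1 aerobic            4.58    3.94       5.72     3.9      5.6 TRUE
#> 2 anaerobic          1.14    0.986      1.43     0.9      1.3 FALSE
```

The aerobic power density of 4.58 W kg⁻¹ at `c_s = 4180` gives 3.94 → 3.9
°C h⁻¹ (consistent); the computed upper bounds 5.7 and 1.4 °C h⁻¹ disagree
with the quoted 5.6 and 1.3 at the last digit and are flagged.

Simulate a week of the default scenario and ask whether the living column's
internal daytime gradient exceeds the control's:

```r
sim <- simulate_columns(scenario_default(days = 7, seed = 1))
sim$log
#> <temp_log> 10081 records, 9 channels, 60s sampling [2022-04-01 00:00 .. 2022-04-08 00:00]

ds_l <- difference_series(sim$log, "tb_int_living")
ds_c <- difference_series(sim$log, "tb_int_control")
phase_boxplot_stats(ds_l, phase = "D2")
#>   phase   min    q1 median    q3   max  mean      sd n_days
#> 1 D2    0.247 0.248  0.250 0.252 0.255 0.250 0.00312      7
phase_boxplot_stats(ds_c, phase = "D2")
#>   phase      min       q1  median      q3     max    mean      sd n_days
#> 1 D2    -0.00257 -0.00153 0.00110 0.00423 0.00637 0.00147 0.00351      7
```

The living column's D2 gradient sits at 0.250 ± 0.003 °C across all seven
days while the control's is indistinguishable from zero — the simulated
microbial source (calibrated to a 0.25 °C gradient excess) is recovered by
the pipeline. The raw-sample Mann–Whitney test on the two gradient series
rejects emphatically (p ≈ 0), while the binned frequency-vector comparison
(`mwu_binned()`) is insensitive to pure location shifts and stays
non-significant here (p ≈ 0.50); see the vignette for why the two
procedures answer different questions.

`run_pipeline()` executes every stage and writes the tidy tables, optional
figures, and a run manifest:

```r
run_pipeline(scenario = scenario_default(days = 9, seed = 1,
               insulation = list(insulation_event(
                 as.POSIXct("2022-04-05 09:00:00", tz = "UTC"),
                 as.POSIXct("2022-04-06 09:00:00", tz = "UTC")))),
             out_dir = "runs/demo")
```

A small synthetic example log in the native dialect ships with the package:

```r
log <- read_temp_log(system.file("extdata", "example_log_synthetic.csv",
                                 package = "thermocol"))
```

A thin command-line wrapper lives at
`inst/scripts/thermocol-pipeline.R` (subcommands `theory`, `simulate`,
`report`).

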