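# apoptomap

Spatiotemporal mapping of cancer-cell apoptosis in tumor-on-chip time-lapse
videos.

Tumor-on-chip devices embed cancer cells in a 3D collagen gel and image them
live for days, with the cancer cells carrying a red vital pre-stain and a
caspase-3/7 reporter that turns green at apoptosis onset. `apoptomap` turns
such two-channel recordings into quantitative death kinetics and a spatial
statistic of death transmissibility. It is aimed at groups running on-chip
cytotoxicity assays (chemotherapy, T-cell killing, stroma co-cultures) who
need per-cell death times, population kinetics, and evidence for or against
induction of death between neighboring cells.

## What it computes

1. **Localization and tracking.** Cells are detected per frame in the red
   channel by Otsu binarization followed by a circular Hough transform over
   an imposed radius range, then linked into tracks by exact minimum-cost
   assignment (squared displacement, gated, with births, gap bridging and
   terminations).
2. **Death calling.** Around each track a 31 px ROI in the green channel
   yields the background-normalized reporter trace
   `mu(t) = (muF - muB)/muB - min_F (muF - muB)/muB`, with the foreground the
   detected cell disk and the background the surrounding annulus. One Otsu
   threshold `th` over all pooled traces per video calls each cell's death at
   the first frame with `mu(t) > th`.
3. **Kinetics.** The apoptosis rate
   `O(t) = 100 * N_ap(t) / N_avg(t)` (events and mean living-track count in
   the trailing window `[t - T_LAG, t]`) and the overall survival
   `OS(t) = 100 * N_avg2(t) / ref` (3-frame-smoothed living count over the
   mean of the first three frames).
4. **Death map and potential of death induction.** Each death seeds a binary
   disk that decays by grayscale disk-erosion (a vanishing "wake"; erosion
   radius = one third of the average cell radius, so a wake lasts at least
   three hourly frames); squared wakes are summed over a forward window
   `T_tilde` into a cumulative map `MC`; its 8-connected objects `s_i`, with
   mean values `m_i` and boundary centroids, give

   `P_death(t) = 1/(2|S|) * sum_{i<j} (m_i + m_j) / dbar(s_i, s_j)`,

   evaluated in sliding 283 um windows and summarized per frame. Clustered,
   intense death patterns score high; sparse random death stays low and flat.
5. **Chains of death.** Deaths within 10 seed radii and within `T_LAG` of
   each other chain together; the chain duration is the seed's induction
   interval (the calibration behind the default `T_tilde = 16` h).

A seeded simulator (`simulate_video()`, `simulate_cohort()`,
`simulate_death_pattern()`) generates ground-truthed videos and abstract
death patterns — constant-hazard, clustered, or contagion-driven — so the
whole pipeline is testable end to end without external data.

## Worked example

```r
library(apoptomap)

cfg <- sim_config(seed = 11)        # 512 x 512 px, 48 hourly frames, ~100 cells,
sim <- simulate_video(cfg)          # constant 0.5%/h death hazard

run <- run_pipeline(run_config(calibration = cfg$calibration, seed = 11),
                    red = sim$red, green = sim$green)
run
#> <apoptomap_run: 102 tracks, 28 death events, th = 1.93, 512 x 512 x 48>

glance(run)[, 1:6]
#> # A tibble: 1 x 6
#>   n_tracks n_events threshold avg_radius_px se_radius_px mean_apoptosis_rate_pct
#>      <int>    <int>     <dbl>         <dbl>        <int>                   <dbl>
#> 1      102       28      1.93          5.50            2                    8.16
```

The 100 simulated cells yield 102 tracks (two brief detection dropouts split
tracks); all 28 programmed deaths are recovered, each within one frame of its
true onset. The pooled reporter threshold 1.93 sits between the basal traces
(minimum-normalized to 0) and the post-onset plateau (~4–5 background
contrast units). `tidy(run)` returns the event table;
`autoplot(run, "rate")`, `"survival"`, `"pdeath"` and `"map"` draw the
kinetics, survival, potential-of-death series and the death scatter map; and
`write_run(run, dir)` emits every table as CSV with a checksummed MANIFEST.

For event tables from other software, `pdeath_from_events()` computes the
map statistic alone. A thin command-line wrapper with `run`, `simulate`,
`pdeath` and `plot` subcommands lives at `inst/cli/apoptomap.R`.

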