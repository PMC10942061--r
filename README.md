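# calcitrack

Segmentation, tracking and spike analysis for calcium fluorescence
time-lapse movies of static, clustered cells — the acquisition regime of
insulin-secreting beta cells loaded with a calcium dye (e.g. Fluo-8) and
imaged for a couple of minutes before and after a stimulus.

Calcium signalling oscillates, so any single frame misses quiet cells, and
clustered cells are hard to separate in the cell channel alone. The
pipeline therefore:

1. builds a **maximum-value composite** (each pixel takes its brightest
   value over the stack), optionally merged with a nuclear-stain channel;
2. segments that composite **once** into a label mask — with a built-in
   deterministic segmenter (log-domain Otsu detection, nuclear-seeded
   splitting of touching cells, per-object half-maximum boundary
   refinement) or any external backend such as Cellpose via an adapter;
3. replicates the static mask over every frame and measures each cell's
   ROI mean intensity, area and centroid into a track table
   (each label *is* a track);
4. subtracts the per-frame mean of `n = 100` randomly sampled
   outside-ROI background pixels;
5. normalizes each trace to a per-cell baseline `F0` — the mean of the
   points before the first ≥ 10% change from the first recorded
   intensity (whole-trace mean if no crossing) — giving `v(t) = I(t)/F0`;
6. calls **spikes** at peaks of `v` by two rules: a single percent step
   `p_t = 100 (v_t − v_{t−1})/v_{t−1} ≥ 10%`, or a cumulative percent
   rise ≥ 10% over the ascent from the preceding trough;
7. summarises trials — pooled-Z outlier removal (|Z| > 3), mean activity
   = spikes / (cells × minutes) — and compares pre/post periods with a
   two-tailed paired t test.

A seeded synthetic-movie generator (`generate_movie()`,
`benchmark_suite()`) renders the exact data-generating model with full
ground truth (mask, dye factors, noise-free traces, spike schedule), so
every stage is benchmarkable without any real data.

## Worked example

Generate a small synthetic trial (8 cells, one scheduled 50% spike each),
write it as TIFF, and run the pipeline:

```r
library(calcitrack)

sched <- tibble::tibble(cell = 1:8, peak_frame = 10L + (0:7),
                        amplitude = 0.5, decay_frames = 3L)
mv <- generate_movie(synth_params(n_cells = 8, image_size = c(128L, 128L),
                                  spike_schedule = sched, seed = 31))
write_stack(frame_stack(round(mv$stack$frames)), "pre.tif")
write_stack(mv$nuclear, "nuc.tif")

res <- run_pipeline("pre.tif", "run1", run_config(z_max = Inf),
                    nuclear = "nuc.tif")
res$summary
#> <trial_summary> run1 [pre]: 8 cells (8 kept), 8 spikes over 2 min, activity 0.5 spikes/cell/min
```

All 8 cells are segmented, each scheduled spike is recovered at its
scheduled frame, and mean activity is 8 spikes / (8 cells × 2 min) = 0.5
spikes per cell per minute. `run1/` now holds `composite.tif`,
`mask.tif`, `tracks.csv`, `traces.csv`, `spikes.csv`, `summary.json` and
`run.log`; the first calls in `spikes.csv`:

```
TRACK_ID,PEAK_FRAME,RULE,MAGNITUDE_PCT
1,10,single_step,50.0755481779613
2,14,single_step,50.1299104981823
```

i.e. track 1 peaks at frame 10 with a ~50% single-step rise, matching the
scheduled amplitude. Plot the normalized traces and the spatial map of
spiking cells with `autoplot(traces, calls)` and
`plot_spike_map(tracks, calls, frame)`; pair pre/post trials with
`compare_periods()`.

The same flow is scriptable from a shell via the thin CLI in
`inst/cli/calcitrack` (`run`, `compare`, `synth` subcommands).

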