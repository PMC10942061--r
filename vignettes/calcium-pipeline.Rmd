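---
title: "Methods: segmentation, trace extraction and spike calling in calcitrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmentation, trace extraction and spike calling in calcitrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calcitrack)
```

## The measurement problem

Insulin-secreting beta cells signal through intracellular Ca²⁺, and a
calcium-sensitive dye such as Fluo-8 turns those transients into
fluorescence. Two properties of such recordings drive every design choice
in this package. First, calcium signalling **oscillates**: a cell can be
nearly dark in any individual frame, so segmenting one frame drops cells
that happen to be quiet. Second, the cells of interest grow in **static,
tightly packed clusters**: they do not migrate on the timescale of a
two-minute recording, but their boundaries are hard to separate in the
cell channel alone.

The pipeline therefore segments **once**, from a maximum-value composite
(every pixel takes its brightest value across the stack, so every
dye-loaded cell is fully lit somewhere in the image), optionally helped by
a nuclear stain (DAPI/NucBlue) to split touching cells, and then
**replicates that single mask across all frames**. Each mask label *is* a
track; no motion model, gap closing or track linking is needed, and the
per-frame measurement reduces to the unweighted mean intensity over each
ROI. This identity-linking design is only valid for recordings with
minimal movement, which is the intended acquisition regime.

## Processing model

For each cell $c$ and frame $t$, with $I_c(t)$ the ROI mean intensity:

1. **Background subtraction.** $n$ pixel locations (default 100) are drawn
   uniformly without replacement from outside every ROI (mask value 0,
   verified per pixel), and their per-frame mean $\bar B(t)$ is subtracted:
   $I^{\mathrm{bs}}_c(t) = I_c(t) - \bar B(t)$. One fixed coordinate set
   serves all frames; the draw is seeded and recorded, so runs are
   reproducible. Subtracted values may legitimately be negative.

2. **Baseline normalization.** Dye loading varies with cell size, cluster
   position and uptake, so traces are divided by a per-cell baseline
   $F_{0,c}$: the mean of the points *before* the first point whose
   absolute change from the first recorded intensity reaches the spike
   threshold (default 10%). A trace that never crosses uses its
   whole-trace mean. The normalized trace is
   $v_c(t) = I^{\mathrm{bs}}_c(t) / F_{0,c}$, a dF/F-style quantity that
   is exactly invariant to rescaling the raw trace.

3. **Spike determination.** With $p_t = 100\,(v_t - v_{t-1})/v_{t-1}$ the
   percent change at $t$, a *peak* is called a spike if either
   - **single-step**: $p_t \ge$ threshold, or
   - **cumulative**: the summed percent changes over the ascent from the
     preceding trough to the peak reach the threshold — catching slow
     multi-frame rises no single step of which qualifies.

   Each peak yields at most one call, with the single-step rule checked
   first.

4. **Trial statistics.** Tracks with any normalized value beyond a pooled
   Z cutoff (default $|Z| > 3$) are removed, mean spiking activity is
   computed as spikes / (cells × minutes), and pre/post periods are
   compared with a two-tailed paired t test across trials.

## Decisions the trace model leaves open

Several details of the procedure above are not forced by the informal
description and had to be fixed; the package's choices are:

* **Peak definition.** A peak is an interior strict local maximum; a
  plateau (run of equal values strictly above both flanks) counts once, at
  its first index; a final frame strictly above its predecessor also
  counts, since a rise cut off by the end of the recording is still a
  rise. Constant traces have no peaks.
* **Trough for the cumulative rule.** The ascent window resets at every
  local minimum: summing signed changes across an intervening drop would
  let the drop cancel genuine rise. The trough is found by walking back
  from the peak while the ascent (weakly) continues.
* **Crossing test.** The baseline search uses the *absolute* relative
  change (a ≥10% decrease also ends the baseline window), and the
  crossing point itself is excluded from the baseline mean — so a crossing
  at the second point leaves a one-point baseline.
* **Degenerate traces.** A first value of exactly 0 makes the fractional
  crossing test undefined; such traces fall back to the whole-trace mean.
  Any trace whose baseline is not positive is flagged invalid and excluded
  from spike analysis (with a message), never silently dropped.
* **Percent changes from non-positive values** are meaningless; peaks
  whose preceding value is ≤ 0 are skipped.

## Segmentation: detection vs boundary placement

The built-in segmenter is deterministic and separates two concerns.

*Detection* — is there a cell here? — Gaussian-smooths the composite
(σ = 2 px by default) and applies a global Otsu threshold **in log
intensity**. Dye loading varies by up to an order of magnitude between
cells; in linear intensity a single global threshold can sit above the
plateau of the dimmest cells and lose them entirely, while log compression
keeps one cut below every cell plateau. Foreground is labelled with
8-connectivity components, or — when a nuclear channel is supplied — split
by nuclear-seeded region growing (`EBImage::propagate`) on the smoothed
cell channel restricted to foreground, which resolves touching cells whose
nuclei are distinct.

*Boundary placement* — where exactly does the cell end? — re-cuts each
detected object at its own **half-maximum**: the threshold halfway between
the global background level (median outside all objects) and the object's
plateau. This is done on a lightly smoothed image (σ = 1): heavier blur
pulls the half-maximum of a small convex object inward by roughly
σ²/2r, which for 6-px cells at σ = 2 is a visible bias. Refinement never
claims pixels belonging to another object of the initial labelling, so
seeded splits survive. Objects below `min_cell_area_px` (default 50 px)
are then discarded and labels are renumbered consecutively in row-major
first-encountered-pixel order — the package-wide tie-break that makes
identical inputs give identical masks.

An external generalist model (e.g. Cellpose) can stand in for the
built-in segmenter through `segment_external()`, which sanitizes whatever
labelled image the backend returns into the same contract. The model
itself is deliberately not bundled; its parameters are pass-through.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `spike_threshold_pct` | 10 | % | crossing for baselines and spike calls |
| `n_background_pixels` | 100 | px | background sample size; estimator error ∝ σ/√n |
| `z_max` | 3 | – | pooled-Z outlier cutoff (`Inf` disables) |
| `min_cell_area_px` | 50 | px | smallest object kept by segmentation |
| `smooth_sigma` | 2 | px | detection smoothing |
| `frame_interval_s` | 5 | s | converts frames to minutes; 25 frames span 2 min |
| `rng_seed` | 1 | – | background sampling; echoed in `summary.json` |

Duration is `(T − 1) × Δt`: intervals, not frames, so the canonical
25-frame, 5-second acquisition spans exactly 2 minutes. Mean activity is
reported in spikes per cell per minute; dividing by time keeps trials of
different length comparable and only rescales a per-trial comparison by a
constant.

## A caveat on Z-score outlier removal

The pooled-Z filter runs *before* spike counting, which is the right
order for its purpose — discarding debris and segmentation faults before
they contaminate counts. But the filter scores every normalized value
against the pooled spread of the whole trial, and that spread is
scale-free with respect to spike amplitude: on a recording where most
cells spike in near lock-step over an otherwise quiet background, the
spike peaks themselves dominate the pooled variance and score |Z| ≈ 4–5
*regardless of amplitude*. On clean synthetic benchmarks this removes
exactly the spiking cells. Real recordings, with their broad cell-to-cell
variability, are far less susceptible, but benchmark-style evaluations of
spike recovery in this package therefore run with `z_max = Inf`, and a
regression test documents the behaviour rather than hiding it.

## The synthetic generator

`generate_movie()` renders the data-generating model the analysis assumes:
static disk cells (radii 6–9 px) on a jittered random layout, a lognormal
per-cell dye factor $L_c$ (σ = 0.2), baseline $B = 1000$, additive
background $b = 200$, Gaussian read noise truncated at zero, optional
Poisson shot noise, and a nuclear channel of smaller concentric disks. The
noise-free value of a pixel of cell $c$ is

$$ L_c \, B \,(1 + A\,g(t)) + b, \qquad
   g(\text{peak}+j) = e^{-3j/k} \;\; (0 \le j \le k), $$

so a scheduled spike of amplitude $A$ multiplies the loaded baseline by
$1+A$ at its peak and decays over $k$ frames. Placement enforces a 6-px
clearance between cell boundaries (about 3σ of the default smoothing):
the default geometry is meant to be *resolvable by construction*, so that
recovery benchmarks measure the pipeline rather than an arbitrary packing;
touching-cell behaviour is exercised separately through the seeded-split
path. `benchmark_suite()` crosses spike amplitudes {5, 10, 15, 20, 50}%
with read noise {0, 1, 2}% of baseline — bracketing the 10% threshold from
both sides — over 15 movies of 20 cells each.

The generator deliberately does **not** emulate cell migration or
division, photobleaching, focus drift, realistic spike waveforms
(plateaus, oscillatory bursting), or spatially correlated background.
Passing its benchmarks therefore demonstrates the correctness of the
arithmetic and the detection logic under the pipeline's own model
assumptions — not robustness to motion, bleaching or waveform diversity in
real recordings.

## Problem sizes and costs

Tests and the acceptance script run on 128²–256² movies of 25 frames with
up to 20 cells — 1/64 the pixel area of a typical 2048² acquisition,
preserving the acquisition geometry (frame count and interval) while
keeping the whole suite fast on a single CPU. Oracle cross-checks
(pixelwise loops, 1000-trace spike enumeration) are exact, not
statistical.

## Known limitations

* Static-mask tracking is wrong for moving cells; there is deliberately no
  drift correction or re-segmentation.
* The spike rules count threshold crossings; no waveform fitting,
  deconvolution, or frequency analysis.
* Nuclear seeding assumes one nucleus per cell; multinucleated or
  anuclear objects will be over- or under-split.
* TIFF input only (8/16-bit grayscale); native microscope formats must be
  converted upstream.
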