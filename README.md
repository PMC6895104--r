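# ardic: Adaptive Reference Digital Image Correlation for beating tissue video

`ardic` measures tissue displacement in time-lapse microscopy of
*spontaneously moving* samples — beating cardiomyocyte (CM) monolayers
being the motivating case — and turns those measurements into a full
spatiotemporal characterization of contraction: velocity and strain
fields, physiology-based contraction detection, beats per minute,
contraction volume, frequency/magnitude heat maps, and a tree-structured
analysis of contracting regions that localizes contraction origins and
their propagation.

The problem it solves: windowed image correlation (PIV/DIC) needs a
reference frame, and beating tissue has no stationary one. Under a static
reference, minor frame shifts after every contraction cycle accumulate, so
the measured "displacement" at rest drifts upward without bound. `ardic`
implements an **adaptive reference** scheme: each frame *t* is measured
against the active reference by multi-pass windowed cross-correlation, and
the Frobenius norm of the displacement matrix

```
||D|| = sqrt( Σ_valid vectors (u² + v²) )     [px]
```

is compared against a threshold `T_adapt`. When `||D|| < T_adapt` the
frame is a rest (diastolic) state and becomes the reference for subsequent
frames, so drift can only accumulate within one cycle. `T_adapt` is
estimated from two quiescent frames (norm rounded up to the next 0.1) and
then refined iteratively until the per-cycle baseline norm stops drifting.

Everything is validated end-to-end against a synthetic speckle-video
generator with exact analytic ground truth (known pulses, drift, rest
noise), which ships as first-class, tested code.

## Worked example

Generate a synthetic beating monolayer (one contraction origin at 1.25 Hz,
5 FPS, 0.9616 µm/px — 75 BPM, the conditions the package targets), run
AR-DIC, and compute contraction metrics:

```r
library(ardic)

sch <- piv_schedule(c(48, 24), c(12, 6), c(24, 12))  # final 12 px grid
fx  <- synth_preset("beating-1", seed = 42)

est <- estimate_tadapt(fx$stack, 1, 2, sch)          # two rest frames
fit <- ardic(fx$stack, sch, ar_config(t_adapt = est$t0))
fit
#> AR-DIC fit: 60 frames, adaptive reference
#>   t_adapt = 0.200 px; 44 reference switches
#>   Frobenius norm: median 0.185, max 21.399 px

blk <- (12 * 0.9616)^2                               # one vector block, um^2
cr  <- contraction_criteria(min_region_area_um2 = 10 * blk,
                            block_area_um2 = blk, norm_area_um2 = blk)
contraction_metrics(fit, cr)
#> contraction_metrics: 60 frames
#>   max beating area 2.463e+04 um^2 (coverage 82.2%)
#>   BPM 75.0 (FFT), 75.0 (peak counter)
#>   CV: max 228, 15 high frames (cutoff max - 1 sigma)

summary(fit)
#> AR-DIC summary: 60 frames (adaptive reference)
#>   t_adapt 0.200 px, 44 switches
#>   max displacement 2.919 px (2.807 um) at frame 31
```

Reading the output: the norm trace is ~0.19 px at rest (the noise floor)
and ~21 px during beats; 44 of 60 frames were adopted as references (every
rest frame), so no drift accumulates. The spectral and peak-counter BPM
agree at 75.0, and the measured peak displacement (2.92 px) is within a few
percent of the generator's planted 3 px pulse. Downstream:

```r
strains <- lapply(Filter(Negate(is.null), fit$fields), strain_fields)
forest  <- contraction_forest(fit, cr)   # region trees per beat cycle
find_origins(forest)                     # ranked contraction origins
asc_map(forest)                          # accumulated spatial contraction
plot(fit, "trace")                       # norm trace with switches
```

The whole pipeline (fields, trace, metrics, heat maps, tree tables, JSON
run manifest) runs in one call — `analyze_stack(stack, "out/")` — or from
the shell via the thin CLI at `inst/scripts/ardic-analyze`:

```sh
Rscript inst/scripts/ardic-analyze --input stack.tif --fps 5 \
    --pixel-size-um 0.9616 --auto-t-adapt --rest-frames 1,3 --refine \
    --out results/
```

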