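---
title: "Adaptive reference DIC for beating tissue: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive reference DIC: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Digital image correlation (DIC) and its windowed variant, particle image
velocimetry (PIV), measure tissue displacement by correlating local
intensity patterns between a *reference* frame and the current frame.
Spontaneously beating cardiomyocyte (CM) monolayers have no stationary
reference: the tissue never returns exactly to its starting configuration,
and small frame shifts after every contraction cycle accumulate into a
drifting baseline when a single static reference is used. After tens of
cycles the "displacement" measured at rest can exceed the beat displacement
itself.

The adaptive reference (AR) scheme implemented here re-selects the
reference frame whenever the tissue returns to rest. Every frame `t` is
measured against the currently active reference `r` by multi-pass PIV, and
the Frobenius norm of the displacement matrix,

    ||D|| = sqrt( sum over valid vectors ( u^2 + v^2 ) )   [px],

is recorded. If `||D|| < T_adapt`, frame `t` is judged to be a rest
(diastolic) state and becomes the reference for subsequent frames; its own
displacement is still reported against the *old* reference, so every frame
has a well-defined measurement (the order of events is a documented choice
-- the criterion itself does not dictate it). Because each adopted
reference is a rest state near zero absolute displacement, displacements
remain *absolute* (relative to a rest configuration) rather than
frame-to-frame relative, and the drift contribution is bounded by what
accumulates within one cycle instead of growing with the number of cycles.

Fields are reported against the active reference, not chained across
references: chaining would re-introduce exactly the error accumulation the
scheme removes. For tissues with genuine secular drift a chained mode
exists behind `ar_config(chain_references = TRUE)`.

## Estimating and refining T_adapt

`T_adapt` represents the latent noise floor of rest frames in Frobenius
norm units. It is initialized from two caller-designated quiescent frames:
`estimate_tadapt()` runs PIV between them and rounds the norm *up* to the
next multiple of `refine_step` (ceiling; a norm of 1.25 with step 0.1
yields 1.3). Rounding up is the conservative direction -- a threshold a
hair below the floor never switches at all.

Two early rest frames can underestimate the long-run floor, so
`refine_tadapt()` iterates: run the full AR analysis, split the record into
beat cycles, collect the minimum norm of each cycle (the baseline), and fit
a least-squares slope of baseline versus cycle index. While the baseline
drifts by more than `drift_tolerance` (px/cycle, default 0.05; 0.03 in the
bundled refinement study), the threshold is raised by `refine_step` and the
analysis repeated. The procedure terminates at the first threshold whose
baseline is flat; exhausting `refine_max_iters` is an error that reports
the full history.

Two operational details are not dictated by the selection criterion and are
fixed here as documented choices: (1) cycles for the baseline fit are
consecutive one-period bins of the norm series, with the period taken from
the dominant FFT component of the *linearly detrended* series (detrending
keeps a drifting baseline from masking the beat frequency); (2) the
baseline statistic is the per-bin minimum.

## The PIV engine

Displacement is measured by windowed zero-mean normalized cross-correlation
(ZNCC):

* The cross term for all lags comes from one zero-padded (linear, not
  circular) FFT correlation; per-lag means and variances over each overlap
  rectangle come from integral images, so the correlation coefficient is
  exact at every lag. Circular correlation or global mean subtraction
  biases sub-pixel peaks outward/inward along the lag direction by several
  hundredths of a pixel -- visible at this application's accuracy targets.
* The integer peak (restricted to the search radius, rejected if it sits on
  the search boundary) is refined by a 2-D Gaussian fit over the 3x3
  neighborhood of log-correlation values (a paraboloid with a cross term).
  Separable 3-point Gaussian fits -- the more common construction -- couple
  the axes when both sub-pixel components are sizable (errors up to ~0.1 px
  at diagonal quarter-pixel offsets on our fixtures); the cross term
  removes that bias. Where the neighborhood is not log-fittable the
  estimator falls back to separable 3-point Gaussian and then parabolic
  fits.
* A vector is valid only if the ZNCC peak height is at least `min_peak`
  (default 0.35) *and* the primary/secondary peak ratio is at least
  `min_peak_ratio` (default 1.2). Pure-noise window pairs peak below 0.3
  at these window sizes while genuine speckle matches sit far above 0.5,
  so the peak-height test alone flags uncorrelated windows essentially
  always; the ratio guards against multi-modal matches. Near-constant
  windows are flagged invalid rather than raising errors.

Passes run coarse to fine (`piv_schedule()`): each pass's validated field
is interpolated to the next grid and the next pass's interrogation windows
are pre-offset by the rounded seed, so the finer pass only measures a
sub-pixel residual. Between passes the normalized-median test (3x3
neighborhood, threshold 2.0, floor 0.1 px) replaces outliers by the median
of their valid neighbors and flags them; a vector with fewer than two valid
neighbors stays invalid -- nothing is fabricated.

Defaults: two passes, 64/32 px windows, 16/8 px search, 32/24 px spacing.
The 24 px final vector spacing is the working resolution for the CM
monolayer analyses this package targets; the window sizes bracketing it are
implementation choices (the spacing, not the windows, is what the
downstream block geometry depends on). The sinusoidal validation studies
use a three-pass schedule ending in 16 px windows, because displacement
gradients across a window smear the correlation peak and the 256 px
wavelength is comfortably resolvable at 16 px.

## Kinematics and strain

Velocity is the backward difference of displacement,
`v = (d_t - d_(t-1)) * pixel_size_um / dt`, in um/s. When the reference
switched between the two frames, `d_(t-1)` is first re-expressed against
the new reference by subtracting the new reference's own displacement
(available by construction, since the switch frame was measured against the
old reference); switch frames are rest states, so the correction is small.

Strain is the infinitesimal (engineering) tensor from central differences
of `(u, v)` on the vector grid (one-sided at borders):
`exx = du/dx`, `eyy = dv/dy`, `exy = (du/dy + dv/dx)/2`. The tensorial
(half-angle) shear convention is used and stated prominently, since maps
labeled "shear strain" are published under both conventions. Observed
strains in this application are below ~10 %, where the infinitesimal and
finite-strain descriptions agree to first order; no finite-strain tensor is
provided. Principal strains use the closed form
`e1,2 = (exx+eyy)/2 +- sqrt(((exx-eyy)/2)^2 + exy^2)` with `e1 >= e2`
(positive = tensile) and `theta_p = atan2(2 exy, exx - eyy)/2`. Optional
Gaussian pre-smoothing of the vector grid (sigma in grid cells, off by
default) is available because differentiation amplifies vector noise.

## Contraction metrics

A grid point is *contracting* when its displacement magnitude exceeds the
average single-sarcomere shortening length, 0.14 um; an alternate threshold
of four sarcomere lengths (0.56 um) is carried alongside. This replaces
manual outlining with a physiological criterion; both thresholds are
configurable (`contraction_criteria()`).

* **Beating area / coverage**: masked blocks x block area; coverage uses
  the number of *valid* grid points as denominator, since border windows
  carry no measurement.
* **BPM**: the displacement signal is the spatial mean |d| over grid points
  that ever exceed the threshold (the aggregation is a documented choice).
  The spectral estimate mean-detrends, applies a Hann window, zero-pads to
  at least 8x, and reads the dominant frequency in (0.2 Hz, fps/2); a flat
  or aperiodic signal reports `NA` with a low-prominence flag, never
  0 BPM. The automated peak counter requires interior maxima above
  mean + 0.5 sd separated by at least 0.33 s (~180 BPM ceiling, above the
  ~150 BPM that 5 FPS sampling resolves). At 5 FPS, narrow systolic pulses
  faster than ~100 BPM can fall between samples, so the peak counter is a
  verification tool for the spectral estimate, not a replacement.
* **Contraction volume (CV)**:
  `cv = sum over masked vectors(|d|_um * block_area) / norm_area`, with the
  normalization block 532.6 um^2 (one 24 px block at 0.9616 um/px). When
  block and normalization areas coincide this reduces to the plain sum of
  supra-threshold |d| in um; both areas stay explicit so non-default grids
  remain correct. "High CV" frames lie within one standard deviation below
  the maximum CV; high/low groups are compared by per-frame maxima of
  speed, tensile e1 and compressive e2 with Welch's t-test and mean +- SEM.
* **Heat maps**: the frequency map is the mean of binary masks over frames
  (fraction of time contracting); the magnitude map is the mean |d| in um.
  Both are pure accumulations, invariant to frame order.

## Region trees, origins, ASC and ASTC

Contracting regions (8-connected components of the grid mask, filtered at
4840 um^2 = ten 24 px blocks) become nodes. Lineage runs forward in time
toward the merged peak-contraction region: processing nodes in ascending
area order, the parent of a node at frame `t` is the smallest-area region
at the first later frame within the cycle whose member set contains the
node's centroid cell; the fully merged region is the root (depth 0), early
small regions are leaves, and leaves of multi-node trees are the
contraction origins. Cycles are maximal runs of frames with a retained
region, bounded by rest frames (a CV-minima segmentation is available
behind a flag). Three details the criterion leaves open are fixed here:
parent search may skip frames (first containing frame wins, tolerating
brief mask dropouts), centroid containment is evaluated on the grid member
set, and unattachable nodes become singleton roots (independent regions,
not origins).

Origins are ranked by depth below the root (deeper = earlier, stronger
origin), ties broken by subtree area; across cycles, leaves are clustered
by centroid proximity (1.5 grid spacings) so each physical origin appears
once. The ASC map assigns each grid point the maximum node depth over all
covering nodes across all trees ("max" rather than "sum" accumulation;
"sum" is available), so origins appear as peaks. The ASTC tables list every
node in space and time plus the parent-child edges; differencing the leaf
onset times of two origins within a cycle measures the beat propagation
delay, quantized by the frame period (0.2 s at 5 FPS).

## The synthetic generator: what it emulates, and what it does not

`beating_sequence()` warps a speckle texture (additive Gaussian blobs,
clipped to [0, 1] -- standard DIC practice, good correlation texture) by an
analytic displacement history, so every downstream stage can be checked
against exact ground truth. The default geometry is 192-256 px square at
0.9616 um/px and 5 FPS -- the pixel pitch at which one 24 px vector block
covers 532.6 um^2, matching the block normalization used throughout.

* **Beat pulses**: raised-cosine temporal envelopes occupying a `duty`
  fraction of each cycle (default 0.5), so genuine diastolic rest frames
  exist between beats -- the AR scheme requires near-motionless frames to
  re-reference. `duty = 1` gives the pure raised cosine, for which two
  origins half a cycle apart have exactly anti-correlated envelopes.
  Spatially, an origin is either a radially converging field (magnitude
  peaking on the ring `r = sigma`, compressive core and tensile surround
  -- the right fixture for strain sign structure) or a rigidly translating
  Gaussian patch ("bump", magnitude peaking at the origin -- the right
  fixture for region tracking, since windowed correlation at the center of
  a radial field straddles opposing motions and reports near-zero
  displacement there).
* **Inter-cycle drift**: a slow rigid translation per frame, emulating the
  frame shifts that build up measurement error under a static reference.
* **Rest-frame noise floor**: deterministic micro-motion states built from
  eight grid-orthonormalized plane-wave modes (equal wavelength, hence
  equal window-averaging attenuation) combined with Hadamard sign rows.
  Any two distinct states are the *same* Frobenius distance apart, giving
  a tight, controllable noise floor; the first frame's state can be scaled
  down so that an initial threshold estimate from two early frames
  underestimates the long-run floor -- the situation threshold refinement
  exists to correct. The bundled `tadapt-refine` preset is calibrated (via
  the analytic window attenuation of the modes, fixed once at design time)
  so the *measured* floor is about 1.45 px on its 15 x 15 grid and the
  first rest pair measures about 1.25, driving the estimate to 1.3 and the
  refinement through 1.3 -> 1.4 -> 1.5.
* **Validation pair**: `dic_challenge_pair()` builds a reference/deformed
  image pair with `u(x) = A sin(phi(x))`, the local wavelength following a
  schedule across column bands with continuous phase (an increasing strain
  gradient when wavelengths shrink). It is warped spectrally (periodic
  sinc interpolation, exact for band-limited content) on a periodic
  speckle texture; short-wavelength bands and the warp seam are excluded
  by the `resolvable()` flag, mirroring how unresolvable content is
  handled in published DIC test sets.

Not emulated: photorealistic cell appearance, out-of-plane motion,
illumination drift, texture decorrelation (blebbing, migration), and
non-rigid rest-state deformation. Passing these tests therefore
demonstrates correctness of the measurement and analysis chain under known
deformation of a well-textured surface -- not robustness to every
biological imaging artifact.

## Numerical choices

* Warping uses inverse mapping `output(x) = input(x - d(x))` with
  Catmull-Rom bicubic interpolation (exact at integer offsets, sub-pixel
  fidelity without ringing); the spectral warp is reserved for the
  column-displacement validation pair where fixture fidelity itself is
  under test.
* Coordinates are 1-based (R convention) with origin at the top-left
  pixel: `x` = column rightward, `y` = row downward, `u`/`v` along
  `x`/`y` in px; um = px x `pixel_size_um`. Window centers are reported
  exactly (half-integer for even windows).
* The Frobenius norm excludes flagged-invalid vectors (whether the
  original toolchain includes them is unknowable from the outside; excluding
  them keeps the score a property of measurements, not of failures), and
  norm units are px of the displacement matrix -- conversion to um is
  presentation-layer only.
* Degenerate inputs error early and loudly: fewer than 2 frames, missing
  fps or pixel size (no silent defaults), all-invalid fields, sub-3x3
  strain grids, beat frequencies at or above Nyquist.
* Determinism: every stochastic step (speckle, noise) derives from the
  spec seed through an isolated RNG scope; writers use fixed float formats
  and column orders, so identical inputs give byte-identical CSVs.

## Study conditions used by the test suite and acceptance script

Chosen as the smallest sizes that exercise every code path with realistic
physiology: 192-256 px frames, 15 x 15 to 19 x 19 vector grids, 40-60
frame records; beat rates 0.25 Hz (slow, multi-frame systole -- region
trees) and 1.25 Hz (75 BPM at 5 FPS, single-frame systole -- rate and
drift studies); pulse amplitudes ~3 px (~2.9 um, a multi-sarcomere
contraction), spatial sigma 22-30 px; drift 0.5 px/cycle for the
suppression study and 0.003 px/frame under the refinement fixture; BPM
recovery on 60 s synthetic signals at 5 FPS across 30-120 BPM. Region
criteria scale with the grid: one block = (spacing x 0.9616)^2 um^2, region
filter = ten blocks, mirroring the 24 px defaults.

## Known limitations

* No window deformation (affine shape functions): strong displacement
  gradients across a window smear the correlation peak; accuracy degrades
  for wavelengths below ~4 windows (such bands are flagged unresolvable
  rather than silently mismeasured).
* A single global reference: regions drifting independently would need
  per-region references, which this implementation deliberately does not
  attempt.
* Video containers are not decoded; stacks must arrive as multi-page TIFF.
* The peak-counter BPM verifier is unreliable above ~100 BPM at 5 FPS for
  narrow systolic pulses (sampling, not implementation).
* At 5 FPS a 1.25 Hz beat has a single-frame systole: region trees within
  such cycles are single nodes, which is a property of the acquisition
  rate, not of the tree construction; slower beats or faster acquisition
  yield multi-level trees.
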