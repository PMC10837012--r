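---
title: "Discovering behavioral modules in worm mating recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering behavioral modules in worm mating recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormmodes)
```

## The problem

*C. elegans* male mating is a multi-step behavior (searching, contacting the
hermaphrodite, backing along her body, turning, locating the vulva, spicule
prodding, insemination) classically scored by hand from video. `wormmodes`
implements an unsupervised alternative: posture and muscle activity are
quantified frame by frame, and a sticky autoregressive hidden Markov model
(AR-HMM) segments the recordings into recurring *modules* — short, stereotyped
motifs of coordinated posture/activity dynamics. Downstream statistics
characterize the modules, and a syntax layer describes how modules pair into
*bi-module repeats*, the "repeat until success/give up" routines that make up
most of the behavior.

## The measurement model

Each frame is reduced to 59 numbers:

* **19 bending angles.** The midline (head to tail, starting behind the
  pharynx) is resampled to 20 equal arc-length segments. The angle at each of
  the 19 internal segment boundaries is the polyline turning angle there,
  scaled by 20/19. The scaling makes each measurement the integral of signed
  curvature over 1/19 of the body, so the 19 angles together tile the total
  tangent turning of the worm: a quarter-circle posture reads
  $(\pi/2)/19 \approx 0.083$ rad at every boundary. (Raw chord turning angles
  at 19 interior vertices only cover 19/20 of the total turning; we chose the
  tiling convention so that angle sums equal total curvature, and the
  synthetic renderer applies the inverse scaling so that the
  render-then-quantify round trip is exact.) Ventral bending is positive;
  because sidedness cannot be recovered from a midline alone, each recording
  carries a ventral-side sign flag.
* **40 activity ratios.** For each segment, ventral and dorsal muscle activity
  is the ratio of summed GCaMP (calcium-sensitive) to summed mDsRed
  (calcium-insensitive) fluorescence. The ratio cancels expression level and
  region area; scaling both channels leaves it unchanged. Intensities may be
  supplied per segment or as image + body-mask rasters, in which case masked
  pixels are assigned to the nearest midline segment by perpendicular
  projection and split by midline side. No background subtraction is applied.

Frames with degenerate midlines or non-positive mDsRed sums are flagged
invalid. Invalid runs up to `max_gap` frames (default 5, i.e. 0.5 s at 10 Hz —
below the ~0.8 s scale of the shortest behavioral units) are linearly
interpolated between valid neighbors; longer runs are excluded and later
collected under a dedicated failed-frame module (id 0). Signed centroid speed
uses the posterior-to-anterior body axis (midline point 15 to point 5) to
decide forward versus backward; with the default calibration of 2.6 µm/pixel
at 10 Hz, 4 pixels/frame is ~104 µm/s. The calibration is implied by the
reported speed correspondence rather than stated directly, and is exposed in
`anatomy_config()`.

## Model-free temporal structure

Three analyses inform the model's time scales:

* `autocorrelation()` — average per-dimension autocorrelation; the fast decay
  (~2 s) motivates a low AR order.
* `welch_psd()` — Hann-tapered, per-window demeaned Welch spectral density.
  The default 25.6 s window (256 samples at 10 Hz) resolves the 0.12 Hz lower
  edge of the behavioral band; 0.12–1.20 Hz corresponds to behavioral units of
  0.8–8 s.
* `changepoints()` — exact penalized least-squares mean-shift segmentation
  (PELT pruning, identical optimum to full dynamic programming). We run it on
  the z-scored principal-component projection rather than the raw 59
  measurements, mirroring the modeling input; whether the original analysis
  used raw measurements or components is not documented, so this is our
  assumption. The penalty is a knob; `tune_changepoint_penalty()` sweeps it so
  the median block duration lands in the 0.4–5 s range where behavioral blocks
  concentrate.

The changepoint block-duration distribution is the reference for tuning the
model's stickiness (below).

## The sticky AR-HMM

Within module $k$, the PC-projected observation vector follows a vector
autoregression
$y_t = A^{(k)} y_{t-1} + b^{(k)} + \epsilon_t$, $\epsilon_t \sim N(0,
\Sigma^{(k)})$; module identity follows a Markov chain whose transition prior
row $j$ is $\mathrm{Dirichlet}(\alpha + \kappa e_j)$. The self-transition bias
$\kappa$ suppresses unrealistically rapid switching: its prior expectation of
the self-transition probability, $(\alpha + \kappa)/(K\alpha + \kappa)$,
increases strictly with $\kappa$, and larger $\kappa$ lengthens module
durations. `tune_kappa()` fits a grid and picks the $\kappa$ minimizing the
Kolmogorov–Smirnov distance between log module durations and log changepoint
block durations — a formal stand-in for the published visual matching, whose
exact criterion is not documented.

Inference is Gibbs sampling with exact conditionals:

1. **Labels** by forward-filter backward-sampling (implemented in C++), one
   pass per uninterrupted chunk; invalid frames split recordings into chunks
   rather than being imputed, so failed data never contaminates the dynamics.
2. **AR parameters** from the conjugate matrix-normal-inverse-Wishart
   posterior. The prior mean of the lag matrix is the identity (posture
   persists frame to frame), the column precision is weak
   (`k0 = 0.01`), and the inverse-Wishart scale is the identity with
   `nu0 = d + 2` — sensible because sequences are globally z-scored before
   fitting.
3. **Transition rows** from the sticky Dirichlet posterior (observed counts
   plus $\alpha$ plus $\kappa$ on the diagonal).

Defaults: AR lag $L = 1$ (one lag captures the fast dynamics at 10 Hz; larger
lags are configurable), finite truncation `K_max` (a weak-limit approximation
of the hierarchical Dirichlet process used by this model family), labels
initialized by k-means on the observations, and MAP labels taken from the
single highest-likelihood retained sweep so blocks stay contiguous for syntax
analysis (per-frame marginal votes would fragment them). All randomness flows
from a single integer seed; two runs with one seed are bit-identical. All
recordings and genotypes are pooled for fitting and separated only for
statistics.

Dimensionality reduction uses PCA with a cumulative-variance target (default
90%) capped at 30 components; modeling 30 of 59 dimensions shrinks the
quadratic AR parameter count by $1 - (30/59)^2 \approx 74\%$.

## Module statistics and syntax

`extract_blocks()` turns label runs into blocks; modules with at least 1% mean
usage are "major". `usage_frequencies()` compares per-recording usage between
genotypes with a two-sided Mann–Whitney U test (normal approximation with tie
correction; an exact pair-counting U is exported for cross-checking) and
Benjamini–Hochberg adjustment across modules — the original analysis reports
starred p-values without naming a correction, so BH is our choice.
`extract_curves()` segments each frame's angles into maximal same-sign runs;
curve size is the summed absolute turning of the run (an aggregation the
source figures do not define; total turning is our reading) with S/M/L classes
at 0.5 and 1.5 rad, and the curve center is the boundary with the largest
absolute angle. `block_percentiles()` contrasts in-block (p5/median/p95 per
segment within a block) against among-block spread over a seeded sample of 100
blocks with at least 10 frames. `skeleton_overlay()` aligns fixed-length
skeletons at their center point to show which body third moves.
`vulva_contact()` calls a block ON when the tail stays within the contact
radius (default two segment lengths — no published threshold exists) for every
frame, inclusively at the boundary.

`detect_repeats()` finds maximal runs of blocks alternating between exactly
two module ids by a greedy left-to-right scan; at least 3 blocks (one full
A-B-A) qualify as a repeat, and a block shared by two candidate alternations
goes to the earlier one — both deterministic conventions we fixed because the
source defines none. The shipped `default_version_map()` covers the published
pairs (f: 9–14, s: 14–24, p: 14–40, m: 24–60, r: 14–60, va: 9–60, alpha:
23–40, gamma: 10–40); the v, beta and delta pairs are not published and fall
back to `other:a-b` codes. `usage_over_time()` bins repeat coverage into 60 s
bins (the published time courses mask the first minute, from which the bin
width is inferred) and `transition_paths()` links consecutive repeats
separated by at most 2 s of unassigned frames.

## What the synthetic generator emulates — and what it does not

`renderable_ground_truth()` + `sample_labels()` + `render_recording()` produce
10 Hz recordings of a 20-segment worm: a sticky Markov chain over 3–5 states,
each with stable AR(1) dynamics around a state-specific posture wave and
activity profile; angles are integrated into a constant arc-length midline
(self-crossings are flagged, not fatal); mDsRed is a smooth per-segment
expression profile with slow drift, and GCaMP equals activity × mDsRed with
log-normal multiplicative noise, so the ratio recovers activity exactly at
zero noise. `corrupt_frames()` plants failure runs at a controlled fraction.

The generator does **not** emulate: real image noise and the pixel-level
appearance the upstream deep-learning tracker consumes, hermaphrodite contact
mechanics, pharyngeal GFP bleed-through, or tracking errors correlated with
posture. Passing tests therefore demonstrate that the pipeline's mathematics
is correct and self-consistent on data obeying its generative assumptions —
not that the tracker-facing steps are robust to real video artifacts.

Desk-scale problem sizes are deliberate: simulation tests use 3 states in 6–12
dimensions with $10^3$–$10^4$ frames and a few hundred Gibbs sweeps, and the
end-to-end runs use two genotype groups of short recordings. These sizes give
stable recovery (label accuracy above 90%, AR matrices within 10% relative
Frobenius error) while keeping the whole suite quick to run.

## Numerical choices and degenerate inputs

* Resampling uses piecewise-linear arc-length interpolation; segment lengths
  agree to <0.1% on smooth midlines.
* The forward filter normalizes per frame (log-domain likelihoods shifted by
  their row maximum) and raises a clear underflow error rather than returning
  garbage.
* `quantile()` type 7 (linear interpolation) is used everywhere percentiles
  are reported.
* Empty states in the sampler draw their parameters from the prior, the
  standard weak-limit treatment.
* Degenerate inputs fail loudly and early: zero-variance series for
  autocorrelation, constant data for PCA, non-finite values for changepoints,
  an all-invalid recording for cleaning.
* Transition-frequency and KS checks on discrete durations evaluate the
  empirical CDF on the integer support (the naive two-sample formula
  overstates the distance for tied data).

## A small worked run

```{r, eval = FALSE}
cfg <- run_config(seed = 7, n_recordings = 1, n_frames = 400, n_states = 3,
                  K_max = 5, n_iter = 25, burn_in = 12)
res <- run_end_to_end(cfg, "run_out")
res$majors          # module usage table with the major flag
res$syntax$repeats  # detected bi-module repeats with version codes
```

The manifest (`run_out/manifest.json`) records every artifact, per-stage seed
and duration, and the configuration hash; re-running with the same seed
reproduces the label and repeat tables byte for byte.

## Known limitations

* The Mann–Whitney comparison uses the normal approximation with tie
  correction for all group sizes; exact enumeration is available separately
  but not wired into `usage_frequencies()`.
* `match_states()` uses greedy overlap assignment, not the full Hungarian
  algorithm; for the small K used here the greedy optimum coincides in
  practice, and it is only an evaluation helper for synthetic data.
* The sampler fixes `K_max` rather than inferring the state count; the
  usage threshold determines which states count as behavioral modules.
* Rendered image stacks (TIFF) are not produced; the generator emits
  per-segment intensity tables, which are the quantification contract.
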