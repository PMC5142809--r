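---
title: "Quantifying calcium activity and behavior in the C. elegans egg-laying circuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying calcium activity and behavior in the C. elegans egg-laying circuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eggcircuit)
library(dplyr)
```

## The measurement problem

The *C. elegans* egg-laying circuit — two serotonergic HSN command neurons,
six cholinergic VC motor neurons, the vulval muscles (vm), and four
neuroendocrine uv1 cells — produces a two-state behavior: quiescent periods
of roughly twenty minutes alternate with active states of a couple of
minutes during which a handful of eggs are laid. Ratiometric calcium
imaging in freely behaving animals (GCaMP5 against a calcium-insensitive
mCherry co-reporter) turns that circuit's activity into per-cell
fluorescence-ratio time series; the analysis problem is to turn those
series, plus manually scored egg-release times and body-bend landmarks,
into the quantities of interest:

* discrete Ca²⁺ transients with peak time, peak ΔR/R amplitude, and width
  at half-maximum;
* egg-laying **active/inactive states** defined operationally as ±1 min
  around each egg-release event, and state-resolved inter-transient
  intervals;
* **rhythmicity** of active-state segments, summarized by the largest
  periodogram peak between 0 and 250 mHz;
* the **body-bend phase** of each transient, interpolated between flanking
  ventral-contraction/relaxation landmarks (0°/360° = contraction,
  180° = relaxation);
* **egg-release-triggered** ensembles of normalized traces, muscle size,
  and locomotion speed.

This package implements that pipeline end to end, together with a
ground-truthed synthetic-recording generator so every stage is testable
without any external data.

## The ratio model and trace processing

The two channels share every multiplicative nuisance (motion, focus,
illumination), so their ratio cancels it; that is the entire point of the
co-reporter. The forward model used by the simulator and assumed by the
pipeline is

$$G(t) = B_G\,\bigl(1 + \Delta R/R(t)\bigr)\, m(t) + \varepsilon_G,\qquad
  M(t) = B_M\, m(t) + \varepsilon_M,$$

with a shared smooth artifact $m(t) > 0$ and independent additive noise per
channel. The pipeline's ratio-invariance property — extraction and ΔR/R are
unchanged by any $m(t)$ when additive noise is absent — is exact, and is
tested as such.

Processing follows the published recipe: a 150 ms (three timepoints at
20 frames/s) centered rolling average; a baseline equal to the mean of the
lowest 10% of ratio values over the whole recording;
$\Delta R/R = (R - R_0)/R_0$. Transients are local maxima with topographic
prominence above a noise-scaled threshold, with half-maximum spans found by
walking outward to the half-amplitude crossings (linear interpolation
between samples; overlapping spans truncate at the inter-peak minimum).
Amplitudes are normalized per recording (maximum peak = 1) for
cross-reporter comparisons.

Two detection choices deserve explanation, because the source recipe relied
on visual confirmation and states no numeric criterion:

* **Noise scale.** The robust scale is $1.4826\,\mathrm{MAD}(\Delta x)/\sqrt 2$
  computed on the *raw* (pre-smoothing) ΔR/R. A k-point rolling average
  correlates adjacent samples and deflates a difference-based estimate by
  $\sqrt k$; estimating on the smoothed trace therefore triples the
  effective false-positive rate at a fixed multiplier.
* **Threshold = 4.5 robust SDs** (`min_prominence_sigmas`). The topographic
  prominence of the *global* maximum of a pure-noise trace spans nearly the
  full range (about 7.5 smoothed-noise SDs for a 10-minute trace), so a
  4-SD bar is crossed on almost every noise-only recording. At 4.5 SDs the
  measured false-positive rate is about 0.12 events per 10 minutes
  (Monte-Carlo null over 100 seeded runs), while remaining an order of
  magnitude below physiological amplitudes (ΔR/R ≳ 0.3 against a noise
  floor of ~0.03).

The lowest-decile baseline is computed on the smoothed ratio by default
(`baseline_on_smoothed = FALSE` switches to the raw ratio); the difference
is far below the noise floor at 20 frames/s.

## The synthetic-data generator

The generator is event-level first (`simulate_behavior()`), then rendered
to traces or image stacks (`render_traces()`, `render_frames()`). Its
defaults *are* the study conditions; they are not tuning knobs:

| quantity | default | why |
|---|---|---|
| frame rate | 20 frames/s | acquisition rate of the recordings |
| inactive / active state means | 1200 s / 120 s (exponential) | ~20 min quiescence, ~2 min active states |
| body-bend period | 10 s, CV 0.1 (per-half-period Gamma jitter) | locomotor rhythm at the vulva |
| HSN burst rhythm | 20 s period, CV 0.05, doublet probability 0.15 at ~5 s offset | see below |
| HSN quiet-state interval | 41 s (renewal) | reported wild-type inactive interval |
| VC / vm | one transient per bend cycle, von Mises phase lock at 270° (κ = 2 / 4) | bend-locked activity, interval ≈ 10 s |
| transient widths | HSN 4 s, VC 2 s, vm 2 s, uv1 3 s at half-max | reported half-max widths |
| vm egg-transient amplitude | 4 × twitch amplitude | reported ~four-fold ratio |
| egg placement | candidate rate 1/s in active states, thinned to HSN half-max spans and a 225° phase window (κ = 2); release at HSN peak + ~1.5 s | yields ~5 eggs per active state, eggs always inside an HSN transient |
| uv1 | rise starts at egg + ~0.5 s, peak ~2 s after release | egg-triggered mechanosensory response |
| noise | 2% additive per channel, 10% shared artifact | typical recording quality |

**Why the HSN doublet mixture.** The wild-type active state exhibits *both*
a ~20 s burst rhythm (dominant spectral peak at 50 mHz) *and* a mean
inter-transient interval of ~17 s. A renewal train with a 17 s mean puts
its spectral peak at ~59 mHz; a clean 20 s oscillator has a 20 s mean
interval. The only structure consistent with both numbers — and with the
observed "single events or trains" — is a rhythmic base train with
occasional doublets: mean interval $20/(1+0.15) \approx 17.4$ s while the
spectral fundamental stays at 50 mHz.

**Why HSN bursting leads and trails the egg cluster** (`burst_lead`,
`burst_tail`, 60 s each). HSN bursting *drives* the active state, so it
begins before the first egg; the operational ±1 min state definition then
lands inside the burst epoch. Without the lead/tail, the egg-defined active
window would dilute burst intervals with quiet-state intervals and the
recovered active-state mean could not match the value the same definition
produced on real recordings.

**Resolvability floor.** Quiet-state renewal trains use a refractory floor
of min(2 FWHM, mean/2) with the exponential tail rescaled to keep the
configured mean: two Gaussian kernels closer than about two widths merge
into a single local maximum, which would make ground-truth counts
unrecoverable by *any* peak detector, noise or not. The same bound applies
to the doublet offset (≥ FWHM + 0.5 s).

What the generator deliberately does **not** emulate: photobleaching and
focus drift beyond the shared multiplicative artifact, cell-shape change
and mechanical deformation of ROIs, tracking failures, asymmetric
anterior/posterior muscle activation, and any biophysics of membrane
potential. Passing tests therefore demonstrate correctness of the
*quantification* under the stated statistical structure, not robustness to
every pathology of real video.

Determinism: every stochastic component draws from its own sub-stream
derived from the single config seed, so edits to one cell's parameters do
not reshuffle another's train, and identical configs are bit-identical.

## ROI extraction

Image stacks are reduced to traces exactly as the pipeline's upstream step
would do it: per frame, a two-pass robust background estimate on the
mCherry channel (mean/SD of all pixels, then of pixels below mean + 2 SD);
a threshold at background mean + 2 SD; 8-connected components of at least
`min_object_px` (default 5) pixels; per-object means; and an area-adjusted
join, $\sum_i a_i r_i / \sum_i a_i$, over the detected objects. The total
object area doubles as the muscle-contraction proxy. Per-channel background
means are subtracted before pixel ratios are formed, so the object ratio
reflects cell fluorescence rather than a cell/background mixture — with
flat-top test blobs and zero background noise the extraction recovers the
ground-truth ratio exactly, and that exactness is tested. Missing frames
(no object) are linearly interpolated up to 10 frames; longer gaps stay
missing, and recordings more than half missing abort. Background can be
estimated per frame (default) or once per recording.

## Rhythm analysis

Active-state ΔR/R segments at least 30 s long are mean-subtracted,
zero-padded to the next power of two ≥ 4× the segment length (≈ 1.2 mHz
grid for a 3-minute segment at 20 frames/s), and transformed; power is the
squared magnitude. No taper is applied by default — segments are short and
the quantity of interest is the dominant peak location, not leakage-free
amplitudes — but a Hann window is available. The dominant peak is the
argmax of power in (0, 250] mHz, zero excluded, ties broken toward the
lower frequency. A hand-written normalized Lomb-Scargle periodogram covers
uneven sampling and event trains (binarized onto a 0.25 s grid), and an
autocorrelation estimate (first significant positive peak beyond the
initial decay, significance bound $2/\sqrt n$) provides a third route; the
three agree within a grid bin on evenly sampled periodic input, and that
agreement is a test, not an assumption.

## Behavior states, intervals, and egg coupling

Each egg contributes a [−60 s, +60 s] window; overlapping windows merge
(`merge_gap = 0`: windows merge only when they touch, so eggs up to two
minutes apart share a state). The complement is inactive. Membership is
half-open [start, end) for deterministic boundary assignment. Intervals are
successive-peak differences within a state; pairs spanning different state
intervals are excluded by default (a config flag includes them). An
inactive state with no successive pairs contributes the operational
boundary intervals — time from recording start to the first transient and
from the last transient to recording end — flagged `kind = "boundary"`, so
silent recordings still yield a (lower-bound) inactive interval estimate. A
transient is egg-coupled when an egg-release time falls inside its closed
half-max span; an egg is covered when some span contains it.

## Locomotion phase

The phase of an event between flanking landmarks $(t_0, k_0)$ and $(t_1,
k_1)$ is $180 f$ degrees after a contraction and $180 + 180 f$ after a
relaxation, with $f = (t - t_0)/(t_1 - t_0)$; 360° is represented as 0°
(half-open convention — both labels name the same pose). The rule is
invariant to time translation and uniform rescaling, hence independent of
speed and locomotion direction, and those invariances are property-tested.
Landmark detection from a bend signal takes prominent extrema
(≥ 25% of the signal range) and repairs any same-kind runs by keeping the
larger extremum, so landmarks always alternate.

Histograms use eight half-open 45° bins. The uniformity test reproduces the
published construction — observed bin counts against an equal number of
uniformly drawn events, compared by a rank-based (Kruskal-Wallis) test
across bins — and additionally reports a Rayleigh test, flagged as an
addition. The binned construction is *conservative*: with eight ranks per
group its smallest achievable p-value is about $8\times10^{-4}$, and even a
fully concentrated sample yields p ≈ 0.01–0.02 (its seven empty bins rank
at the bottom while the loaded bin ranks at the top, so rank separation is
never complete). The Rayleigh addition is calibrated (measured type-I error
0.047 at α = 0.05) and is the one to use for inference; the binned test is
kept because it is the published construction.

## Egg-triggered alignment

Snippets of ±10 s (a window chosen to contain the peri-event dynamics of
all four cell types) around each egg with a full window inside the
recording; each snippet normalized to its own peak (= 100%) for traces, or
to its pre-event mean for muscle size; pointwise median across events.
Peak offsets use the nearest detected transient peak when a transient table
is available, otherwise the snippet argmax. Speed is the centroid central
difference smoothed with the same 3-point average, with a pointwise 95%
t-interval and paired t-tests of speed at 0 s against ±1 s. No resampling
is performed when recordings share a frame rate; linear interpolation
otherwise.

## Group comparisons

Medians and quartiles are computed in-package; hypothesis tests are library
calls (`wilcox.test`, `kruskal.test`), with Dunn's pairwise z-tests on mean
ranks (standard tie correction, Bonferroni adjustment) implemented here
because no installed library provides them. Identical groups compare with
p ≈ 1; a simulated 17 s vs 13 s interval contrast at ≥ 100 intervals per
group is detected at α = 0.05 in ≥ 95% of seeded runs, mirroring the
published wild-type/mutant comparison.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(duration = 7920, seed = 1)   # six state cycles
sim <- run_simulate(cfg, cells = c("hsn", "vm"))
ann <- dplyr::bind_rows(
  tibble::tibble(time_s = sim$truth$eggs$time_s, event_type = "egg"),
  tibble::tibble(time_s = sim$truth$landmarks$time_s,
                 event_type = paste0("ventral_", sim$truth$landmarks$kind)))
res <- run_analyze(sim$traces, ann)
glance(res)
autoplot(res$cells$hsn$trace, transients = res$cells$hsn$transients)
plot_phase_histogram(res$cells$vm$phase_histogram)
```

## Problem sizes and numerical choices

* Parameter-recovery checks (rhythms, intervals) run on one 79,200 s
  simulated recording (60 state cycles), which yields ≥ 20 analyzable
  active states and ≥ 300 active-state HSN transients.
* The power comparison uses ground-truth transient trains (rendering and
  detection change interval means by far less than the 4 s contrast) over
  100 seeded runs per arm with shortened quiescent periods, which changes
  the number of active states per recording but not the interval
  distributions being compared.
* Degenerate inputs: zero-duration configs give empty ground truth; flat
  traces give no transients; traces with no eggs give a single inactive
  state; a non-positive baseline aborts; constant bend signals give no
  landmarks; an event at a span edge belongs to the later interval.
* Tie-breaks: dominant-peak ties go to the lower frequency; equal-height
  landmark repairs keep the earlier extremum.

## Known limitations

State segmentation is event-based, as published; no hidden-Markov or
changepoint inference from activity alone. No motion registration,
multi-cell tracking, bleaching correction, or spike inference. Cell types
are analyzed independently (the source recordings were never simultaneous).
The simulator couples egg release to HSN spans only; VC egg-coincidence
arises from bend-phase locking plus a forced accompanying transient, since
whether egg release additionally *requires* VC coincidence is not
established.
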