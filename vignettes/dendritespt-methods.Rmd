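---
title: "Motion-state inference and spatial statistics for dendritic vesicle traffic"
author: "dendritespt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motion-state inference and spatial statistics for dendritic vesicle traffic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendritespt)
```

## The problem

Receptor-carrying vesicles in dendrites alternate between Brownian
diffusion and motor-driven directed transport. Synaptic stimulation
(chemical LTP, or glutamate uncaging at a single spine) locally remodels
the actin cytoskeleton of the dendritic shaft, which confines vesicles
near the stimulated site: the fraction of vesicles in active transport
drops, diffusion slows, transport-to-diffusion switching increases, and
vesicles accumulate — feeding local exocytosis. Quantifying this requires
a chain of analyses: particle detection and tracking, per-trajectory
motion-state inference, identification of genuine intracellular vesicles
among other labelled species, and spatial statistics referenced to the
dendrite's own geometry. `dendritespt` implements that chain, plus a
synthetic-data generator rich enough to test every stage against known
ground truth.

## The motion model

A trajectory is a time series of 2D positions sampled at interval
$\Delta t$ (default 0.05 s, i.e. 20 Hz acquisition). Its displacement per
frame is modelled by a hidden Markov chain over $K \le 3$ states. Each
state is either purely diffusive (kind `D`) or directed transport (kind
`DV`, drift plus diffusion). Conditional on state $k$, the per-axis step
is Gaussian:

$$\Delta x \sim \mathcal{N}(V_{k,x}\,\Delta t,\; 2 D_k \Delta t + 2\sigma_{loc}^2),$$

independently per axis, where $D_k$ is the diffusion coefficient
(µm²/s), $V_k$ the state's constant velocity vector (µm/s; zero for `D`
states) and $\sigma_{loc}$ the localisation noise (default 20 nm per
axis). The corresponding mean squared displacement of a single state is
the classic two-dimensional diffusion-plus-drift law

$$\langle r^2 \rangle = 4 D \Delta t + (V \Delta t)^2,$$

which is also the model `fit_msd_model()` fits to time-averaged MSD
curves, with both coefficients constrained non-negative.

### Fitting and model selection

`fit_hmm()` enumerates all state-kind layouts for $K \in \{1,2,3\}$
(9 candidate models), fits each by Baum–Welch EM on the displacement
series (the forward–backward and Viterbi cores are compiled), and selects
by BIC, with ties within 2 BIC units resolved toward fewer states, then
fewer parameters. Single-state models are fitted in closed form; the
$K=1$ diffusive estimate equals the noise-corrected mean-squared-step
estimator $\hat D = \sum_i \lvert\Delta r_i\rvert^2 / (4 n \Delta t) -
\sigma_{loc}^2/\Delta t$ (floored at zero). EM initialisation uses
k-means on step speeds with 5 restarts (jittered after the first), a
fixed internal seed, at most 50 iterations and a relative log-likelihood
tolerance of $10^{-5}$; these iteration limits were chosen by checking
that tightening them further does not change selected models or decoded
paths on simulated cohorts. Bayesian model selection is approximated by
BIC because it is deterministic and easily audited; the selection margin
is a parameter.

Two caveats discovered and characterised during development:

- **Viterbi dwell bias.** Decoded state paths absorb dwells too short to
  overcome the transition penalty, so transition probabilities counted on
  decoded paths (`transition_rates()`) underestimate fast switching. The
  bias is negligible when mean dwells are long relative to the evidence
  accumulation length (roughly $\ell^\ast \approx 2\log((1-k)/k) /
  \mathrm{LLR}_{step}$ steps); parameter-recovery tests therefore use
  switching probabilities of ~0.01/frame with strong transport
  ($|V| = 2$ µm/s), where the bias sits inside the sampling band.
- **Speed aggregation bias.** The per-trajectory MSD speed estimate is
  $\sqrt{\hat b}$ of the fitted quadratic coefficient $\hat b = V^2$.
  $\hat b$ aggregates without bias across a cohort, but the mean of
  per-trajectory square roots is biased low by concavity (about 10% at
  200-step trajectories with $D = 0.1$, $|V| = 0.5$). Cohort-level
  comparisons should aggregate $\hat b$ (root-mean-square speed), which
  is what the tests assert at 10%; the mean-of-roots is asserted at 15%.

### MSD validation

Following standard practice, diffusion coefficients from the HMM are
cross-validated against MSD curve fitting: `fit_msd_model()` also reports
a pure-diffusion (through-origin linear) fit whose $R^2 \ge 0.8$ gates
acceptance. Because time-averaged MSD values at long lags are strongly
correlated and noisy, the validation fit should use only the first few
lags (the tests use the first 1% of lags of 1000-step trajectories, i.e.
10 lags); with that choice HMM and MSD estimates agree within 25% on
single-state synthetic data. `fit_anomalous_exponent()` reports the
log–log slope $\alpha$ ($1$ = Brownian, $2$ = ballistic, $<1$ =
subdiffusion); no threshold on $\alpha$ is applied anywhere — it is a
descriptive statistic.

## The synthetic-data generator

The generator is the package's substitute for unreleased live-cell
imaging; its defaults encode the study conditions the analyses are meant
to face.

**Geometry.** `simulate_dendrite()` builds a centerline of exact total
arc length (default discretisation 1 µm) whose heading performs a
Gaussian random walk scaled by a `curvature` parameter; `curvature = 0`
gives a straight shaft. Spines are small quadrilaterals attached to the
shaft boundary in disjoint arc-length slots. The uncaging site is an
arc-length coordinate. The worked zone construction (90 µm dendrite,
zone 1 = the 30 µm flanking the site, zone 2 = two 15 µm stretches,
zone 3 = the rest) follows from `assign_zone()`'s piecewise rule
$\delta = |s - u|$: zone 1 iff $\delta \le L/6$, zone 2 iff $\delta \le
L/3$, zone 3 otherwise. Zones are deliberately not re-centred when the
site sits near a dendrite end, matching the printed construction; they
then cover unequal lengths.

**Motion.** `simulate_trajectory()` runs the Markov chain with two
dendrite-specific additions the plain HMM lacks: (i) optional reflecting
boundaries at the shaft walls and dendrite ends (reflection preserves
dwell inside the shaft without biasing $D$ at the scales tested); and
(ii) directed-state headings drawn once per state entry — aligned with
the local centerline tangent with random sign for `longitudinal` states,
or with the local normal for `lateral` states. The heading re-draw means
dendritic trajectories are *not* exactly the HMM's generative model (a
`DV` state's velocity flips sign between entries); parameter-recovery
tests therefore use `simulate_hmm_steps()`, which draws from the emission
model exactly, while pipeline-level tests use the dendrite generator.
Region modulation (a different transition matrix and a $D$ scale factor
inside $|s - u| \le 15$ µm) is evaluated at the particle's true position
before each step and recorded per step in the ground truth.

**Study-condition defaults.** The control configuration is a two-state
vesicle model ($D = 0.1$ µm²/s diffusive; $D = 0.05$ µm²/s with
$|V| = 1$ µm/s transport; balanced switching 0.02/frame), spatially
uniform. The stimulated configuration applies, inside the 30 µm region,
a threefold-raised transport-to-diffusion probability (0.06), a
suppressed diffusion-to-transport probability (0.005) and a $D$ scale of
0.4. The paper-scale gates motivate the fixed category parameters of
`simulate_experiment()`: surface receptors $D = 0.6$ µm²/s with
tetramer bleaching, PSD-trapped receptors $D = 0.005$ µm²/s,
spine-localized particles confined to a spine polygon. Effect sizes for
stimulation are not published as numbers anywhere, so these defaults were
chosen once to be unambiguous at desk-scale cohort sizes (100
trajectories per condition) and are not revisited; they set the
*direction* of every contrast the pipeline must recover, not its
magnitude.

**Bleaching.** Each fluorophore survives a geometric number of frames at
per-frame probability `p_bleach` (default 0.04); a surface particle
carries 4 fluorophores (a labelled receptor homotetramer), so its
complete-bleach time is the maximum of 4 geometrics — about 93% bleach
completely within 100 frames at the default, which is the basis of the
100-frame vesicle-identification filter. Vesicle-like particles are
treated as carrying an effectively inexhaustible dye pool (many receptors
per vesicle) and never fully bleach.

**Rendering.** `render_movie()` integrates each emitter's Gaussian PSF
over pixels (160 nm default pixel, PSF $\sigma$ 160 nm), adds a flat
background, and applies Poisson shot noise, camera gain, offset and
Gaussian read noise. The renderer and the detector's fit model use the
same pixel-integrated PSF, so noiseless movies reconstruct exactly.

**What the generator does not emulate.** Real dendrites have varying
shaft width, out-of-focus light, vesicles leaving the focal plane,
heterogeneous background, motor pausing substructure, and photophysics
beyond bleaching (blinking is absent except as a test construction).
Passing tests demonstrate the analysis chain is correct and well
calibrated under the stated model — not that the model captures every
property of real recordings.

## Detection and tracking

`detect_particles()` runs a matched-filter generalized-likelihood-ratio
test of a Gaussian peak against a locally flat background in a sliding
window, thresholded at the configured per-pixel false-alarm probability
(default $10^{-6}$, the "localisation error" convention of
multiple-target-tracing software). Accepted candidates are refined by
least-squares pixel-integrated 2D Gaussian fits (PSF width bounded to
±15% of the configured guess). Deflation (default 3 loops) subtracts
fitted spots, re-detects on the residual, and additionally attempts to
split each spot into two emitters with a Poisson-weighted two-emitter fit
accepted by an F-test at the same false-alarm probability; this recovers
pairs down to ~1.5 PSF $\sigma$ separation at adequate SNR, at the cost
of a small (~3% per bright spot) false-split rate at shot-noise-limited
SNR — noiseless data are unaffected.

`link_trajectories()` performs frame-by-frame greedy assignment with the
gating radius $r_{max} = \sqrt{4 D_{max} \Delta t\,(gap+1)}$
($D_{max} = 1$ µm²/s for receptor-scale particles, 3 µm²/s for
rheological probes), scoring up to `max_competitors` hypotheses per
localisation by displacement likelihood plus relative intensity change.
Ties break by smaller displacement then lower track id, so linking is
deterministic and invariant to input row order. Gap closing bridges up to
2 missed frames. $D_{max}$ bounds linking only; it does not filter
outputs. Manual track curation is replaced by `filter_tracks()` (minimum
10 steps).

## Vesicle identification

`classify_particle()` applies the filters in a fixed order: spine
majority (> 0.5 of points inside a spine polygon) → active transport (any
selected `DV` state faster than 0.1 µm/s → vesicle) → complete bleach
within 100 frames (diffusion-only particles only → excluded as surface) →
$D > 0.45$ µm²/s → surface; $D < 0.02$ µm²/s → PSD-trapped; otherwise
vesicle. The gated $D$ is the diffusive-state coefficient (the `D`-kind
state with the largest decoded occupancy), not a transport state's $D$,
because the gates are applied after the transport branch. "Bleached
completely" is operationalised as intensity staying within 2 SD of
background for all remaining frames (a single-frame dip that recovers is
blinking, not bleaching); the 2 SD band is a package choice.

## Spatial statistics

`project_to_path()` projects points segment-wise onto the centerline
(ties toward smaller arc length). Trajectory-level zone/region assignment
uses the projection of the trajectory centroid by default (`stepwise`
majority voting is available) — the assignment rule is a package choice
and is configurable.

The **radius of confinement** is the maximum distance from the trajectory
centroid to any of its points. The **directional-bias angle** $\theta$ is
the unsigned angle between the line from the centroid (CM) to its nearest
centerline point and the line from the CM to the trajectory point
farthest from the CM: $\theta = \arccos\lvert u \cdot v\rvert \in
[0°, 90°]$, with 90° = longitudinal and 0° = lateral motion. The unsigned
(line–line, not ray–ray) reading is used because the two stated endpoint
behaviours only span [0°, 90°]; ties for the farthest point break toward
the earliest time, and a centroid lying on the centerline (within 1 nm)
uses the local normal as reference direction, which is the continuity
limit of the off-axis definition.

**Photobleach-adjusted counts** multiply a post-stimulation count by the
fold loss observed in no-stimulation controls
(`n_pre_control / n_post_control`). **Exocytosis detection** finds sudden
persistent local intensity appearances: per-pixel frame differences
thresholded at $k = 6$ pooled MADs (floored at the global MAD), required
to start from the pixel's temporal-median baseline and stay elevated for
≥ 2 frames, clustered in space–time, and localised by a Gaussian fit of
the onset difference image; the rate is events per µm of dendrite per
minute. **Pre-exocytosis linkage** labels a trajectory when its terminal
position lies within 0.32 µm (2 pixels) and within 10 frames before an
event onset — defaults chosen as 2 pixels / 0.5 s because no published
values exist — and strips the terminal decoded immobile segment
($D < 0.01$ µm²/s) before re-summarising motion, since docking precedes
exocytosis and would otherwise dominate the motion summary.

## Actin quantification

The filament pipeline mirrors common live-reporter practice: background
subtraction (grayscale opening, default radius 12 px ≈ 2 µm at Airyscan
sampling), a 1 px minimum filter, spine masking, Otsu thresholding (256
bins, between-class-variance maximisation — for well-separated modes the
variance curve has a flat plateau, so any threshold on the plateau is
equivalent), Zhang–Suen thinning to a 1 px skeleton, pruning of spur
branches shorter than 3 px (configurable; the usual skeleton-analysis
convention), and length as $\sum$ (1 per 4-neighbour pair, $\sqrt 2$ per
diagonal pair) × pixel size, with diagonal pairs that share an orthogonal
skeleton neighbour skipped so L-turns are not double-counted. The
(1, $\sqrt 2$) step weighting is the field convention but carries a known
slope-dependent digitisation bias for smooth oblique curves (up to ~8.5%
near slope 0.414, vanishing for axis-aligned and exactly diagonal
strokes); length comparisons against analytic arc lengths are therefore
accurate to a few percent only for curves dominated by gentle or
near-diagonal slopes, which is the regime the tests probe. Fixed-sample images use Intermodes
thresholding (iterative histogram smoothing to bimodality, midpoint of
the two modes) for spine masking and report the shaft mean fluorescence
intensity instead of a skeleton, matching the lower SNR of such data.

## Reporting layer

`knockin_efficiency()` implements the count formula
$\mathrm{KI} = n_{tag+} / ((n_{marker+}/n_{total})^2\, n_{total})$ — the
squared marker rate extrapolates the co-transfection rate when only one
construct carries a marker. `linearized_nt_for_distance()` converts a
physical distance to nucleotides at 0.34 nm rise, truncating (0.5 µm →
1470 nt; rounding would give 1471, so truncation is the convention that
reproduces the printed value). `kde_density()` uses the Sheather–Jones
plug-in bandwidth (Silverman fallback, rule recorded in the output).
`compare_distributions()` wraps the two-sample Kolmogorov–Smirnov,
Mann–Whitney and Wilcoxon matched-pairs tests, flagging degenerate
paired input.

## Problem sizes used in the tests

The statistical tests run at desk scale, chosen once: MSD closed-form
checks on 1000 trajectories × 200 steps (lags ≤ 10); single-state
recovery on 100 seeds × 1000 steps; two-state recovery on 25 seeds
(states $D = 0.02$ µm²/s vs $D = 0.02$, $|V| = 1.2$ µm/s, mean dwell 50
frames — per-step drift ≈ 1.2 step-SD, which is the separation regime the
selection criterion is reliable in); transition recovery on 10⁴ decoded
steps; classification on a 200-particle cohort; and the
stimulated-versus-control pipeline on 100 trajectories of 150 frames per
condition. Bands follow binomial or empirical 3 SE except where a
tolerance is stated directly.

## Known limitations

- The HMM assumes a constant velocity vector within a state; curved
  transport runs and heading reversals are represented by extra states
  (up to the K ≤ 3 cap), not by rotating drift.
- Decoded-path transition rates inherit the Viterbi dwell bias described
  above; for fast switching, use the EM-estimated transition matrix
  (`$trans`) rather than decoded counts.
- The overlap-splitting F-test assumes locally Gaussian noise after
  Poisson weighting; at very low SNR it stops splitting before detection
  stops detecting.
- `detect_exocytosis()` requires appearances to start near the pixel's
  temporal median; an exocytic burst on top of an already-docked bright
  vesicle in the same pixel is attenuated by design (the pre-onset
  baseline condition).
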