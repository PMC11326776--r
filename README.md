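# dendritespt

Single-particle tracking and spatial analysis of vesicle traffic in
neuronal dendrites.

## What this package is for

AMPA-type glutamate receptors are carried through dendrites in vesicles and
inserted into the membrane by exocytosis. Live-cell imaging of labelled
receptor subunits produces single-particle trajectories whose motion —
Brownian diffusion interrupted by bouts of motor-driven directed transport
— changes when synaptic plasticity is induced: vesicles near the stimulated
site become confined, concentrate locally, and feed local exocytosis.
`dendritespt` implements the full analysis machinery needed to quantify
this behaviour, together with a synthetic-data generator so that every
stage can be exercised and validated without experimental data:

- **Synthetic data** (`simulate_dendrite`, `sim_config`,
  `simulate_trajectory`, `simulate_bleaching`, `simulate_experiment`,
  `render_movie`, `simulate_hmm_steps`, `simulate_filament_image`):
  dendrite geometries with spines and an uncaging site, Markov-switching
  vesicle motion with stimulation-dependent spatial modulation, tetrameric
  stochastic photobleaching, exocytosis events with docked pre-exocytosis
  tails, and rendered 16-bit fluorescence movies with Poisson/read noise —
  all with full ground truth.
- **Detection and tracking** (`detect_particles`, `detect_movie`,
  `link_trajectories`): GLRT spot detection at a configured per-pixel
  false-alarm probability, sub-pixel localisation by pixel-integrated 2D
  Gaussian fitting, deflation with two-emitter splitting to recover
  overlapping particles, and multi-target linking gated by
  `r_max = sqrt(4 D_max dt (gap+1))`.
- **Motion models** (`fit_hmm`, `compute_msd`, `fit_msd_model`,
  `fit_anomalous_exponent`, `transition_rates`, `classify_motion_type`,
  `segment_and_refit`): per-trajectory hidden Markov motion-state
  inference over diffusive (D) and directed-transport (D+V) states with
  BIC model selection (K ≤ 3), validated against the mean-squared
  displacement model `<r²> = 4 D Δt + (V Δt)²`.
- **Vesicle identification** (`spine_fraction`,
  `bleach_frame_from_intensity`, `classify_particle`, `classify_cohort`):
  the sequential filters separating intracellular vesicles from surface
  receptors (D > 0.45 µm²/s or complete tetramer bleaching within 100
  frames), PSD-trapped receptors (D < 0.02 µm²/s), and spine-localized
  particles.
- **Dendrite-referenced spatial statistics** (`project_to_path`,
  `assign_zone`, `assign_region`, `radius_of_confinement`,
  `directional_bias_theta`, `adjust_counts`, `detect_exocytosis`,
  `link_pre_exocytosis`, `analyze_cohort`): arc-length projection, the
  three equal proximity zones and the 30 µm IN region around the uncaging
  site, the confinement radius (max centroid-to-point distance), the
  directional-bias angle θ (90° = longitudinal, 0° = lateral), the
  photobleach fold-loss count adjustment, and exocytosis event detection
  with pre-exocytosis trajectory linkage.
- **Actin-filament quantification** (`preprocess_tractin`,
  `threshold_mask`, `skeletonize_and_measure`, `shaft_mfi`): background
  subtraction and minimum filtering, Otsu/Intermodes thresholding,
  skeletonisation with 4-/8-neighbour step-weighted length, and shaft
  mean fluorescence intensity.
- **Reporting statistics** (`knockin_efficiency`,
  `linearized_nt_for_distance`, `peak_separation`, `kde_density`,
  `compare_distributions`): the knock-in efficiency count formula, the
  0.34 nm/nt distance-to-nucleotide conversion, line-profile peak
  separation, kernel density summaries, and the standard two-sample tests.

## Worked example

```r
library(dendritespt)

# a 90 um dendrite, uncaging site at its midpoint
dend <- simulate_dendrite(90, n_spines = 0, uncaging_fraction = 0.5, seed = 1)

# control vs stimulated experiment: inside the 30 um region flanking the
# uncaging site the stimulated config suppresses transport and scales D
ex <- simulate_experiment(sim_config_control(), sim_config_stimulated(),
                          dend, n_particles = 100, n_frames = 150, seed = 7)
stim <- subset(ex$trajectories, condition == "stimulated")
res  <- analyze_cohort(stim, dend)

tapply(res$motion_type == "active_transport", res$region, mean)
#>        IN       OUT
#> 0.0750000 0.4166667

wilcox.test(res$d_diffusive_um2_s[res$region == "IN"],
            res$d_diffusive_um2_s[res$region == "OUT"],
            alternative = "less")$p.value
#> [1] 4.708269e-24
```

Only 7.5% of trajectories inside the stimulated region exhibit active
transport versus 42% outside, and the diffusion coefficients inside are
stochastically smaller — the motion signature of local vesicle confinement
recovered end-to-end from raw trajectories by the HMM, the vesicle
filters and the dendrite-referenced spatial assignment.

The directional-bias angle behaves as designed at its endpoints:

```r
long <- data.frame(trajectory_id = 1, frame = 1:9, t_s = (0:8) * 0.05,
                   x_um = seq(0, 4, length.out = 9), y_um = 1,
                   intensity = 1000, channel = "demo")
directional_bias_theta(long, dend)$theta_deg
#> [1] 90
```

## Vignette

`vignettes/dendritespt-methods.Rmd` describes the motion model and its
assumptions, every tunable parameter with units and defaults, what the
synthetic data do and do not emulate, and the numerical choices made
throughout.
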