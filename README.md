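# kymoclear

Quantification of motor-driven protein clearance on single-molecule DNA
curtains.

In a DNA-curtain experiment, many long ssDNA molecules are tethered side by
side in a flowcell and imaged by TIRF microscopy. Each molecule is coated
with a fluorescent ssDNA-binding protein (RPA-GFP, or an unlabelled RAD51
filament reported by RPA-GFP influx), and a translocating motor protein —
here the SF2 helicase domain of DNA polymerase θ, a 3′→5′ ssDNA motor —
strips the coating as it moves. The growing protein-free gap appears as a
spreading punctum in a kymograph (position along the DNA versus time).
`kymoclear` turns those image stacks into per-motor biophysical numbers and
population statistics:

* **Clearance-front fitting** — per frame, the 3-px molecule band is summed
  into a profile, background-subtracted, and fit with a Gaussian or
  two-edge step (Heaviside) model; the FWHM, converted through a
  model-based PSF calibration, measures the cleared extent in nucleotides.
* **Velocity and processivity** — a flat–rising–flat changepoint model of
  extent versus time gives the rise slope *v* (nt/s) and terminal plateau
  *P* (knt) per motor, with explicit handling of sub-resolution gaps,
  resolution-limited (sub-frame) rises, and right-censored motors still
  running at the movie end. Populations are summarized as median and IQR.
* **Polarity** — which gap edge moves (barrier side = 5′) classifies each
  event as 3′→5′, 5′→3′, or ambiguous.
* **Foci and intensity** — diffraction-limited puncta counting per unit
  length (5 robust-σ threshold), normalized total-intensity time traces
  (mean ± SEM across molecules), 3×3-pixel focus brightness, and
  Kaplan–Meier lifetimes of DNA bridges after a challenge.
* **Particle tracking** — nearest-neighbour linking of foci into
  trajectories and position-versus-time velocities.
* **Ensemble binding** — one-site hyperbolic fits
  f = B·[P]/(K_d+[P]) to gel-shift titrations (SEM-weighted, with an
  honest "K_d > bound" report when the titration cannot constrain K_d from
  above) and normalized dissociation time courses with k_off.
* **Simulator** — a forward model (log-normal motor populations, Gaussian
  PSF, Poisson + Gaussian camera noise, photobleaching) that renders
  ground-truth-annotated TIFF stacks and synthetic titrations, so every
  stage of the pipeline is testable without raw microscopy data.

## Worked example

Simulate one field of motors drawn from a population with median velocity
63 nt/s (IQR 28–117) and median processivity 3.9 knt (IQR 2.7–5.1), run
the full pipeline, and summarize:

```r
library(kymoclear)

cfg <- sim_config(n_frames = 60)                      # 25 knt / 13 um, 15 s frames
pop <- motor_population(63, c(28, 117), 3.9, c(2.7, 5.1), n_motors = 12)
motors <- sample_motors(pop, cfg, seed = 7)

events <- do.call(rbind, lapply(seq_len(nrow(motors)), function(i) {
  stk <- render_kymograph(motors[i, ], cfg, seed = 7000 + i)
  motor_event(build_trace(stk), molecule_id = paste0("mol", i))
}))
population_summary(events, "velocity")
#>   condition statistic   median       q1       q3  n units
#> 1      <NA>  velocity 66.12623 38.96759 141.5311 11  nt/s
population_summary(events, "processivity")
#>   condition    statistic   median       q1      q3  n units
#> 1      <NA> processivity 4.068826 3.003019 5.86866 11   knt
```

The recovered medians (66.1 nt/s, 4.07 knt here; one of the twelve traces
is dropped as unusable) sit within a few percent of the configured
population values; at N = 12 the remaining spread is dominated by
per-event measurement noise. `run_pipeline()` wraps the same
chain behind a config list and writes traces, events, summaries and a
manifest to an output directory; `fit_titration()` /
`dissociation_timecourse()` cover the ensemble binding side.

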