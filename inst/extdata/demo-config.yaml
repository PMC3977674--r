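# Demo configuration for the froa pipeline.
# Two task groups scan the same synthetic multi-part stimuli: the
# "basic" group with short saccades and the "subordinate" group with
# long saccades (means as in the motivating eye-movement study), plus a
# mixture preference toward the concave ROI for both.
geometry:
  frame_px: 800
  frame_deg: 18.0

shape_models:
  smoothing_sigma: 5
  kappa_min: 0.005
  r_min: 2
  r_max: 20
  kappa_sat: 0.1
  prominence: 0.005
  band_px: 10

froa:
  region_radius_deg: 1.0
  n_iterations: 300
  null_density: uniform_object
  ci: one_sided

stats:
  bonferroni: false
  welch: false

experiment:
  n_trials: 4
  stimuli: [dumbbell, chain3, barbell]
  groups:
    basic:
      n_participants: 6
      n_fixations: 12
      roi_preference: 0.6
    subordinate:
      n_participants: 6
      n_fixations: 12
      roi_preference: 0.6

seed: 20260925
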