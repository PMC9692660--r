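# Example experiment configuration for the periofuse CLI.
# periofuse run --config example-config.yaml --seed 1 --out results/
cohort:
  n_subjects: 24
  gender_ratio: 0.65
  n_stimuli: 6
  session_duration_s: 10
  pupil_age_slope: 0.4
  pupil_subject_sd: 0.6
  seed: 42
experiment:
  task: age
  with_concatenation: true
  families: [decision_tree, random_forest, knn, svm]
  k_range: [2, 3]
  select_threshold: 0.5
  sizes: [2]
  seed: 42
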