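seed: 42
language: de
cohort:
  n_records: 8000
  insertion_fraction: 0.9537118
  male_fraction: 0.545
  age_distribution:
    mean: 84.259
    sd: 41.288
    min: 18.0
    max: 101.0
  outcome_model:
    intercept: -1.7971444
    beta_age: -0.011809
    beta_gender: 0.200964
  size_distribution:
    mean: 40.0
    sd: 25.0
    min: 2.0
    max: 140.0
  hours_range:
  - 0.0
  - 12.0
lexicon:
  misspelling_rate: 0.1
  negation_distractor_rate: 0.3
  contraindication_rate: 0.05
  abbreviation_rate: 0.3
  include_size_sentence: yes
features:
  ngram_order: 2
  prune_fraction: 0.01
  prune_mode: doc_freq
  use_stopwords: yes
smote:
  enabled: yes
  k_neighbors: 5
  target_ratio: 1.0
forest:
  n_trees: 250
  mtry: 2
  vote_threshold: 0.5
split:
  ratio: 0.8
stats:
  continuity_correction: yes
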