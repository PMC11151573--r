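# Demo audit: a synthetic 10-practice cohort of 5,000 patients.
seed: 7
synthetic:
  n_practices: 10
  patients_per_practice: 500
window:
  start: 2021-01-01
  end: 2022-12-31
dictionary: null
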