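n_households: 387
seed: 20180615
income_lognormal:
  meanlog: 8.667
  sdlog: 0.592
engel:
  baseline: 0.42
  elasticity: 0.08
  noise_sd: 0.08
household_size_probs:
- 0.09
- 0.16
- 0.22
- 0.22
- 0.15
- 0.08
- 0.04
- 0.02
- 0.01
- 0.01
diagnosis_probs:
  schizophrenia: 0.3
  hyperactive: 0.25
  anxiety: 0.15
  other: 0.3
patient_male_prob: 0.74
patient_employed_prob: 0.25
caregiver_female_prob: 0.86
single_prob: 0.928
oop_model:
  oop_consultation:
    p0: 0.9
    meanlog: 5.5214609
    sdlog: 0.7
    prob_loadings: []
    mean_loadings:
      missed_work_days: 0.04
  oop_hospitalization:
    p0: 0.18
    meanlog: 7.824046
    sdlog: 0.9
    prob_loadings:
      male: 0.5
      employed: -0.6
      schizophrenia: 0.8
      anxiety: -1.5
      missed_work_days: 0.08
    mean_loadings:
      male: 0.3
  oop_medicines:
    p0: 0.95
    meanlog: 6.8023948
    sdlog: 0.8
    prob_loadings:
      anxiety: -1.0
    mean_loadings:
      male: 0.3
      schizophrenia: 0.5
      anxiety: -0.8
      household_size: 0.05
  oop_diagnostics:
    p0: 0.45
    meanlog: 6.2146081
    sdlog: 0.8
    prob_loadings:
      schizophrenia: 0.3
    mean_loadings: []
  oop_transport:
    p0: 0.92
    meanlog: 5.2983174
    sdlog: 0.6
    prob_loadings: []
    mean_loadings:
      missed_work_days: 0.03
oop_scale: 1.0
target_incidence: 0.348
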