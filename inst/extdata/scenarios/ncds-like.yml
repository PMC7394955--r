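cohort_id: ncds-like
wave_labels:
- '33'
- '42'
- '50'
mediator_var: inactive
exposure_var: obese
gender_var: male
baseline:
  male: 0.48
  low_social_class: 0.3
  smoker_early: 0.35
  poor_mental_health: 0.15
confounders:
  smoker:
  - (Intercept): -2.1
    smoker_early: 2.8
    low_social_class: 0.4
  - (Intercept): -2.8
    smoker_w1: 3.6
    smoker_early: 0.8
    low_social_class: 0.2
  - (Intercept): -3.0
    smoker_w2: 3.6
    smoker_early: 0.8
    low_social_class: 0.2
  depressed:
  - (Intercept): -2.3
    poor_mental_health: 1.6
    low_social_class: 0.3
    male: -0.3
  - (Intercept): -2.4
    depressed_w1: 1.8
    poor_mental_health: 1.0
    obese_w1: 0.3
    male: -0.3
  - (Intercept): -2.4
    depressed_w2: 1.8
    poor_mental_health: 1.0
    obese_w2: 0.3
    male: -0.3
  poor_srh:
  - (Intercept): -2.2
    poor_mental_health: 1.0
    low_social_class: 0.4
  - (Intercept): -2.3
    poor_srh_w1: 1.8
    obese_w1: 0.4
    poor_mental_health: 0.6
  - (Intercept): -2.3
    poor_srh_w2: 1.8
    obese_w2: 0.4
    poor_mental_health: 0.6
mediator:
- (Intercept): -1.146444271462
  low_social_class: 0.4
  poor_mental_health: 0.3
  depressed_w1: 0.3
  smoker_w1: 0.2
- (Intercept): -1.313771069005
  inactive_w1: 1.4
  obese_w1: 0.5
  depressed_w2: 0.3
  low_social_class: 0.2
- (Intercept): -1.62857621035
  inactive_w2: 1.5
  obese_w2: 0.5
  depressed_w3: 0.3
  low_social_class: 0.2
exposure:
- (Intercept): -2.386414523664
  low_social_class: 0.4
  inactive_w1: 0.5
- (Intercept): -3.170303327082
  obese_w1: 6.0
  inactive_w2: 0.4
  low_social_class: 0.3
- (Intercept): -2.446145406906
  obese_w2: 6.0
  inactive_w3: 0.4
  low_social_class: 0.3
outcome:
  (Intercept): -3.2
  obese_w1: 0.2
  obese_w2: 0.15
  obese_w3: 0.2
  inactive_w3: 0.8
  inactive_w2: 0.2
  inactive_w1: 0.1
  poor_srh_w3: 0.6
  depressed_w3: 0.4
  smoker_w3: 0.3
  low_social_class: 0.3
  poor_mental_health: 0.2
score:
  coef:
    (Intercept): 66.0
    male: 4.0
    obese_w1: -1.5
    obese_w2: -1.5
    obese_w3: -1.5
    inactive_w3: -5.0
    inactive_w2: -2.0
    poor_srh_w3: -4.0
    depressed_w3: -3.0
    smoker_w3: -2.0
    low_social_class: -2.0
    poor_mental_health: -2.0
  sd: 8.0
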