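cohort_id: null-mediation
wave_labels:
- '1'
- '2'
mediator_var: inactive
exposure_var: obese
gender_var: male
baseline:
  male: 0.5
  low_social_class: 0.3
confounders:
  smoker:
  - (Intercept): -0.8
    low_social_class: 0.5
  - (Intercept): -1.5
    smoker_w1: 2.2
    low_social_class: 0.3
mediator:
- (Intercept): -0.7
  smoker_w1: 0.4
  low_social_class: 0.4
  male: -0.3
- (Intercept): -1.2
  inactive_w1: 1.6
  smoker_w2: 0.4
  male: -0.3
exposure:
- (Intercept): -1.1
  low_social_class: 0.3
  inactive_w1: 0.3
- (Intercept): -2.0
  obese_w1: 4.5
  inactive_w2: 0.3
outcome:
  (Intercept): -1.0
  inactive_w2: 0.5
  inactive_w1: 0.2
  smoker_w2: 0.4
  low_social_class: 0.3
  male: -0.2
score: ~
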