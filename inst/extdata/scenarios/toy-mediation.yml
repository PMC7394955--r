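cohort_id: toy-mediation
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
    obese_w1: 0.3
    low_social_class: 0.3
mediator:
- (Intercept): -0.6
  smoker_w1: 0.4
  male: -0.3
- (Intercept): -1.1
  inactive_w1: 1.4
  obese_w1: 0.8
  smoker_w2: 0.3
  male: -0.3
exposure:
- (Intercept): -1.0
  inactive_w1: 0.4
  low_social_class: 0.3
- (Intercept): -1.8
  obese_w1: 4.5
  inactive_w2: 0.4
outcome:
  (Intercept): -1.6
  obese_w1: 0.7
  obese_w2: 0.5
  inactive_w2: 0.9
  inactive_w1: 0.4
  smoker_w2: 0.3
  low_social_class: 0.3
  male: -0.2
score: ~
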