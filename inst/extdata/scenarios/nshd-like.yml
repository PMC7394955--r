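cohort_id: nshd-like
wave_labels:
- '36'
- '43'
- '53'
- 60-64
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
  - (Intercept): -2.2
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
  - (Intercept): -3.2
    smoker_w3: 3.6
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
  - (Intercept): -2.4
    depressed_w3: 1.8
    poor_mental_health: 1.0
    obese_w3: 0.3
    male: -0.3
mediator:
- (Intercept): -0.686555334777
  male: -0.5
  low_social_class: 0.4
  poor_mental_health: 0.4
  depressed_w1: 0.3
  smoker_w1: 0.2
- (Intercept): -0.462041263782
  inactive_w1: 1.3
  male: -0.35
  obese_w1: 0.5
  depressed_w2: 0.3
  low_social_class: 0.2
- (Intercept): -1.060415807401
  inactive_w2: 1.4
  male: -0.15
  obese_w2: 0.5
  depressed_w3: 0.3
  low_social_class: 0.2
- (Intercept): -0.261418523385
  inactive_w3: 1.3
  obese_w3: 0.4
  depressed_w4: 0.3
  low_social_class: 0.2
exposure:
- (Intercept): -3.136680275642
  male: -0.15
  low_social_class: 0.4
  inactive_w1: 0.5
- (Intercept): -2.883202381943
  obese_w1: 6.0
  inactive_w2: 0.4
  low_social_class: 0.3
- (Intercept): -2.078194427685
  obese_w2: 6.0
  inactive_w3: 0.4
  low_social_class: 0.3
- (Intercept): -2.80692126862
  obese_w3: 6.0
  inactive_w4: 0.4
  low_social_class: 0.3
outcome:
  (Intercept): -3.3
  obese_w1: 0.35
  obese_w2: 0.2
  obese_w3: 0.2
  obese_w4: 0.3
  inactive_w4: 0.7
  inactive_w3: 0.25
  inactive_w2: 0.1
  inactive_w1: 0.1
  depressed_w4: 0.5
  smoker_w4: 0.4
  low_social_class: 0.3
  poor_mental_health: 0.3
  male: -0.1
score:
  coef:
    (Intercept): 55.0
    obese_w1: -2.0
    obese_w2: -1.5
    obese_w3: -1.5
    obese_w4: -2.5
    inactive_w4: -5.0
    inactive_w3: -2.0
    depressed_w4: -3.0
    smoker_w4: -2.0
    low_social_class: -2.0
    poor_mental_health: -2.0
    male: 2.0
  sd: 8.0
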