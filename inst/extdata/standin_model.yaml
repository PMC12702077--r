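# Synthetic stand-in SGLT2i-DPP4i treatment selection model.
# NOT a published or fitted model: coefficients are invented with clinically
# plausible signs, for simulation ground truth and examples only.
intercept: 10.4
terms:
- feature: baseline_hba1c
  basis: 1
  coef: 0.62
- feature: baseline_hba1c
  basis: 2
  coef: 1.5
- feature: age
  basis: 1
  coef: -0.06
- feature: bmi
  basis: 1
  coef: 0.08
- feature: egfr
  basis: 1
  coef: -0.025
- feature: egfr
  basis: 2
  coef: 0.8
- feature: log_alt
  basis: 1
  coef: 1.1
drug_main: 19.800000000000001
drug_interactions:
- feature: baseline_hba1c
  basis: 1
  coef: -0.15
- feature: bmi
  basis: 1
  coef: -0.25
- feature: bmi
  basis: 2
  coef: -0.5
- feature: egfr
  basis: 1
  coef: -0.12
- feature: age
  basis: 1
  coef: 0.12
knots:
  baseline_hba1c:
  - 57.0
  - 72.0
  - 92.0
  age:
  - 46.0
  - 61.0
  - 75.0
  bmi:
  - 25.0
  - 32.0
  - 41.0
  egfr:
  - 68.0
  - 91.0
  - 112.0
  log_alt:
  - 2.7
  - 3.3
  - 4.0
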