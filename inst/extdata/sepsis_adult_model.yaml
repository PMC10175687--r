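# Final adult-sepsis teicoplanin population model (2-compartment IV infusion).
# Typical values in L/h and L; omega2 are log-normal IIV variances;
# sigma2_prop is the proportional residual variance (SD 17.4%).
theta:
  CL: 1.03
  V1: 20.1
  Q: 3.12
  V2: 101.0
covariate_effects:
- parameter: CL
  covariate: GFR
  beta: 0.437
  type: power
  reference: 71.88
omega2:
  CL: 0.29
  V1: 0.37
  Q: 0.29
  V2: 0.10
sigma2_prop: 0.030276
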