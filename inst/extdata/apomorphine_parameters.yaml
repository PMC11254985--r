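# Population typical values for on-demand apomorphine, as estimated in the
# source population analyses of each formulation.
#
# Units: cl (CL/F) L/h; v (V/F) L; ka, k12, k21, ke0 1/h; f fraction;
# ec50 ng/mL; b0, mcic UPDRS Part III points; emax fraction; g dimensionless.
sc:
  pk:
    cl: 191.0
    v: 153.0
    ka: 14.9
    f: 1.0
sl:
  pk:
    cl: 80.7
    v: 438.0
    ka: 6.58
    k12: 0.613
    k21: 0.0048
    f: 0.206
pd:
  ke0: 5.36
  ec50: 10.7
  b0: 24.3
  emax: 1.0
  g: 3.0
  mcic: 3.25
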