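name: M1
structure: parent_milk
typical:
  cl_parent: 8.42
  v_parent: 690.0
  ka: 0.3
  cl_metab: ~
  v_metab: ~
  fm: 1.0
  mpr: 0.59
fixed:
- ka
covariates: []
iiv:
  cl_parent: 0.38
  mpr: 0.32
ruv:
  parent:
    prop: 0.08
    add: 0.0
covariate_defaults: []

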