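name: M2
structure: parent
typical:
  cl_parent: 0.181
  v_parent: 37.4
  ka: 0.666
  cl_metab: ~
  v_metab: ~
  fm: 1.0
  mpr: ~
fixed:
- ka
covariates:
- parameter: cl_parent
  covariate: WT
  form: linear
  theta: 1.0
- parameter: v_parent
  covariate: WT
  form: linear
  theta: 1.0
iiv:
  cl_parent: 0.52
  v_parent: 0.205
ruv:
  parent:
    prop: 0.18
    add: 0.0
covariate_defaults:
  WT: 53.6

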