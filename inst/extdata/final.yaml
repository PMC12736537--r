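name: FINAL
structure: parent_metabolite
typical:
  cl_parent: 2.91
  v_parent: 24.9
  ka: 0.3
  cl_metab: 3.24
  v_metab: 1.52
  fm: 1.0
  mpr: ~
fixed:
- ka
- fm
covariates:
- parameter: cl_parent
  covariate: SEX
  form: fractional
  theta: 0.165
iiv:
  cl_parent: 0.316
  cl_metab: 0.209
ruv:
  parent:
    prop: 0.341
    add: 14.9
  metabolite:
    prop: 0.305
    add: 22.9
covariate_defaults:
  SEX: 0.0

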