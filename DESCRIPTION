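Package: fluoxpk
Title: Joint Population Pharmacokinetics of Fluoxetine and Norfluoxetine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for population-pharmacokinetic analysis of fluoxetine and its
    active metabolite norfluoxetine from trough-only therapeutic drug monitoring
    data. Provides closed-form one-compartment and parent-metabolite catenary
    concentration models with a numerical ODE fallback, a repository of published
    fluoxetine PopPK models including a joint parent-metabolite model with a sex
    effect on clearance, NONMEM-style dataset input and output, a synthetic
    trough-only cohort generator, MAP Bayesian and FOCE-type mixed-effects
    estimation with stepwise covariate selection and bootstrap,
    external-evaluation diagnostics (prediction errors, NPDE, CWRES, VPC), and
    Monte Carlo dose-regimen simulation reporting probability of target
    attainment against the 120-500 ng/mL active-moiety trough window.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    graphics,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
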