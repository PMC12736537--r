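# Shared fixtures built in code.

# Day-30 trough values for the joint model's typical female subject on
# 60 mg QD, computed up front by independent numerical integration of the
# depot -> parent -> metabolite system (deSolve, rtol/atol 1e-12, 30 dose
# events) and frozen here.
ORACLE_F60 <- c(parent = 251.3245, metab = 238.5402, active = 489.8647)
ORACLE_M60_ACTIVE <- 362.741

final_params <- function(sex = 0) {
  individual_parameters(builtin_model("FINAL"), covariates = list(SEX = sex))
}

# single-subject record: one steady-state QD dose, troughs at 24h intervals
make_subject <- function(id = 1, dose = 40, obs, sex = 0, age = 25, wt = 59,
                         ii = 24) {
  list(id = id,
       doses = data.frame(time = 0, amt = dose, ii = ii, ss = TRUE, addl = 0),
       obs = obs,
       covariates = list(SEX = sex, AGE = age, WT = wt))
}

trough_obs <- function(values, analytes, times = NULL) {
  if (is.null(times)) times <- rep(24, length(values))
  data.frame(time = times, analyte = analytes, dv = values,
             blq = logical(length(values)))
}

# independent reimplementation of the per-subject MAP objective from its
# definition, for use as a brute-force oracle
map_objective_oracle <- function(model, subject, eta) {
  p <- individual_parameters(model, subject$covariates, eta)
  reg <- dosing_regimen(subject$doses$amt[1], subject$doses$ii[1])
  obj <- 0
  for (j in seq_len(nrow(subject$obs))) {
    f <- if (subject$obs$analyte[j] == "parent") {
      parent_conc(p, reg, subject$obs$time[j] %% reg$interval +
                  ifelse(subject$obs$time[j] %% reg$interval == 0, reg$interval, 0))
    } else {
      metabolite_conc(p, reg, subject$obs$time[j] %% reg$interval +
                      ifelse(subject$obs$time[j] %% reg$interval == 0, reg$interval, 0))
    }
    ruv <- model$ruv[[subject$obs$analyte[j]]]
    g <- (ruv[["prop"]] * f)^2 + ruv[["add"]]^2
    obj <- obj + (subject$obs$dv[j] - f)^2 / g + log(g)
  }
  om <- unlist(model$iiv)
  for (k in names(eta)) obj <- obj + eta[[k]]^2 / om[[k]]^2
  obj
}
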