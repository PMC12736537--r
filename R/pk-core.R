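# Structural pharmacokinetics: one-compartment oral absorption for the parent
# drug and the catenary depot -> parent -> metabolite extension. Closed forms
# are used everywhere; a numerical ODE path (deSolve) serves as fallback when
# rate constants collide and as an independent oracle.
#
# Unit conventions: doses in mg, volumes in L, clearances in L/h. Amounts are
# propagated in mg and concentrations in mg/L internally; every value returned
# to the caller is converted to ng/mL (x 1000).

#' Pharmacokinetic parameter set
#'
#' Bundles the apparent (oral) parameters of the joint fluoxetine ->
#' norfluoxetine model: parent clearance and volume, first-order absorption
#' rate, metabolite clearance and volume, the fraction of parent converted to
#' metabolite, and optionally a milk-to-plasma ratio. Bioavailability is not
#' separable from trough-only oral data, so all clearances and volumes are
#' apparent (CL/F, V/F) and F is implicitly 1.
#'
#' @param cl_parent Apparent parent clearance CL/F, L/h.
#' @param v_parent Apparent parent central volume V/F, L.
#' @param ka First-order absorption rate constant, 1/h.
#' @param cl_metab Apparent metabolite clearance, L/h (`NA` for parent-only
#'   models).
#' @param v_metab Apparent metabolite volume, L (`NA` for parent-only models).
#' @param fm Fraction of eliminated parent converted to the metabolite, in
#'   (0, 1].
#' @param mpr Milk-to-plasma concentration ratio (optional; only used by models
#'   that scale plasma into breast milk).
#' @return An object of class `pk_parameters`.
#' @examples
#' pk_parameters(cl_parent = 2.91, v_parent = 24.9, ka = 0.3,
#'               cl_metab = 3.24, v_metab = 1.52)
#' @export
pk_parameters <- function(cl_parent, v_parent, ka,
                          cl_metab = NA_real_, v_metab = NA_real_,
                          fm = 1, mpr = NA_real_) {
  stopifnot(is.numeric(cl_parent), is.numeric(v_parent), is.numeric(ka))
  if (!all(c(cl_parent, v_parent, ka) > 0)) {
    stop("cl_parent, v_parent and ka must be strictly positive", call. = FALSE)
  }
  has_metab <- !is.na(cl_metab) || !is.na(v_metab)
  if (has_metab) {
    if (!all(c(cl_metab, v_metab) > 0)) {
      stop("cl_metab and v_metab must be strictly positive when supplied",
           call. = FALSE)
    }
  }
  if (!is.na(fm) && (fm < 0 || fm > 1)) {
    stop("fm must lie in [0, 1]", call. = FALSE)
  }
  structure(list(cl_parent = unname(cl_parent), v_parent = unname(v_parent),
                 ka = unname(ka), cl_metab = unname(cl_metab),
                 v_metab = unname(v_metab), fm = unname(fm),
                 mpr = unname(mpr)),
            class = "pk_parameters")
}

#' Oral dosing regimen
#'
#' @param dose Dose per administration, mg (zero allowed).
#' @param interval Dosing interval tau, h.
#' @param n_doses Number of administrations; `Inf` denotes the steady-state
#'   limit.
#' @return An object of class `dosing_regimen`.
#' @examples
#' dosing_regimen(60, interval = 24, n_doses = 30)   # 60 mg QD for 30 days
#' dosing_regimen(20)                                # steady-state 20 mg QD
#' @export
dosing_regimen <- function(dose, interval = 24, n_doses = Inf) {
  if (!is.numeric(dose) || dose < 0) stop("dose must be >= 0", call. = FALSE)
  if (!is.numeric(interval) || interval <= 0) {
    stop("interval must be > 0", call. = FALSE)
  }
  if (!(is.infinite(n_doses) || (n_doses >= 1 && n_doses == round(n_doses)))) {
    stop("n_doses must be a positive integer or Inf (steady state)",
         call. = FALSE)
  }
  structure(list(dose = dose, interval = interval, n_doses = n_doses),
            class = "dosing_regimen")
}

# relative gap below which two rate constants are treated as colliding
.EIG_TOL <- 1e-6

# Accumulation-weighted exponential: exp(-lambda*t) * (1-exp(-n*lambda*tau)) /
# (1-exp(-lambda*tau)); n = Inf gives the steady-state limit. Vectorized.
.accum_exp <- function(lambda, t, tau, n) {
  if (all(is.infinite(n))) {
    return(exp(-lambda * t) / (1 - exp(-lambda * tau)))
  }
  num <- ifelse(is.infinite(n), 1, 1 - exp(-n * lambda * tau))
  exp(-lambda * t) * num / (1 - exp(-lambda * tau))
}

# Closed-form parent concentration, ng/mL. Fully vectorized over all numeric
# arguments (recycled). Colliding ka/kE are nudged by 2*.EIG_TOL, which keeps
# the result within O(1e-6) relative of the analytic limit; the exported
# wrappers route collisions through the ODE instead.
.cf_parent <- function(t, dose, tau, n, cl, v, ka) {
  ke <- cl / v
  collide <- abs(ka - ke) < .EIG_TOL * pmax(ka, ke)
  collide[is.na(collide)] <- FALSE  # non-finite trial params flow to NaN
  if (any(collide)) ke <- ifelse(collide, ke * (1 - 2 * .EIG_TOL), ke)
  pre <- dose * ka / (v * (ka - ke))
  1000 * pre * (.accum_exp(ke, t, tau, n) - .accum_exp(ka, t, tau, n))
}

# Closed-form metabolite concentration (catenary depot->parent->metabolite),
# ng/mL. Tri-exponential partial-fraction form; vectorized; collisions among
# {ka, kE, km} nudged as above.
.cf_metab <- function(t, dose, tau, n, cl_p, v_p, ka, cl_m, v_m, fm) {
  ke <- cl_p / v_p
  km <- cl_m / v_m
  mx <- pmax(ka, ke, km)
  near <- function(a, b) {
    z <- abs(a - b) < .EIG_TOL * mx
    z[is.na(z)] <- FALSE  # non-finite trial params flow to NaN
    z
  }
  if (any(near(ka, ke))) ke <- ifelse(near(ka, ke), ke * (1 - 2 * .EIG_TOL), ke)
  if (any(near(ka, km))) km <- ifelse(near(ka, km), km * (1 + 2 * .EIG_TOL), km)
  if (any(near(ke, km))) km <- ifelse(near(ke, km), km * (1 + 4 * .EIG_TOL), km)
  pre <- fm * dose * ka * ke / v_m
  s <- .accum_exp(ka, t, tau, n) / ((ke - ka) * (km - ka)) +
       .accum_exp(ke, t, tau, n) / ((ka - ke) * (km - ke)) +
       .accum_exp(km, t, tau, n) / ((ka - km) * (ke - km))
  1000 * pre * s
}

.has_collision <- function(params) {
  ke <- params$cl_parent / params$v_parent
  rates <- c(params$ka, ke)
  if (!is.na(params$cl_metab)) rates <- c(rates, params$cl_metab / params$v_metab)
  mx <- max(rates)
  any(abs(outer(rates, rates, "-"))[lower.tri(diag(length(rates)))] < .EIG_TOL * mx)
}

.max_half_life <- function(params) {
  rates <- c(params$cl_parent / params$v_parent)
  if (!is.na(params$cl_metab)) rates <- c(rates, params$cl_metab / params$v_metab)
  max(log(2) / rates)
}

# number of doses after which the finite profile is numerically at steady state
.n_doses_to_ss <- function(params, interval) {
  ceiling(7 * .max_half_life(params) / interval) + 1
}

#' Parent (fluoxetine) concentration under multiple oral dosing
#'
#' Superposition solution of the one-compartment first-order-absorption model:
#' at steady state
#' \deqn{C(t) = \frac{D k_a}{V (k_a - k_E)} \left[
#'   \frac{e^{-k_E t}}{1 - e^{-k_E \tau}} -
#'   \frac{e^{-k_a t}}{1 - e^{-k_a \tau}} \right]}
#' with \eqn{k_E = CL/V}; for a finite number of doses each exponential term is
#' weighted by its truncated geometric sum. If `ka` and `kE` collide within
#' relative tolerance `1e-6` the profile is computed by numerical integration
#' instead (never `NaN`).
#'
#' @param params A [pk_parameters()] object.
#' @param regimen A [dosing_regimen()] object.
#' @param t Time since the last administered dose, h (vectorized).
#' @return Concentration(s) in ng/mL.
#' @examples
#' p <- pk_parameters(2.91, 24.9, 0.3)
#' parent_conc(p, dosing_regimen(60), t = 24)  # steady-state trough
#' @export
parent_conc <- function(params, regimen, t) {
  stopifnot(inherits(params, "pk_parameters"), inherits(regimen, "dosing_regimen"))
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  if (regimen$dose == 0) return(rep(0, length(t)))
  if (.has_collision(params)) {
    return(.ode_at_trough(params, regimen, t)[, "parent"])
  }
  .cf_parent(t, regimen$dose, regimen$interval, regimen$n_doses,
             params$cl_parent, params$v_parent, params$ka)
}

#' Metabolite (norfluoxetine) concentration under multiple oral dosing
#'
#' Tri-exponential superposition solution of the catenary
#' depot \eqn{\to} parent \eqn{\to} metabolite system,
#' \deqn{C_m(t) = \frac{F_M D k_a k_E}{V_m} \sum_{\lambda \in \{k_a,k_E,k_m\}}
#'   \frac{e^{-\lambda t}}{\prod_{\mu \neq \lambda}(\mu - \lambda)
#'   \,(1 - e^{-\lambda \tau})}}
#' at steady state, with truncated geometric weights for finite regimens.
#' Eigenvalue collisions fall back to numerical integration.
#'
#' @inheritParams parent_conc
#' @return Concentration(s) in ng/mL.
#' @export
metabolite_conc <- function(params, regimen, t) {
  stopifnot(inherits(params, "pk_parameters"), inherits(regimen, "dosing_regimen"))
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  if (is.na(params$cl_metab)) {
    stop("params carry no metabolite disposition (cl_metab/v_metab missing)",
         call. = FALSE)
  }
  if (regimen$dose == 0 || params$fm == 0) return(rep(0, length(t)))
  if (.has_collision(params)) {
    return(.ode_at_trough(params, regimen, t)[, "metab"])
  }
  .cf_metab(t, regimen$dose, regimen$interval, regimen$n_doses,
            params$cl_parent, params$v_parent, params$ka,
            params$cl_metab, params$v_metab, params$fm)
}

.ode_rhs <- function(t, A, p) {
  list(c(-p["ka"] * A[1],
         p["ka"] * A[1] - p["ke"] * A[2],
         p["fm"] * p["ke"] * A[2] - p["km"] * A[3]))
}

#' Numerically integrated concentration profile
#'
#' Integrates the linear depot \eqn{\to} parent \eqn{\to} metabolite system
#' with instantaneous dose resets using [deSolve::ode()]. This is the
#' brute-force reference for the closed forms and the fallback used when rate
#' constants collide. Steady-state regimens (`n_doses = Inf`) are realized as
#' enough doses to cover seven terminal half-lives.
#'
#' @inheritParams parent_conc
#' @param grid Strictly increasing vector of times since the first dose, h.
#' @return A data.frame with columns `time`, `parent`, `metab`,
#'   `active_moiety` (ng/mL).
#' @export
ode_profile <- function(params, regimen, grid) {
  stopifnot(inherits(params, "pk_parameters"), inherits(regimen, "dosing_regimen"))
  if (any(diff(grid) <= 0) || any(grid < 0)) {
    stop("grid must be strictly increasing and non-negative", call. = FALSE)
  }
  n <- regimen$n_doses
  if (is.infinite(n)) n <- .n_doses_to_ss(params, regimen$interval)
  has_m <- !is.na(params$cl_metab)
  p <- c(ka = params$ka, ke = params$cl_parent / params$v_parent,
         km = if (has_m) params$cl_metab / params$v_metab else 1,
         fm = if (has_m) params$fm else 0)
  ev <- data.frame(var = "depot", time = regimen$interval * (0:(n - 1)),
                   value = regimen$dose, method = "add")
  ev <- ev[ev$time <= max(grid), , drop = FALSE]
  times <- sort(unique(c(0, ev$time, grid)))
  out <- tryCatch(
    deSolve::ode(y = c(depot = 0, parent = 0, metab = 0), times = times,
                 func = .ode_rhs, parms = p, events = list(data = ev),
                 rtol = 1e-10, atol = 1e-10),
    error = function(e) stop("ODE integration failed (CL=", params$cl_parent,
                             ", V=", params$v_parent, ", ka=", params$ka,
                             "): ", conditionMessage(e), call. = FALSE))
  i <- match(grid, out[, "time"])
  parent <- 1000 * out[i, "parent"] / params$v_parent
  metab <- if (has_m) 1000 * out[i, "metab"] / params$v_metab else rep(NA_real_, length(i))
  data.frame(time = grid, parent = parent, metab = metab,
             active_moiety = parent + ifelse(is.na(metab), 0, metab))
}

# ODE evaluated at "t hours after the last dose" for the given regimen
.ode_at_trough <- function(params, regimen, t) {
  n <- regimen$n_doses
  if (is.infinite(n)) n <- .n_doses_to_ss(params, regimen$interval)
  abs_t <- sort(unique((n - 1) * regimen$interval + t))
  prof <- ode_profile(params,
                      dosing_regimen(regimen$dose, regimen$interval, n),
                      grid = abs_t)
  prof[match((n - 1) * regimen$interval + t, prof$time), , drop = FALSE]
}

#' Steady-state trough concentrations
#'
#' Trough (concentration at \eqn{t = \tau} after a dose) under the analytic
#' steady-state superposition limit, for the parent, the metabolite and the
#' active moiety (their sum). If a finite regimen is supplied whose duration
#' covers fewer than five terminal half-lives, a warning notes that the trough
#' may not have reached steady state.
#'
#' @inheritParams parent_conc
#' @return Named numeric vector `parent`, `metabolite`, `active_moiety`
#'   (ng/mL); `metabolite` is `NA` for parent-only parameter sets.
#' @examples
#' p <- pk_parameters(2.91, 24.9, 0.3, 3.24, 1.52)
#' steady_state_trough(p, dosing_regimen(60))
#' @export
steady_state_trough <- function(params, regimen) {
  stopifnot(inherits(params, "pk_parameters"), inherits(regimen, "dosing_regimen"))
  if (is.finite(regimen$n_doses)) {
    dur <- regimen$n_doses * regimen$interval
    if (dur < 5 * .max_half_life(params)) {
      warning("regimen covers fewer than 5 terminal half-lives; ",
              "trough may be below its steady-state value", call. = FALSE)
    }
  }
  tau <- regimen$interval
  par_t <- parent_conc(params, regimen, tau)
  met_t <- if (!is.na(params$cl_metab)) metabolite_conc(params, regimen, tau) else NA_real_
  c(parent = par_t,
    metabolite = met_t,
    active_moiety = par_t + ifelse(is.na(met_t), 0, met_t))
}
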