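# Synthetic trough-only TDM cohort generator. Emulates the statistical
# structure of a real-world fluoxetine monitoring dataset: 198 patients
# (146 female / 52 male), a pediatric/adult age mixture (12-17 median 15;
# 18-56 median 21), right-skewed weights with median 59 kg in [35.9, 115],
# once-daily doses of 20-60 mg, steady-state troughs only (one or two per
# subject, mean 241/198), paired parent/metabolite samples, LLOQ 1 ng/mL.

#' Design of a synthetic TDM cohort
#'
#' Defaults reproduce the target cohort: exact sex split (the female count is
#' `round(n_subjects * (1 - male_fraction))`), a 102:92 pediatric:adult age
#' mixture, log-normal weights fitted to median 59 kg with the stated range as
#' its 0.1/99.9 percentiles (truncated by resampling), dose levels
#' 20/40/60 mg QD with probabilities 0.4/0.4/0.2, and one trough per subject
#' with probability 0.78, two with 0.22 (mean 1.22 observations).
#'
#' @param n_subjects Number of subjects.
#' @param male_fraction Fraction of males (default 52/198).
#' @param pediatric_fraction Weight of the pediatric (12-17 y) component of
#'   the age mixture (default 102/194).
#' @param dose_levels,dose_probs Once-daily dose levels (mg) and their
#'   sampling probabilities (must sum to 1).
#' @param obs_probs Probabilities of 1 and 2 observations per subject.
#' @param weight_meanlog,weight_sdlog Log-normal weight parameters; defaults
#'   give median 59 kg.
#' @param weight_range Truncation range for weight, kg.
#' @param model Generating [pk_model()] (default `builtin_model("FINAL")`).
#' @param interval Dosing interval, h.
#' @param lloq Lower limit of quantification, ng/mL.
#' @param seed Integer seed; fully determines [generate_cohort()] output.
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(n_subjects = 198, male_fraction = 52 / 198,
                          pediatric_fraction = 102 / 194,
                          dose_levels = c(20, 40, 60),
                          dose_probs = c(0.4, 0.4, 0.2),
                          obs_probs = c(0.78, 0.22),
                          weight_meanlog = log(59), weight_sdlog = 0.19,
                          weight_range = c(35.9, 115),
                          model = builtin_model("FINAL"),
                          interval = 24, lloq = 1, seed = NULL) {
  if (abs(sum(dose_probs) - 1) > 1e-9 || abs(sum(obs_probs) - 1) > 1e-9) {
    stop("dose_probs and obs_probs must each sum to 1", call. = FALSE)
  }
  if (any(dose_probs < 0) || any(obs_probs < 0)) {
    stop("sampling probabilities must be non-negative", call. = FALSE)
  }
  if (weight_range[1] >= weight_range[2] || weight_range[1] <= 0) {
    stop("invalid weight_range", call. = FALSE)
  }
  stopifnot(inherits(model, "pk_model"), n_subjects >= 1)
  structure(list(n_subjects = n_subjects, male_fraction = male_fraction,
                 pediatric_fraction = pediatric_fraction,
                 dose_levels = dose_levels, dose_probs = dose_probs,
                 obs_probs = obs_probs, weight_meanlog = weight_meanlog,
                 weight_sdlog = weight_sdlog, weight_range = weight_range,
                 model = model, interval = interval, lloq = lloq, seed = seed),
            class = "cohort_design")
}

# truncated sampler by resampling; deterministic given the RNG state
.rtrunc <- function(n, rfun, lo, hi) {
  x <- rfun(n)
  for (it in 1:100) {
    bad <- x < lo | x > hi
    if (!any(bad)) break
    x[bad] <- rfun(sum(bad))
  }
  pmin(pmax(x, lo), hi)
}

#' Generate a synthetic trough-only cohort
#'
#' For each subject: draw covariates (sex, age, weight), a once-daily dose and
#' a number of troughs; draw random effects \eqn{\eta \sim N(0, \omega^2)} per
#' IIV key of the generating model; compute the steady-state trough per
#' analyte; add combined residual noise
#' \eqn{y = f (1 + \varepsilon_p) + \varepsilon_a}; floor at zero and flag
#' values below the LLOQ. Parent and metabolite observations are emitted in
#' pairs at identical times (troughs at 24 h, 48 h, ...). With
#' `noise = FALSE` residual errors are skipped and observations equal the
#' closed-form predictions at the drawn random effects.
#'
#' @param design A [cohort_design()].
#' @param noise Draw residual errors (default `TRUE`).
#' @return A [pk_cohort()]; provenance records the design and seed.
#' @examples
#' coh <- generate_cohort(cohort_design(n_subjects = 20, seed = 42))
#' summary_tab <- cohort_summary(coh)
#' @export
generate_cohort <- function(design, noise = TRUE) {
  stopifnot(inherits(design, "cohort_design"))
  if (!is.null(design$seed)) set.seed(design$seed)
  n <- design$n_subjects
  model <- design$model
  n_male <- round(n * design$male_fraction)
  sex <- sample(c(rep(1, n_male), rep(0, n - n_male)))
  pediatric <- stats::runif(n) < design$pediatric_fraction
  age <- numeric(n)
  age[pediatric] <- stats::runif(sum(pediatric), 12, 18)
  age[!pediatric] <- .rtrunc(sum(!pediatric),
                             function(m) 18 + stats::rlnorm(m, log(3), 0.8),
                             18, 56)
  wt <- .rtrunc(n, function(m) stats::rlnorm(m, design$weight_meanlog,
                                             design$weight_sdlog),
                design$weight_range[1], design$weight_range[2])
  dose <- design$dose_levels[sample.int(length(design$dose_levels), n,
                                        replace = TRUE,
                                        prob = design$dose_probs)]
  n_obs <- sample(seq_along(design$obs_probs), n, replace = TRUE,
                  prob = design$obs_probs)
  omega <- unlist(model$iiv)
  keys <- names(omega)
  E <- matrix(stats::rnorm(n * length(keys)), n, length(keys),
              dimnames = list(NULL, keys))
  E <- sweep(E, 2, omega, "*")
  covs <- list(SEX = sex, AGE = age, WT = wt)
  tv <- .typical_by_subject(model, covs, n)
  ind <- tv
  for (k in keys) ind[[k]] <- ind[[k]] * exp(E[, k])
  tau <- design$interval
  f_par <- .cf_parent(tau, dose, tau, Inf, ind$cl_parent, ind$v_parent, ind$ka)
  f_met <- if (model$structure == "parent_metabolite") {
    .cf_metab(tau, dose, tau, Inf, ind$cl_parent, ind$v_parent, ind$ka,
              ind$cl_metab, ind$v_metab, ind$fm)
  }
  rm_ <- model$ruv$metabolite
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    times <- tau * seq_len(n_obs[i])
    draw <- function(f, ruv) {
      y <- rep(f, n_obs[i])
      if (noise) {
        y <- y * (1 + stats::rnorm(n_obs[i], 0, ruv[["prop"]])) +
          stats::rnorm(n_obs[i], 0, ruv[["add"]])
      }
      pmax(y, 0)
    }
    yp <- draw(f_par[i], model$ruv$parent)
    obs <- data.frame(time = times, analyte = "parent", dv = yp,
                      blq = yp < design$lloq)
    if (!is.null(f_met)) {
      ym <- draw(f_met[i], rm_)
      obs <- rbind(obs, data.frame(time = times, analyte = "metabolite",
                                   dv = ym, blq = ym < design$lloq))
    }
    obs <- obs[order(obs$time, obs$analyte), , drop = FALSE]
    rownames(obs) <- NULL
    subjects[[i]] <- list(
      id = i,
      doses = data.frame(time = 0, amt = dose[i], ii = tau, ss = TRUE,
                         addl = 0),
      obs = obs,
      covariates = list(SEX = sex[i], AGE = age[i], WT = wt[i]))
  }
  pk_cohort(subjects,
            provenance = sprintf("generate_cohort(n=%d, model=%s, seed=%s)",
                                 n, model$name,
                                 if (is.null(design$seed)) "NULL" else design$seed))
}
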