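# Internal vectorized prediction machinery. A "design" flattens a cohort into
# observation rows plus (observation x dose-event) contribution rows, so model
# predictions for the whole cohort are a handful of vectorized closed-form
# evaluations followed by a rowsum. Superposition makes dose events additive,
# which keeps this exact for arbitrary dosing histories.

# Map each (observation, dose event) pair to an effective time-since-last-dose
# and dose count. SS events use the periodic steady-state profile; finite
# trains count administered doses up to the observation time.
.event_timing <- function(t_rel, ii, ss, addl) {
  if (ss) {
    list(t = t_rel - ii * floor((t_rel - 1e-9) / ii), n = Inf, tau = ii)
  } else if (ii > 0 && addl > 0) {
    m <- min(addl + 1, floor(t_rel / ii + 1e-9) + 1)
    list(t = t_rel - (m - 1) * ii, n = m, tau = ii)
  } else {
    list(t = t_rel, n = 1, tau = 24)  # tau is inert when n = 1
  }
}

# Flatten a cohort against a model. Observations for analytes the model does
# not predict are dropped; BLQ observations are dropped when drop_blq.
.cohort_design <- function(model, cohort, drop_blq = TRUE) {
  ns <- length(cohort$subjects)
  obs_l <- vector("list", ns)
  row_l <- vector("list", ns)
  for (i in seq_len(ns)) {
    s <- cohort$subjects[[i]]
    ob <- s$obs
    keep <- ob$analyte %in% model$analytes
    if (drop_blq) keep <- keep & !ob$blq
    ob <- ob[keep, , drop = FALSE]
    if (!nrow(ob)) next
    obs_l[[i]] <- data.frame(subj = i, analyte = ob$analyte, y = ob$dv,
                             time = ob$time)
    rw <- list()
    for (j in seq_len(nrow(ob))) {
      for (k in seq_len(nrow(s$doses))) {
        t_rel <- ob$time[j] - s$doses$time[k]
        if (t_rel <= 0 || s$doses$amt[k] <= 0) next
        tm <- .event_timing(t_rel, s$doses$ii[k], s$doses$ss[k], s$doses$addl[k])
        rw[[length(rw) + 1L]] <- c(j, s$doses$amt[k], tm$tau, tm$n, tm$t)
      }
    }
    if (length(rw)) {
      m <- do.call(rbind, rw)
      row_l[[i]] <- data.frame(obs_local = m[, 1], subj = i, dose = m[, 2],
                               tau = m[, 3], n = m[, 4], t = m[, 5])
    }
  }
  obs <- do.call(rbind, obs_l)
  if (is.null(obs) || !nrow(obs)) stop("no usable observations", call. = FALSE)
  obs$idx <- seq_len(nrow(obs))
  off <- c(0, cumsum(vapply(obs_l, function(d) if (is.null(d)) 0L else nrow(d),
                            integer(1))))
  rows <- do.call(rbind, lapply(seq_len(ns), function(i) {
    r <- row_l[[i]]
    if (is.null(r)) return(NULL)
    r$obs_idx <- r$obs_local + off[i]
    r
  }))
  list(obs = obs, rows = rows, n_subjects = ns,
       subj_of_obs = obs$subj, is_parent = obs$analyte == "parent")
}

# IIV keys that actually carry variability; keys with omega = 0 are excluded
# from the random-effects machinery (their eta is identically zero).
.active_omega <- function(model) {
  om <- unlist(model$iiv)
  om[om > 0]
}

# Covariate values (with default substitution) needed by the model's effects,
# one row per subject.
.design_covariates <- function(model, cohort) {
  need <- unique(vapply(model$covariates, function(ce) ce$covariate, character(1)))
  out <- list()
  for (cn in need) {
    v <- vapply(cohort$subjects, function(s) {
      x <- s$covariates[[cn]]
      if (is.null(x) || is.na(x)) {
        d <- model$covariate_defaults[[cn]]
        if (is.null(d)) {
          stop("covariate '", cn, "' required by model ", model$name,
               " is missing and has no default", call. = FALSE)
        }
        d
      } else x
    }, numeric(1))
    out[[cn]] <- v
  }
  out
}

# Per-subject covariate-adjusted typical values, as a list of vectors.
.typical_by_subject <- function(model, covs, n_subjects) {
  tv <- lapply(unclass(model$typical), function(v) rep(v, n_subjects))
  for (ce in model$covariates) {
    tv[[ce$parameter]] <- tv[[ce$parameter]] * .cov_factor(ce, covs[[ce$covariate]])
  }
  tv
}

# Precompute the static row vectors the hot prediction path needs.
.design_cache <- function(design) {
  r <- design$rows
  is_par <- design$is_parent[r$obs_idx]
  ip <- which(is_par); im <- which(!is_par)
  design$cache <- list(
    p = list(i = ip, t = r$t[ip], dose = r$dose[ip], tau = r$tau[ip],
             n = r$n[ip], s = r$subj[ip], obs = r$obs_idx[ip]),
    m = list(i = im, t = r$t[im], dose = r$dose[im], tau = r$tau[im],
             n = r$n[im], s = r$subj[im], obs = r$obs_idx[im]),
    # one contribution per observation, in order: skip the rowsum
    identity = nrow(r) == nrow(design$obs) &&
      !is.unsorted(r$obs_idx, strictly = TRUE),
    n_rows = nrow(r))
  design
}

# Model prediction per observation for a matrix of random effects.
# tv: list from .typical_by_subject; E: n_subjects x k matrix with colnames
# equal to IIV keys (absent keys treated as zero).
.design_f <- function(design, model, tv, E = NULL) {
  ind <- tv
  if (!is.null(E)) {
    for (k in colnames(E)) ind[[k]] <- ind[[k]] * exp(E[, k])
  }
  cc <- design$cache
  if (is.null(cc)) {
    design <- .design_cache(design)
    cc <- design$cache
  }
  contrib <- numeric(cc$n_rows)
  p <- cc$p
  if (length(p$i)) {
    contrib[p$i] <- .cf_parent(p$t, p$dose, p$tau, p$n, ind$cl_parent[p$s],
                               ind$v_parent[p$s], ind$ka[p$s])
  }
  m <- cc$m
  if (length(m$i)) {
    contrib[m$i] <- .cf_metab(m$t, m$dose, m$tau, m$n, ind$cl_parent[m$s],
                              ind$v_parent[m$s], ind$ka[m$s],
                              ind$cl_metab[m$s], ind$v_metab[m$s], ind$fm[m$s])
  }
  if (cc$identity) return(contrib)
  f <- numeric(nrow(design$obs))
  agg <- rowsum(contrib, design$rows$obs_idx)
  f[as.integer(rownames(agg))] <- agg[, 1]
  f
}

# Residual variance g = (sigma_prop * f)^2 + sigma_add^2, per observation.
.design_g <- function(design, model, f) {
  rm_ <- model$ruv$metabolite
  if (is.null(rm_)) rm_ <- c(prop = 0, add = 0)
  prop <- ifelse(design$is_parent, model$ruv$parent[["prop"]], rm_[["prop"]])
  add <- ifelse(design$is_parent, model$ruv$parent[["add"]], rm_[["add"]])
  (prop * f)^2 + add^2
}
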