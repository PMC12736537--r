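# Mixed-effects estimation: per-subject MAP Bayesian estimation and a
# desk-scale FOCE-with-interaction population estimator, plus stepwise
# covariate selection and nonparametric bootstrap.
#
# The population objective is the classic first-order-conditional
# approximation: for each subject the conditional mode eta_hat of
#   l_i(eta) = sum_j [ (y_j - f_j(eta))^2 / g_j(eta) + log g_j(eta) ]
#              + sum_k eta_k^2 / omega_k^2
# is located (vectorized damped Newton across subjects), f is linearized about
# eta_hat with interaction retained in the residual variance, and
#   OFV = sum_i [ log det V_i + r_i' V_i^{-1} r_i ] + N log 2*pi,
#   V_i = F_i Omega F_i' + diag(g_i(eta_hat)),
#   r_i = y_i - f_i(eta_hat) + F_i eta_hat_i .

# ---- free-parameter bookkeeping -------------------------------------------

.STRUCTURAL <- c("cl_parent", "v_parent", "ka", "cl_metab", "v_metab", "fm")

.theta_name <- function(ce) paste("theta", ce$parameter, ce$covariate, sep = ".")

# Table of estimable parameters for a model; 'free' (character) subsets it.
.par_table <- function(model, free = NULL) {
  rows <- list()
  add <- function(name, kind, a = NA, b = NA, transform, init) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, kind = kind, target = a, component = b,
      transform = transform, init = init, stringsAsFactors = FALSE)
  }
  for (p in .STRUCTURAL) {
    v <- model$typical[[p]]
    if (!is.na(v) && !(p %in% model$fixed)) add(p, "typical", p, NA, "log", v)
  }
  for (i in seq_along(model$covariates)) {
    ce <- model$covariates[[i]]
    tr <- switch(ce$form, fractional = "log1p", linear = "log",
                 linear_centered = "identity")
    add(.theta_name(ce), "theta", i, NA, tr, ce$theta)
  }
  for (k in names(model$iiv)) {
    add(paste0("omega.", k), "omega", k, NA, "log", max(model$iiv[[k]], 0.05))
  }
  for (an in names(model$ruv)) {
    for (cmp in c("prop", "add")) {
      v <- model$ruv[[an]][[cmp]]
      if (v > 0) add(paste("sigma", an, cmp, sep = "."), "sigma", an, cmp,
                     "log", v)
    }
  }
  tab <- do.call(rbind, rows)
  if (!is.null(free)) {
    bad <- setdiff(free, tab$name)
    if (length(bad)) stop("unknown free parameter(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    tab <- tab[tab$name %in% free, , drop = FALSE]
  }
  if (!nrow(tab)) stop("free-parameter set is empty", call. = FALSE)
  rownames(tab) <- NULL
  tab
}

.to_work <- function(x, tr) {
  switch(tr, log = log(x), log1p = log(1 + x), identity = x)
}
.from_work <- function(w, tr) {
  switch(tr, log = exp(w), log1p = expm1(w), identity = w)
}

.work_init <- function(tab) {
  w <- mapply(.to_work, tab$init, tab$transform)
  names(w) <- tab$name
  w
}

.apply_par <- function(model, tab, w) {
  for (r in seq_len(nrow(tab))) {
    v <- .from_work(w[r], tab$transform[r])
    switch(tab$kind[r],
           typical = { model$typical[[tab$target[r]]] <- v },
           theta = { model$covariates[[as.integer(tab$target[r])]]$theta <- v },
           omega = { model$iiv[[tab$target[r]]] <- v },
           sigma = { model$ruv[[tab$target[r]]][[tab$component[r]]] <- v })
  }
  model
}

.natural_estimates <- function(tab, w) {
  v <- mapply(.from_work, w, tab$transform)
  names(v) <- tab$name
  v
}

# ---- vectorized inner (conditional-mode) problem --------------------------

# Penalized per-subject objective for an n x k matrix of random effects.
.inner_obj <- function(design, model, tv, omega, E) {
  f <- .design_f(design, model, tv, E)
  g <- .design_g(design, model, f)
  term <- (design$obs$y - f)^2 / g + log(g)
  term[!is.finite(term)] <- 1e10  # out-of-domain trial point, not an answer
  v <- numeric(design$n_subjects)
  agg <- rowsum(term, design$subj_of_obs)
  v[as.integer(rownames(agg))] <- agg[, 1]
  pen <- E^2 %*% (1 / omega^2)
  v + pen[, 1]
}

# Damped Newton across all subjects simultaneously; finite-difference
# derivatives share vectorized objective evaluations.
.inner_map_v <- function(design, model, tv, omega, E0 = NULL,
                         maxit = 25, tol = 1e-6, h = 1e-4) {
  keys <- names(omega)
  k <- length(keys)
  n <- design$n_subjects
  E <- if (is.null(E0)) matrix(0, n, k, dimnames = list(NULL, keys)) else E0
  obj <- function(E) .inner_obj(design, model, tv, omega, E)
  cur <- obj(E)
  for (it in seq_len(maxit)) {
    gp <- gm <- vector("list", k)
    grad <- hdiag <- matrix(0, n, k)
    for (d in seq_len(k)) {
      Ep <- E; Ep[, d] <- Ep[, d] + h
      Em <- E; Em[, d] <- Em[, d] - h
      gp[[d]] <- obj(Ep); gm[[d]] <- obj(Em)
      grad[, d] <- (gp[[d]] - gm[[d]]) / (2 * h)
      hdiag[, d] <- (gp[[d]] + gm[[d]] - 2 * cur) / h^2
    }
    # prior curvature floors the diagonal; keeps H positive definite
    for (d in seq_len(k)) hdiag[, d] <- pmax(hdiag[, d], 1 / omega[d]^2)
    step <- matrix(0, n, k)
    if (k == 1L) {
      step[, 1] <- grad[, 1] / hdiag[, 1]
    } else if (k == 2L) {
      Epp <- E; Epp[, 1] <- Epp[, 1] + h; Epp[, 2] <- Epp[, 2] + h
      h12 <- (obj(Epp) - gp[[1]] - gp[[2]] + cur) / h^2
      lim <- 0.95 * sqrt(hdiag[, 1] * hdiag[, 2])
      h12 <- pmin(pmax(h12, -lim), lim)
      det <- hdiag[, 1] * hdiag[, 2] - h12^2
      step[, 1] <- (hdiag[, 2] * grad[, 1] - h12 * grad[, 2]) / det
      step[, 2] <- (hdiag[, 1] * grad[, 2] - h12 * grad[, 1]) / det
    } else {
      for (i in seq_len(n)) {
        H <- diag(hdiag[i, ], k)
        step[i, ] <- tryCatch(solve(H, grad[i, ]), error = function(e) grad[i, ] * 0)
      }
    }
    step[!is.finite(step)] <- 0
    # trust-region style cap: negative-curvature regions (possible with
    # proportional error far from the mode) otherwise yield huge steps that
    # no amount of halving rescues
    step <- pmin(pmax(step, -2), 2)
    lam <- rep(1, n)
    for (half in 1:8) {
      Enew <- pmin(pmax(E - lam * step, -6), 6)
      new <- obj(Enew)
      worse <- !is.finite(new) | new > cur + 1e-12
      if (!any(worse)) break
      lam[worse] <- lam[worse] / 2
    }
    improved <- is.finite(new) & new <= cur
    moved <- max(abs((lam * step)[improved, , drop = FALSE]), 0)
    E[improved, ] <- Enew[improved, ]
    cur[improved] <- new[improved]
    if (moved < tol) break
  }
  f <- .design_f(design, model, tv, E)
  list(E = E, obj = cur, f = f, g = .design_g(design, model, f))
}

# FOCE-I marginal -2 log-likelihood given the conditional modes. Subjects
# with one or two observations (the bulk of trough-only data) are handled by
# vectorized closed forms; larger blocks fall back to a Cholesky loop.
.foce_ofv <- function(design, model, tv, omega, E, h = 1e-4) {
  keys <- names(omega)
  k <- length(keys)
  f_hat <- .design_f(design, model, tv, E)
  g_hat <- .design_g(design, model, f_hat)
  n_obs <- nrow(design$obs)
  Fm <- matrix(0, n_obs, k)
  for (d in seq_len(k)) {
    Ep <- E; Ep[, d] <- Ep[, d] + h
    Em <- E; Em[, d] <- Em[, d] - h
    Fm[, d] <- (.design_f(design, model, tv, Ep) -
                .design_f(design, model, tv, Em)) / (2 * h)
  }
  subj <- design$subj_of_obs
  r <- design$obs$y - f_hat + rowSums(Fm * E[subj, , drop = FALSE])
  if (!all(is.finite(r)) || !all(is.finite(Fm)) || !all(is.finite(g_hat))) {
    return(1e10)
  }
  om2 <- omega^2
  # FOmF[j1, j2] = F_j1' Omega F_j2 for observation pairs
  FO <- sweep(Fm, 2, om2, "*")
  ofv <- n_obs * log(2 * pi)
  cnt <- design$obs_count
  if (is.null(cnt)) cnt <- tabulate(subj)[subj]
  one <- which(cnt == 1L)
  if (length(one)) {
    v <- rowSums(FO[one, , drop = FALSE] * Fm[one, , drop = FALSE]) + g_hat[one]
    ofv <- ofv + sum(log(v) + r[one]^2 / v)
  }
  two <- which(cnt == 2L)
  if (length(two)) {
    i1 <- two[seq(1, length(two), 2)]
    i2 <- two[seq(2, length(two), 2)]
    a <- rowSums(FO[i1, , drop = FALSE] * Fm[i1, , drop = FALSE]) + g_hat[i1]
    c_ <- rowSums(FO[i2, , drop = FALSE] * Fm[i2, , drop = FALSE]) + g_hat[i2]
    b <- rowSums(FO[i1, , drop = FALSE] * Fm[i2, , drop = FALSE])
    det <- a * c_ - b^2
    if (any(!is.finite(det)) || any(det <= 0)) return(1e10)
    quad <- (c_ * r[i1]^2 - 2 * b * r[i1] * r[i2] + a * r[i2]^2) / det
    ofv <- ofv + sum(log(det) + quad)
  }
  big <- which(cnt > 2L)
  if (length(big)) {
    Om <- diag(om2, k)
    for (i in unique(subj[big])) {
      idx <- design$obs_by_subj[[as.character(i)]]
      Fi <- Fm[idx, , drop = FALSE]
      Vi <- Fi %*% Om %*% t(Fi) + diag(g_hat[idx], length(idx))
      ch <- tryCatch(chol(Vi), error = function(e) NULL)
      if (is.null(ch)) {
        Vi <- Vi + diag(1e-6 * mean(diag(Vi)), nrow(Vi))
        ch <- tryCatch(chol(Vi), error = function(e) NULL)
        if (is.null(ch)) return(1e10)
      }
      z <- backsolve(ch, r[idx], transpose = TRUE)
      ofv <- ofv + 2 * sum(log(diag(ch))) + sum(z^2)
    }
  }
  if (!is.finite(ofv)) ofv <- 1e10  # keeps line searches away, never NaN
  ofv
}

.design_index <- function(design) {
  design$obs_by_subj <- split(seq_len(nrow(design$obs)), design$subj_of_obs)
  design$obs_count <- tabulate(design$subj_of_obs)[design$subj_of_obs]
  .design_cache(design)
}

# ---- population fit -------------------------------------------------------

#' Control settings for [pkfit()]
#'
#' @param maxit Maximum outer BFGS iterations.
#' @param reltol Outer convergence tolerance (relative change in OFV).
#' @param inner_maxit Maximum Newton iterations for the conditional modes.
#' @param inner_tol Convergence tolerance for the conditional-mode search.
#' @param grad_step Finite-difference step for the outer gradient (working
#'   scale).
#' @param max_cycles Maximum anchored optimization cycles (see Details in
#'   [pkfit()]).
#' @param cycle_tol OFV improvement below which cycling stops.
#' @return A list of class `pkfit_control`.
#' @export
pkfit_control <- function(maxit = 100, reltol = 1e-10, inner_maxit = 25,
                          inner_tol = 1e-7, grad_step = 1e-5,
                          max_cycles = 10, cycle_tol = 1e-5) {
  structure(list(maxit = maxit, reltol = reltol, inner_maxit = inner_maxit,
                 inner_tol = inner_tol, grad_step = grad_step,
                 max_cycles = max_cycles, cycle_tol = cycle_tol),
            class = "pkfit_control")
}

#' Fit a population PK model by FOCE-type estimation
#'
#' Maximizes the first-order-conditional (with interaction) approximation to
#' the marginal likelihood of a nonlinear mixed-effects model over fixed
#' effects, covariate effects, between-subject SDs and residual-error SDs.
#' Positive parameters are estimated on the log scale; fractional covariate
#' shifts via \eqn{\log(1+\theta)}. Standard errors come from the
#' finite-difference observed information at the optimum; shrinkage is
#' SD-based, \eqn{100 (1 - SD(\hat\eta_k)/\omega_k)}.
#'
#' @param model A [pk_model()] acting as the structural template; parameters
#'   named in `model$fixed` (conventionally `ka` and `fm`) are not estimated.
#' @param data A [pk_cohort()] with at least two subjects. BLQ-flagged
#'   observations are excluded.
#' @param free Character vector naming the parameters to estimate (see
#'   the `free` table in the fitted object); default: all structural
#'   parameters not fixed, all covariate effects, all IIV and residual SDs.
#' @param init Optional [pk_model()] providing starting values (same
#'   structure as `model`); defaults to `model` itself.
#' @param estimate_se Compute the observed-information standard errors
#'   (adds a Hessian evaluation; disable inside bootstrap loops).
#' @param control A [pkfit_control()] list.
#' @return An object of class `pkfit`; see [coef.pkfit()], [summary.pkfit()],
#'   [predict.pkfit()], [residuals.pkfit()], [simulate.pkfit()].
#' @examples
#' \donttest{
#' set.seed(1)
#' coh <- generate_cohort(cohort_design(n_subjects = 40))
#' fit <- pkfit(builtin_model("FINAL"), coh, estimate_se = FALSE,
#'              control = pkfit_control(maxit = 50))
#' coef(fit)
#' }
#' @export
pkfit <- function(model, data, free = NULL, init = NULL, estimate_se = TRUE,
                  control = pkfit_control()) {
  stopifnot(inherits(model, "pk_model"), inherits(data, "pk_cohort"))
  if (length(data$subjects) < 2) stop("need at least 2 subjects", call. = FALSE)
  tab <- .par_table(model, free)
  if (!is.null(init)) {
    itab <- .par_table(init)
    m <- match(tab$name, itab$name)
    tab$init[!is.na(m)] <- itab$init[m[!is.na(m)]]
  }
  design <- .design_index(.cohort_design(model, data))
  covs <- .design_covariates(model, data)
  env <- new.env()
  env$evals <- 0L
  act_keys <- names(.active_omega(model))
  core <- function(w, E0 = NULL) {
    m <- .apply_par(model, tab, w)
    # keys are pinned to the template; floor guards exp() underflow when the
    # optimizer probes extreme log-omega values
    omega <- pmax(unlist(m$iiv)[act_keys], 1e-8)
    tv <- .typical_by_subject(m, covs, design$n_subjects)
    im <- .inner_map_v(design, m, tv, omega, E0,
                       maxit = control$inner_maxit, tol = control$inner_tol)
    env$evals <- env$evals + 1L
    list(ofv = .foce_ofv(design, m, tv, omega, im$E), E = im$E)
  }
  # Anchored-cycle optimization. The raw FOCE objective has rare step
  # discontinuities where a subject's conditional mode switches basins, which
  # stalls quasi-Newton line searches. Each cycle therefore (i) locates the
  # conditional modes from a cold start at the current parameters, (ii)
  # freezes them as the warm start for every objective/gradient evaluation --
  # giving the smooth local branch of the same objective -- and (iii) runs
  # BFGS on that branch. Cycles repeat until the anchored OFV stops improving.
  w_hat <- .work_init(tab)
  h <- control$grad_step
  prev <- Inf
  opt <- NULL
  for (cycle in seq_len(control$max_cycles)) {
    anchor <- core(w_hat, NULL)
    E0 <- anchor$E
    fnw <- function(w) core(w, E0)$ofv
    grw <- function(w) {
      g <- numeric(length(w))
      for (i in seq_along(w)) {
        wp <- w; wp[i] <- wp[i] + h
        wm <- w; wm[i] <- wm[i] - h
        g[i] <- (core(wp, E0)$ofv - core(wm, E0)$ofv) / (2 * h)
      }
      g
    }
    opt <- stats::optim(w_hat, fnw, grw, method = "BFGS",
                        control = list(maxit = control$maxit,
                                       reltol = control$reltol))
    w_hat <- opt$par
    if (prev - opt$value < control$cycle_tol) break
    prev <- opt$value
  }
  m_hat <- .apply_par(model, tab, w_hat)
  omega <- unlist(m_hat$iiv)
  tv <- .typical_by_subject(m_hat, covs, design$n_subjects)
  im <- .inner_map_v(design, m_hat, tv, omega, NULL,
                     maxit = 2 * control$inner_maxit, tol = control$inner_tol / 10)
  # standard errors from the observed information (central differences)
  se <- rse <- rep(NA_real_, nrow(tab))
  cov_w <- NULL
  if (estimate_se) {
    # warm-start every Hessian evaluation from the optimum's conditional
    # modes: keeps each subject in its local basin, so the finite differences
    # see the smooth local surface rather than rare mode switches
    H <- .num_hessian(function(w) core(w, im$E)$ofv, w_hat)
    cov_w <- tryCatch(2 * solve(H), error = function(e) NULL)
    if (is.null(cov_w) || any(diag(cov_w) <= 0)) {
      warning("observed information not positive definite; SEs unavailable",
              call. = FALSE)
      cov_w <- NULL
    } else {
      sd_w <- sqrt(diag(cov_w))
      nat <- .natural_estimates(tab, w_hat)
      dnat <- mapply(function(w, tr) switch(tr, log = exp(w),
                                            log1p = exp(w), identity = 1),
                     w_hat, tab$transform)
      se <- sd_w * dnat
      rse <- 100 * abs(se / nat)
    }
  }
  eta_sd <- apply(im$E, 2, stats::sd)
  shrink <- 100 * (1 - eta_sd / omega)
  iwres <- (design$obs$y - im$f) / sqrt(im$g)
  eps_shrink <- vapply(split(iwres, design$obs$analyte),
                       function(v) 100 * (1 - stats::sd(v)), numeric(1))
  out <- list(model = m_hat, estimates = .natural_estimates(tab, w_hat),
              se = stats::setNames(se, tab$name),
              rse = stats::setNames(rse, tab$name),
              ofv = opt$value, free = tab, cov_work = cov_w,
              eta = im$E, eta_shrinkage = shrink, eps_shrinkage = eps_shrink,
              convergence = list(status = opt$convergence,
                                 converged = opt$convergence == 0,
                                 evaluations = env$evals,
                                 counts = opt$counts),
              n_subjects = design$n_subjects, n_obs = nrow(design$obs),
              data = data, control = control, template = model)
  class(out) <- "pkfit"
  if (opt$convergence != 0) {
    warning("outer optimizer did not report convergence (status ",
            opt$convergence, "); partial estimates returned", call. = FALSE)
  }
  out
}

.num_hessian <- function(fn, x, h = 1e-4) {
  p <- length(x)
  H <- matrix(0, p, p)
  f0 <- fn(x)
  fp <- fm <- numeric(p)
  for (i in seq_len(p)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    fp[i] <- fn(xp); fm[i] <- fn(xm)
    H[i, i] <- (fp[i] + fm[i] - 2 * f0) / h^2
  }
  if (p > 1) {
    for (i in 1:(p - 1)) {
      for (j in (i + 1):p) {
        xpp <- x; xpp[i] <- xpp[i] + h; xpp[j] <- xpp[j] + h
        H[i, j] <- H[j, i] <- (fn(xpp) - fp[i] - fp[j] + f0) / h^2
      }
    }
  }
  (H + t(H)) / 2
}

# ---- MAP estimation and individual predictions ----------------------------

.single_cohort <- function(subject) pk_cohort(list(subject))

#' MAP Bayesian estimate of a subject's random effects
#'
#' Minimizes the penalized conditional objective
#' \deqn{\sum_j \left[ \frac{(y_j - f_j(\eta))^2}{g_j(\eta)} + \ln g_j(\eta)
#'   \right] + \sum_k \frac{\eta_k^2}{\omega_k^2}}
#' with combined residual variance \eqn{g = (\sigma_p f)^2 + \sigma_a^2}.
#' Deterministic: quasi-Newton from \eqn{\eta = 0} plus one fixed offset
#' restart, keeping the lower objective.
#'
#' @param model A [pk_model()].
#' @param subject A subject record (element of a [pk_cohort()]).
#' @return Named numeric vector of log-scale deviations (the model's IIV
#'   keys), with attribute `"objective"`.
#' @export
map_estimate <- function(model, subject) {
  stopifnot(inherits(model, "pk_model"))
  if (!length(model$iiv)) return(structure(numeric(), objective = NA_real_))
  coh <- .single_cohort(subject)
  d0 <- tryCatch(.cohort_design(model, coh), error = function(e) NULL)
  if (is.null(d0)) {
    stop("subject ", subject$id, " has no usable (non-BLQ) observation for ",
         "an analyte predicted by model ", model$name, call. = FALSE)
  }
  design <- .design_index(d0)
  covs <- .design_covariates(model, coh)
  tv <- .typical_by_subject(model, covs, 1L)
  omega <- .active_omega(model)
  keys <- names(omega)
  if (!length(keys)) return(structure(numeric(), objective = NA_real_))
  fn <- function(e) {
    E <- matrix(e, 1, dimnames = list(NULL, keys))
    .inner_obj(design, model, tv, omega, E)
  }
  best <- NULL
  for (start in list(rep(0, length(keys)), rep(0.1, length(keys)))) {
    o <- stats::optim(start, fn, method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-12))
    if (is.null(best) || o$value < best$value - 1e-10) best <- o
  }
  structure(stats::setNames(best$par, keys), objective = best$value)
}

#' Population and individual predictions for one subject
#'
#' @param model A [pk_model()].
#' @param subject A subject record.
#' @param eta Named random-effect vector; defaults to the MAP estimate.
#' @return Data frame with `time`, `analyte`, `obs`, `pred` (population,
#'   \eqn{\eta = 0}) and `ipred` (individual) in ng/mL.
#' @export
individual_predictions <- function(model, subject, eta = NULL) {
  if (is.null(eta)) eta <- map_estimate(model, subject)
  coh <- .single_cohort(subject)
  design <- .cohort_design(model, coh, drop_blq = FALSE)
  covs <- .design_covariates(model, coh)
  tv <- .typical_by_subject(model, covs, 1L)
  keys <- names(model$iiv)
  E <- matrix(0, 1, length(keys), dimnames = list(NULL, keys))
  pred <- .design_f(design, model, tv, E)
  if (length(keys)) E[1, names(eta)] <- eta
  ipred <- .design_f(design, model, tv, E)
  data.frame(time = design$obs$time, analyte = design$obs$analyte,
             obs = design$obs$y, pred = pred, ipred = ipred)
}

# ---- stepwise covariate selection -----------------------------------------

#' Stepwise covariate selection by likelihood-ratio testing
#'
#' Greedy forward inclusion followed by backward elimination on the FOCE OFV:
#' a candidate enters if it improves the OFV by at least `forward_dofv`
#' (default 6.635, the chi-square(1) 1% point) and survives elimination only
#' if its removal worsens the OFV by at least `backward_dofv` (default
#' 10.828, the 0.1% point).
#'
#' @param model Base [pk_model()] without the candidate effects.
#' @param data A [pk_cohort()].
#' @param candidates List of [cov_effect()] objects to screen.
#' @param forward_dofv,backward_dofv OFV-drop thresholds.
#' @param free Optional character vector restricting the estimated parameters
#'   (candidate effect magnitudes are always appended when their effect is in
#'   the model under trial).
#' @param estimate_se Passed to the final refit.
#' @param control A [pkfit_control()].
#' @return List with `fit` (final [pkfit()]), `model` (selected spec) and
#'   `steps` (audit trail data.frame).
#' @export
stepwise_covariates <- function(model, data, candidates,
                                forward_dofv = qchisq(0.99, 1),
                                backward_dofv = qchisq(0.999, 1),
                                free = NULL, estimate_se = FALSE,
                                control = pkfit_control()) {
  for (ce in candidates) {
    cn <- ce$covariate
    present <- vapply(data$subjects,
                      function(s) !is.null(s$covariates[[cn]]), logical(1))
    if (!all(present)) {
      stop("candidate covariate '", cn, "' absent from the dataset",
           call. = FALSE)
    }
  }
  fit_of <- function(m) {
    fr <- if (is.null(free)) NULL else {
      unique(c(free, vapply(m$covariates, .theta_name, character(1))))
    }
    pkfit(m, data, free = fr, estimate_se = FALSE, control = control)
  }
  add_cov <- function(m, ce) { m$covariates <- c(m$covariates, list(ce)); m }
  steps <- list()
  log_step <- function(phase, cand, ofv, dofv, action) {
    steps[[length(steps) + 1L]] <<- data.frame(
      phase = phase, candidate = cand, ofv = ofv, delta_ofv = dofv,
      action = action, stringsAsFactors = FALSE)
  }
  current <- model
  base_fit <- fit_of(current)
  log_step("base", "", base_fit$ofv, NA, "start")
  remaining <- candidates
  included <- list()
  repeat {
    if (!length(remaining)) break
    trial <- lapply(remaining, function(ce) fit_of(add_cov(current, ce)))
    dofv <- base_fit$ofv - vapply(trial, function(f) f$ofv, numeric(1))
    best <- which.max(dofv)
    for (j in seq_along(remaining)) {
      log_step("forward", .theta_name(remaining[[j]]), trial[[j]]$ofv, dofv[j],
               if (j == best && dofv[j] >= forward_dofv) "added" else "not added")
    }
    if (dofv[best] < forward_dofv) break
    current <- add_cov(current, remaining[[best]])
    included <- c(included, remaining[best])
    base_fit <- trial[[best]]
    remaining <- remaining[-best]
  }
  repeat {
    if (!length(included)) break
    drop_fit <- lapply(seq_along(included), function(j) {
      m <- current
      keep <- !vapply(m$covariates, identical, logical(1), included[[j]])
      m$covariates <- m$covariates[keep]
      fit_of(m)
    })
    dofv <- vapply(drop_fit, function(f) f$ofv, numeric(1)) - base_fit$ofv
    worst <- which.min(dofv)
    if (dofv[worst] >= backward_dofv) {
      for (j in seq_along(included)) {
        log_step("backward", .theta_name(included[[j]]), drop_fit[[j]]$ofv,
                 dofv[j], "retained")
      }
      break
    }
    log_step("backward", .theta_name(included[[worst]]), drop_fit[[worst]]$ofv,
             dofv[worst], "removed")
    ce <- included[[worst]]
    keep <- !vapply(current$covariates, identical, logical(1), ce)
    current$covariates <- current$covariates[keep]
    base_fit <- drop_fit[[worst]]
    included <- included[-worst]
  }
  fr <- if (is.null(free)) NULL else {
    unique(c(free, vapply(current$covariates, .theta_name, character(1))))
  }
  final <- pkfit(current, data, free = fr, estimate_se = estimate_se,
                 control = control)
  list(fit = final, model = final$model, steps = do.call(rbind, steps))
}

# ---- bootstrap ------------------------------------------------------------

#' Nonparametric bootstrap of a population fit
#'
#' Resamples subjects with replacement within strata (default: sex), refits
#' the model on each replicate and summarizes per-parameter medians and
#' 2.5/97.5 percentiles. Replicates that error or fail to converge are
#' counted; a result with more than 20% failures is flagged unstable.
#'
#' @param model A [pk_model()] template.
#' @param data A [pk_cohort()].
#' @param n_replicates Number of bootstrap datasets.
#' @param strata Covariate name used for stratified resampling (`NULL` for
#'   unstratified).
#' @param seed Integer seed for reproducibility.
#' @param free,control Passed to [pkfit()].
#' @param resample_fun Optional function `(ids) -> ids` overriding the
#'   resampler (used for deterministic checks).
#' @return An object of class `pk_bootstrap`.
#' @export
pk_bootstrap <- function(model, data, n_replicates = 1000, strata = "SEX",
                         seed = NULL, free = NULL, control = pkfit_control(),
                         resample_fun = NULL) {
  stopifnot(n_replicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  orig <- pkfit(model, data, free = free, estimate_se = FALSE, control = control)
  init_model <- orig$model
  ns <- length(data$subjects)
  strat <- if (is.null(strata)) rep(1, ns) else {
    vapply(data$subjects, function(s) {
      v <- s$covariates[[strata]]
      if (is.null(v)) NA_real_ else v
    }, numeric(1))
  }
  groups <- split(seq_len(ns), strat)
  est <- matrix(NA_real_, n_replicates, nrow(orig$free),
                dimnames = list(NULL, orig$free$name))
  failed <- 0L
  for (b in seq_len(n_replicates)) {
    idx <- if (!is.null(resample_fun)) {
      resample_fun(seq_len(ns))
    } else {
      unlist(lapply(groups, function(g) sample(g, length(g), replace = TRUE)))
    }
    subjects <- lapply(seq_along(idx), function(j) {
      s <- data$subjects[[idx[j]]]
      s$id <- j
      s
    })
    rep_data <- pk_cohort(subjects)
    fit <- tryCatch(
      pkfit(model, rep_data, free = free, init = init_model,
            estimate_se = FALSE, control = control),
      warning = function(w) NULL, error = function(e) NULL)
    if (is.null(fit)) { failed <- failed + 1L; next }
    est[b, ] <- fit$estimates
  }
  ok <- stats::complete.cases(est)
  qs <- apply(est[ok, , drop = FALSE], 2, stats::quantile,
              probs = c(0.5, 0.025, 0.975))
  out <- list(original = orig$estimates, n_replicates = n_replicates,
              n_failed = failed,
              unstable = failed > 0.2 * n_replicates,
              median = qs[1, ], ci_lower = qs[2, ], ci_upper = qs[3, ],
              estimates = est, strata = strata)
  class(out) <- "pk_bootstrap"
  out
}

#' @export
print.pk_bootstrap <- function(x, ...) {
  cat(sprintf("Bootstrap: %d replicates (%d failed%s)\n", x$n_replicates,
              x$n_failed, if (x$unstable) ", UNSTABLE" else ""))
  tab <- data.frame(original = signif(x$original, 4),
                    median = signif(x$median, 4),
                    `2.5%` = signif(x$ci_lower, 4),
                    `97.5%` = signif(x$ci_upper, 4), check.names = FALSE)
  print(tab)
  invisible(x)
}
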