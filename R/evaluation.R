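# External-evaluation metrics and simulation-based diagnostics: relative
# prediction errors (PE/MPE/RMSE), NPDE with its three hypothesis tests,
# conditional weighted residuals, and (prediction-corrected) VPC percentiles.

#' Relative prediction errors
#'
#' Per-observation relative prediction error
#' \eqn{PE_j = (C_{pred,j} - C_{obs,j}) / C_{obs,j}}, with
#' \eqn{MPE = \mathrm{mean}(PE)} and \eqn{RMSE = \sqrt{\mathrm{mean}(PE^2)}},
#' the latter two (and the median PE) reported in percent. A positive MPE
#' therefore denotes overprediction. Observations that are zero or negative
#' cannot support a relative error and are excluded with a warning.
#'
#' @param obs,pred Equal-length numeric vectors, ng/mL.
#' @return List with `pe` (fractional, per retained observation),
#'   `median_pe`, `mpe`, `rmse` (percent) and `n_excluded`.
#' @examples
#' prediction_errors(c(100, 100), c(110, 90))  # MPE 0%, RMSE 10%
#' @export
prediction_errors <- function(obs, pred) {
  if (length(obs) != length(pred)) {
    stop("obs and pred must have equal length", call. = FALSE)
  }
  bad <- obs <= 0
  if (any(bad)) {
    warning(sum(bad), " observation(s) <= 0 excluded from prediction errors",
            call. = FALSE)
    obs <- obs[!bad]; pred <- pred[!bad]
  }
  pe <- (pred - obs) / obs
  list(pe = pe,
       median_pe = 100 * stats::median(pe),
       mpe = 100 * mean(pe),
       rmse = 100 * sqrt(mean(pe^2)),
       n_excluded = sum(bad))
}

# Conditional modes, predictions and CWRES for a whole cohort in one pass.
.evaluate_parts <- function(model, cohort) {
  design <- .design_index(.cohort_design(model, cohort))
  covs <- .design_covariates(model, cohort)
  tv <- .typical_by_subject(model, covs, design$n_subjects)
  omega <- .active_omega(model)
  keys <- names(omega)
  E0 <- matrix(0, design$n_subjects, length(keys),
               dimnames = list(NULL, keys))
  pred <- .design_f(design, model, tv, E0)
  im <- .inner_map_v(design, model, tv, omega, NULL, maxit = 50, tol = 1e-7)
  # CWRES from the FOCE linearization about the conditional modes
  h <- 1e-4
  k <- length(keys)
  Fm <- matrix(0, nrow(design$obs), k)
  for (d in seq_len(k)) {
    Ep <- im$E; Ep[, d] <- Ep[, d] + h
    Em <- im$E; Em[, d] <- Em[, d] - h
    Fm[, d] <- (.design_f(design, model, tv, Ep) -
                .design_f(design, model, tv, Em)) / (2 * h)
  }
  Om <- diag(omega^2, k)
  cwres <- numeric(nrow(design$obs))
  for (i in unique(design$subj_of_obs)) {
    idx <- design$obs_by_subj[[as.character(i)]]
    Fi <- Fm[idx, , drop = FALSE]
    Vi <- Fi %*% Om %*% t(Fi) + diag(im$g[idx], length(idx))
    ri <- design$obs$y[idx] - im$f[idx] + as.vector(Fi %*% im$E[i, ])
    ch <- tryCatch(chol(Vi), error = function(e) NULL)
    if (is.null(ch)) {
      warning("linearized covariance not positive definite for subject ",
              cohort$subjects[[i]]$id, "; ridge applied", call. = FALSE)
      ch <- chol(Vi + diag(1e-6 * mean(diag(Vi)), nrow(Vi)))
    }
    cwres[idx] <- backsolve(ch, ri, transpose = TRUE)
  }
  ids <- vapply(cohort$subjects, function(s) s$id, numeric(1))
  list(design = design, tv = tv, pred = pred, ipred = im$f, eta = im$E,
       cwres = cwres, id = ids[design$subj_of_obs])
}

#' Externally evaluate a model against a cohort
#'
#' Computes population predictions (\eqn{\eta = 0}), individual predictions at
#' the MAP conditional modes, conditional weighted residuals and the
#' PE/MPE/RMSE accuracy metrics at both prediction levels. Only observations
#' of analytes the model predicts are used (a parent-only model is evaluated
#' on parent observations alone); covariates the model requires but the data
#' lack are substituted from the model's recorded source-population central
#' values.
#'
#' @param model A [pk_model()].
#' @param cohort A [pk_cohort()].
#' @return An object of class `pk_evaluation`: `gof` data.frame (`id`,
#'   `time`, `analyte`, `obs`, `pred`, `ipred`, `cwres`) and `metrics`, a
#'   list with `pred` and `ipred` sublists (`median_pe`, `mpe`, `rmse`, in
#'   percent).
#' @export
external_evaluate <- function(model, cohort) {
  stopifnot(inherits(model, "pk_model"), inherits(cohort, "pk_cohort"))
  analytes <- unique(unlist(lapply(cohort$subjects, function(s) s$obs$analyte)))
  if (!length(intersect(analytes, model$analytes))) {
    stop("no overlap between cohort analytes and model analytes", call. = FALSE)
  }
  parts <- .evaluate_parts(model, cohort)
  gof <- data.frame(id = parts$id, time = parts$design$obs$time,
                    analyte = parts$design$obs$analyte,
                    obs = parts$design$obs$y, pred = parts$pred,
                    ipred = parts$ipred, cwres = parts$cwres)
  metr <- function(p) {
    m <- prediction_errors(gof$obs, p)
    m[c("median_pe", "mpe", "rmse")]
  }
  out <- list(gof = gof,
              metrics = list(pred = metr(gof$pred), ipred = metr(gof$ipred)),
              model = model$name, n_obs = nrow(gof))
  class(out) <- "pk_evaluation"
  out
}

#' @export
print.pk_evaluation <- function(x, ...) {
  cat("External evaluation of model", x$model, "on", x$n_obs, "observations\n")
  for (lvl in c("ipred", "pred")) {
    m <- x$metrics[[lvl]]
    cat(sprintf("  %-5s median PE %7.2f%%   MPE %7.2f%%   RMSE %8.2f%%\n",
                toupper(lvl), m$median_pe, m$mpe, m$rmse))
  }
  invisible(x)
}

# Simulate replicate observation vectors under the model: returns an
# n_obs x n_sim matrix. Residual noise enters through the combined-variance
# normal equivalent y = f + sqrt(g) z.
.sim_matrix <- function(model, design, tv, n_sim, include_residual = TRUE) {
  omega <- .active_omega(model)
  keys <- names(omega)
  n <- design$n_subjects
  out <- matrix(0, nrow(design$obs), n_sim)
  for (r in seq_len(n_sim)) {
    E <- matrix(stats::rnorm(n * length(keys)), n, length(keys),
                dimnames = list(NULL, keys))
    E <- sweep(E, 2, omega, "*")
    f <- .design_f(design, model, tv, E)
    if (include_residual) {
      g <- .design_g(design, model, f)
      f <- f + sqrt(g) * stats::rnorm(length(f))
    }
    out[, r] <- f
  }
  out
}

#' Normalized prediction distribution errors
#'
#' Simulates `n_sim` replicate observation vectors per subject (new random
#' effects and residual errors), decorrelates observed and simulated vectors
#' with the empirical mean and Cholesky factor of the simulated covariance,
#' converts the mid-rank of each decorrelated observation among its
#' simulations to a normal score, and runs three tests on the pooled NPDE
#' vector: Wilcoxon signed-rank (H0 mean 0), a chi-square variance test
#' (H0 variance 1) and Shapiro-Wilk (H0 normality).
#'
#' @param model A [pk_model()].
#' @param cohort A [pk_cohort()].
#' @param n_sim Number of Monte Carlo replicates (>= 100).
#' @param seed Integer seed.
#' @return An object of class `pk_npde`: `npde`, `pde`, and `tests` (named
#'   p-values `wilcoxon`, `fisher`, `shapiro`).
#' @export
npde <- function(model, cohort, n_sim = 1000, seed = NULL) {
  stopifnot(inherits(model, "pk_model"), inherits(cohort, "pk_cohort"))
  if (n_sim < 100) stop("n_sim must be >= 100", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  design <- .design_index(.cohort_design(model, cohort))
  covs <- .design_covariates(model, cohort)
  tv <- .typical_by_subject(model, covs, design$n_subjects)
  sims <- .sim_matrix(model, design, tv, n_sim)
  pde <- numeric(nrow(design$obs))
  for (i in unique(design$subj_of_obs)) {
    idx <- design$obs_by_subj[[as.character(i)]]
    Si <- sims[idx, , drop = FALSE]
    mu <- rowMeans(Si)
    ni <- length(idx)
    if (ni == 1L) {
      sdi <- stats::sd(Si[1, ])
      ystar <- (design$obs$y[idx] - mu) / sdi
      sstar <- (Si - mu) / sdi
    } else {
      Vi <- stats::cov(t(Si))
      ch <- tryCatch(chol(Vi), error = function(e) NULL)
      if (is.null(ch)) {
        warning("singular simulated covariance for subject ", i,
                "; ridge applied", call. = FALSE)
        ch <- chol(Vi + diag(1e-8 * mean(diag(Vi)), ni))
      }
      ystar <- backsolve(ch, design$obs$y[idx] - mu, transpose = TRUE)
      sstar <- backsolve(ch, Si - mu, transpose = TRUE)
    }
    for (j in seq_len(ni)) {
      r <- (sum(sstar[j, ] < ystar[j]) + 0.5 * sum(sstar[j, ] == ystar[j])) / n_sim
      pde[idx[j]] <- min(max(r, 1 / (2 * n_sim)), 1 - 1 / (2 * n_sim))
    }
  }
  npde_v <- stats::qnorm(pde)
  n <- length(npde_v)
  v_stat <- (n - 1) * stats::var(npde_v)
  p_fisher <- 2 * min(stats::pchisq(v_stat, n - 1),
                      1 - stats::pchisq(v_stat, n - 1))
  p_shapiro <- if (n >= 3 && n <= 5000) {
    stats::shapiro.test(npde_v)$p.value
  } else {
    NA_real_  # outside the test's supported sample-size range
  }
  tests <- c(wilcoxon = stats::wilcox.test(npde_v, mu = 0)$p.value,
             fisher = p_fisher,
             shapiro = p_shapiro)
  structure(list(npde = npde_v, pde = pde, tests = tests, n_sim = n_sim),
            class = "pk_npde")
}

#' @export
print.pk_npde <- function(x, ...) {
  cat(sprintf("NPDE (%d obs, %d simulations): mean %.3f, var %.3f\n",
              length(x$npde), x$n_sim, mean(x$npde), stats::var(x$npde)))
  cat(sprintf("  Wilcoxon p = %.3g, variance p = %.3g, Shapiro-Wilk p = %.3g\n",
              x$tests["wilcoxon"], x$tests["fisher"], x$tests["shapiro"]))
  invisible(x)
}

#' Conditional weighted residuals
#'
#' Residuals of the FOCE linearization about each subject's conditional mode,
#' scaled by the Cholesky square root of the linearized covariance; under a
#' correct model the pooled CWRES are approximately standard normal.
#'
#' @param model A [pk_model()].
#' @param data A [pk_cohort()] or a single subject record.
#' @return Data frame `id`, `time`, `analyte`, `cwres` (one row per retained
#'   observation).
#' @export
cwres <- function(model, data) {
  if (!inherits(data, "pk_cohort")) data <- .single_cohort(data)
  parts <- .evaluate_parts(model, data)
  data.frame(id = parts$id, time = parts$design$obs$time,
             analyte = parts$design$obs$analyte, cwres = parts$cwres)
}

#' Visual predictive check percentiles
#'
#' Simulates `n_sim` replicate cohorts and compares observed 5th/50th/95th
#' percentiles per bin with the 95% simulation intervals of those
#' percentiles. Default binning is by dose level (the natural axis for
#' trough-only data); `bin_by = "time"` splits observation times into
#' `n_bins` quantile bins. Bins with fewer than 5 observations are merged
#' with their neighbor. With `prediction_corrected = TRUE` every observed and
#' simulated value is scaled by `median(PRED in bin) / PRED` of its own
#' subject-observation (standard prediction correction, pooling dose levels).
#'
#' @param model A [pk_model()].
#' @param cohort A [pk_cohort()].
#' @param n_sim Number of simulated replicate cohorts (>= 200).
#' @param bin_by `"dose"` or `"time"`.
#' @param prediction_corrected Logical.
#' @param n_bins Number of time bins when `bin_by = "time"`.
#' @param seed Integer seed.
#' @return An object of class `pk_vpc` with a `table` data.frame: one row per
#'   bin and percentile, columns `bin`, `n`, `stat`, `observed`, `sim_lower`,
#'   `sim_median`, `sim_upper`.
#' @export
vpc <- function(model, cohort, n_sim = 200, bin_by = c("dose", "time"),
                prediction_corrected = FALSE, n_bins = 4, seed = NULL) {
  bin_by <- match.arg(bin_by)
  if (n_sim < 200) stop("n_sim must be >= 200", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  design <- .design_index(.cohort_design(model, cohort))
  covs <- .design_covariates(model, cohort)
  tv <- .typical_by_subject(model, covs, design$n_subjects)
  # bin labels per observation
  if (bin_by == "dose") {
    obs_dose <- numeric(nrow(design$obs))
    agg <- rowsum(design$rows$dose, design$rows$obs_idx)
    obs_dose[as.integer(rownames(agg))] <- agg[, 1]
    bin <- obs_dose
  } else {
    qs <- unique(stats::quantile(design$obs$time, probs = seq(0, 1, length.out = n_bins + 1)))
    bin <- as.numeric(cut(design$obs$time, breaks = qs, include.lowest = TRUE))
  }
  # merge small bins with their upper neighbor
  repeat {
    tb <- table(bin)
    small <- names(tb)[tb < 5]
    if (!length(small) || length(tb) == 1L) break
    lv <- sort(as.numeric(names(tb)))
    s <- as.numeric(small[1])
    nb <- if (s == max(lv)) lv[which(lv == s) - 1] else lv[which(lv == s) + 1]
    bin[bin == s] <- nb
  }
  y <- design$obs$y
  sims <- .sim_matrix(model, design, tv, n_sim)
  if (prediction_corrected) {
    keys <- names(model$iiv)
    E0 <- matrix(0, design$n_subjects, length(keys), dimnames = list(NULL, keys))
    pred <- .design_f(design, model, tv, E0)
    corr <- stats::ave(pred, bin, FUN = stats::median) / pred
    y <- y * corr
    sims <- sims * corr
  }
  probs <- c(0.05, 0.5, 0.95)
  rows <- list()
  for (b in sort(unique(bin))) {
    idx <- which(bin == b)
    ob <- stats::quantile(y[idx], probs)
    sq <- apply(sims[idx, , drop = FALSE], 2, stats::quantile, probs = probs)
    ci <- apply(sq, 1, stats::quantile, probs = c(0.025, 0.5, 0.975))
    for (p in seq_along(probs)) {
      rows[[length(rows) + 1L]] <- data.frame(
        bin = b, n = length(idx), stat = paste0("p", 100 * probs[p]),
        observed = ob[p], sim_lower = ci[1, p], sim_median = ci[2, p],
        sim_upper = ci[3, p])
    }
  }
  structure(list(table = do.call(rbind, rows), bin_by = bin_by,
                 prediction_corrected = prediction_corrected, n_sim = n_sim),
            class = "pk_vpc")
}

#' @export
print.pk_vpc <- function(x, ...) {
  cat(sprintf("VPC (%s-binned%s, %d simulations)\n", x$bin_by,
              if (x$prediction_corrected) ", prediction-corrected" else "",
              x$n_sim))
  print(x$table, row.names = FALSE)
  invisible(x)
}
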