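# S3 methods for fitted population models.

#' @export
print.pkfit <- function(x, ...) {
  cat("Population PK fit (FOCE-I):", x$model$name, "\n")
  cat(sprintf("  %d subjects, %d observations, OFV = %.3f%s\n",
              x$n_subjects, x$n_obs, x$ofv,
              if (x$convergence$converged) "" else " (NOT CONVERGED)"))
  cat("  estimates:\n")
  est <- signif(x$estimates, 4)
  for (i in seq_along(est)) {
    cat(sprintf("    %-28s %g\n", names(est)[i], est[i]))
  }
  invisible(x)
}

#' Summary of a population PK fit
#'
#' Tabulates estimates with relative standard errors and, for random-effect
#' and residual SDs, shrinkage — mirroring the conventional PopPK reporting
#' layout (estimate (RSE%) \[shrinkage\]).
#'
#' @param object A [pkfit()] object.
#' @param ... Unused.
#' @return An object of class `summary.pkfit` with a `table` data.frame.
#' @export
summary.pkfit <- function(object, ...) {
  tab <- object$free
  shr <- rep(NA_real_, nrow(tab))
  for (r in seq_len(nrow(tab))) {
    if (tab$kind[r] == "omega") {
      shr[r] <- object$eta_shrinkage[[tab$target[r]]]
    } else if (tab$kind[r] == "sigma") {
      shr[r] <- object$eps_shrinkage[[tab$target[r]]]
    }
  }
  out <- list(table = data.frame(parameter = tab$name,
                                 estimate = unname(object$estimates),
                                 rse_pct = unname(object$rse),
                                 shrinkage_pct = shr),
              ofv = object$ofv, n_subjects = object$n_subjects,
              n_obs = object$n_obs, convergence = object$convergence,
              model = object$model$name)
  class(out) <- "summary.pkfit"
  out
}

#' @export
print.summary.pkfit <- function(x, ...) {
  cat("Population PK fit:", x$model, "\n")
  cat(sprintf("%d subjects, %d observations, OFV = %.3f\n",
              x$n_subjects, x$n_obs, x$ofv))
  tab <- x$table
  tab$estimate <- signif(tab$estimate, 4)
  tab$rse_pct <- round(tab$rse_pct, 1)
  tab$shrinkage_pct <- round(tab$shrinkage_pct, 1)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.pkfit <- function(object, ...) object$estimates

#' @export
logLik.pkfit <- function(object, ...) {
  structure(-object$ofv / 2, df = nrow(object$free),
            nobs = object$n_obs, class = "logLik")
}

#' Predictions from a fitted population model
#'
#' @param object A [pkfit()] object.
#' @param newdata A [pk_cohort()]; defaults to the fitting data.
#' @param ... Unused.
#' @return Data frame `id`, `time`, `analyte`, `obs`, `pred` (population)
#'   and `ipred` (at the conditional modes), ng/mL.
#' @export
predict.pkfit <- function(object, newdata = object$data, ...) {
  parts <- .evaluate_parts(object$model, newdata)
  data.frame(id = parts$id, time = parts$design$obs$time,
             analyte = parts$design$obs$analyte, obs = parts$design$obs$y,
             pred = parts$pred, ipred = parts$ipred)
}

#' Residuals of a fitted population model
#'
#' @param object A [pkfit()] object.
#' @param type `"cwres"` (conditional weighted residuals), `"iwres"`
#'   (individual weighted residuals) or `"pe"` (fractional relative
#'   prediction error at the individual level).
#' @param ... Unused.
#' @return Numeric vector, one element per retained observation.
#' @export
residuals.pkfit <- function(object, type = c("cwres", "iwres", "pe"), ...) {
  type <- match.arg(type)
  parts <- .evaluate_parts(object$model, object$data)
  y <- parts$design$obs$y
  switch(type,
         cwres = parts$cwres,
         iwres = {
           g <- .design_g(parts$design, object$model, parts$ipred)
           (y - parts$ipred) / sqrt(g)
         },
         pe = (parts$ipred - y) / y)
}

#' Simulate replicate observation sets from a fitted model
#'
#' Draws new random effects and residual errors at the design points of the
#' fitting data (a posterior-predictive style replicate per simulation).
#'
#' @param object A [pkfit()] object.
#' @param nsim Number of replicates.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return Data frame with `id`, `time`, `analyte` and columns
#'   `sim_1 ... sim_nsim`, ng/mL.
#' @export
simulate.pkfit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  model <- object$model
  design <- .design_index(.cohort_design(model, object$data))
  covs <- .design_covariates(model, object$data)
  tv <- .typical_by_subject(model, covs, design$n_subjects)
  sims <- .sim_matrix(model, design, tv, nsim)
  colnames(sims) <- paste0("sim_", seq_len(nsim))
  ids <- vapply(object$data$subjects, function(s) s$id, numeric(1))
  cbind(data.frame(id = ids[design$subj_of_obs], time = design$obs$time,
                   analyte = design$obs$analyte), as.data.frame(sims))
}

#' Goodness-of-fit plots for a fitted population model
#'
#' Four base-graphics panels: observations versus population and individual
#' predictions (identity line), and CWRES versus population prediction and
#' time (zero line).
#'
#' @param x A [pkfit()] object.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.pkfit <- function(x, ...) {
  pr <- predict(x)
  cw <- residuals(x, type = "cwres")
  old <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  pchs <- ifelse(pr$analyte == "parent", 1, 2)
  lim <- range(c(pr$obs, pr$pred, pr$ipred))
  graphics::plot(pr$pred, pr$obs, xlab = "PRED (ng/mL)", ylab = "Observed",
                 pch = pchs, xlim = lim, ylim = lim, ...)
  graphics::abline(0, 1, lty = 2)
  graphics::plot(pr$ipred, pr$obs, xlab = "IPRED (ng/mL)", ylab = "Observed",
                 pch = pchs, xlim = lim, ylim = lim, ...)
  graphics::abline(0, 1, lty = 2)
  graphics::plot(pr$pred, cw, xlab = "PRED (ng/mL)", ylab = "CWRES",
                 pch = pchs, ...)
  graphics::abline(h = 0, lty = 2)
  graphics::plot(pr$time, cw, xlab = "Time (h)", ylab = "CWRES",
                 pch = pchs, ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
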