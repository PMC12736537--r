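# Prediction-error metrics, external evaluation, NPDE, CWRES, VPC.

test_that("prediction errors follow their defining identities", {
  # identity prediction
  m0 <- prediction_errors(c(50, 120, 300), c(50, 120, 300))
  expect_equal(m0$mpe, 0)
  expect_equal(m0$rmse, 0)
  expect_equal(m0$median_pe, 0)
  # hand-worked case: symmetric 10% errors cancel in MPE, not in RMSE
  m1 <- prediction_errors(c(100, 100), c(110, 90))
  expect_identical(m1$mpe, 0)
  expect_identical(m1$rmse, 10)
  # constant relative bias
  obs <- c(80, 150, 400)
  m2 <- prediction_errors(obs, 1.5 * obs)
  expect_equal(m2$mpe, 50, tolerance = 1e-12)
  expect_equal(m2$rmse, 50, tolerance = 1e-12)
  # RMSE^2 = MPE^2 + Var(PE) (population variance) on random vectors
  set.seed(601)
  for (r in 1:10) {
    o <- runif(37, 10, 500)
    p <- o * exp(rnorm(37, 0, 0.4))
    m <- prediction_errors(o, p)
    v <- mean((m$pe - mean(m$pe))^2) * 1e4
    expect_equal(m$rmse^2, m$mpe^2 + v, tolerance = 1e-12)
  }
  # zero observations excluded with warning
  expect_warning(mz <- prediction_errors(c(0, 100), c(10, 100)), "excluded")
  expect_equal(mz$n_excluded, 1)
  expect_length(mz$pe, 1)
  expect_error(prediction_errors(1:3, 1:2), "equal length")
})

test_that("self-evaluation with small noise gives near-zero individual error", {
  gen <- builtin_model("M1")
  gen$ruv <- list(parent = c(prop = 0.01, add = 0))
  coh <- generate_cohort(cohort_design(n_subjects = 30, model = gen, seed = 61))
  ev <- external_evaluate(gen, coh)
  expect_lt(abs(ev$metrics$ipred$mpe), 1)
  expect_lt(ev$metrics$ipred$rmse, 2)
  # exactly one prediction-error row per retained observation
  expect_equal(nrow(ev$gof), sum(vapply(coh$subjects,
                                        function(s) sum(!s$obs$blq), numeric(1))))
})

test_that("a misspecified model shows larger population-level bias", {
  coh <- generate_cohort(cohort_design(n_subjects = 60, seed = 62))
  ev_true <- external_evaluate(builtin_model("FINAL"), coh)
  biased <- builtin_model("FINAL")
  biased$typical$cl_parent <- 2 * biased$typical$cl_parent  # halves predictions
  ev_bad <- external_evaluate(biased, coh)
  expect_gt(abs(ev_bad$metrics$pred$median_pe),
            abs(ev_true$metrics$pred$median_pe))
  # individual-level fits absorb the structural shift via the MAP etas, so
  # the misspecification shows at the population level, not the IPRED level
  expect_lt(abs(ev_bad$metrics$ipred$median_pe), 25)
})

test_that("evaluation requires overlapping analytes and substitutes covariates", {
  s <- make_subject(id = 1, obs = trough_obs(100, "metabolite"))
  coh <- pk_cohort(list(s))
  expect_error(external_evaluate(builtin_model("M1"), coh), "overlap")
  # M2 needs weight; a cohort without WT falls back to the recorded default
  s2 <- make_subject(id = 1, obs = trough_obs(c(100, 104), c("parent", "parent"),
                                              times = c(24, 48)))
  s2$covariates$WT <- NULL
  ev <- external_evaluate(builtin_model("M2"), pk_cohort(list(s2, {
    s3 <- make_subject(id = 2, obs = trough_obs(90, "parent")); s3
  })))
  expect_true(all(is.finite(ev$gof$pred)))
})

test_that("npde is reproducible, centred on well-specified data, and calibrated", {
  m1 <- builtin_model("M1")
  coh <- generate_cohort(cohort_design(n_subjects = 50, model = m1, seed = 63))
  r1 <- npde(m1, coh, n_sim = 400, seed = 99)
  r2 <- npde(m1, coh, n_sim = 400, seed = 99)
  expect_identical(r1$npde, r2$npde)
  expect_length(r1$npde, sum(vapply(coh$subjects,
                                    function(s) sum(!s$obs$blq), numeric(1))))
  expect_true(all(r1$pde > 0 & r1$pde < 1))
  # under the true model the pooled npde is near standard normal
  expect_lt(abs(mean(r1$npde)), 0.35)
  expect_gt(var(r1$npde), 0.6)
  expect_lt(var(r1$npde), 1.5)
  # gross inflation of the data is flagged by the location test
  coh2 <- coh
  for (i in seq_along(coh2$subjects)) coh2$subjects[[i]]$obs$dv <-
      2 * coh2$subjects[[i]]$obs$dv
  r3 <- npde(m1, coh2, n_sim = 400, seed = 99)
  expect_lt(r3$tests[["wilcoxon"]], 0.01)
})

test_that("pde converges to the analytic normal CDF value for a fixed subject", {
  # no between-subject variability: the simulated trough distribution is the
  # residual normal, so pde -> Phi((y - f) / sd)
  m <- builtin_model("M1")
  m$iiv <- c(cl_parent = 0)
  p <- individual_parameters(m, covariates = list())
  f <- parent_conc(p, dosing_regimen(20), 24)
  sdv <- m$ruv$parent[["prop"]] * f
  y <- f + 0.7 * sdv
  s <- make_subject(id = 1, dose = 20, obs = trough_obs(y, "parent"))
  r <- npde(m, pk_cohort(list(s)), n_sim = 4000, seed = 7)
  expect_equal(r$pde[1], pnorm(0.7), tolerance = 0.02)
  # an observation at the simulated median scores npde ~ 0
  s0 <- make_subject(id = 1, dose = 20, obs = trough_obs(f, "parent"))
  r0 <- npde(m, pk_cohort(list(s0)), n_sim = 4000, seed = 7)
  expect_lt(abs(r0$npde[1]), 0.05)
})

test_that("cwres is near standard normal under the true model", {
  fin <- builtin_model("FINAL")
  coh <- generate_cohort(cohort_design(n_subjects = 150, seed = 64))
  cw <- cwres(fin, coh)
  expect_equal(nrow(cw), sum(vapply(coh$subjects,
                                    function(s) sum(!s$obs$blq), numeric(1))))
  expect_gt(nrow(cw), 200)
  expect_lt(abs(mean(cw$cwres)), 0.25)
  expect_gt(sd(cw$cwres), 0.8)
  expect_lt(sd(cw$cwres), 1.2)
  # noise-free self-simulated data give vanishing residuals
  gen <- fin
  gen$iiv <- c(cl_parent = 0, cl_metab = 0)
  coh0 <- generate_cohort(cohort_design(n_subjects = 10, model = gen, seed = 65),
                          noise = FALSE)
  cw0 <- cwres(fin, coh0)
  expect_lt(max(abs(cw0$cwres)), 0.05)
})

test_that("vpc percentile bands behave under the true model", {
  fin <- builtin_model("FINAL")
  coh <- generate_cohort(cohort_design(n_subjects = 120, seed = 66))
  v <- vpc(fin, coh, n_sim = 200, seed = 11)
  tab <- v$table
  # ordering of percentiles within every bin
  for (b in unique(tab$bin)) {
    o <- tab$observed[tab$bin == b]
    expect_true(o[1] <= o[2] && o[2] <= o[3])
    ci <- tab[tab$bin == b, ]
    expect_true(all(ci$sim_lower <= ci$sim_median &
                    ci$sim_median <= ci$sim_upper))
  }
  # observed medians covered by the simulated median CI (true model)
  med <- tab[tab$stat == "p50", ]
  covered <- mean(med$observed >= med$sim_lower & med$observed <= med$sim_upper)
  expect_gte(covered, 2 / 3)
  # prediction correction with time bins pools the dose levels: the
  # within-bin spread (p95/p5) shrinks because the dose-driven part of the
  # variability is divided out
  raw_t <- vpc(fin, coh, n_sim = 200, bin_by = "time", seed = 11)
  pc_t <- vpc(fin, coh, n_sim = 200, bin_by = "time",
              prediction_corrected = TRUE, seed = 11)
  b1 <- unique(raw_t$table$bin)[1]
  spread <- function(v, b) {
    t_ <- v$table[v$table$bin == b, ]
    t_$observed[t_$stat == "p95"] / t_$observed[t_$stat == "p5"]
  }
  expect_lt(spread(pc_t, b1), spread(raw_t, b1))
})

test_that("small vpc bins are merged", {
  fin <- builtin_model("FINAL")
  d <- cohort_design(n_subjects = 40, dose_levels = c(20, 40, 60),
                     dose_probs = c(0.9, 0.05, 0.05), seed = 67)
  coh <- generate_cohort(d)
  v <- vpc(fin, coh, n_sim = 200, seed = 12)
  counts <- unique(v$table[, c("bin", "n")])
  expect_true(all(counts$n >= 5))
})
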