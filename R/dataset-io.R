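# NONMEM-style rectangular dataset input/output and structural validation for
# trough-only steady-state TDM data. Compartment coding: 1 depot, 2 parent
# (fluoxetine), 3 metabolite (norfluoxetine). Dose rows are EVID = 1;
# observation rows EVID = 0 with MDV = 0.

.REQUIRED_COLS <- c("ID", "TIME", "AMT", "DV", "CMT", "EVID", "MDV")
.ALL_COLS <- c(.REQUIRED_COLS, "SS", "II", "ADDL", "SEX", "AGE", "WT", "BLQ")

#' Assemble a cohort of subject records
#'
#' @param subjects List of subject records as built by [read_pkdata()] or
#'   [generate_cohort()]: each a list with `id`, `doses` (data.frame `time`,
#'   `amt`, `ii`, `ss`, `addl`), `obs` (data.frame `time`, `analyte`, `dv`,
#'   `blq`) and `covariates` (named list).
#' @param provenance Free-form origin note (file path or generator config).
#' @return An object of class `pk_cohort`.
#' @export
pk_cohort <- function(subjects, provenance = NULL) {
  ids <- vapply(subjects, function(s) as.character(s$id), character(1))
  if (anyDuplicated(ids)) stop("subject ids must be unique", call. = FALSE)
  for (s in subjects) {
    tms <- c(s$doses$time, s$obs$time)
    if (length(tms) && any(tms < 0)) {
      stop("subject ", s$id, ": negative times", call. = FALSE)
    }
    if (nrow(s$doses) && any(s$doses$ss & s$doses$ii <= 0)) {
      stop("subject ", s$id, ": steady-state dose without positive interval",
           call. = FALSE)
    }
    if (nrow(s$obs) && !all(s$obs$analyte %in% c("parent", "metabolite"))) {
      stop("subject ", s$id, ": unknown analyte", call. = FALSE)
    }
  }
  structure(list(subjects = subjects, provenance = provenance),
            class = "pk_cohort")
}

#' @export
print.pk_cohort <- function(x, ...) {
  nobs <- sum(vapply(x$subjects, function(s) nrow(s$obs), integer(1)))
  cat("PK cohort:", length(x$subjects), "subjects,", nobs, "observations\n")
  if (!is.null(x$provenance)) cat("  provenance:", format(x$provenance), "\n")
  invisible(x)
}

#' Read a NONMEM-style CSV dataset
#'
#' Required columns: `ID, TIME, AMT, DV, CMT, EVID, MDV`; recognized optional
#' columns: `SS, II, ADDL, SEX, AGE, WT, BLQ`. Rows with `EVID = 1` become
#' dose events (`SS = 1` with `II` marks steady-state dosing; `ADDL` expands
#' additional doses); rows with `EVID = 0` and `MDV = 0` become observations,
#' with `CMT` 2 mapped to the parent and 3 to the metabolite. Observations
#' below `lloq` are flagged (and by default excluded later from fitting), not
#' dropped.
#'
#' @param path CSV file path.
#' @param lloq Lower limit of quantification, ng/mL (assay default 1).
#' @return A [pk_cohort()].
#' @export
read_pkdata <- function(path, lloq = 1) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.REQUIRED_COLS, names(df))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (cn in intersect(.ALL_COLS, names(df))) {
    if (!is.numeric(df[[cn]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[cn]]))) & !is.na(df[[cn]]))
      if (length(bad)) {
        stop("non-numeric value in column ", cn, " at data row ", bad[1],
             call. = FALSE)
      }
      df[[cn]] <- as.numeric(df[[cn]])
    }
  }
  for (cn in c("SS", "II", "ADDL")) if (is.null(df[[cn]])) df[[cn]] <- 0
  df$.row <- seq_len(nrow(df))
  subjects <- lapply(split(df, factor(df$ID, levels = unique(df$ID))), function(d) {
    dr <- d[d$EVID == 1, , drop = FALSE]
    ob <- d[d$EVID == 0 & d$MDV == 0, , drop = FALSE]
    if (nrow(ob) && !all(ob$CMT %in% c(2, 3))) {
      stop("observation with unknown CMT at data row ",
           ob$.row[which(!ob$CMT %in% c(2, 3))[1]], call. = FALSE)
    }
    blq <- if ("BLQ" %in% names(ob)) ob$BLQ > 0 else ob$DV < lloq
    covs <- list()
    for (cn in c("SEX", "AGE", "WT")) {
      if (!is.null(d[[cn]])) covs[[cn]] <- d[[cn]][1]
    }
    list(id = d$ID[1],
         doses = data.frame(time = dr$TIME, amt = dr$AMT, ii = dr$II,
                            ss = dr$SS > 0, addl = dr$ADDL),
         obs = data.frame(time = ob$TIME,
                          analyte = c("2" = "parent", "3" = "metabolite")[as.character(ob$CMT)],
                          dv = ob$DV, blq = blq, row.names = NULL),
         covariates = covs)
  })
  names(subjects) <- NULL
  pk_cohort(subjects, provenance = path)
}

#' Write a cohort as a NONMEM-style CSV dataset
#'
#' Inverse of [read_pkdata()] on the documented column set.
#'
#' @param cohort A [pk_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pkdata <- function(cohort, path) {
  stopifnot(inherits(cohort, "pk_cohort"))
  rows <- lapply(cohort$subjects, function(s) {
    cv <- function(k) if (!is.null(s$covariates[[k]])) s$covariates[[k]] else NA_real_
    base <- data.frame(ID = s$id, SEX = cv("SEX"), AGE = cv("AGE"), WT = cv("WT"))
    d <- if (nrow(s$doses)) {
      cbind(base, data.frame(TIME = s$doses$time, AMT = s$doses$amt, DV = 0,
                             CMT = 1, EVID = 1, MDV = 1, SS = as.integer(s$doses$ss),
                             II = s$doses$ii, ADDL = s$doses$addl, BLQ = 0))
    }
    o <- if (nrow(s$obs)) {
      cbind(base, data.frame(TIME = s$obs$time, AMT = 0,
                             DV = s$obs$dv,
                             CMT = ifelse(s$obs$analyte == "parent", 2, 3),
                             EVID = 0, MDV = 0, SS = 0, II = 0, ADDL = 0,
                             BLQ = as.integer(s$obs$blq)))
    }
    out <- rbind(d, o)
    out[order(out$TIME, out$EVID == 0), , drop = FALSE]
  })
  df <- do.call(rbind, rows)
  df <- df[, c(.REQUIRED_COLS, "SS", "II", "ADDL", "SEX", "AGE", "WT", "BLQ")]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate the trough-only steady-state structure of a cohort
#'
#' The analysis assumes every observation is a trough drawn at an integer
#' number of dosing intervals after a steady-state (or expanded) dose event.
#' This reports each observation that is not at an interval end, and each
#' subject carrying observations without any dose event.
#'
#' @param cohort A [pk_cohort()].
#' @param tol Absolute time tolerance, h.
#' @return A data.frame of violations (`id`, `time`, `reason`); zero rows for
#'   a conforming cohort.
#' @export
validate_trough_structure <- function(cohort, tol = 1e-6) {
  stopifnot(inherits(cohort, "pk_cohort"))
  out <- list()
  for (s in cohort$subjects) {
    if (!nrow(s$obs)) next
    if (!nrow(s$doses)) {
      out[[length(out) + 1L]] <-
        data.frame(id = s$id, time = NA_real_,
                   reason = "observations without any dose event")
      next
    }
    for (j in seq_len(nrow(s$obs))) {
      t_obs <- s$obs$time[j]
      ok <- FALSE
      for (k in seq_len(nrow(s$doses))) {
        ii <- s$doses$ii[k]
        if (ii <= 0) next
        rel <- t_obs - s$doses$time[k]
        if (rel < ii - tol) next
        mult <- rel / ii
        at_end <- abs(mult - round(mult)) < tol / ii
        within <- s$doses$ss[k] || round(mult) <= s$doses$addl[k] + 1
        if (at_end && within) { ok <- TRUE; break }
      }
      if (!ok) {
        out[[length(out) + 1L]] <-
          data.frame(id = s$id, time = t_obs,
                     reason = "observation not at an interval end")
      }
    }
  }
  if (!length(out)) {
    data.frame(id = numeric(), time = numeric(), reason = character())
  } else {
    do.call(rbind, out)
  }
}

#' Descriptive cohort summary
#'
#' Reports the same descriptive statistics used to characterize trough-only
#' TDM cohorts: size, sex split, median \[range\] age and weight, and
#' per-analyte observation counts and median \[range\] concentrations.
#' Subjects without observations contribute to the demographic but not the
#' concentration summaries.
#'
#' @param cohort A [pk_cohort()].
#' @return A list of class `pk_cohort_summary`.
#' @export
cohort_summary <- function(cohort) {
  stopifnot(inherits(cohort, "pk_cohort"))
  if (!length(cohort$subjects)) stop("empty cohort", call. = FALSE)
  cov <- function(k) {
    vapply(cohort$subjects,
           function(s) if (is.null(s$covariates[[k]])) NA_real_ else s$covariates[[k]],
           numeric(1))
  }
  sex <- cov("SEX")
  obs <- do.call(rbind, lapply(cohort$subjects, function(s) s$obs))
  conc <- lapply(split(obs$dv, obs$analyte), function(v) {
    c(n = length(v), median = stats::median(v), min = min(v), max = max(v))
  })
  mr <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(c(median = NA_real_, min = NA_real_, max = NA_real_))
    c(median = stats::median(v), min = min(v), max = max(v))
  }
  structure(list(n = length(cohort$subjects),
                 n_female = sum(sex == 0, na.rm = TRUE),
                 n_male = sum(sex == 1, na.rm = TRUE),
                 age = mr(cov("AGE")), weight = mr(cov("WT")),
                 concentrations = conc),
            class = "pk_cohort_summary")
}

#' @export
print.pk_cohort_summary <- function(x, ...) {
  cat(sprintf("n = %d (female %d / male %d)\n", x$n, x$n_female, x$n_male))
  cat(sprintf("age    median %.4g [%.4g-%.4g]\n", x$age["median"],
              x$age["min"], x$age["max"]))
  cat(sprintf("weight median %.4g [%.4g-%.4g] kg\n", x$weight["median"],
              x$weight["min"], x$weight["max"]))
  for (an in names(x$concentrations)) {
    v <- x$concentrations[[an]]
    cat(sprintf("%-11s n = %d, median %.4g [%.4g-%.4g] ng/mL\n",
                an, v["n"], v["median"], v["min"], v["max"]))
  }
  invisible(x)
}
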