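# Declarative store of fully parameterized PopPK models: the two published
# fluoxetine models (M1: perinatal women with milk scaling; M2: pediatric,
# weight-linear) and the joint parent-metabolite model with a sex effect on
# parent clearance. A model couples typical values, covariate effects,
# between-subject variability (log-scale SDs) and residual error per analyte.

#' Covariate effect on a PK parameter
#'
#' Three forms are expressible, matching the structures that appear in
#' published fluoxetine models:
#' \describe{
#'   \item{`fractional`}{factor \eqn{(1+\theta)^X} for a 0/1 covariate
#'     (e.g. a 16.5% male shift on clearance: \eqn{\theta = 0.165},
#'     females coded 0, males 1).}
#'   \item{`linear`}{factor \eqn{\theta X} for a strictly positive covariate;
#'     the typical value is then the per-unit coefficient (e.g.
#'     \eqn{CL/F = 0.181 \times BW}).}
#'   \item{`linear_centered`}{factor \eqn{1 + \theta (X - X_{ref})}; equals 1
#'     at the reference covariate value. Used for candidate effects during
#'     stepwise selection.}
#' }
#'
#' @param parameter Name of the target PK parameter (`"cl_parent"` etc.).
#' @param covariate Covariate column name (`"SEX"`, `"WT"`, ...).
#' @param form One of `"fractional"`, `"linear"`, `"linear_centered"`.
#' @param theta Effect magnitude.
#' @param ref Reference covariate value (required for `linear_centered`).
#' @return An object of class `cov_effect`.
#' @export
cov_effect <- function(parameter, covariate,
                       form = c("fractional", "linear", "linear_centered"),
                       theta = 0, ref = NULL) {
  form <- match.arg(form)
  if (form == "linear_centered" && is.null(ref)) {
    stop("linear_centered effects need a reference value 'ref'", call. = FALSE)
  }
  structure(list(parameter = parameter, covariate = covariate, form = form,
                 theta = theta, ref = ref),
            class = "cov_effect")
}

.cov_factor <- function(effect, x) {
  switch(effect$form,
         fractional = {
           if (!all(x %in% c(0, 1))) {
             stop("covariate ", effect$covariate,
                  " must be coded 0/1 for a fractional effect", call. = FALSE)
           }
           (1 + effect$theta)^x
         },
         linear = {
           if (any(x <= 0)) {
             stop("covariate ", effect$covariate,
                  " must be strictly positive for a linear effect", call. = FALSE)
           }
           effect$theta * x
         },
         linear_centered = 1 + effect$theta * (x - effect$ref))
}

#' Construct a PopPK model specification
#'
#' @param name Model identifier.
#' @param structure `"parent"`, `"parent_metabolite"` or `"parent_milk"`.
#' @param typical A [pk_parameters()] object holding typical values at the
#'   reference covariates (for `linear` covariate forms, the per-unit
#'   coefficient).
#' @param fixed Character vector of parameters fixed, not estimated
#'   (conventionally `ka` and `fm`).
#' @param covariates List of [cov_effect()] objects.
#' @param iiv Named numeric vector of between-subject SDs on the log scale
#'   (printed CV% / 100), keyed by parameter name.
#' @param ruv Named list per analyte (`parent`, `metabolite`), each a vector
#'   with elements `prop` (proportional SD as a fraction) and `add` (additive
#'   SD, ng/mL), e.g. `c(prop = 0.341, add = 14.9)`.
#' @param covariate_defaults Named list of central covariate values from the
#'   model's source population, substituted when a covariate is absent from a
#'   dataset under evaluation.
#' @return An object of class `pk_model`.
#' @export
pk_model <- function(name, structure = c("parent", "parent_metabolite", "parent_milk"),
                     typical, fixed = c("ka", "fm"), covariates = list(),
                     iiv = numeric(), ruv = list(),
                     covariate_defaults = list()) {
  structure <- match.arg(structure)
  stopifnot(inherits(typical, "pk_parameters"))
  if (any(unlist(iiv) < 0)) stop("IIV SDs must be >= 0", call. = FALSE)
  bad <- setdiff(names(iiv), names(typical))
  if (length(bad)) stop("IIV keys do not name parameters: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  for (an in names(ruv)) {
    if (all(ruv[[an]] <= 0)) {
      stop("analyte ", an, " needs at least one nonzero residual component",
           call. = FALSE)
    }
  }
  analytes <- if (structure == "parent_metabolite") c("parent", "metabolite") else "parent"
  obj <- list(name = name, structure = structure, typical = typical,
              fixed = fixed, covariates = covariates, iiv = iiv, ruv = ruv,
              covariate_defaults = covariate_defaults, analytes = analytes)
  class(obj) <- "pk_model"
  obj
}

#' @export
print.pk_model <- function(x, ...) {
  cat("PopPK model:", x$name, "(", x$structure, ")\n")
  tv <- unlist(x$typical)
  tv <- tv[!is.na(tv)]
  cat("  typical values:",
      paste(names(tv), signif(tv, 4), sep = " = ", collapse = ", "), "\n")
  if (length(x$covariates)) {
    for (ce in x$covariates) {
      cat("  covariate:", ce$covariate, "on", ce$parameter,
          sprintf("(%s, theta = %g)\n", ce$form, ce$theta))
    }
  }
  if (length(x$iiv)) {
    cat("  IIV (log-SD):",
        paste(names(x$iiv), signif(unlist(x$iiv), 3), sep = " = ",
              collapse = ", "), "\n")
  }
  for (an in names(x$ruv)) {
    cat(sprintf("  residual (%s): prop %.1f%%, add %.1f ng/mL\n",
                an, 100 * x$ruv[[an]]["prop"], x$ruv[[an]]["add"]))
  }
  invisible(x)
}

#' Built-in fluoxetine PopPK models
#'
#' Returns one of the three shipped parameterizations:
#' \describe{
#'   \item{`M1`}{Perinatal one-compartment model: CL/F 8.42 L/h, V/F 690 L,
#'     ka 0.3/h fixed, milk-to-plasma ratio 0.59; IIV 38% on CL and 32% on
#'     MPR; 8% proportional residual error in plasma.}
#'   \item{`M2`}{Pediatric weight-linear model: CL/F = 0.181 x BW L/h,
#'     V/F = 37.4 x BW L, ka 0.666/h fixed; IIV 52% on CL, 20.5% on V; 18%
#'     proportional residual error.}
#'   \item{`FINAL`}{Joint parent-metabolite model: CL_P/F 2.91 L/h with a
#'     +16.5% male shift, V_P/F 24.9 L, ka 0.3/h fixed, CL_M/F 3.24 L/h,
#'     V_M/F 1.52 L, FM fixed at 1; IIV 31.6% (CL_P) and 20.9% (CL_M);
#'     combined residual error 34.1% + 14.9 ng/mL (parent) and
#'     30.5% + 22.9 ng/mL (metabolite). Sex coded female = 0, male = 1.}
#' }
#'
#' @param name One of `"M1"`, `"M2"`, `"FINAL"`.
#' @return A [pk_model()] object.
#' @examples
#' builtin_model("FINAL")
#' @export
builtin_model <- function(name) {
  switch(toupper(name),
    M1 = pk_model(
      name = "M1", structure = "parent_milk",
      typical = pk_parameters(cl_parent = 8.42, v_parent = 690, ka = 0.3,
                              mpr = 0.59),
      fixed = c("ka"),
      iiv = c(cl_parent = 0.38, mpr = 0.32),
      ruv = list(parent = c(prop = 0.08, add = 0))),
    M2 = pk_model(
      name = "M2", structure = "parent",
      typical = pk_parameters(cl_parent = 0.181, v_parent = 37.4, ka = 0.666),
      fixed = c("ka"),
      covariates = list(cov_effect("cl_parent", "WT", "linear", theta = 1),
                        cov_effect("v_parent", "WT", "linear", theta = 1)),
      iiv = c(cl_parent = 0.52, v_parent = 0.205),
      ruv = list(parent = c(prop = 0.18, add = 0)),
      covariate_defaults = list(WT = 53.6)),
    FINAL = pk_model(
      name = "FINAL", structure = "parent_metabolite",
      typical = pk_parameters(cl_parent = 2.91, v_parent = 24.9, ka = 0.3,
                              cl_metab = 3.24, v_metab = 1.52, fm = 1),
      fixed = c("ka", "fm"),
      covariates = list(cov_effect("cl_parent", "SEX", "fractional",
                                   theta = 0.165)),
      iiv = c(cl_parent = 0.316, cl_metab = 0.209),
      ruv = list(parent = c(prop = 0.341, add = 14.9),
                 metabolite = c(prop = 0.305, add = 22.9)),
      covariate_defaults = list(SEX = 0)),
    stop("unknown model '", name, "'; available: M1, M2, FINAL", call. = FALSE))
}

#' Individual PK parameters from covariates and random effects
#'
#' Applies the model's covariate effects and exponential random effects to the
#' typical values: \eqn{P_i = TV_P \cdot \prod_c f_c(x_i) \cdot e^{\eta_P}}.
#' Parameters without IIV pass through at their covariate-adjusted typical
#' value. Covariates a model does not use are accepted and ignored; a
#' covariate the model needs but the data lack is substituted from the model's
#' `covariate_defaults` when available, otherwise an error names it.
#'
#' @param model A [pk_model()].
#' @param covariates Named list/vector of covariate values (`SEX`, `WT`, ...).
#' @param eta Named numeric vector of log-scale deviations; names must be a
#'   subset of the model's IIV keys. Default: all zero.
#' @return A [pk_parameters()] object.
#' @examples
#' individual_parameters(builtin_model("FINAL"), covariates = list(SEX = 1))
#' @export
individual_parameters <- function(model, covariates = list(), eta = numeric()) {
  stopifnot(inherits(model, "pk_model"))
  if (length(eta)) {
    bad <- setdiff(names(eta), names(model$iiv))
    if (length(bad)) stop("eta keys not in model IIV: ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  vals <- unclass(model$typical)
  for (ce in model$covariates) {
    x <- covariates[[ce$covariate]]
    if (is.null(x) || is.na(x)) x <- model$covariate_defaults[[ce$covariate]]
    if (is.null(x)) {
      stop("covariate '", ce$covariate, "' required by model ", model$name,
           " is missing and has no default", call. = FALSE)
    }
    vals[[ce$parameter]] <- vals[[ce$parameter]] * .cov_factor(ce, x)
  }
  for (k in names(eta)) vals[[k]] <- vals[[k]] * exp(eta[[k]])
  do.call(pk_parameters, vals[c("cl_parent", "v_parent", "ka", "cl_metab",
                                "v_metab", "fm", "mpr")])
}

#' Breast-milk concentration via the milk-to-plasma ratio
#'
#' @param plasma Plasma concentration(s), ng/mL.
#' @param model A [pk_model()] carrying an MPR (e.g. `builtin_model("M1")`).
#' @return Milk concentration(s), ng/mL (`plasma * MPR`).
#' @export
milk_concentration <- function(plasma, model) {
  stopifnot(inherits(model, "pk_model"))
  if (is.na(model$typical$mpr)) {
    stop("model ", model$name, " has no milk-to-plasma ratio", call. = FALSE)
  }
  plasma * model$typical$mpr
}

#' Write / read a model specification as YAML
#'
#' Serialization round-trips losslessly: `read_model(write_model(m, f))`
#' reproduces `m` field for field.
#'
#' @param model A [pk_model()].
#' @param path File path.
#' @return `write_model` returns `path` invisibly; `read_model` a
#'   [pk_model()].
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "pk_model"))
  doc <- list(
    name = model$name, structure = model$structure,
    typical = lapply(unclass(model$typical), function(v) if (is.na(v)) NULL else v),
    fixed = as.list(model$fixed),
    covariates = lapply(model$covariates, function(ce) {
      out <- list(parameter = ce$parameter, covariate = ce$covariate,
                  form = ce$form, theta = ce$theta)
      if (!is.null(ce$ref)) out$ref <- ce$ref
      out
    }),
    iiv = as.list(model$iiv),
    ruv = lapply(model$ruv, as.list),
    covariate_defaults = model$covariate_defaults)
  writeLines(yaml::as.yaml(doc, precision = 12), path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  doc <- yaml::read_yaml(path)
  tv <- doc$typical
  typical <- pk_parameters(
    cl_parent = tv$cl_parent, v_parent = tv$v_parent, ka = tv$ka,
    cl_metab = if (is.null(tv$cl_metab)) NA_real_ else tv$cl_metab,
    v_metab = if (is.null(tv$v_metab)) NA_real_ else tv$v_metab,
    fm = if (is.null(tv$fm)) NA_real_ else tv$fm,
    mpr = if (is.null(tv$mpr)) NA_real_ else tv$mpr)
  covs <- lapply(doc$covariates, function(ce) {
    cov_effect(ce$parameter, ce$covariate, ce$form, ce$theta,
               ref = ce$ref)
  })
  pk_model(name = doc$name, structure = doc$structure, typical = typical,
           fixed = unlist(doc$fixed), covariates = covs,
           iiv = unlist(doc$iiv),
           ruv = lapply(doc$ruv, function(r) unlist(r)),
           covariate_defaults = doc$covariate_defaults)
}
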