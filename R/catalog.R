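#' @importFrom rlang abort %||%
NULL

# Bounds by parameter kind. All parameters are constrained to be
# non-negative; the fractional contribution beta lives in [0, 1].
# Upper bounds are generous scale-based boxes for the bounded optimizer:
# amplitudes in %IA cannot plausibly exceed 1e4, clearance rates 100 /h.
param_bounds <- function(name) {
  if (name == "beta") return(c(0, 1))
  if (grepl("^A", name)) return(c(0, 1e4))
  c(0, 100) # lambda-type
}

new_model_spec <- function(model_id, per_patient_params, shared_param,
                           eval_fn, tia_fn, formula_str, tia_str,
                           fixed_constants = list()) {
  params <- c(per_patient_params, shared_param)
  bounds <- lapply(stats::setNames(params, params), param_bounds)
  structure(
    list(
      model_id = model_id,
      per_patient_params = per_patient_params,
      shared_param = shared_param, # NULL if none
      params_per_patient = length(per_patient_params),
      fixed_constants = fixed_constants,
      bounds = bounds,
      eval_fn = eval_fn,
      tia_fn = tia_fn,
      formula_str = formula_str,
      tia_str = tia_str
    ),
    class = "pbms_model"
  )
}

#' @export
print.pbms_model <- function(x, ...) {
  shared <- if (is.null(x$shared_param)) "none" else x$shared_param
  cat(sprintf("<pbms_model> %s: f(t) = %s\n", x$model_id, x$formula_str))
  cat(sprintf("  per-patient parameters: %s; shared: %s\n",
              paste(x$per_patient_params, collapse = ", "), shared))
  cat(sprintf("  TIA = %s\n", x$tia_str))
  invisible(x)
}

#' Catalog of exponential time-activity fit functions
#'
#' Builds the fixed 20-entry catalog of mono- and bi-exponential fit
#' functions used for population-based (PBMS) and individual-based (IBMS)
#' model selection. Every function carries the physical decay
#' \eqn{\lambda_{phys}} as an explicit factor, so all fitted rates
#' \eqn{\lambda_i \ge 0} are biological clearance rates. The six `S`
#' variants are population models derived from `f3a` in which one
#' parameter is shared (estimated once for the whole population).
#'
#' Activity is expressed in percent of injected activity (%IA); the
#' literal prefactor 100 appearing in `f2a`, `f2e`, `f3c` and `f2c3d`
#' pins the curve scale to 100 %IA.
#'
#' @return A named list of 20 `pbms_model` objects in catalog order:
#'   f2a, f2b, f2c, f2d, f2e, f3a, f3b, f3c, f3d, f2a3d, f2b3d, f2c3d,
#'   f3aS1, f3aS2, f3aS3, f3aS4, f3aS5, f3aS6, f1, f4.
#' @seealso [get_model()], [catalog_table()], [closed_form_tia()]
#' @examples
#' cat20 <- model_catalog()
#' length(cat20)
#' cat20$f3aS4
#' @export
model_catalog <- function() {
  e <- function(rate, t) exp(-rate * t)

  models <- list(
    new_model_spec(
      "f2a", c("lambda1", "lambda2"), NULL,
      function(p, lp, t) 100 * e(p[["lambda1"]] + lp, t) - 100 * e(p[["lambda2"]] + lp, t),
      function(p, lp) 100 / (p[["lambda1"]] + lp) - 100 / (p[["lambda2"]] + lp),
      "100 exp(-(lambda1+lphys) t) - 100 exp(-(lambda2+lphys) t)",
      "100/(lambda1+lphys) - 100/(lambda2+lphys)",
      fixed_constants = list(A = 100)
    ),
    new_model_spec(
      "f2b", c("A1", "lambda1"), NULL,
      function(p, lp, t) p[["A1"]] * e(p[["lambda1"]] + lp, t),
      function(p, lp) p[["A1"]] / (p[["lambda1"]] + lp),
      "A1 exp(-(lambda1+lphys) t)",
      "A1/(lambda1+lphys)"
    ),
    new_model_spec(
      "f2c", c("A1", "lambda1"), NULL,
      function(p, lp, t) p[["A1"]] * e(p[["lambda1"]] + lp, t) - p[["A1"]] * e(lp, t),
      function(p, lp) p[["A1"]] / (p[["lambda1"]] + lp) - p[["A1"]] / lp,
      "A1 exp(-(lambda1+lphys) t) - A1 exp(-lphys t)",
      "A1/(lambda1+lphys) - A1/lphys"
    ),
    new_model_spec(
      "f2d", c("A1", "lambda1"), NULL,
      function(p, lp, t) -p[["A1"]] * e(p[["lambda1"]] + lp, t) + p[["A1"]] * e(lp, t),
      function(p, lp) p[["A1"]] / lp - p[["A1"]] / (p[["lambda1"]] + lp),
      "-A1 exp(-(lambda1+lphys) t) + A1 exp(-lphys t)",
      "A1/lphys - A1/(lambda1+lphys)"
    ),
    new_model_spec(
      "f2e", c("A1", "lambda1"), NULL,
      function(p, lp, t) p[["A1"]] * e(p[["lambda1"]] + lp, t) + (100 - p[["A1"]]) * e(lp, t),
      function(p, lp) p[["A1"]] / (p[["lambda1"]] + lp) + (100 - p[["A1"]]) / lp,
      "A1 exp(-(lambda1+lphys) t) + (100-A1) exp(-lphys t)",
      "A1/(lambda1+lphys) + (100-A1)/lphys",
      fixed_constants = list(total = 100)
    ),
    new_model_spec(
      "f3a", c("A1", "lambda1", "A2"), NULL,
      function(p, lp, t) p[["A1"]] * e(p[["lambda1"]] + lp, t) + p[["A2"]] * e(lp, t),
      function(p, lp) p[["A1"]] / (p[["lambda1"]] + lp) + p[["A2"]] / lp,
      "A1 exp(-(lambda1+lphys) t) + A2 exp(-lphys t)",
      "A1/(lambda1+lphys) + A2/lphys"
    ),
    new_model_spec(
      "f3b", c("A1", "lambda1", "lambda2"), NULL,
      function(p, lp, t) p[["A1"]] * e(p[["lambda1"]] + lp, t) - p[["A1"]] * e(p[["lambda2"]] + lp, t),
      function(p, lp) p[["A1"]] / (p[["lambda1"]] + lp) - p[["A1"]] / (p[["lambda2"]] + lp),
      "A1 exp(-(lambda1+lphys) t) - A1 exp(-(lambda2+lphys) t)",
      "A1/(lambda1+lphys) - A1/(lambda2+lphys)"
    ),
    new_model_spec(
      "f3c", c("A1", "lambda1", "lambda2"), NULL,
      function(p, lp, t) p[["A1"]] * e(p[["lambda1"]] + lp, t) + (100 - p[["A1"]]) * e(p[["lambda2"]] + lp, t),
      function(p, lp) p[["A1"]] / (p[["lambda1"]] + lp) + (100 - p[["A1"]]) / (p[["lambda2"]] + lp),
      "A1 exp(-(lambda1+lphys) t) + (100-A1) exp(-(lambda2+lphys) t)",
      "A1/(lambda1+lphys) + (100-A1)/(lambda2+lphys)",
      fixed_constants = list(total = 100)
    ),
    # Degenerate-eigenvalue family: note the extra factor t on the first term.
    new_model_spec(
      "f3d", c("A1", "lambda1", "A2"), NULL,
      function(p, lp, t) p[["A1"]] * t * e(p[["lambda1"]] + lp, t) + p[["A2"]] * e(p[["lambda1"]] + lp, t),
      function(p, lp) p[["A1"]] / (p[["lambda1"]] + lp)^2 + p[["A2"]] / (p[["lambda1"]] + lp),
      "A1 t exp(-(lambda1+lphys) t) + A2 exp(-(lambda1+lphys) t)",
      "A1/(lambda1+lphys)^2 + A2/(lambda1+lphys)"
    ),
    new_model_spec(
      "f2a3d", c("A1", "A2"), NULL,
      function(p, lp, t) p[["A1"]] * t * e(lp, t) + p[["A2"]] * e(lp, t),
      function(p, lp) p[["A1"]] / lp^2 + p[["A2"]] / lp,
      "A1 t exp(-lphys t) + A2 exp(-lphys t)",
      "A1/lphys^2 + A2/lphys"
    ),
    new_model_spec(
      "f2b3d", c("A1", "lambda1"), NULL,
      function(p, lp, t) p[["A1"]] * t * e(p[["lambda1"]] + lp, t),
      function(p, lp) p[["A1"]] / (p[["lambda1"]] + lp)^2,
      "A1 t exp(-(lambda1+lphys) t)",
      "A1/(lambda1+lphys)^2"
    ),
    new_model_spec(
      "f2c3d", c("A1", "lambda1"), NULL,
      function(p, lp, t) p[["A1"]] * t * e(p[["lambda1"]] + lp, t) + 100 * e(p[["lambda1"]] + lp, t),
      function(p, lp) p[["A1"]] / (p[["lambda1"]] + lp)^2 + 100 / (p[["lambda1"]] + lp),
      "A1 t exp(-(lambda1+lphys) t) + 100 exp(-(lambda1+lphys) t)",
      "A1/(lambda1+lphys)^2 + 100/(lambda1+lphys)",
      fixed_constants = list(A = 100)
    ),
    # Shared-parameter variants of f3a (population models).
    new_model_spec(
      "f3aS1", c("lambda1", "A2"), "A1",
      function(p, lp, t) p[["A1"]] * e(p[["lambda1"]] + lp, t) + p[["A2"]] * e(lp, t),
      function(p, lp) p[["A1"]] / (p[["lambda1"]] + lp) + p[["A2"]] / lp,
      "A1 exp(-(lambda1+lphys) t) + A2 exp(-lphys t), shared A1",
      "A1/(lambda1+lphys) + A2/lphys"
    ),
    new_model_spec(
      "f3aS2", c("A1", "A2"), "lambda1",
      function(p, lp, t) p[["A1"]] * e(p[["lambda1"]] + lp, t) + p[["A2"]] * e(lp, t),
      function(p, lp) p[["A1"]] / (p[["lambda1"]] + lp) + p[["A2"]] / lp,
      "A1 exp(-(lambda1+lphys) t) + A2 exp(-lphys t), shared lambda1",
      "A1/(lambda1+lphys) + A2/lphys"
    ),
    new_model_spec(
      "f3aS3", c("A1", "lambda1"), "A2",
      function(p, lp, t) p[["A1"]] * e(p[["lambda1"]] + lp, t) + p[["A2"]] * e(lp, t),
      function(p, lp) p[["A1"]] / (p[["lambda1"]] + lp) + p[["A2"]] / lp,
      "A1 exp(-(lambda1+lphys) t) + A2 exp(-lphys t), shared A2",
      "A1/(lambda1+lphys) + A2/lphys"
    ),
    new_model_spec(
      "f3aS4", c("A1", "lambda1"), "beta",
      function(p, lp, t) {
        p[["A1"]] * p[["beta"]] * e(p[["lambda1"]] + lp, t) +
          p[["A1"]] * (1 - p[["beta"]]) * e(lp, t)
      },
      function(p, lp) {
        p[["A1"]] * p[["beta"]] / (p[["lambda1"]] + lp) +
          p[["A1"]] * (1 - p[["beta"]]) / lp
      },
      "A1 beta exp(-(lambda1+lphys) t) + A1 (1-beta) exp(-lphys t), shared beta",
      "A1*beta/(lambda1+lphys) + A1*(1-beta)/lphys"
    ),
    new_model_spec(
      "f3aS5", c("lambda1", "beta"), "A1",
      function(p, lp, t) {
        p[["A1"]] * p[["beta"]] * e(p[["lambda1"]] + lp, t) +
          p[["A1"]] * (1 - p[["beta"]]) * e(lp, t)
      },
      function(p, lp) {
        p[["A1"]] * p[["beta"]] / (p[["lambda1"]] + lp) +
          p[["A1"]] * (1 - p[["beta"]]) / lp
      },
      "A1 beta exp(-(lambda1+lphys) t) + A1 (1-beta) exp(-lphys t), shared A1",
      "A1*beta/(lambda1+lphys) + A1*(1-beta)/lphys"
    ),
    new_model_spec(
      "f3aS6", c("A1", "beta"), "lambda1",
      function(p, lp, t) {
        p[["A1"]] * p[["beta"]] * e(p[["lambda1"]] + lp, t) +
          p[["A1"]] * (1 - p[["beta"]]) * e(lp, t)
      },
      function(p, lp) {
        p[["A1"]] * p[["beta"]] / (p[["lambda1"]] + lp) +
          p[["A1"]] * (1 - p[["beta"]]) / lp
      },
      "A1 beta exp(-(lambda1+lphys) t) + A1 (1-beta) exp(-lphys t), shared lambda1",
      "A1*beta/(lambda1+lphys) + A1*(1-beta)/lphys"
    ),
    new_model_spec(
      "f1", "A1", NULL,
      function(p, lp, t) p[["A1"]] * e(lp, t),
      function(p, lp) p[["A1"]] / lp,
      "A1 exp(-lphys t)",
      "A1/lphys"
    ),
    new_model_spec(
      "f4", c("A1", "lambda1", "A2", "lambda2"), NULL,
      function(p, lp, t) p[["A1"]] * e(p[["lambda1"]] + lp, t) + p[["A2"]] * e(p[["lambda2"]] + lp, t),
      function(p, lp) p[["A1"]] / (p[["lambda1"]] + lp) + p[["A2"]] / (p[["lambda2"]] + lp),
      "A1 exp(-(lambda1+lphys) t) + A2 exp(-(lambda2+lphys) t)",
      "A1/(lambda1+lphys) + A2/(lambda2+lphys)"
    )
  )
  stats::setNames(models, vapply(models, `[[`, "", "model_id"))
}

#' Look up one catalog model
#'
#' @param model A model id string (e.g. `"f3aS4"`) or a `pbms_model` object,
#'   which is returned unchanged.
#' @return A `pbms_model` object.
#' @examples
#' get_model("f2b")
#' @export
get_model <- function(model) {
  if (inherits(model, "pbms_model")) return(model)
  if (!is.character(model) || length(model) != 1L) {
    abort("`model` must be a single model id string or a <pbms_model>.")
  }
  cat20 <- model_catalog()
  if (!model %in% names(cat20)) {
    abort(sprintf("Unknown model id '%s'. Known ids: %s.",
                  model, paste(names(cat20), collapse = ", ")))
  }
  cat20[[model]]
}

#' Tabular view of the model catalog
#'
#' @return A tibble with one row per catalog model: id, number of parameters
#'   per patient, shared parameter (NA if none), and the function and TIA
#'   formulas as strings.
#' @examples
#' catalog_table()
#' @export
catalog_table <- function() {
  cat20 <- model_catalog()
  tibble::tibble(
    model_id = names(cat20),
    params_per_patient = vapply(cat20, `[[`, 0L, "params_per_patient"),
    per_patient_params = vapply(cat20, function(m) paste(m$per_patient_params, collapse = ","), ""),
    shared_param = vapply(cat20, function(m) m$shared_param %||% NA_character_, ""),
    formula = vapply(cat20, `[[`, "", "formula_str"),
    tia_formula = vapply(cat20, `[[`, "", "tia_str")
  )
}

#' Write a machine-readable catalog dump
#'
#' Serializes the catalog (parameters, bounds, shared parameter, formula and
#' TIA strings) as JSON, e.g. for downstream tooling or configuration UIs.
#'
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_catalog_json <- function(path) {
  cat20 <- model_catalog()
  dump <- lapply(cat20, function(m) {
    list(
      model_id = m$model_id,
      per_patient_params = as.list(m$per_patient_params),
      shared_param = m$shared_param,
      params_per_patient = m$params_per_patient,
      fixed_constants = m$fixed_constants,
      bounds = m$bounds,
      formula = m$formula_str,
      tia_formula = m$tia_str
    )
  })
  jsonlite::write_json(dump, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# Validates a named parameter vector/list against a model's requirements.
# Returns the parameters as a named numeric vector in catalog order.
check_params <- function(model, params) {
  needed <- c(model$per_patient_params, model$shared_param)
  params <- unlist(params)
  missing <- setdiff(needed, names(params))
  if (length(missing) > 0) {
    abort(sprintf("Model %s: missing parameter(s) %s.",
                  model$model_id, paste(missing, collapse = ", ")))
  }
  params <- params[needed]
  for (nm in needed) {
    b <- model$bounds[[nm]]
    v <- params[[nm]]
    if (!is.finite(v) || v < b[1] || v > b[2]) {
      abort(sprintf("Model %s: parameter %s = %g outside bounds [%g, %g].",
                    model$model_id, nm, v, b[1], b[2]))
    }
  }
  params
}

#' Evaluate a catalog model
#'
#' Computes the model activity (in %IA) at times `t` for a given named
#' parameter set, including the physical-decay factor.
#'
#' @param model Model id or `pbms_model`.
#' @param params Named numeric vector or list containing all per-patient
#'   parameters and, if the model has one, the shared parameter.
#' @param t Times in hours post-injection (vectorized), `t >= 0`.
#' @param decay A [radionuclide()] object; default [lu177()].
#' @return Numeric vector of activities (%IA), same length as `t`.
#' @examples
#' evaluate_model("f2b", c(A1 = 12, lambda1 = 0.02), t = c(0, 24, 96))
#' @export
evaluate_model <- function(model, params, t, decay = lu177()) {
  model <- get_model(model)
  decay <- as_decay(decay)
  if (any(t < 0)) abort("`t` must be non-negative (hours post-injection).")
  params <- check_params(model, params)
  model$eval_fn(params, decay$lambda_phys, t)
}

#' Number of adjustable parameters K of a model for a population
#'
#' For a population of `n_patients` patients,
#' `K = params_per_patient * n_patients + 1` if the model has a shared
#' parameter (estimated once for the whole population), otherwise
#' `K = params_per_patient * n_patients`.
#'
#' @inheritParams evaluate_model
#' @param n_patients Number of patients jointly fitted (>= 1).
#' @return Integer K.
#' @examples
#' count_parameters("f2b", 13)   # 26
#' count_parameters("f3aS4", 13) # 26 + 1 = 27
#' @export
count_parameters <- function(model, n_patients) {
  model <- get_model(model)
  if (!is.numeric(n_patients) || length(n_patients) != 1L || n_patients < 1) {
    abort("`n_patients` must be a single integer >= 1.")
  }
  as.integer(model$params_per_patient * n_patients + !is.null(model$shared_param))
}

#' Closed-form time-integrated activity (TIA)
#'
#' Integrates the model analytically from zero to infinity using
#' \eqn{\int_0^\infty A e^{-\lambda t} dt = A/\lambda} and
#' \eqn{\int_0^\infty A t e^{-\lambda t} dt = A/\lambda^2}. The result has
#' units %IA·h; dividing by 100 and multiplying by the injected activity
#' converts to MBq·h (the number of disintegrations up to a unit constant).
#'
#' @inheritParams evaluate_model
#' @return TIA in %IA·h.
#' @examples
#' closed_form_tia("f1", c(A1 = 100), decay = radionuclide(log(2) / 0.01))
#' @export
closed_form_tia <- function(model, params, decay = lu177()) {
  model <- get_model(model)
  decay <- as_decay(decay)
  params <- check_params(model, params)
  lp <- decay$lambda_phys
  rates <- lp + c(0, params[grepl("^lambda", names(params))])
  if (any(rates <= 0)) {
    abort(sprintf("Model %s: non-positive effective decay rate; the integral diverges.",
                  model$model_id))
  }
  unname(model$tia_fn(params, lp))
}
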