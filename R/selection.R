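#' Corrected Akaike Information Criterion
#'
#' \eqn{AICc = -2\ln L + 2K + 2K(K+1)/(N-K-1)}, the small-sample correction
#' appropriate when the ratio of data points N to parameters K is low
#' (N/K < 40), as is typical for sparse time-activity curves.
#'
#' @param minus2lnL Value of the minimized -2 log-likelihood.
#' @param k Number of adjustable parameters.
#' @param n Number of data points.
#' @return AICc value.
#' @examples
#' aicc(0, k = 27, n = 46)  # 138: the correction term dominates at N/K ~ 1.7
#' @export
aicc <- function(minus2lnL, k, n) {
  if (n - k - 1 < 1) {
    abort(sprintf("AICc undefined: need N - K - 1 >= 1, got N = %d, K = %d.", n, k))
  }
  minus2lnL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights
#'
#' Normalized model evidence: \eqn{\Delta_i = AICc_i - AICc_{min}},
#' \eqn{w_i = e^{-\Delta_i/2} / \sum_j e^{-\Delta_j/2}}. Computed with the
#' minimum shifted out first so large AICc values cannot underflow the
#' normalization. A weight is read as the probability that model i is the
#' best of the considered set.
#'
#' @param aicc_values Numeric vector of finite AICc values.
#' @return Numeric vector of weights summing to 1.
#' @examples
#' akaike_weights(c(100, 102))  # 0.731, 0.269
#' @export
akaike_weights <- function(aicc_values) {
  if (length(aicc_values) == 0 || any(!is.finite(aicc_values))) {
    abort("`aicc_values` must be a non-empty vector of finite values.")
  }
  d <- aicc_values - min(aicc_values)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Feasibility of a model for a given amount of data
#'
#' AICc requires at least \eqn{N - K - 1 \ge 1}, i.e. the largest usable
#' model has \eqn{K_{max} = N - 2} parameters. A model is feasible for a
#' dataset when its total parameter count does not exceed that.
#'
#' @inheritParams count_parameters
#' @param n_obs Total number of data points N.
#' @return `TRUE` if `count_parameters(model, n_patients) <= n_obs - 2`.
#' @examples
#' is_feasible("f4", n_obs = 46, n_patients = 13)  # K = 52 > 44: FALSE
#' @export
is_feasible <- function(model, n_obs, n_patients) {
  count_parameters(model, n_patients) <= n_obs - 2
}

#' Goodness-of-fit gate thresholds
#'
#' @param cv_max Largest acceptable parameter coefficient of variation
#'   (default 0.5).
#' @param corr_max Fail when any off-diagonal correlation reaches this
#'   absolute value (default 0.90; the nominal guideline is |r| < 0.8 for
#'   most elements, with values only slightly above 0.8 tolerated).
#' @param resid_max Largest acceptable |standardized residual| for the
#'   automated curve-shape check (default 4).
#' @return A list of class `pbms_gof_control`.
#' @export
gof_control <- function(cv_max = 0.5, corr_max = 0.90, resid_max = 4) {
  stopifnot(cv_max > 0, corr_max > 0, resid_max > 0)
  structure(list(cv_max = cv_max, corr_max = corr_max, resid_max = resid_max),
            class = "pbms_gof_control")
}

# Largest |off-diagonal| correlations of a fit, sorted decreasing.
top_correlations <- function(corr, n_top = 3) {
  if (is.null(corr) || nrow(corr) < 2) return(numeric(0))
  v <- abs(corr[lower.tri(corr)])
  v <- v[is.finite(v)]
  utils::head(sort(v, decreasing = TRUE), n_top)
}

#' Goodness-of-fit gate for a fitted model
#'
#' Screens a fit before model selection:
#' * `cv_pass` — every parameter CV (SD/|estimate|) below `cv_max`;
#' * `corr_pass` — no off-diagonal parameter correlation with
#'   |r| >= `corr_max`;
#' * `shape_pass` — automated stand-in for visual inspection: the fitted
#'   curve is non-negative over `[0, 2 x last sample time]` for every
#'   patient and no standardized residual exceeds `resid_max` in absolute
#'   value;
#' * a degenerate (singular) information matrix fails the gate outright.
#'
#' @param fit A `pbms_fit`.
#' @param control A [gof_control()] list.
#' @return A list of class `pbms_gof`: flags, `cv_max` observed, the three
#'   largest |off-diagonal| correlations, `verdict` (`"pass"`/`"fail"`) and
#'   `reasons` (character vector of reason codes, empty on pass).
#' @export
goodness_of_fit <- function(fit, control = gof_control()) {
  stopifnot(inherits(fit, "pbms_fit"))
  cvs <- fit$parameters$cv
  cv_obs <- if (length(cvs)) max(cvs) else 0
  top3 <- top_correlations(fit$correlation)

  cv_pass <- is.finite(cv_obs) && cv_obs < control$cv_max
  corr_pass <- length(top3) == 0 || max(top3) < control$corr_max

  shape_pass <- TRUE
  model <- get_model(fit$model_id)
  for (id in unique(fit$data$patient_id)) {
    d <- fit$data[fit$data$patient_id == id, ]
    grid <- seq(0, 2 * max(d$time_h), length.out = 201)
    p <- patient_param_vector(fit, id)
    f <- model$eval_fn(p, fit$decay$lambda_phys, grid)
    if (any(f < -1e-9)) { shape_pass <- FALSE; break }
  }
  if (shape_pass && any(abs(fit$fitted$std_resid) > control$resid_max)) {
    shape_pass <- FALSE
  }

  degenerate <- isTRUE(fit$degenerate) || !isTRUE(fit$converged)
  flags <- list(cv_pass = cv_pass, corr_pass = corr_pass,
                shape_pass = shape_pass, degenerate = degenerate)
  reasons <- c(
    if (!cv_pass) "cv",
    if (!corr_pass) "correlation",
    if (!shape_pass) "shape",
    if (degenerate) "degenerate"
  )
  structure(list(cv_max = cv_obs, top_corr = top3, flags = flags,
                 verdict = if (length(reasons) == 0) "pass" else "fail",
                 reasons = reasons %||% character(0)),
            class = "pbms_gof")
}

#' @export
print.pbms_gof <- function(x, ...) {
  cat(sprintf("<pbms_gof> verdict: %s%s\n", x$verdict,
              if (length(x$reasons)) paste0(" (", paste(x$reasons, collapse = ", "), ")") else ""))
  cat(sprintf("  max CV = %.3g; top |corr|: %s\n", x$cv_max,
              paste(sprintf("%.2f", x$top_corr), collapse = "; ")))
  invisible(x)
}

select_one_mode <- function(data, models, mode_label, decay, fsd, control,
                            gof, weight_threshold, ibms = FALSE) {
  n_obs <- nrow(data)
  n_pat <- length(unique(data$patient_id))
  counts <- table(data$patient_id)

  rows <- list()
  fits <- list()
  gofs <- list()
  for (m in models) {
    model <- get_model(m)
    id <- model$model_id
    K <- count_parameters(model, n_pat)
    row <- tibble::tibble(
      model_id = id, K = K, N = n_obs, minus2lnL = NA_real_,
      aicc = NA_real_, delta = NA_real_, weight = NA_real_,
      cv_max = NA_real_, top_corr = NA_character_,
      gof_verdict = NA_character_, excluded_reason = NA_character_)

    if (ibms && !is.null(model$shared_param)) {
      row$excluded_reason <- "shared_parameter_model"
    } else if (!is_feasible(model, n_obs, n_pat)) {
      row$excluded_reason <- "infeasible_K_exceeds_N_minus_2"
    } else if (any(counts < model$params_per_patient)) {
      row$excluded_reason <- "insufficient_data_per_patient"
    } else {
      fit <- tryCatch(
        fit_population(data, model, decay = decay, fsd = fsd, control = control),
        error = function(e) NULL)
      if (is.null(fit)) {
        row$excluded_reason <- "fit_error"
      } else {
        g <- goodness_of_fit(fit, gof)
        fits[[id]] <- fit
        gofs[[id]] <- g
        row$minus2lnL <- fit$minus2lnL
        row$aicc <- aicc(fit$minus2lnL, fit$K, fit$N)
        row$cv_max <- g$cv_max
        row$top_corr <- paste(sprintf("%.2f", g$top_corr), collapse = ";")
        row$gof_verdict <- g$verdict
        if (g$verdict != "pass") {
          row$excluded_reason <- paste0("gof_failed:", paste(g$reasons, collapse = "+"))
        }
      }
    }
    rows[[id]] <- row
  }
  tab <- dplyr::bind_rows(rows)

  inc <- which(is.na(tab$excluded_reason))
  if (length(inc) > 0) {
    tab$delta[inc] <- tab$aicc[inc] - min(tab$aicc[inc])
    tab$weight[inc] <- akaike_weights(tab$aicc[inc])
  }
  best <- if (length(inc)) tab$model_id[inc][which.max(tab$weight[inc])] else NA_character_
  supported <- if (length(inc)) tab$model_id[inc][tab$weight[inc] > weight_threshold] else character(0)

  structure(tab, class = c("pbms_selection", class(tab)),
            mode = mode_label, best_model = best, supported_models = supported,
            weight_threshold = weight_threshold, fits = fits, gof = gofs)
}

#' Model selection over the catalog (PBMS or IBMS)
#'
#' Fits each candidate model, screens it with the goodness-of-fit gate, and
#' ranks the survivors by AICc/Akaike weight.
#'
#' In `"PBMS"` mode (population-based model selection) every model is fitted
#' jointly to all patients; N is the pooled sample count and K the total
#' parameter count including a shared parameter where present. In `"IBMS"`
#' mode (individual-based) selection runs separately per patient on that
#' patient's data only; shared-parameter models are excluded by design, and
#' K and N are per patient.
#'
#' Models are excluded — and carry no Akaike weight — when infeasible
#' (K > N - 2), when a patient has fewer points than per-patient parameters,
#' when the fit errors, or when the gate fails; weights are normalized over
#' the gate-passing subset only. If no model passes, the supported set is
#' empty (with per-model diagnostics in `excluded_reason`).
#'
#' @inheritParams fit_population
#' @param mode `"PBMS"` or `"IBMS"`.
#' @param models Character vector of catalog model ids (default: whole
#'   catalog).
#' @param gof A [gof_control()] list.
#' @param weight_threshold Models with weight above this are reported as
#'   supported (default 0.05).
#' @return A `pbms_selection` tibble (one row per model; for IBMS, per
#'   patient and model with a `patient_id` column). Attributes:
#'   `best_model`, `supported_models`, `fits` (named list of `pbms_fit`),
#'   `gof`. For IBMS `best_model` is a named vector, one entry per patient.
#' @examples
#' \donttest{
#' sim <- simulate_population(seed = 1)
#' sel <- select_models(sim$data, mode = "PBMS",
#'                      models = c("f2b", "f3aS3", "f3aS4"))
#' attr(sel, "best_model")
#' }
#' @export
select_models <- function(data, mode = c("PBMS", "IBMS"), models = NULL,
                          decay = lu177(), fsd = 0.15,
                          control = fit_control(), gof = gof_control(),
                          weight_threshold = 0.05) {
  mode <- match.arg(mode)
  data <- check_population(data, fsd = fsd)
  models <- models %||% names(model_catalog())

  if (mode == "PBMS") {
    return(select_one_mode(data, models, "PBMS", decay, fsd, control, gof,
                           weight_threshold))
  }

  ids <- unique(data$patient_id)
  per <- lapply(ids, function(id) {
    tab <- select_one_mode(data[data$patient_id == id, ], models, "IBMS",
                           decay, fsd, control, gof, weight_threshold,
                           ibms = TRUE)
    tibble::as_tibble(tab) |>
      dplyr::mutate(patient_id = id, .before = 1) |>
      structure(best = attr(tab, "best_model"),
                supported = attr(tab, "supported_models"),
                fits = attr(tab, "fits"))
  })
  tab <- dplyr::bind_rows(lapply(per, tibble::as_tibble))
  structure(tab, class = c("pbms_selection", class(tab)),
            mode = "IBMS",
            best_model = stats::setNames(vapply(per, attr, "", "best"), ids),
            supported_models = stats::setNames(lapply(per, attr, "supported"), ids),
            weight_threshold = weight_threshold,
            fits = stats::setNames(lapply(per, attr, "fits"), ids))
}

#' @export
print.pbms_selection <- function(x, ...) {
  cat(sprintf("<pbms_selection> mode %s\n", attr(x, "mode")))
  best <- attr(x, "best_model")
  if (length(best)) {
    cat("  best model:", paste(
      if (is.null(names(best))) best else paste0(names(best), "=", best),
      collapse = ", "), "\n")
  }
  NextMethod()
}

#' Jackknife stability of population-based model selection
#'
#' Reruns the full PBMS selection (fits, gate, weights) once per patient
#' with that patient left out, and summarizes each model's leave-one-out
#' Akaike weights as median [min, max]. Models excluded in a replicate
#' (gate failure, infeasibility) enter that replicate with weight 0, so
#' every replicate's weights still sum to 1 over its included set.
#'
#' @inheritParams select_models
#' @return A list of class `pbms_jackknife`: `replicates` (tibble with
#'   columns `left_out`, `model_id`, `weight`, `excluded_reason`, `N`, `K`)
#'   and `summary` (per model: `median`, `min`, `max` weight).
#' @export
jackknife_selection <- function(data, models = NULL, decay = lu177(),
                                fsd = 0.15, control = fit_control(),
                                gof = gof_control(), weight_threshold = 0.05) {
  data <- check_population(data, fsd = fsd)
  ids <- unique(data$patient_id)
  if (length(ids) < 2) abort("Jackknife needs at least 2 patients.")
  models <- models %||% names(model_catalog())

  reps <- lapply(ids, function(id) {
    sub <- data[data$patient_id != id, ]
    tab <- select_models(sub, mode = "PBMS", models = models, decay = decay,
                         fsd = fsd, control = control, gof = gof,
                         weight_threshold = weight_threshold)
    tibble::tibble(left_out = id, model_id = tab$model_id,
                   weight = ifelse(is.na(tab$weight), 0, tab$weight),
                   excluded_reason = tab$excluded_reason,
                   N = tab$N, K = tab$K)
  })
  replicates <- dplyr::bind_rows(reps)
  summary <- replicates |>
    dplyr::group_by(.data$model_id) |>
    dplyr::summarise(median = stats::median(.data$weight),
                     min = min(.data$weight), max = max(.data$weight),
                     .groups = "drop")
  structure(list(replicates = replicates, summary = summary,
                 n_replicates = length(ids)),
            class = "pbms_jackknife")
}

#' @export
print.pbms_jackknife <- function(x, ...) {
  cat(sprintf("<pbms_jackknife> %d leave-one-out replicates\n", x$n_replicates))
  s <- dplyr::arrange(x$summary, dplyr::desc(.data$median))
  print(s, n = 10)
  invisible(x)
}
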