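#' @importFrom generics tidy glance augment
#' @export
generics::tidy

#' @export
generics::glance

#' @export
generics::augment

#' Tidy a fitted model
#'
#' @param x A `pbms_fit`.
#' @param ... Unused.
#' @return Tibble with one row per estimated parameter: `patient_id`
#'   (`"(shared)"` for the population-shared parameter), `parameter`,
#'   `estimate`, `sd`, `cv`, `shared`, `at_bound`.
#' @export
tidy.pbms_fit <- function(x, ...) x$parameters

#' One-row summary of a fitted model
#'
#' @inheritParams tidy.pbms_fit
#' @return Tibble: `model_id`, `mode`, `minus2lnL`, `wrss`, `N`, `K`,
#'   `n_patients`, `converged`, `degenerate`, `n_starts_used`.
#' @export
glance.pbms_fit <- function(x, ...) {
  tibble::tibble(model_id = x$model_id, mode = x$mode,
                 minus2lnL = x$minus2lnL, wrss = x$wrss, N = x$N, K = x$K,
                 n_patients = x$n_patients, converged = x$converged,
                 degenerate = x$degenerate, n_starts_used = x$n_starts_used)
}

#' Per-sample fit diagnostics
#'
#' @inheritParams tidy.pbms_fit
#' @return Tibble with the observed data plus `fitted` values and
#'   `std_resid` (weighted residuals).
#' @export
augment.pbms_fit <- function(x, ...) x$fitted

#' Tidy a selection table
#'
#' @param x A `pbms_selection`.
#' @param ... Unused.
#' @return The underlying tibble (one row per candidate model, or per
#'   patient and model for IBMS).
#' @export
tidy.pbms_selection <- function(x, ...) tibble::as_tibble(x)

#' One-row summary of a model-selection run
#'
#' @inheritParams tidy.pbms_selection
#' @return Tibble: mode, numbers of candidate/fitted/passing models, the
#'   best model and its weight (PBMS mode).
#' @export
glance.pbms_selection <- function(x, ...) {
  tab <- tibble::as_tibble(x)
  best <- attr(x, "best_model")
  best_id <- if (length(best) == 1 && is.null(names(best))) best else NA_character_
  tibble::tibble(
    mode = attr(x, "mode"),
    n_models = length(unique(tab$model_id)),
    n_fitted = sum(!is.na(tab$minus2lnL)),
    n_passed = sum(!is.na(tab$weight)),
    best_model = best_id,
    best_weight = if (!is.na(best_id)) max(tab$weight, na.rm = TRUE) else NA_real_)
}

#' Tidy a jackknife result
#'
#' @param x A `pbms_jackknife`.
#' @param ... Unused.
#' @return The per-model summary tibble (`model_id`, `median`, `min`,
#'   `max` leave-one-out Akaike weight).
#' @export
tidy.pbms_jackknife <- function(x, ...) x$summary
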