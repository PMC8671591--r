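#' Attach measurement SDs from the fractional-SD variance model
#'
#' The weighting used throughout is the absolute, data-based variance model
#' \eqn{\sigma_i = fsd \cdot y_i}: each measured activity gets a standard
#' deviation proportional to its value. Weights are fixed by the data, so
#' the fitting objective is identical across models and AICc differences
#' compare likelihoods on the same footing.
#'
#' @param data Data frame with columns `patient_id`, `time_h`,
#'   `activity_pct_ia` (all activities must be > 0).
#' @param fsd Fractional standard deviation; default 0.15.
#' @return The data as a tibble with a `sigma` column added (existing
#'   `sigma` is overwritten), sorted by patient and time.
#' @examples
#' df <- tibble::tibble(patient_id = "P1", time_h = c(2, 24),
#'                      activity_pct_ia = c(10, 6))
#' add_measurement_sd(df)$sigma  # 1.5 0.9
#' @export
add_measurement_sd <- function(data, fsd = 0.15) {
  data$sigma <- NULL
  check_population(data, fsd = fsd)
}

#' Fitting control options
#'
#' @param n_starts Number of optimizer starts: a data-driven heuristic
#'   start and deterministic grid starts (over the shared parameter and/or
#'   the clearance-rate decade), topped up with seeded jittered and
#'   log-uniform random starts.
#' @param seed Integer seed controlling the random starts (deterministic:
#'   the same seed gives bit-identical fits).
#' @param ftol,ptol Relative tolerances on the objective and parameters
#'   passed to the trust-region least-squares optimizer.
#' @param maxiter Maximum iterations per start.
#' @return A list of class `pbms_fit_control`.
#' @export
fit_control <- function(n_starts = 10, seed = 1L, ftol = 1e-12, ptol = 1e-12,
                        maxiter = 500) {
  stopifnot(n_starts >= 1, maxiter >= 1)
  structure(list(n_starts = as.integer(n_starts), seed = as.integer(seed),
                 ftol = ftol, ptol = ptol, maxiter = as.integer(maxiter)),
            class = "pbms_fit_control")
}

#' Gaussian -2 log-likelihood of a parameter set
#'
#' Computes \eqn{-2\ln L = \sum_i (y_i - f(t_i))^2/\sigma_i^2 +
#' \sum_i \ln(2\pi\sigma_i^2)} over all samples. With the fixed data-based
#' weights the second sum is a constant shared by all models, so AICc
#' differences do not depend on `include_constant`.
#'
#' @inheritParams add_measurement_sd
#' @param model Model id or `pbms_model`.
#' @param params Named numeric vector of parameters. For multi-patient data
#'   pass a named list keyed by patient id (each element a full named
#'   parameter vector, shared parameter included).
#' @param decay A [radionuclide()] object.
#' @param include_constant Include the \eqn{\sum \ln(2\pi\sigma_i^2)} term.
#' @return A single number.
#' @export
neg2_log_likelihood <- function(data, model, params, decay = lu177(),
                                fsd = 0.15, include_constant = TRUE) {
  model <- get_model(model)
  decay <- as_decay(decay)
  data <- check_population(data, fsd = fsd)
  curves <- split_curves(data)
  if (is.numeric(params)) {
    params <- stats::setNames(rep(list(params), length(curves)), names(curves))
  } else if (!is.list(params) || !all(names(curves) %in% names(params))) {
    abort("`params` must be a named numeric vector or a list keyed by patient_id.")
  }
  wrss <- 0
  const <- 0
  for (cv in curves) {
    f <- evaluate_model(model, params[[cv$patient_id]], cv$t, decay)
    wrss <- wrss + sum(((cv$y - f) / cv$sigma)^2)
    const <- const + sum(log(2 * pi * cv$sigma^2))
  }
  wrss + if (include_constant) const else 0
}

# ---------------------------------------------------------------------------
# Internal joint-objective machinery
# ---------------------------------------------------------------------------

# Builds the packed parameter vector layout and weighted-residual function
# for a joint fit of `curves` under `model`. If `fixed_shared` is non-NULL
# the shared parameter is held at that value and excluded from theta.
make_objective <- function(model, curves, lp, fixed_shared = NULL) {
  ppp <- model$params_per_patient
  npat <- length(curves)
  has_shared <- !is.null(model$shared_param) && is.null(fixed_shared)

  theta_names <- character(0)
  for (cv in curves) {
    theta_names <- c(theta_names, paste0(cv$patient_id, ":", model$per_patient_params))
  }
  if (has_shared) theta_names <- c(theta_names, paste0("(shared):", model$shared_param))

  par_of <- c(rep(model$per_patient_params, npat),
              if (has_shared) model$shared_param)
  lower <- vapply(par_of, function(nm) model$bounds[[nm]][1], 0)
  upper <- vapply(par_of, function(nm) model$bounds[[nm]][2], 0)

  idx <- lapply(seq_len(npat), function(i) (i - 1L) * ppp + seq_len(ppp))
  shared_idx <- if (has_shared) npat * ppp + 1L else NA_integer_

  patient_params <- function(theta, i) {
    p <- stats::setNames(theta[idx[[i]]], model$per_patient_params)
    if (!is.null(model$shared_param)) {
      p[model$shared_param] <- if (has_shared) theta[shared_idx] else fixed_shared
    }
    p
  }

  resid_fn <- function(theta) {
    unlist(lapply(seq_len(npat), function(i) {
      cv <- curves[[i]]
      f <- model$eval_fn(patient_params(theta, i), lp, cv$t)
      (cv$y - f) / cv$sigma
    }), use.names = FALSE)
  }

  list(model = model, curves = curves, lp = lp, fixed_shared = fixed_shared,
       has_shared = has_shared, theta_names = theta_names, par_of = par_of,
       lower = lower, upper = upper, n_theta = length(par_of),
       idx = idx, shared_idx = shared_idx,
       patient_params = patient_params, resid_fn = resid_fn)
}

# Data-driven heuristic start for one curve: effective terminal rate from a
# log-linear fit through the last two points, amplitudes back-extrapolated
# to t = 0, beta started high (most activity in the washout term).
heuristic_curve_start <- function(curve, lp) {
  n <- length(curve$t)
  if (n >= 2) {
    i <- c(n - 1L, n)
    ylog <- log(pmax(curve$y[i], 1e-8))
    slope <- (ylog[2] - ylog[1]) / (curve$t[i[2]] - curve$t[i[1]])
    lam_eff <- max(-slope, lp * 1.01)
  } else {
    lam_eff <- lp + 0.01
  }
  lam1 <- min(max(lam_eff - lp, 1e-3), 99)
  y0 <- curve$y[1] * exp(min(lam_eff * curve$t[1], 20))
  c(A1 = min(max(y0, 0.1), 9e3),
    A2 = min(max(y0 / 5, 0.05), 9e3),
    lambda1 = lam1,
    lambda2 = min(lam1 * 5 + 1e-3, 99),
    beta = 0.9)
}

heuristic_start <- function(obj) {
  per <- lapply(obj$curves, heuristic_curve_start, lp = obj$lp)
  theta <- numeric(obj$n_theta)
  for (i in seq_along(obj$curves)) {
    theta[obj$idx[[i]]] <- per[[i]][obj$model$per_patient_params]
  }
  if (obj$has_shared) {
    theta[obj$shared_idx] <- mean(vapply(per, `[[`, 0, obj$model$shared_param))
  }
  pmin(pmax(theta, obj$lower + 1e-6 * (obj$upper - obj$lower)),
       obj$upper - 1e-6 * (obj$upper - obj$lower))
}

# Log-uniform random start over plausible scales (well inside the bounds):
# amplitudes 0.5-500 %IA, biological rates 1e-4 to 1 /h, beta uniform.
random_start <- function(obj) {
  vapply(obj$par_of, function(nm) {
    if (nm == "beta") stats::runif(1, 0.02, 0.98)
    else if (grepl("^A", nm)) exp(stats::runif(1, log(0.5), log(500)))
    else exp(stats::runif(1, log(1e-4), log(1)))
  }, 0)
}

# Multiplicative jitter around a reference start; beta-type entries are
# jittered on the logit scale so they stay inside (0, 1).
jitter_start <- function(obj, ref) {
  out <- vapply(seq_along(ref), function(j) {
    if (obj$par_of[j] == "beta") {
      stats::plogis(stats::qlogis(min(max(ref[j], 0.01), 0.99)) + stats::rnorm(1, 0, 1))
    } else {
      ref[j] * exp(stats::rnorm(1, 0, 0.7))
    }
  }, 0)
  pmin(pmax(out, obj$lower + 1e-8), obj$upper - 1e-8 * (obj$upper - obj$lower))
}

# Start list: the data-driven heuristic; a deterministic grid over the
# shared parameter for shared models (the only direction strongly coupling
# the patients); for single-curve problems a deterministic grid over the
# clearance-rate decade with the amplitude back-extrapolated through the
# first sample (mono- and bi-exponential objectives have distinct fast- and
# slow-decay basins); then seeded jittered and global random starts up to
# n_starts total (the deterministic starts are always kept).
start_list <- function(obj, control) {
  h <- heuristic_start(obj)
  starts <- list(h)
  clamp <- function(v, j) {
    min(max(v, obj$lower[j] + 1e-8),
        obj$upper[j] - 1e-8 * max(obj$upper[j] - obj$lower[j], 1))
  }
  if (obj$has_shared) {
    sn <- obj$model$shared_param
    vals <- if (sn == "beta") c(0.3, 0.6, 0.8, 0.97)
            else h[obj$shared_idx] * c(0.1, 0.3, 3, 10)
    for (v in vals) {
      s <- h
      s[obj$shared_idx] <- clamp(v, obj$shared_idx)
      starts <- c(starts, list(s))
    }
  }
  if (length(obj$curves) == 1 && any(obj$par_of == "lambda1")) {
    cv <- obj$curves[[1]]
    for (lam in c(0.005, 0.05, 0.5, 5)) {
      s <- h
      a0 <- cv$y[1] * exp(min((lam + obj$lp) * cv$t[1], 12))
      for (j in seq_along(obj$par_of)) {
        if (obj$par_of[j] == "lambda1") s[j] <- clamp(lam, j)
        if (obj$par_of[j] == "A1") s[j] <- clamp(a0, j)
      }
      starts <- c(starts, list(s))
    }
  }
  n_more <- control$n_starts - length(starts)
  if (n_more > 0) {
    extra <- with_seed(control$seed, {
      lapply(seq_len(n_more), function(i) {
        if (i %% 2 == 1) jitter_start(obj, h) else random_start(obj)
      })
    })
    starts <- c(starts, extra)
  }
  starts
}

lm_once <- function(obj, start, control) {
  tryCatch(
    suppressWarnings(minpack.lm::nls.lm(
      par = start, lower = obj$lower, upper = obj$upper,
      fn = obj$resid_fn,
      control = minpack.lm::nls.lm.control(
        ftol = control$ftol, ptol = control$ptol,
        maxiter = control$maxiter, maxfev = 100000L))),
    error = function(e) NULL)
}

# Profile-style starts for shared-parameter models: for each grid value of
# the shared parameter, solve every patient's (small) conditional problem
# by multi-start, then let the joint optimizer refine all parameters. The
# shared value is the only direction coupling the patients, so this
# reliably reaches the joint optimum where naive joint starts stall in
# per-patient local minima.
profile_candidates <- function(obj, control) {
  h <- heuristic_start(obj)
  sn <- obj$model$shared_param
  grid <- if (sn == "beta") c(0.3, 0.6, 0.8, 0.9, 0.97)
          else h[obj$shared_idx] * c(0.1, 0.3, 1, 3, 10)
  sub_control <- fit_control(n_starts = 6, seed = control$seed,
                             ftol = control$ftol, ptol = control$ptol,
                             maxiter = control$maxiter)
  lapply(grid, function(v) {
    v <- min(max(v, obj$lower[obj$shared_idx] + 1e-8),
             obj$upper[obj$shared_idx] -
               1e-8 * (obj$upper[obj$shared_idx] - obj$lower[obj$shared_idx]))
    theta <- numeric(obj$n_theta)
    for (i in seq_along(obj$curves)) {
      sub <- make_objective(obj$model, obj$curves[i], obj$lp, fixed_shared = v)
      theta[obj$idx[[i]]] <- run_multistart_basic(sub, sub_control)$theta
    }
    theta[obj$shared_idx] <- v
    theta
  })
}

# Alternating refinement of a joint optimum: per-patient conditional
# re-fits at the current shared value, then a joint refit; repeated while
# the objective improves.
polish_shared <- function(obj, theta, dev, control) {
  sub_control <- fit_control(n_starts = 6, seed = control$seed,
                             ftol = control$ftol, ptol = control$ptol,
                             maxiter = control$maxiter)
  for (round in 1:5) {
    v <- theta[obj$shared_idx]
    cand <- theta
    for (i in seq_along(obj$curves)) {
      sub <- make_objective(obj$model, obj$curves[i], obj$lp, fixed_shared = v)
      cand[obj$idx[[i]]] <- run_multistart_basic(sub, sub_control)$theta
    }
    res <- lm_once(obj, cand, control)
    if (is.null(res) || !is.finite(res$deviance) || res$deviance >= dev - 1e-10) break
    theta <- unname(unlist(res$par))
    dev <- res$deviance
  }
  list(theta = theta, dev = dev)
}

run_multistart_basic <- function(obj, control) {
  starts <- start_list(obj, control)
  best <- NULL
  best_dev <- Inf
  n_ok <- 0L
  for (s in seq_along(starts)) {
    res <- tryCatch(
      suppressWarnings(minpack.lm::nls.lm(
        par = starts[[s]], lower = obj$lower, upper = obj$upper,
        fn = obj$resid_fn,
        control = minpack.lm::nls.lm.control(
          ftol = control$ftol, ptol = control$ptol,
          maxiter = control$maxiter, maxfev = 100000L))),
      error = function(e) NULL)
    if (is.null(res)) next
    ok <- res$info %in% 1:4
    if (ok) n_ok <- n_ok + 1L
    dev <- res$deviance
    if (is.finite(dev) && dev < best_dev - 1e-10) {
      best <- res; best_dev <- dev
    }
  }
  if (is.null(best)) {
    return(list(theta = starts[[1]], wrss = Inf, converged = FALSE,
                n_starts_used = length(starts)))
  }
  list(theta = unname(unlist(best$par)), wrss = best$deviance,
       converged = n_ok > 0L, n_starts_used = length(starts))
}

run_multistart <- function(obj, control) {
  opt <- run_multistart_basic(obj, control)
  if (!obj$has_shared) return(opt)
  # profile starts over the shared parameter, then joint refinement
  n_extra <- 0L
  for (theta0 in profile_candidates(obj, control)) {
    n_extra <- n_extra + 1L
    res <- lm_once(obj, theta0, control)
    if (!is.null(res) && is.finite(res$deviance) &&
        res$deviance < opt$wrss - 1e-10) {
      opt$theta <- unname(unlist(res$par))
      opt$wrss <- res$deviance
      opt$converged <- opt$converged || res$info %in% 1:4
    }
  }
  pol <- polish_shared(obj, opt$theta, opt$wrss, control)
  opt$theta <- pol$theta
  opt$wrss <- pol$dev
  opt$n_starts_used <- opt$n_starts_used + n_extra
  opt
}

# Central-difference jacobian of the weighted residual vector, with steps
# folded back inside the box at active bounds.
numeric_jacobian <- function(resid_fn, theta, lower, upper) {
  r0 <- resid_fn(theta)
  J <- matrix(0, nrow = length(r0), ncol = length(theta))
  for (j in seq_along(theta)) {
    h <- max(1e-7 * abs(theta[j]), 1e-9)
    up <- pmin(replace(theta, j, theta[j] + h), upper)
    dn <- pmax(replace(theta, j, theta[j] - h), lower)
    denom <- up[j] - dn[j]
    if (denom <= 0) next
    J[, j] <- (resid_fn(up) - resid_fn(dn)) / denom
  }
  J
}

# Gauss-Newton covariance at the optimum: (J'WJ)^{-1} on weighted residuals
# (the weights are already inside the residuals). Singular information is
# reported as a degeneracy, not an error.
theta_uncertainty <- function(obj, theta) {
  J <- numeric_jacobian(obj$resid_fn, theta, obj$lower, obj$upper)
  fim <- crossprod(J)
  k <- ncol(fim)
  degenerate <- FALSE
  cov <- tryCatch({
    if (k == 0 || !all(is.finite(fim)) || rcond(fim) < 1e-14) stop("singular")
    solve(fim)
  }, error = function(e) NULL)
  if (is.null(cov) || any(!is.finite(diag(cov))) || any(diag(cov) < 0)) {
    degenerate <- TRUE
    sds <- rep(Inf, k)
    corr <- matrix(NA_real_, k, k)
  } else {
    sds <- sqrt(diag(cov))
    denom <- outer(sds, sds)
    corr <- cov / denom
    corr[denom == 0] <- 0
    diag(corr) <- 1
  }
  dimnames(corr) <- list(obj$theta_names, obj$theta_names)
  list(sds = stats::setNames(sds, obj$theta_names), correlation = corr,
       degenerate = degenerate)
}

new_pbms_fit <- function(obj, opt, unc, mode, control, decay, fsd, data, K) {
  curves <- obj$curves
  npat <- length(curves)
  const <- sum(unlist(lapply(curves, function(cv) log(2 * pi * cv$sigma^2))))
  theta <- opt$theta

  rows <- list()
  for (i in seq_len(npat)) {
    nm <- obj$model$per_patient_params
    est <- theta[obj$idx[[i]]]
    tn <- paste0(curves[[i]]$patient_id, ":", nm)
    rows[[i]] <- tibble::tibble(
      patient_id = curves[[i]]$patient_id, parameter = nm, estimate = est,
      sd = unname(unc$sds[tn]), shared = FALSE,
      lower = obj$lower[obj$idx[[i]]], upper = obj$upper[obj$idx[[i]]])
  }
  params <- dplyr::bind_rows(rows)
  if (obj$has_shared) {
    sn <- obj$model$shared_param
    params <- dplyr::bind_rows(params, tibble::tibble(
      patient_id = "(shared)", parameter = sn, estimate = theta[obj$shared_idx],
      sd = unname(unc$sds[paste0("(shared):", sn)]), shared = TRUE,
      lower = obj$lower[obj$shared_idx], upper = obj$upper[obj$shared_idx]))
  }
  span <- params$upper - params$lower
  params$cv <- params$sd / pmax(abs(params$estimate), .Machine$double.eps)
  params$at_bound <- (params$estimate - params$lower) < 1e-8 * span |
    (params$upper - params$estimate) < 1e-8 * span
  params <- params[c("patient_id", "parameter", "estimate", "sd", "cv",
                     "shared", "at_bound")]

  fitted <- dplyr::bind_rows(lapply(seq_len(npat), function(i) {
    cv <- curves[[i]]
    f <- obj$model$eval_fn(obj$patient_params(theta, i), obj$lp, cv$t)
    tibble::tibble(patient_id = cv$patient_id, time_h = cv$t,
                   activity_pct_ia = cv$y, sigma = cv$sigma, fitted = f,
                   std_resid = (cv$y - f) / cv$sigma)
  }))

  structure(
    list(
      model_id = obj$model$model_id, mode = mode,
      parameters = params, correlation = unc$correlation,
      wrss = opt$wrss, loglik_constant = const,
      minus2lnL = opt$wrss + const,
      N = sum(vapply(curves, function(cv) length(cv$t), 0L)),
      K = as.integer(K), n_patients = npat,
      converged = opt$converged, degenerate = unc$degenerate,
      n_starts_used = opt$n_starts_used,
      fixed_shared = obj$fixed_shared,
      fitted = fitted, data = data, decay = decay, fsd = fsd,
      theta = theta, theta_names = obj$theta_names, control = control
    ),
    class = "pbms_fit"
  )
}

check_min_points <- function(model, curves) {
  for (cv in curves) {
    if (length(cv$t) < model$params_per_patient) {
      abort(sprintf(
        "Model %s needs %d parameters per patient but patient %s has only %d data point(s).",
        model$model_id, model$params_per_patient, cv$patient_id, length(cv$t)))
    }
  }
}

fit_joint <- function(model, data, mode, decay, fsd, control, fixed_shared = NULL,
                      K = NULL) {
  decay <- as_decay(decay)
  data <- check_population(data, fsd = fsd)
  curves <- split_curves(data)
  check_min_points(model, curves)
  obj <- make_objective(model, curves, decay$lambda_phys, fixed_shared)
  opt <- run_multistart(obj, control)
  unc <- theta_uncertainty(obj, opt$theta)
  if (is.null(K)) K <- obj$n_theta
  new_pbms_fit(obj, opt, unc, mode, control, decay, fsd, data, K)
}

# Combines independent per-patient fits into one pooled fit object with
# joint bookkeeping (summed -2lnL, pooled N, total K, block-diagonal
# correlation matrix).
combine_fits <- function(fits, model, mode, decay, fsd, control, data,
                         extra_K = 0L, fixed_shared = NULL) {
  corr_names <- unlist(lapply(fits, function(f) f$theta_names))
  k <- length(corr_names)
  corr <- matrix(0, k, k, dimnames = list(corr_names, corr_names))
  off <- 0L
  for (f in fits) {
    ki <- length(f$theta_names)
    corr[off + seq_len(ki), off + seq_len(ki)] <- f$correlation
    off <- off + ki
  }
  structure(
    list(
      model_id = model$model_id, mode = mode,
      parameters = dplyr::bind_rows(lapply(fits, `[[`, "parameters")),
      correlation = corr,
      wrss = sum(vapply(fits, `[[`, 0, "wrss")),
      loglik_constant = sum(vapply(fits, `[[`, 0, "loglik_constant")),
      minus2lnL = sum(vapply(fits, `[[`, 0, "minus2lnL")),
      N = sum(vapply(fits, `[[`, 0L, "N")),
      K = as.integer(sum(vapply(fits, `[[`, 0L, "K")) + extra_K),
      n_patients = length(fits),
      converged = all(vapply(fits, `[[`, TRUE, "converged")),
      degenerate = any(vapply(fits, `[[`, FALSE, "degenerate")),
      n_starts_used = max(vapply(fits, `[[`, 0L, "n_starts_used")),
      fixed_shared = fixed_shared,
      fitted = dplyr::bind_rows(lapply(fits, `[[`, "fitted")),
      data = data, decay = as_decay(decay), fsd = fsd,
      theta = unlist(lapply(fits, `[[`, "theta")),
      theta_names = corr_names, control = control
    ),
    class = "pbms_fit"
  )
}

#' Fit one model to a single patient's time-activity curve
#'
#' Individual (per-patient) weighted nonlinear least squares: minimizes the
#' Gaussian -2 log-likelihood with fixed data-based weights over box
#' constraints, using a deterministic multi-start strategy. Models with a
#' population-shared parameter are rejected here; they are only meaningful
#' in [fit_population()].
#'
#' @inheritParams neg2_log_likelihood
#' @param control A [fit_control()] list.
#' @return A `pbms_fit` object; see [tidy.pbms_fit()], [glance.pbms_fit()]
#'   and [autoplot.pbms_fit()].
#' @examples
#' df <- tibble::tibble(patient_id = "P1", time_h = c(1, 24, 48, 96, 160),
#'                      activity_pct_ia = evaluate_model(
#'                        "f2b", c(A1 = 12, lambda1 = 0.02),
#'                        c(1, 24, 48, 96, 160)))
#' fit <- fit_individual(df, "f2b")
#' tidy(fit)
#' @export
fit_individual <- function(data, model, decay = lu177(), fsd = 0.15,
                           control = fit_control()) {
  model <- get_model(model)
  if (!is.null(model$shared_param)) {
    abort(sprintf(
      "Model %s has a population-shared parameter (%s); use fit_population() or fit_fixed_shared().",
      model$model_id, model$shared_param))
  }
  data <- check_population(data, fsd = fsd)
  if (length(unique(data$patient_id)) != 1L) {
    abort("`fit_individual()` expects data from exactly one patient; use fit_population() for several.")
  }
  fit_joint(model, data, "individual", decay, fsd, control)
}

#' Fit one model jointly to a patient population
#'
#' Population fit: all per-patient parameters plus (if the model has one)
#' a single population-shared parameter are estimated jointly by minimizing
#' the pooled weighted -2 log-likelihood. For models without a shared
#' parameter the pooled objective separates exactly into independent
#' per-patient problems, which are solved individually and combined with
#' joint bookkeeping (pooled N, total K, summed -2lnL).
#'
#' @inheritParams fit_individual
#' @return A `pbms_fit` object with one parameter set per patient and, for
#'   shared-parameter models, one `(shared)` row.
#' @export
fit_population <- function(data, model, decay = lu177(), fsd = 0.15,
                           control = fit_control()) {
  model <- get_model(model)
  data <- check_population(data, fsd = fsd)
  if (is.null(model$shared_param)) {
    curves <- split_curves(data)
    check_min_points(model, curves)
    fits <- lapply(curves, function(cv) {
      d <- data[data$patient_id == cv$patient_id, ]
      fit_joint(model, d, "individual", decay, fsd, control)
    })
    out <- combine_fits(fits, model, "population", decay, fsd, control, data)
    return(out)
  }
  fit_joint(model, data, "population", decay, fsd, control)
}

#' Fit per-patient parameters with the shared parameter held fixed
#'
#' The "future patient" workflow: once a population analysis has estimated
#' a shared parameter (e.g. the fraction beta of f3aS4), new patients with
#' very few samples can be fitted by holding the shared parameter at the
#' population value and estimating only their per-patient parameters. K
#' excludes the fixed parameter.
#'
#' @inheritParams fit_individual
#' @param shared_value Value at which the model's shared parameter is fixed;
#'   must lie within its bounds.
#' @return A `pbms_fit` object (mode `"fixed_shared"`).
#' @export
fit_fixed_shared <- function(data, model, shared_value, decay = lu177(),
                             fsd = 0.15, control = fit_control()) {
  model <- get_model(model)
  if (is.null(model$shared_param)) {
    abort(sprintf("Model %s has no shared parameter to fix.", model$model_id))
  }
  b <- model$bounds[[model$shared_param]]
  if (!is.numeric(shared_value) || length(shared_value) != 1L ||
      !is.finite(shared_value) || shared_value < b[1] || shared_value > b[2]) {
    abort(sprintf("`shared_value` = %g outside the bounds [%g, %g] of %s.",
                  shared_value, b[1], b[2], model$shared_param))
  }
  data <- check_population(data, fsd = fsd)
  curves <- split_curves(data)
  check_min_points(model, curves)
  fits <- lapply(curves, function(cv) {
    d <- data[data$patient_id == cv$patient_id, ]
    fit_joint(model, d, "fixed_shared", decay, fsd, control,
              fixed_shared = shared_value)
  })
  if (length(fits) == 1L) return(fits[[1]])
  combine_fits(fits, model, "fixed_shared", decay, fsd, control, data,
               fixed_shared = shared_value)
}

#' @export
print.pbms_fit <- function(x, ...) {
  cat(sprintf("<pbms_fit> model %s (%s fit)\n", x$model_id, x$mode))
  cat(sprintf("  %d patient(s), N = %d samples, K = %d parameters\n",
              x$n_patients, x$N, x$K))
  cat(sprintf("  -2lnL = %.4f (WRSS = %.4f), converged: %s%s\n",
              x$minus2lnL, x$wrss, x$converged,
              if (x$degenerate) ", DEGENERATE information matrix" else ""))
  if (!is.null(x$fixed_shared)) {
    cat(sprintf("  shared parameter fixed at %g\n", x$fixed_shared))
  }
  print(x$parameters, n = 10)
  invisible(x)
}

# Shared-parameter estimate of a fit (NA if none).
shared_estimate <- function(fit) {
  i <- which(fit$parameters$shared)
  if (length(i) == 0) return(NA_real_)
  fit$parameters$estimate[i[1]]
}

# Named parameter vector for one patient, shared/fixed value included.
patient_param_vector <- function(fit, patient_id) {
  p <- fit$parameters
  rows <- p[!p$shared & p$patient_id == patient_id, ]
  out <- stats::setNames(rows$estimate, rows$parameter)
  model <- get_model(fit$model_id)
  if (!is.null(model$shared_param) && !model$shared_param %in% names(out)) {
    out[model$shared_param] <- if (!is.null(fit$fixed_shared)) fit$fixed_shared
                               else shared_estimate(fit)
  }
  out
}
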