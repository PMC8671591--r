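# Shared fixtures: all data are generated in code at test time.

# Noise-free time-activity tibble for one patient.
noise_free_curve <- function(model, params, times, patient_id = "P1",
                             decay = lu177()) {
  tibble::tibble(
    patient_id = patient_id, time_h = times,
    activity_pct_ia = evaluate_model(model, params, times, decay))
}

# Independent TIA oracle: adaptive quadrature of the model, piecewise over
# nested time windows out to 10^4 h plus the infinite tail (negligible for
# every admissible rate: exp(-lambda_phys * 1e4) ~ 1e-19).
quadrature_tia <- function(model, params, decay = lu177()) {
  m <- get_model(model)
  f <- function(t) evaluate_model(m, params, t, decay)
  breaks <- c(0, 0.5, 5, 50, 500, 1e4)
  pieces <- vapply(seq_len(length(breaks) - 1), function(i) {
    stats::integrate(f, breaks[i], breaks[i + 1], rel.tol = 1e-10,
                     subdivisions = 500L)$value
  }, 0)
  tail <- stats::integrate(f, 1e4, Inf, rel.tol = 1e-8,
                           subdivisions = 500L)$value
  sum(pieces) + tail
}

# In-bounds random parameter draw for a model, over scales where both the
# closed form and the quadrature oracle are well conditioned.
draw_params <- function(model) {
  m <- get_model(model)
  nms <- c(m$per_patient_params, m$shared_param)
  vapply(stats::setNames(nms, nms), function(nm) {
    if (nm == "beta") stats::runif(1, 0.05, 0.95)
    else if (grepl("^A", nm)) stats::runif(1, 0.5, 200)
    else exp(stats::runif(1, log(5e-4), log(2)))
  }, 0)
}

# Standard 5-session sampling times (nominal session means).
nominal_sessions <- c(1.1, 20.7, 51.0, 92.3, 163.8)
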