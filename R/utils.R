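# Internal helpers shared across modules.

# Runs `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so simulation helpers do not perturb user scripts.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Validates a time-activity data frame and returns it as a tibble with
# columns patient_id (character), time_h, activity_pct_ia and sigma, sorted
# by patient and time. sigma is filled from the fractional-SD variance model
# when absent.
check_population <- function(data, fsd = 0.15, context = "data") {
  req <- c("patient_id", "time_h", "activity_pct_ia")
  if (!is.data.frame(data)) abort(sprintf("`%s` must be a data frame.", context))
  missing <- setdiff(req, names(data))
  if (length(missing) > 0) {
    abort(sprintf("`%s` is missing column(s): %s.", context,
                  paste(missing, collapse = ", ")))
  }
  out <- tibble::as_tibble(data)
  out$patient_id <- as.character(out$patient_id)
  for (col in c("time_h", "activity_pct_ia")) {
    if (!is.numeric(out[[col]])) abort(sprintf("Column `%s` must be numeric.", col))
    if (anyNA(out[[col]])) abort(sprintf("Column `%s` contains missing values.", col))
  }
  if (any(out$time_h < 0)) abort("`time_h` must be non-negative.")
  out <- dplyr::arrange(out, .data$patient_id, .data$time_h)
  dup <- duplicated(out[c("patient_id", "time_h")])
  if (any(dup)) {
    bad <- out[dup, ]
    abort(sprintf("Duplicate (patient_id, time_h) pair: patient %s at t = %g h.",
                  bad$patient_id[1], bad$time_h[1]))
  }
  if (!"sigma" %in% names(out)) {
    out$sigma <- sigma_fsd(out$activity_pct_ia, fsd)
  } else if (any(!is.finite(out$sigma) | out$sigma <= 0)) {
    abort("Column `sigma` must be strictly positive.")
  }
  out
}

# fractional-SD (absolute data-based) variance model: sigma_i = fsd * y_i
sigma_fsd <- function(y, fsd) {
  if (!is.numeric(fsd) || length(fsd) != 1L || !is.finite(fsd) || fsd <= 0) {
    abort("`fsd` must be a single positive fraction.")
  }
  if (any(y <= 0)) {
    abort("All activities must be > 0 to apply the fractional-SD variance model.")
  }
  fsd * y
}

# Splits a validated population tibble into a named list of curves:
# list(patient_id, t, y, sigma), in order of first appearance after sorting.
split_curves <- function(data) {
  ids <- unique(data$patient_id)
  stats::setNames(lapply(ids, function(id) {
    d <- data[data$patient_id == id, ]
    list(patient_id = id, t = d$time_h, y = d$activity_pct_ia, sigma = d$sigma)
  }), ids)
}
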