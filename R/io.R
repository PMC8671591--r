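#' Read a population time-activity CSV
#'
#' Expected columns: `patient_id`, `time_h`, `activity_pct_ia` (header
#' required); an optional `sigma` column carries measurement SDs, otherwise
#' SDs are attached later by [add_measurement_sd()] or by the fitting
#' functions. Samples are sorted by time within each patient and validated
#' (non-negative times, no duplicate (patient, time) pair, numeric fields).
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_population_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = TRUE)
  req <- c("patient_id", "time_h", "activity_pct_ia")
  missing <- setdiff(req, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("%s: missing column(s) %s.", path, paste(missing, collapse = ", ")))
  }
  for (col in c("time_h", "activity_pct_ia")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad) > 0) {
      abort(sprintf("%s: non-numeric value '%s' in column %s at data row %d.",
                    path, raw[[col]][bad[1]], col, bad[1]))
    }
    if (anyNA(v)) abort(sprintf("%s: missing value in column %s.", path, col))
    raw[[col]] <- v
  }
  out <- tibble::as_tibble(raw[intersect(c(req, "sigma"), names(raw))])
  out <- dplyr::arrange(out, .data$patient_id, .data$time_h)
  dup <- duplicated(out[c("patient_id", "time_h")])
  if (any(dup)) {
    abort(sprintf("%s: duplicate time %g h for patient %s.",
                  path, out$time_h[dup][1], out$patient_id[dup][1]))
  }
  out$patient_id <- as.character(out$patient_id)
  out
}

#' Write a population time-activity CSV
#'
#' @param data Data frame with at least `patient_id`, `time_h`,
#'   `activity_pct_ia`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_population_csv <- function(data, path) {
  req <- c("patient_id", "time_h", "activity_pct_ia")
  missing <- setdiff(req, names(data))
  if (length(missing) > 0) {
    abort(sprintf("Missing column(s): %s.", paste(missing, collapse = ", ")))
  }
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Reads and lightly validates a JSON run configuration; unknown keys error
# so typos do not silently fall back to defaults.
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("fsd", "cv_max", "corr_max", "resid_max", "weight_threshold",
             "half_life_h", "n_starts", "seed", "models", "shared_beta",
             "injected_activity_mbq")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown config key(s): %s.", paste(unknown, collapse = ", ")))
  }
  for (k in setdiff(known, "models")) {
    if (!is.null(cfg[[k]]) && (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1L)) {
      abort(sprintf("Config key '%s' must be a single number.", k))
    }
    if (!is.null(cfg[[k]]) && k != "seed" && cfg[[k]] <= 0) {
      abort(sprintf("Config key '%s' must be positive.", k))
    }
  }
  cfg
}

# Provenance stamp written next to every CLI output.
run_info <- function(out_dir, seed, config) {
  info <- list(seed = seed, config = config,
               config_hash = rlang::hash(list(seed = seed, config = config)),
               package_version = as.character(utils::packageVersion("pbmselect")))
  jsonlite::write_json(info, file.path(out_dir, "run_info.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(info)
}
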