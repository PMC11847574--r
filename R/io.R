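#' Read an amplitude table into an observation set
#'
#' Reads a CSV with columns `condition_id` and `amplitude` (one row per
#' sweep; RFC 4180, "." decimal). The baseline noise SD comes either from
#' the `noise_sd` argument or from a JSON sidecar `<path>.json` with a
#' `noise_sd` field. Row order is preserved within each condition.
#'
#' @param path Path to the CSV file.
#' @param noise_sd Baseline noise SD; overrides any sidecar value.
#' @param sign `1` or `-1`: sign convention applied on input (use `-1` for
#'   inward currents / hyperpolarizing potentials).
#' @return An [observation_set()].
#' @export
read_observation_csv <- function(path, noise_sd = NULL, sign = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("format error: '", path, "' contains no rows")
  need <- c("condition_id", "amplitude")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("format error: missing column(s) ", paste(miss, collapse = ", "))
  amp <- suppressWarnings(as.numeric(df$amplitude))
  if (anyNA(amp))
    stop("format error: non-numeric amplitude at row ",
         which(is.na(amp))[1L])
  if (is.null(noise_sd)) {
    sidecar <- paste0(path, ".json")
    if (file.exists(sidecar)) {
      meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
      noise_sd <- meta$noise_sd
    }
    if (is.null(noise_sd))
      stop("noise_sd not supplied and no sidecar '", sidecar, "' found")
  }
  cond <- factor(df$condition_id, levels = unique(df$condition_id))
  amps <- split(amp, cond)
  small <- which(vapply(amps, length, integer(1)) < 2L)
  if (length(small))
    stop("format error: condition '", names(amps)[small[1L]],
         "' has fewer than 2 sweeps")
  observation_set(amps, noise_sd = noise_sd,
                  condition_labels = levels(cond), sign = sign)
}

#' Write an observation set as an amplitude table
#'
#' Writes the `condition_id, amplitude` CSV and a JSON sidecar
#' (`<path>.json`) carrying `noise_sd` and the condition summary.
#'
#' @param obs An [observation_set()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_observation_csv <- function(obs, path) {
  stopifnot(inherits(obs, "observation_set"))
  df <- data.frame(
    condition_id = rep(obs$condition_labels, obs$counts),
    amplitude = unlist(obs$amplitudes, use.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(noise_sd = obs$noise_sd,
               condition_labels = obs$condition_labels,
               means = obs$means, ses = obs$ses, counts = obs$counts)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read/write sweep traces as two-column CSV
#'
#' The CSV has columns `time_s` and `value`; metadata (units, stimulus
#' times, baseline window) travel in a JSON sidecar `<path>.json`.
#'
#' @param path CSV path.
#' @return A [sweep_trace()].
#' @export
read_sweep_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "value") %in% names(df)))
    stop("format error: sweep CSV needs columns time_s, value")
  dt <- diff(df$time_s)
  if (any(dt <= 0) || diff(range(dt)) > 1e-9 * mean(dt))
    stop("format error: time_s must be regularly increasing")
  meta <- list()
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar))
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  sweep_trace(df$value, sample_interval = mean(dt),
              stimulus_times = meta$stimulus_times %||% numeric(),
              baseline_window = meta$baseline_window,
              units = meta$units %||% NA_character_)
}

#' @rdname read_sweep_csv
#' @param trace A [sweep_trace()].
#' @export
write_sweep_csv <- function(trace, path) {
  stopifnot(inherits(trace, "sweep_trace"))
  df <- data.frame(time_s = trace_times(trace), value = trace$samples)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(units = trace$units, stimulus_times = trace$stimulus_times,
               baseline_window = trace$baseline_window)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a long-format group table
#'
#' Columns: `group`, `unit_id`, `value`, and optionally `animal_id`.
#'
#' @param path CSV path.
#' @return A [group_sample()].
#' @export
read_group_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("group", "unit_id", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("format error: missing column(s) ", paste(miss, collapse = ", "))
  val <- suppressWarnings(as.numeric(df$value))
  if (anyNA(val))
    stop("format error: non-numeric value at row ", which(is.na(val))[1L])
  group_sample(val, group = df$group, unit_id = df$unit_id,
               animal_id = df$animal_id %||% NA)
}

#' Serialize quantal estimates to JSON
#'
#' Writes the point estimates, release probabilities and marginal posteriors
#' of a fit, plus a manifest (grid settings) sufficient to reproduce the
#' deterministic inference.
#'
#' @param fit A `bqa_fit` from [fit_bqa()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_estimates_json <- function(fit, path) {
  stopifnot(inherits(fit, "bqa_fit"))
  est <- fit$estimates
  out <- list(
    n_hat = est$n_hat, q_hat = est$q_hat, gamma_hat = est$gamma_hat,
    lambda_hat = est$lambda_hat, cv_hat = est$cv_hat, p_hat = est$p_hat,
    p_hat_warning = est$p_hat_warning,
    marginals = list(
      n_values = est$marginals$n_values, n = est$marginals$n,
      log_q_axis = est$marginals$log_q_axis, log_q = est$marginals$log_q,
      log_gamma_axis = est$marginals$log_gamma_axis,
      log_gamma = est$marginals$log_gamma),
    manifest = list(
      grid = unclass(fit$grid$spec), offset_L = fit$grid$offset_L,
      noise_sd = fit$obs$noise_sd, condition_means = fit$obs$means,
      condition_ses = fit$obs$ses, counts = fit$obs$counts,
      package_version = as.character(utils::packageVersion("synquant"))))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
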