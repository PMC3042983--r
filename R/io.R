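#' Write / read an ICP trajectory as CSV
#'
#' Trajectories are stored as UTF-8 CSV with header exactly
#' `time_min,icp_mmHg`, decimal point, one row per grid time. Metadata
#' (parameters, scheme, seed, step) goes to a sidecar JSON file with the
#' same basename and extension `.json`.
#'
#' @param trajectory An `icp_trajectory` (any tibble with columns
#'   `time_min`, `icp_mmHg` is accepted for writing).
#' @param path Output CSV path; the sidecar is written next to it.
#' @return `write_trajectory()`: the path, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  if (!all(c("time_min", "icp_mmHg") %in% names(trajectory))) {
    stop("trajectory must have columns time_min and icp_mmHg", call. = FALSE)
  }
  df <- data.frame(time_min = format_num(trajectory$time_min),
                   icp_mmHg = format_num(trajectory$icp_mmHg))
  readr::write_csv(df, path)
  meta <- list(
    scheme = attr(trajectory, "scheme"),
    seed = attr(trajectory, "seed"),
    dt = attr(trajectory, "dt"),
    params = params_to_list(attr(trajectory, "params"))
  )
  meta <- meta[!vapply(meta, is.null, logical(1))]
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

format_num <- function(x) {
  # fixed 15-significant-digit formatting keeps re-runs byte-identical
  sub("\\.?0+$", "", formatC(x, format = "f", digits = 15))
}

sidecar_path <- function(path) {
  paste0(sub("\\.[Cc][Ss][Vv]$", "", path), ".json")
}

params_to_list <- function(params) {
  if (is.null(params)) return(NULL)
  as.list(params[c("E", "R", "p_b", "I", "sigma")])
}

#' @rdname write_trajectory
#'
#' @details
#' `read_trajectory()` enforces the dialect: any header other than
#' `time_min,icp_mmHg` is a format error, non-numeric cells and
#' non-monotone times are reported with their row number. Rows with
#' non-positive pressures are kept — clinical recordings can contain
#' artifacts — but produce a warning and are listed in the `flagged_rows`
#' attribute.
#'
#' @return `read_trajectory()`: an `icp_trajectory` tibble; metadata
#'   restored from the sidecar JSON when present.
#' @export
read_trajectory <- function(path) {
  header <- readLines(path, n = 1L)
  if (!identical(header, "time_min,icp_mmHg")) {
    stop("format error in ", path, ": header must be exactly ",
         "'time_min,icp_mmHg' (got '", header, "')", call. = FALSE)
  }
  raw <- utils::read.csv(path, colClasses = "character")
  t <- suppressWarnings(as.numeric(raw$time_min))
  p <- suppressWarnings(as.numeric(raw$icp_mmHg))
  bad <- which(is.na(t) | is.na(p))
  if (length(bad)) {
    stop("format error in ", path, ": non-numeric cell(s) at data row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  nonmono <- which(diff(t) <= 0)
  if (length(nonmono)) {
    stop("format error in ", path, ": times not strictly increasing at data ",
         "row(s) ", paste(utils::head(nonmono + 1L, 5), collapse = ", "),
         call. = FALSE)
  }
  flagged <- which(p <= 0)
  if (length(flagged)) {
    warning("non-positive pressure at data row(s) ",
            paste(utils::head(flagged, 5), collapse = ", "),
            " (kept; see attr(, 'flagged_rows'))")
  }
  meta_file <- sidecar_path(path)
  meta <- if (file.exists(meta_file)) jsonlite::read_json(meta_file) else list()
  params <- if (!is.null(meta$params)) do.call(csf_params, meta$params) else NULL
  out <- new_trajectory(t, p,
                        scheme = meta$scheme %||% NA_character_,
                        seed = meta$seed %||% NA_integer_,
                        dt = meta$dt %||% stats::median(diff(t)),
                        params = params)
  attr(out, "flagged_rows") <- flagged
  out
}

#' Read / write a flat parameter config
#'
#' Parameter sets are exchanged as flat key/value JSON or YAML with keys
#' exactly `E`, `R`, `p_b`, `I`, `sigma` (units: mL^-1; mmHg.mL^-1.min;
#' mmHg; mL/min; mL/min). The format is chosen from the file extension
#' (`.json` vs `.yml`/`.yaml`).
#'
#' @param path File path.
#' @return `read_config()`: a validated [csf_params()] object.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    json = jsonlite::read_json(path),
    yml = ,
    yaml = yaml::read_yaml(path),
    stop("config must be .json, .yml or .yaml (got .", ext, ")", call. = FALSE)
  )
  keep <- intersect(c("E", "R", "p_b", "I", "sigma"), names(vals))
  do.call(csf_params, lapply(vals[keep], as.numeric))
}

#' @rdname read_config
#' @param params A [csf_params()] object.
#' @return `write_config()`: the path, invisibly.
#' @export
write_config <- function(params, path) {
  params <- validate_csf_params(params)
  vals <- params_to_list(params)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    json = jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA),
    yml = ,
    yaml = yaml::write_yaml(vals, path),
    stop("config must be .json, .yml or .yaml (got .", ext, ")", call. = FALSE)
  )
  invisible(path)
}

#' Synthetic infusion-study ICP recording
#'
#' Emulates a noisy constant-rate infusion study: a baseline phase with no
#' external infusion (`I = 0`, pressure settling around the baseline `p_b`)
#' followed by a constant-infusion phase at `infusion_rate` (standard
#' clinical rate 1.5 mL/min), simulated with the positivity-preserving
#' log-Euler scheme at a fine internal step and resampled at
#' `sampling_interval`. With `sigma = 0` the trace is piecewise
#' deterministic: flat at `p_b`, then a logistic rise toward `R*I + p_b`.
#'
#' @param params A [csf_params()] object; its `I` field is ignored in the
#'   baseline phase and replaced by `infusion_rate` during infusion.
#' @param baseline_duration Baseline phase length, min (> 0; default 10).
#' @param infusion_duration Infusion phase length, min (> 0; default 50).
#' @param infusion_rate Infusion rate, mL/min (default 1.5).
#' @param sampling_interval Output sampling interval, min (default 0.1,
#'   i.e. 6 s; must not exceed either phase duration).
#' @param p_init Initial pressure, mmHg; defaults to `p_b`.
#' @param seed Integer seed, or `NULL`.
#' @param dt Internal simulation step, min (default 1e-3).
#' @return An `icp_trajectory` tibble spanning both phases (time 0 =
#'   recording start; infusion begins at `baseline_duration`), with a
#'   `protocol` attribute recording the phase structure.
#' @examples
#' rec <- synth_infusion_recording(csf_params(), baseline_duration = 2,
#'                                 infusion_duration = 5, seed = 1)
#' tail(rec)
#' @export
synth_infusion_recording <- function(params, baseline_duration = 10,
                                     infusion_duration = 50,
                                     infusion_rate = 1.5,
                                     sampling_interval = 0.1,
                                     p_init = params$p_b, seed = NULL,
                                     dt = 1e-3) {
  params <- validate_csf_params(params)
  stopifnot(baseline_duration > 0, infusion_duration > 0,
            sampling_interval > 0,
            sampling_interval <= baseline_duration,
            sampling_interval <= infusion_duration,
            infusion_rate >= 0)
  thin <- max(1L, as.integer(round(sampling_interval / dt)))
  base_params <- params
  base_params$I <- 0
  inf_params <- params
  inf_params$I <- infusion_rate
  if (!is.null(seed)) seed <- as.integer(seed)
  scheme <- if (params$sigma == 0) "deterministic" else "log-euler"
  base <- simulate_icp(base_params, t_max = baseline_duration, dt = dt,
                       p_init = p_init,
                       seed = if (is.null(seed)) NULL else derive_seed(seed, 1L),
                       scheme = scheme, thin = thin)
  p_handoff <- base$icp_mmHg[nrow(base)]
  inf <- simulate_icp(inf_params, t_max = infusion_duration, dt = dt,
                      p_init = p_handoff,
                      seed = if (is.null(seed)) NULL else derive_seed(seed, 2L),
                      scheme = scheme, thin = thin)
  out <- new_trajectory(
    c(base$time_min, baseline_duration + inf$time_min[-1]),
    c(base$icp_mmHg, inf$icp_mmHg[-1]),
    scheme = scheme,
    seed = seed %||% NA_integer_,
    dt = dt, params = params
  )
  attr(out, "protocol") <- list(baseline_duration = baseline_duration,
                                infusion_duration = infusion_duration,
                                infusion_rate = infusion_rate,
                                sampling_interval = sampling_interval)
  out
}
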