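#' Load a run configuration from a YAML file
#'
#' The file is a flat key-value document. Unspecified fields are filled from
#' a named preset (`preset:` key, default `"valine_memory"`); unknown keys
#' are rejected. Recognized keys: `preset`, the kinetic parameters (`k1`,
#' `k_minus1`, `k2`, `k3`, `k4`, `k5`, `n`, `theta`, `c_total`,
#' `germination_threshold`), `pulses` (list of `start`/`end`/`concentration`
#' mappings), `horizon`, `gamma_shape`, `gamma_scale`, `n_spores`, `seed`.
#' All invariants of the component constructors are enforced.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated configuration list with elements `preset`, `params`,
#'   `protocol`, `gamma`, `n_spores`, `seed` (and `Ri_values` for the
#'   deterministic scan preset).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config must be a key-value mapping", call. = FALSE)
  # YAML 1.1 reads a bare `n` key as boolean FALSE; restore the Hill key
  names(raw)[names(raw) == "FALSE"] <- "n"
  kin_keys <- c("k1", "k_minus1", "k2", "k3", "k4", "k5", "n", "theta",
                "c_total", "germination_threshold")
  known <- c("preset", kin_keys, "pulses", "horizon",
             "gamma_shape", "gamma_scale", "n_spores", "seed")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)

  preset <- if (!is.null(raw$preset)) raw$preset else "valine_memory"
  base <- preset_config(preset)

  kin <- unclass(base$params)
  for (k in intersect(kin_keys, names(raw))) kin[[k]] <- raw[[k]]
  params <- do.call(kinetic_params, kin)

  protocol <- base$protocol
  if (!is.null(raw$pulses) || !is.null(raw$horizon)) {
    horizon <- if (!is.null(raw$horizon)) raw$horizon else protocol$horizon
    if (!is.null(raw$pulses)) {
      pl <- raw$pulses
      protocol <- pulse_protocol(
        start = vapply(pl, function(p) as.numeric(p$start), numeric(1)),
        end = vapply(pl, function(p) as.numeric(p$end), numeric(1)),
        concentration = vapply(pl, function(p) as.numeric(p$concentration),
                               numeric(1)),
        horizon = horizon)
    } else {
      protocol <- pulse_protocol(protocol$pulses$start, protocol$pulses$end,
                                 protocol$pulses$concentration, horizon)
    }
  }

  cfg <- list(preset = preset, params = params, protocol = protocol)
  if (!is.null(base$gamma)) {
    shape <- if (!is.null(raw$gamma_shape)) raw$gamma_shape else base$gamma$shape
    scale <- if (!is.null(raw$gamma_scale)) raw$gamma_scale else base$gamma$scale
    cfg$gamma <- gamma_spec(shape, scale)
    cfg$n_spores <- if (!is.null(raw$n_spores)) raw$n_spores else base$n_spores
    cfg$seed <- if (!is.null(raw$seed)) as.integer(raw$seed) else base$seed
  } else {
    cfg$Ri_values <- base$Ri_values
  }
  cfg
}

#' Write and read tables as CSV
#'
#' All tabular output uses comma-separated UTF-8 text with a mandatory
#' header row and `.` as the decimal mark.
#'
#' @param trajectory A `spore_trajectory`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @name table_io
NULL

#' @rdname table_io
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "spore_trajectory"))
  utils::write.csv(as.data.frame(trajectory), path, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @param result An `ensemble_result`.
#' @export
write_ensemble_table <- function(result, path) {
  stopifnot(inherits(result, "ensemble_result"))
  utils::write.csv(result$records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @param curve A `germination_curve` data frame.
#' @export
write_germination_curve <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_germination_curve <- function(path) {
  df <- utils::read.csv(path)
  structure(df, class = c("germination_curve", "data.frame"))
}

#' Read an experimental percentage-germination curve
#'
#' Expects delimited text with a header naming a time column (matching
#' `time`) and a percentage column (matching `percent` or `pct`); extra
#' columns are kept as metadata attributes. Percentages must lie in
#' `[0, 100]`; unsorted times are sorted with a warning.
#'
#' @param path Path to the CSV file.
#' @return An object of classes `experimental_curve`/`data.frame` with
#'   columns `time_min` and `percent_germinated`.
#' @export
read_experimental_curve <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  tcol <- grep("time", names(df), ignore.case = TRUE, value = TRUE)
  pcol <- grep("percent|pct", names(df), ignore.case = TRUE, value = TRUE)
  if (length(tcol) < 1L || length(pcol) < 1L)
    stop("need a time column and a percent column", call. = FALSE)
  t <- df[[tcol[1L]]]; p <- df[[pcol[1L]]]
  if (!is.numeric(t) || !is.numeric(p) || anyNA(t) || anyNA(p))
    stop("time and percent columns must be numeric without missing values",
         call. = FALSE)
  if (any(p < 0 | p > 100))
    stop("percentages must lie in [0, 100]", call. = FALSE)
  if (is.unsorted(t)) {
    warning("times were not sorted; sorting", call. = FALSE)
    o <- order(t); t <- t[o]; p <- p[o]
  }
  structure(data.frame(time_min = t, percent_germinated = p),
            class = c("experimental_curve", "data.frame"))
}

#' Compare a model curve with an experimental curve
#'
#' Linearly interpolates the model curve onto the experimental time points
#' (restricted to the overlap of the two time ranges) and reports deviations
#' in percentage points.
#'
#' @param model A `germination_curve` (columns `time_min`,
#'   `pct_germinated`).
#' @param data An `experimental_curve` from [read_experimental_curve()] (or
#'   any data frame with `time_min` and `percent_germinated`).
#' @return List with `rmse`, `max_abs_dev`, `n_points` and `residuals`
#'   (data frame: `time_min`, `model`, `data`, `delta`).
#' @export
compare_curves <- function(model, data) {
  mt <- model$time_min; mp <- model$pct_germinated
  dt <- data$time_min; dp <- data$percent_germinated
  lo <- max(min(mt), min(dt)); hi <- min(max(mt), max(dt))
  if (lo > hi) stop("curves have disjoint time ranges", call. = FALSE)
  keep <- dt >= lo & dt <= hi
  if (!any(keep)) stop("no experimental points inside the overlap", call. = FALSE)
  dt <- dt[keep]; dp <- dp[keep]
  mi <- stats::approx(mt, mp, xout = dt)$y
  delta <- mi - dp
  list(rmse = sqrt(mean(delta^2)),
       max_abs_dev = max(abs(delta)),
       n_points = length(delta),
       residuals = data.frame(time_min = dt, model = mi, data = dp,
                              delta = delta))
}

#' Write a reproducibility manifest
#'
#' Records everything needed to re-run a simulation bit-identically: the
#' configuration snapshot, seed, solver tolerances, package version, a
#' timestamp and an MD5-checksummed inventory of the output files.
#'
#' @param path Manifest output path (JSON).
#' @param config Configuration list (as from [load_config()] or an
#'   `ensemble_config`).
#' @param files Character vector of produced output files.
#' @param seed Integer seed used.
#' @param tolerances Named list of solver tolerances.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, config, files, seed,
                           tolerances = list(rtol = 1e-8, atol = 1e-8)) {
  inventory <- lapply(files, function(f) list(
    file = f, md5 = unname(tools::md5sum(f)), bytes = file.size(f)))
  manifest <- list(
    package = "sporemem",
    version = as.character(utils::packageVersion("sporemem")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    tolerances = tolerances,
    config = serialize_config(config),
    outputs = inventory)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

serialize_config <- function(config) {
  strip <- function(x) {
    if (inherits(x, "pulse_protocol"))
      return(list(pulses = as.list(x$pulses), horizon = x$horizon))
    if (is.data.frame(x)) return(as.list(x))
    if (is.list(x)) return(lapply(unclass(x), strip))
    x
  }
  strip(config)
}
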