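#' @name io
#' @title File formats
#' @description CSV is the interchange format for all time-series (markers,
#'   EMG envelopes, states, forces): an explicit `time` column in seconds, one
#'   named column per channel, and a leading `#` comment row stating units.
#'   Models round-trip through a YAML schema mirroring the `msk_model`
#'   structure; every run writes a JSON sidecar with the resolved
#'   configuration, seeds and a content hash of the model. All writes are
#'   atomic (temp file + rename).
NULL

atomic_write <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

write_timeseries_csv <- function(path, time, mat, names, units) {
  df <- tibble::as_tibble(setNames(as.data.frame(t(mat)), names))
  df <- dplyr::bind_cols(tibble::tibble(time = time), df)
  atomic_write(path, function(tmp) {
    writeLines(paste0("# units: time s, channels ", units), tmp)
    readr::write_csv(df, tmp, append = TRUE, col_names = TRUE)
  })
}

read_timeseries_csv <- function(path) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  if (!"time" %in% names(df)) abort("CSV must contain a 'time' column")
  if (any(diff(df$time) <= 0)) abort("non-monotone timestamps")
  list(time = df$time,
       mat = t(as.matrix(df[, setdiff(names(df), "time"), drop = FALSE])))
}

#' Write / read marker trajectories as CSV
#'
#' Columns `<MARKER>_x/_y/_z` in meters plus `time` in seconds.
#'
#' @param markers matrix (3*nmark x T), rows x,y,z per marker.
#' @param time timestamps (s).
#' @param names marker names.
#' @param path file path.
#' @return `read_markers_csv`: list with `time`, `markers` (3*nmark x T) and
#'   `names`; when `model` is given, columns are reconciled against (and
#'   reordered to) the model's marker names.
#' @export
write_markers_csv <- function(markers, time, names, path) {
  cols <- as.vector(t(outer(names, c("x", "y", "z"), paste, sep = "_")))
  write_timeseries_csv(path, time, markers, cols, "m")
}

#' @rdname write_markers_csv
#' @param model optional `msk_model` for label reconciliation.
#' @export
read_markers_csv <- function(path, model = NULL) {
  ts <- read_timeseries_csv(path)
  lab <- rownames(ts$mat)
  mk <- unique(sub("_[xyz]$", "", lab))
  want <- as.vector(t(outer(mk, c("x", "y", "z"), paste, sep = "_")))
  if (!setequal(lab, want)) abort("marker CSV needs _x/_y/_z triplets")
  mat <- ts$mat[match(want, lab), , drop = FALSE]
  if (!is.null(model)) {
    mn <- cm(model)$marker_names
    if (!setequal(mk, mn))
      abort(paste0("marker labels do not match the model: missing ",
                   paste(setdiff(mn, mk), collapse = ", ")))
    ord <- as.vector(t(outer(mn, c("x", "y", "z"), paste, sep = "_")))
    mat <- mat[match(ord, want), , drop = FALSE]
    mk <- mn
  }
  list(time = ts$time, markers = unname(mat), names = mk)
}

#' Write / read EMG envelopes as CSV
#'
#' One column per muscle element, values in `[0, 1]`; values within
#' `[-0.01, 1.01]` are clipped with a warning, values outside are an error.
#'
#' @param emg matrix (nmus x T).
#' @param time timestamps (s).
#' @param names muscle element names.
#' @param path file path.
#' @return `read_emg_csv`: list with `time`, `emg`, `names` (model order
#'   when `model` given).
#' @export
write_emg_csv <- function(emg, time, names, path) {
  write_timeseries_csv(path, time, emg, names, "normalized excitation [0,1]")
}

#' @rdname write_emg_csv
#' @param model optional `msk_model` for channel reconciliation.
#' @export
read_emg_csv <- function(path, model = NULL) {
  ts <- read_timeseries_csv(path)
  emg <- ts$mat
  if (any(emg < -0.01 | emg > 1.01)) abort("EMG values far outside [0, 1]")
  if (any(emg < 0 | emg > 1)) {
    warn("EMG values slightly outside [0, 1]; clipping")
    emg <- pmin(pmax(emg, 0), 1)
  }
  nm <- rownames(ts$mat)
  if (!is.null(model)) {
    mn <- cm(model)$muscle_names
    if (!setequal(nm, mn))
      abort(paste0("EMG channels do not match the model: unknown ",
                   paste(setdiff(nm, mn), collapse = ", ")))
    emg <- emg[match(mn, nm), , drop = FALSE]
    nm <- mn
  }
  list(time = ts$time, emg = unname(emg), names = nm)
}

#' Write / read a model as YAML
#'
#' @param model a `msk_model`.
#' @param path file path.
#' @return `read_model_yaml` returns a validated `msk_model`.
#' @export
write_model_yaml <- function(model, path) {
  obj <- list(name = model$name, gravity = model$gravity,
              passive_scale = model$passive_scale,
              act_switch_k = model$act_switch_k,
              segments = model$segments, markers = model$markers,
              muscles = model$muscles)
  atomic_write(path, function(tmp) yaml::write_yaml(obj, tmp, precision = 12))
}

#' @rdname write_model_yaml
#' @export
read_model_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  msk_model(obj$segments, obj$markers, obj$muscles,
            gravity = obj$gravity %||% c(0, 0, -9.81),
            name = obj$name %||% "model",
            passive_scale = obj$passive_scale %||% 1,
            act_switch_k = obj$act_switch_k %||% 100)
}

#' Run sidecar (JSON provenance)
#'
#' @param path sidecar path.
#' @param config named list (settings, seeds, noise levels, ...).
#' @param model optional model whose content hash is embedded.
#' @return `read_run_sidecar` returns the parsed list.
#' @export
write_run_sidecar <- function(path, config, model = NULL) {
  config$package_version <- as.character(packageVersion("mhemuscle"))
  if (!is.null(model)) config$model_hash <- hash(cm(model))
  atomic_write(path, function(tmp)
    jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE))
}

#' @rdname write_run_sidecar
#' @export
read_run_sidecar <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

#' Write a reference dataset to a directory
#'
#' Emits `markers.csv`, `emg.csv` (clean excitations), `states.csv`,
#' `forces.csv` and `reference.json` (provenance sidecar).
#'
#' @param ref a `ref_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_reference <- function(ref, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cmod <- cm(ref$model)
  nq <- cmod$nq
  write_markers_csv(ref$markers, ref$time, cmod$marker_names,
                    file.path(dir, "markers.csv"))
  Tu <- ncol(ref$excitations)
  write_emg_csv(ref$excitations, ref$time[seq_len(Tu)], cmod$muscle_names,
                file.path(dir, "emg.csv"))
  st_names <- c(paste0("q_", cmod$joint_names), paste0("qd_", cmod$joint_names),
                paste0("a_", cmod$muscle_names))
  write_timeseries_csv(file.path(dir, "states.csv"), ref$time, ref$states,
                       st_names, "rad, rad/s, activation")
  write_timeseries_csv(file.path(dir, "forces.csv"), ref$time, ref$forces,
                       paste0("F_", cmod$muscle_names), "N")
  write_run_sidecar(file.path(dir, "reference.json"),
                    list(kind = "reference", duration = ref$duration,
                         n_nodes = ref$n_nodes,
                         cocontraction = ref$cocontraction,
                         seed = ref$seed, config_hash = ref$config_hash),
                    ref$model)
  invisible(dir)
}
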