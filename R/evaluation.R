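#' Root-mean-square error between estimated and reference trajectories
#'
#' Aligns the stored estimates with the reference on timestamps (inner join
#' on the time grid) and pools the squared differences over channels and
#' time. Units: degrees for joint angles, newtons for muscle forces, meters
#' for marker positions (angles are converted rad -> deg at this reporting
#' boundary only).
#'
#' @param estimated an `mhe_fit`.
#' @param reference a `ref_dataset`.
#' @param quantity `"angles"`, `"forces"` or `"markers"`.
#' @return A single RMSE value.
#' @export
rmse <- function(estimated, reference,
                 quantity = c("angles", "forces", "markers")) {
  quantity <- match.arg(quantity)
  al <- align_frames(estimated, reference)
  if (length(al$est_idx) == 0) abort("no overlapping timestamps")
  cmod <- cm(reference$model)
  nq <- cmod$nq
  diff <- switch(
    quantity,
    angles = (estimated$states[seq_len(nq), al$est_idx, drop = FALSE] -
                reference$states[seq_len(nq), al$ref_idx, drop = FALSE]) *
      180 / pi,
    forces = estimated$forces[, al$est_idx, drop = FALSE] -
      reference$forces[, al$ref_idx, drop = FALSE],
    markers = {
      qest <- estimated$states[seq_len(nq), al$est_idx, drop = FALSE]
      est_m <- apply(qest, 2, function(q) fk_markers_flat(cmod, q))
      est_m - reference$markers[, al$ref_idx, drop = FALSE]
    })
  sqrt(mean(diff^2))
}

align_frames <- function(estimated, reference) {
  te <- round(estimated$time, 9)
  tr <- round(reference$time, 9)
  common <- intersect(te, tr)
  list(est_idx = match(common, te), ref_idx = match(common, tr))
}

#' Score one estimation run against its reference
#'
#' @param fit an `mhe_fit`.
#' @param ref the generating `ref_dataset`.
#' @return One-row tibble: RMSE on angles (deg), forces (N), markers (m),
#'   convergence rate, and the `kept` flag (convergence rate > 90%, the
#'   trial-exclusion rule).
#' @export
score_run <- function(fit, ref) {
  tibble::tibble(
    rmse_q_deg = rmse(fit, ref, "angles"),
    rmse_force_n = rmse(fit, ref, "forces"),
    rmse_markers_m = rmse(fit, ref, "markers"),
    convergence_rate = fit$convergence_rate,
    kept = fit$convergence_rate > 0.9)
}

#' Real-time subsampling factor for a window size
#'
#' Emulates the real-time coupling between window size and effective
#' measurement rate: larger windows solve more slowly, so the 100 Hz data
#' must be subsampled more aggressively. The linear rate model (about 30 Hz
#' at window 3 decaying to about 10 Hz at window 20) reproduces the
#' characteristic operating points, including factor 4 (~25 Hz) at window 7.
#'
#' @param window window size in frames.
#' @param native_rate_hz native data rate.
#' @return Integer subsampling factor >= 1.
#' @export
realtime_subsample_factor <- function(window, native_rate_hz = 100) {
  rate <- pmax(8, 33.5 - 1.2 * window)
  pmax(1L, as.integer(round(native_rate_hz / rate)))
}

#' Window-size sweep on noiseless data
#'
#' Runs the estimator for each window size on the (noiseless) reference
#' stream, subsampled per [realtime_subsample_factor()], and scores joint
#' angle, force and marker RMSE. Optionally adds the offline full-window
#' baseline as `window = Inf`.
#'
#' @param model a `msk_model`.
#' @param ref a `ref_dataset` generated with that model.
#' @param sizes integer window sizes (default 3 to 20).
#' @param formulations subset of `c("excitation", "activation")`.
#' @param weights a [cost_weights()].
#' @param full_window also run the offline baseline.
#' @param subsample_rule function window -> integer factor.
#' @return A `window_sweep` tibble: window, formulation, subsample factor,
#'   the three RMSE columns, convergence rate.
#' @export
window_sweep <- function(model, ref, sizes = 3:20,
                         formulations = "excitation",
                         weights = cost_weights(),
                         full_window = FALSE,
                         subsample_rule = realtime_subsample_factor) {
  stream0 <- as_measurement_stream(ref)
  rows <- list()
  for (form in formulations) {
    for (N in sizes) {
      k <- subsample_rule(N)
      stream <- subsample_stream(stream0, k)
      row <- tibble::tibble(window = N, formulation = form,
                            subsample = k)
      fit <- tryCatch(
        run_mhe(stream, mhe_problem(model, N, form, weights)),
        error = function(e) e)
      if (inherits(fit, "error")) {
        row$error <- conditionMessage(fit)
        rows[[length(rows) + 1]] <- row
        next
      }
      rows[[length(rows) + 1]] <- dplyr::bind_cols(row, score_run(fit, ref))
    }
    if (full_window) {
      fit <- full_window_estimate(stream0, mhe_problem(model, 2, form, weights))
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble::tibble(window = Inf, formulation = form, subsample = 1L),
        score_run(fit, ref))
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("window_sweep", class(out))
  out
}

noise_levels <- c("none", "low", "mid", "high")

#' Fully crossed experimental grid
#'
#' The study design: marker noise x EMG noise x co-contraction, each at four
#' levels, with seeded repetitions (full scale 4 x 4 x 4 x 30).
#'
#' @param marker_levels,emg_levels,cocontraction_levels factor levels.
#' @param reps repetitions per cell.
#' @param variants cost variants to run.
#' @param seed_base base seed; each (cell, repetition) gets a unique seed.
#' @return An `experiment_grid` tibble with one row per cell x repetition.
#' @export
experiment_grid <- function(marker_levels = noise_levels,
                            emg_levels = noise_levels,
                            cocontraction_levels = noise_levels,
                            reps = 30,
                            variants = c("track_emg_high_marker",
                                         "min_excitation"),
                            seed_base = 1000L) {
  g <- tidyr::expand_grid(
    marker_noise = factor(marker_levels, noise_levels),
    emg_noise = factor(emg_levels, noise_levels),
    cocontraction = factor(cocontraction_levels, noise_levels),
    rep = seq_len(reps))
  g$seed <- seed_base + 17L * (seq_len(nrow(g)) - 1L)
  attr(g, "variants") <- variants
  class(g) <- c("experiment_grid", class(g))
  g
}

#' Run the noise / co-contraction grid
#'
#' For every cell x repetition: corrupt the matching reference with the
#' cell's seeded noise draw, run the estimator at the fixed window for each
#' cost variant, and score it. Trials whose convergence rate is not above
#' 90% are flagged `kept = FALSE` and excluded from downstream ANOVA.
#'
#' @param grid an [experiment_grid()].
#' @param model a `msk_model`.
#' @param refs named list of `ref_dataset`s, one per co-contraction level
#'   appearing in the grid.
#' @param window window size (study choice: 7).
#' @param subsample subsampling factor (study operating point: 4).
#' @param formulation model formulation.
#' @return A `score_table` tibble: factors, rep, variant, RMSE columns,
#'   convergence rate, kept flag.
#' @export
run_grid <- function(grid, model, refs, window = 7, subsample = 4,
                     formulation = "excitation") {
  variants <- attr(grid, "variants") %||% "track_emg_high_marker"
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    cell <- grid[i, ]
    ref <- refs[[as.character(cell$cocontraction)]]
    if (is.null(ref)) abort(paste0("missing reference for co-contraction '",
                                   as.character(cell$cocontraction), "'"))
    spec <- noise_spec(emg_level = as.character(cell$emg_noise),
                       marker_level = as.character(cell$marker_noise),
                       seed = cell$seed)
    stream <- corrupt_reference(ref, spec)
    stream <- subsample_stream(stream, subsample)
    for (v in variants) {
      fit <- tryCatch(
        run_mhe(stream, mhe_problem(model, window, formulation,
                                    cost_weights(v))),
        error = function(e) e)
      base <- dplyr::bind_cols(
        cell[, c("marker_noise", "emg_noise", "cocontraction", "rep", "seed")],
        tibble::tibble(variant = v))
      if (inherits(fit, "error")) {
        base$error <- conditionMessage(fit)
        rows[[length(rows) + 1]] <- base
      } else {
        rows[[length(rows) + 1]] <- dplyr::bind_cols(base, score_run(fit, ref))
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("score_table", class(out))
  out
}
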