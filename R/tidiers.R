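#' Tidy a reference dataset
#'
#' @param x a `ref_dataset`.
#' @param ... unused.
#' @return Long tibble: `time`, `kind` (angle / velocity / activation /
#'   excitation / force), `channel`, `value`.
#' @export
tidy.ref_dataset <- function(x, ...) {
  cmod <- cm(x$model)
  nq <- cmod$nq
  long <- function(mat, kind, channels, time) {
    tidyr::pivot_longer(
      dplyr::bind_cols(tibble::tibble(time = time),
                       setNames(as.data.frame(t(mat)), channels)),
      -"time", names_to = "channel", values_to = "value") |>
      dplyr::mutate(kind = kind, .after = "time")
  }
  dplyr::bind_rows(
    long(x$states[seq_len(nq), , drop = FALSE], "angle",
         cmod$joint_names, x$time),
    long(x$states[nq + seq_len(nq), , drop = FALSE], "velocity",
         cmod$joint_names, x$time),
    long(x$states[2 * nq + seq_len(cmod$nmus), , drop = FALSE], "activation",
         cmod$muscle_names, x$time),
    long(x$excitations, "excitation", cmod$muscle_names,
         x$time[seq_len(ncol(x$excitations))]),
    long(x$forces, "force", cmod$muscle_names, x$time))
}

#' Tidy an estimation result
#'
#' @param x an `mhe_fit`.
#' @param ... unused.
#' @return Long tibble: `time`, `kind`, `channel`, `value` of the stored
#'   estimates (angles, velocities, controls, forces).
#' @export
tidy.mhe_fit <- function(x, ...) {
  cmod <- cm(x$problem$model)
  nq <- cmod$nq
  long <- function(mat, kind, channels) {
    tidyr::pivot_longer(
      dplyr::bind_cols(tibble::tibble(time = x$time),
                       setNames(as.data.frame(t(mat)), channels)),
      -"time", names_to = "channel", values_to = "value") |>
      dplyr::mutate(kind = kind, .after = "time")
  }
  dplyr::bind_rows(
    long(x$states[seq_len(nq), , drop = FALSE], "angle", cmod$joint_names),
    long(x$states[nq + seq_len(nq), , drop = FALSE], "velocity",
         cmod$joint_names),
    long(x$controls, "control", cmod$muscle_names),
    long(x$forces, "force", cmod$muscle_names))
}

#' One-row summary of an estimation run
#'
#' @param x an `mhe_fit`.
#' @param ... unused.
#' @return Tibble: solves, convergence rate, achieved flag, median
#'   iterations, window, dt, formulation, variant.
#' @export
glance.mhe_fit <- function(x, ...) {
  tibble::tibble(
    n_solves = length(x$converged),
    convergence_rate = x$convergence_rate,
    achieved = x$achieved,
    median_iterations = median(x$iterations),
    window = x$window, dt = x$dt,
    formulation = x$formulation, variant = x$variant)
}

#' Tidy ANOVA effects
#'
#' @param x an `mhe_anova`.
#' @param ... unused.
#' @return The effects tibble (term, df, sumsq, statistic, p.value).
#' @export
tidy.mhe_anova <- function(x, ...) x$effects

#' One-row ANOVA summary
#'
#' @param x an `mhe_anova`.
#' @param ... unused.
#' @return Tibble: response, n, number of significant terms at alpha.
#' @export
glance.mhe_anova <- function(x, ...) {
  tibble::tibble(
    response = x$response, n = x$n, alpha = x$alpha,
    n_significant_terms = sum(x$effects$p.value < x$alpha, na.rm = TRUE))
}
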