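#' Noise specification
#'
#' Defines the two synthetic noise channels: low-frequency Fourier-domain EMG
#' noise (complex Gaussian perturbations of all coefficients up to
#' `emg_cutoff_hz`, conjugate-symmetric so the inverse transform is real) and
#' marker placement error (a single isotropic Gaussian displacement of each
#' marker's local position on a surrogate model).
#'
#' @param emg_level,marker_level `"none"`, `"low"`, `"mid"` or `"high"`.
#' @param emg_sd named vector mapping EMG levels to the time-domain standard
#'   deviation of the added low-frequency perturbation (normalized excitation
#'   units).
#' @param marker_sd named vector mapping marker levels to placement standard
#'   deviations in meters (0, 2, 5, 10 mm).
#' @param emg_cutoff_hz highest perturbed frequency (Hz).
#' @param seed RNG seed for reproducible draws.
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(emg_level = "none", marker_level = "none",
                       emg_sd = c(none = 0, low = 0.05, mid = 0.1, high = 0.2),
                       marker_sd = c(none = 0, low = 0.002, mid = 0.005,
                                     high = 0.010),
                       emg_cutoff_hz = 2.125, seed = 1L) {
  emg_level <- match.arg(emg_level, names(emg_sd))
  marker_level <- match.arg(marker_level, names(marker_sd))
  stopifnot(all(emg_sd >= 0), all(marker_sd >= 0), emg_cutoff_hz > 0)
  structure(list(emg_level = emg_level, marker_level = marker_level,
                 emg_sd = emg_sd, marker_sd = marker_sd,
                 emg_cutoff_hz = emg_cutoff_hz, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Corrupt EMG envelopes with low-frequency Fourier-domain noise
#'
#' Per channel: discrete Fourier transform, additive complex Gaussian
#' perturbation of every coefficient with |frequency| <= cutoff (conjugate
#' symmetry preserved; DC kept real), inverse transform, clip to `[0, 1]`.
#' The input is never modified; the clean ground truth stays with the caller.
#'
#' @param excitations matrix (muscles x frames) of clean envelopes in
#'   `[0, 1]`.
#' @param spec a [noise_spec()].
#' @param rate sampling rate in Hz (uniform grid required).
#' @param seed overrides `spec$seed` when given.
#' @return Noisy matrix, same shape, values in `[0, 1]`.
#' @export
corrupt_emg <- function(excitations, spec, rate = 100, seed = NULL) {
  stopifnot(is.matrix(excitations))
  sdt <- spec$emg_sd[[spec$emg_level]]
  if (sdt == 0) return(excitations)
  T <- ncol(excitations)
  kk <- 0:(T - 1)
  freq <- pmin(kk, T - kk) * rate / T
  pert_half <- which(freq[1:(floor(T / 2) + 1)] <= spec$emg_cutoff_hz)  # 1-based
  n_half <- length(pert_half)
  # The level is calibrated on the full-scale signal (8 s at 100 Hz, where
  # 35 coefficients fall below the 2.125 Hz cutoff): the added noise has
  # time-domain std level/sqrt(35) regardless of the record length, so
  # shorter desk-scale records carry the same noise magnitude.
  sd_time <- sdt / sqrt(35)
  sc <- sd_time * T / sqrt(2 * n_half - 1)
  withr_seed <- seed %||% spec$seed
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(withr_seed)
  out <- excitations
  for (ch in seq_len(nrow(excitations))) {
    co <- fft(excitations[ch, ])
    for (j in pert_half) {
      k <- j - 1                              # 0-based frequency index
      if (k == 0 || (T %% 2 == 0 && k == T / 2)) {
        co[j] <- co[j] + rnorm(1, sd = sc)    # self-conjugate bins stay real
      } else {
        d <- complex(real = rnorm(1, sd = sc), imaginary = rnorm(1, sd = sc))
        co[k + 1] <- co[k + 1] + d
        co[T - k + 1] <- co[T - k + 1] + Conj(d)
      }
    }
    out[ch, ] <- pmin(pmax(Re(fft(co, inverse = TRUE)) / T, 0), 1)
  }
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Displace marker placements on a surrogate model
#'
#' Draws one zero-mean isotropic Gaussian 3-vector per marker (per-axis std
#' `sigma/sqrt(3)`) and adds it to the marker's LOCAL position; segments and
#' muscles are untouched. The displacement is constant over time (a placement
#' error, not per-frame jitter). Offsets are recorded for audit.
#'
#' @param model a `msk_model`.
#' @param marker_level noise level (or a [noise_spec()]).
#' @param seed RNG seed.
#' @return The surrogate `msk_model`; drawn offsets (m) in attribute
#'   `"placement_offsets"`.
#' @export
corrupt_marker_placement <- function(model, marker_level = "mid", seed = 1L) {
  spec <- if (inherits(marker_level, "noise_spec")) marker_level else
    noise_spec(marker_level = marker_level, seed = seed)
  sigma <- spec$marker_sd[[spec$marker_level]]
  nm <- length(model$markers)
  if (sigma == 0) {
    offsets <- matrix(0, 3, nm)
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    offsets <- matrix(rnorm(3 * nm, sd = sigma / sqrt(3)), 3, nm)
  }
  surrogate <- model
  for (i in seq_len(nm))
    surrogate$markers[[i]]$position <-
      as.numeric(surrogate$markers[[i]]$position) + offsets[, i]
  surrogate$compiled <- compile_model(surrogate)
  colnames(offsets) <- vapply(model$markers, `[[`, "", "name")
  attr(surrogate, "placement_offsets") <- offsets
  surrogate
}

#' Re-simulate marker trajectories with a surrogate model
#'
#' Forward kinematics of the surrogate at every frame of a joint-angle
#' trajectory; how placement error propagates into the tracked marker data.
#'
#' @param surrogate a (surrogate) `msk_model`.
#' @param q_trajectory matrix nq x T of joint angles.
#' @return Matrix (3*nmark x T) of marker positions, rows ordered x,y,z per
#'   marker.
#' @export
resimulate_markers <- function(surrogate, q_trajectory) {
  cmod <- cm(surrogate)
  apply(q_trajectory, 2, function(q) fk_markers_flat(cmod, q))
}

#' Corrupt a reference dataset into a noisy measurement stream
#'
#' Applies both noise channels at the reference rate and returns a
#' measurement stream ready for estimation; the reference is not modified.
#'
#' @param ref a `ref_dataset`.
#' @param spec a [noise_spec()].
#' @param seed overrides `spec$seed`.
#' @return A `measurement_stream` with noisy markers and EMG; the surrogate
#'   placement offsets ride along as attribute `"placement_offsets"`.
#' @export
corrupt_reference <- function(ref, spec, seed = NULL) {
  seed <- seed %||% spec$seed
  stream <- as_measurement_stream(ref)
  emg_noisy <- corrupt_emg(stream$emg, spec, rate = 1 / ref$dt, seed = seed)
  surrogate <- corrupt_marker_placement(ref$model, spec, seed = seed + 1L)
  nq <- cm(ref$model)$nq
  stream$emg <- emg_noisy
  stream$markers <- resimulate_markers(surrogate,
                                       ref$states[seq_len(nq), , drop = FALSE])
  attr(stream, "placement_offsets") <- attr(surrogate, "placement_offsets")
  stream$noise <- list(emg_level = spec$emg_level,
                       marker_level = spec$marker_level, seed = seed)
  stream
}
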