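test_that("RMSE has the closed-form behavior and reporting units", {
  ref <- fixture_ref()
  fit <- memo("fit_noiseless", function() {
    run_mhe(as_measurement_stream(ref), mhe_problem(fixture_model(), 7))
  })
  # identical trajectories score zero
  self <- fit
  self$states <- ref$states[, seq_along(fit$time)]
  self$forces <- ref$forces[, seq_along(fit$time)]
  self$time <- ref$time[seq_along(fit$time)]
  expect_equal(rmse(self, ref, "angles"), 0)
  expect_equal(rmse(self, ref, "forces"), 0)
  expect_equal(rmse(self, ref, "markers"), 0)
  # a constant offset on every channel scores |offset| (in degrees)
  off <- self
  off$states <- off$states + 0.1
  expect_equal(rmse(off, ref, "angles"), 0.1 * 180 / pi, tolerance = 1e-10)
  off$forces <- self$forces - 2.5
  expect_equal(rmse(off, ref, "forces"), 2.5, tolerance = 1e-10)
  # disjoint time grids are an alignment error
  shifted <- self
  shifted$time <- self$time + 1e-3
  expect_error(rmse(shifted, ref, "angles"), "overlap")
})

test_that("score_run applies the 90% convergence exclusion rule", {
  ref <- fixture_ref()
  fit <- memo("fit_noiseless", function() {
    run_mhe(as_measurement_stream(ref), mhe_problem(fixture_model(), 7))
  })
  sc <- score_run(fit, ref)
  expect_named(sc, c("rmse_q_deg", "rmse_force_n", "rmse_markers_m",
                     "convergence_rate", "kept"))
  expect_equal(sc$kept, sc$convergence_rate > 0.9)
  fit2 <- fit
  fit2$convergence_rate <- 0.85
  expect_false(score_run(fit2, ref)$kept)
})

test_that("the real-time subsampling rule reproduces the operating points", {
  expect_equal(realtime_subsample_factor(7), 4L)    # ~25 Hz at window 7
  expect_gte(realtime_subsample_factor(20), 10L)    # ~10 Hz at window 20
  expect_lte(realtime_subsample_factor(3), 4L)      # ~30 Hz at window 3
  expect_true(all(diff(realtime_subsample_factor(3:20)) >= 0))
})

test_that("window sweep scores several sizes and flags per-run errors", {
  sweep <- memo("sweep", function() {
    window_sweep(fixture_model(), fixture_ref(), sizes = c(3, 5, 7, 11, 15))
  })
  expect_s3_class(sweep, "window_sweep")
  expect_equal(nrow(sweep), 5)
  expect_true(all(is.finite(sweep$rmse_force_n)))
  expect_true(all(sweep$subsample == realtime_subsample_factor(sweep$window)))
})

test_that("a reduced seeded grid completes, reproduces bit-exactly, and keeps factors", {
  refs <- list(none = fixture_ref_cc("none"), mid = fixture_ref_cc("mid"))
  grid <- experiment_grid(marker_levels = "mid", emg_levels = c("none", "mid"),
                          cocontraction_levels = c("none", "mid"), reps = 1,
                          variants = c("track_emg_high_marker",
                                       "min_excitation"),
                          seed_base = 4000L)
  expect_equal(nrow(grid), 4)
  expect_equal(length(unique(grid$seed)), 4)
  scores <- memo("grid_scores", function()
    run_grid(grid, fixture_model(), refs, window = 7, subsample = 2))
  expect_s3_class(scores, "score_table")
  expect_equal(nrow(scores), 8)          # 4 cells x 2 variants
  expect_true(all(c("rmse_force_n", "convergence_rate", "kept") %in%
                    names(scores)))
  scores2 <- run_grid(grid, fixture_model(), refs, window = 7, subsample = 2)
  expect_identical(scores$rmse_force_n, scores2$rmse_force_n)
})

test_that("force error directions match the co-contraction physics", {
  refs <- list(none = fixture_ref_cc("none"), high = fixture_ref_cc("high"))
  grid <- experiment_grid(marker_levels = "none", emg_levels = "none",
                          cocontraction_levels = c("none", "high"), reps = 1,
                          variants = c("track_emg_high_marker",
                                       "min_excitation"),
                          seed_base = 5000L)
  scores <- memo("cc_scores", function()
    run_grid(grid, fixture_model(), refs, window = 7, subsample = 2))
  wide <- tidyr::pivot_wider(
    scores[, c("cocontraction", "variant", "rmse_force_n")],
    names_from = "variant", values_from = "rmse_force_n")
  contrast <- function(v) v[wide$cocontraction == "high"] -
    v[wide$cocontraction == "none"]
  c_min <- contrast(wide$min_excitation)
  c_trk <- contrast(wide$track_emg_high_marker)
  # minimizing excitations misses co-contraction; tracking EMG does not
  expect_gt(c_min, 0)
  expect_gt(c_min, 2 * abs(c_trk))
})

test_that("two-way ANOVA machinery detects injected effects and nulls", {
  set.seed(41)
  base <- tidyr::expand_grid(emg_noise = factor(c("none", "low", "mid", "high")),
                             cocontraction = factor(c("none", "low", "mid", "high")),
                             rep = 1:6)
  # null response: nothing significant at the reporting threshold
  base$rmse_force_n <- rnorm(nrow(base), 10, 1)
  base$kept <- TRUE
  null_fit <- anova_two_way(base)
  expect_true(all(null_fit$effects$p.value[1:3] > 0.001, na.rm = TRUE))
  # a 5-sigma additive factor effect is detected
  eff <- base
  eff$rmse_force_n <- eff$rmse_force_n + 5 * (as.integer(eff$emg_noise) - 1)
  eff_fit <- anova_two_way(eff)
  p_emg <- eff_fit$effects$p.value[eff_fit$effects$term == "emg_noise"]
  expect_lt(p_emg, 0.001)
  # Bonferroni arithmetic: m pairwise tests scale the raw p-value by m
  ph <- eff_fit$posthoc[eff_fit$posthoc$factor == "emg_noise", ]
  expect_equal(nrow(ph), choose(4, 2))
  raw <- pairwise.t.test(eff$rmse_force_n, eff$emg_noise,
                         p.adjust.method = "none")$p.value
  adj <- pairwise.t.test(eff$rmse_force_n, eff$emg_noise,
                         p.adjust.method = "bonferroni")$p.value
  expect_equal(adj[1, 1], min(1, raw[1, 1] * choose(4, 2)))
})

test_that("three-way ANOVA handles all interactions and the exclusion rule", {
  set.seed(42)
  base <- tidyr::expand_grid(marker_noise = factor(c("none", "mid")),
                             emg_noise = factor(c("none", "mid")),
                             variant = factor(c("high", "low")),
                             rep = 1:8)
  base$rmse_q_deg <- rnorm(nrow(base), 1, 0.1) +
    3 * (base$marker_noise == "mid")
  base$kept <- rep(c(TRUE, TRUE, TRUE, FALSE), length.out = nrow(base))
  fit <- anova_three_way(base)
  expect_equal(fit$n, sum(base$kept))
  expect_equal(nrow(fit$effects), 8)     # 3 mains + 3 two-way + 1 three-way + resid
  p_mk <- fit$effects$p.value[fit$effects$term == "marker_noise"]
  expect_lt(p_mk, 0.001)
  base$kept <- FALSE
  base$kept[base$marker_noise == "none"] <- TRUE
  expect_error(anova_three_way(base), ">= 2 levels")
})

test_that("tidiers and plots produce well-formed objects", {
  ref <- fixture_ref()
  fit <- memo("fit_noiseless", function() {
    run_mhe(as_measurement_stream(ref), mhe_problem(fixture_model(), 7))
  })
  td <- tidy(fit)
  expect_true(all(c("time", "kind", "channel", "value") %in% names(td)))
  expect_setequal(unique(td$kind), c("angle", "velocity", "control", "force"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  tdr <- tidy(ref)
  expect_true("excitation" %in% tdr$kind)
  p1 <- ggplot2::autoplot(fit, ref = ref)
  expect_s3_class(p1, "ggplot")
  p2 <- plot_forces(fit, ref, muscles = c("ELFLX", "ELEXT"))
  expect_s3_class(p2, "ggplot")
  sw <- memo("sweep", function() {
    window_sweep(fixture_model(), fixture_ref(), sizes = c(3, 5, 7, 11, 15))
  })
  expect_s3_class(ggplot2::autoplot(sw), "ggplot")
})
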