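#' Two-way ANOVA with Bonferroni post hocs on a score table
#'
#' Fixed-effects two-way analysis of variance (main effects + interaction)
#' of an RMSE response against two design factors, on kept trials only,
#' followed by pairwise post-hoc t-tests with Bonferroni correction. The
#' study's reporting threshold is p < 0.001.
#'
#' @param scores a `score_table` from [run_grid()].
#' @param response response column (default `"rmse_force_n"`).
#' @param factors character vector of two factor columns (default EMG noise
#'   and co-contraction).
#' @param log_transform analyse `log(response)` instead of the raw RMSE.
#' @param alpha reporting threshold.
#' @return An `mhe_anova`: `$effects` (term, df, sumsq, statistic, p.value),
#'   `$posthoc` (per factor: pair, p.value adjusted), `$alpha`.
#' @export
anova_two_way <- function(scores, response = "rmse_force_n",
                          factors = c("emg_noise", "cocontraction"),
                          log_transform = FALSE, alpha = 0.001) {
  anova_nway(scores, response, factors, log_transform, alpha)
}

#' Three-way ANOVA with Bonferroni post hocs on a score table
#'
#' As [anova_two_way()] with three factors and all interactions; the study
#' uses it for joint-angle RMSE against marker noise, EMG noise and the
#' marker-tracking-weight variant.
#'
#' @inheritParams anova_two_way
#' @export
anova_three_way <- function(scores, response = "rmse_q_deg",
                            factors = c("marker_noise", "emg_noise",
                                        "variant"),
                            log_transform = FALSE, alpha = 0.001) {
  anova_nway(scores, response, factors, log_transform, alpha)
}

anova_nway <- function(scores, response, factors, log_transform, alpha) {
  if ("kept" %in% names(scores)) scores <- scores[scores$kept %in% TRUE, ]
  for (f in factors) {
    scores[[f]] <- droplevels(factor(scores[[f]]))
    if (nlevels(scores[[f]]) < 2)
      abort(paste0("factor '", f, "' needs >= 2 levels in the kept trials"))
  }
  y <- scores[[response]]
  if (log_transform) y <- log(y)
  dat <- scores[, factors, drop = FALSE]
  dat$.y <- y
  form <- stats::as.formula(paste(".y ~", paste(factors, collapse = " * ")))
  fit <- aov(form, data = dat)
  sm <- summary(fit)[[1]]
  effects <- tibble::tibble(
    term = trimws(rownames(sm)),
    df = sm[["Df"]], sumsq = sm[["Sum Sq"]],
    statistic = sm[["F value"]], p.value = sm[["Pr(>F)"]])
  posthoc <- purrr::map_dfr(factors, function(f) {
    pt <- pairwise.t.test(dat$.y, dat[[f]], p.adjust.method = "bonferroni")
    pm <- pt$p.value
    idx <- which(!is.na(pm), arr.ind = TRUE)
    tibble::tibble(
      factor = f,
      level_1 = rownames(pm)[idx[, 1]], level_2 = colnames(pm)[idx[, 2]],
      p.value = pm[idx])
  })
  posthoc$significant <- posthoc$p.value < alpha
  structure(list(effects = effects, posthoc = posthoc, alpha = alpha,
                 response = response, factors = factors,
                 n = nrow(dat)),
            class = "mhe_anova")
}

#' @export
print.mhe_anova <- function(x, ...) {
  cat("<mhe_anova> ", x$response, " ~ ", paste(x$factors, collapse = " * "),
      "  (n = ", x$n, ", alpha = ", x$alpha, ")\n", sep = "")
  print(x$effects)
  invisible(x)
}
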