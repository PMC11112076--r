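# Cleaning-performance evaluation: relative error, Monte-Carlo condition
# grid, and two-way ANOVA with eta-squared effect sizes.

#' Trial-averaged relative error between cleaned data and ground truth
#'
#' Per trial i the relative error is the energy ratio
#' `sum_c sum_t (y~ - y)^2 / sum_c sum_t y^2` over the window; the reported
#' RE is the arithmetic mean over trials, as a fraction (multiply by 100
#' for percent).  `root = TRUE` gives the square-root (amplitude-ratio)
#' alternative reading.
#'
#' @param cleaned,truth matching `epoched_data`.
#' @param window time window in ms (default 0 to 50).
#' @param root take the square root of each per-trial energy ratio.
#' @return list of class `re_result`: `per_trial_re`, `mean_re`,
#'   `window_ms`.
#' @export
relative_error <- function(cleaned, truth, window = c(0, 50), root = FALSE) {
  stopifnot(identical(dim(cleaned$data), dim(truth$data)))
  idx <- time_window_idx(truth, window)
  ntr <- n_trials(truth)
  per <- numeric(ntr)
  for (i in seq_len(ntr)) {
    num <- sum((cleaned$data[, idx, i] - truth$data[, idx, i])^2)
    den <- sum(truth$data[, idx, i]^2)
    if (den == 0)
      stop("ground truth has zero energy in the window for trial ", i)
    per[i] <- num / den
  }
  if (root) per <- sqrt(per)
  out <- list(per_trial_re = per, mean_re = mean(per), window_ms = window,
              root = root)
  class(out) <- "re_result"
  out
}

#' Log-transform relative errors
#'
#' `log10` of the RE expressed in units of 100%: values of 1, 0 and -1
#' correspond to relative errors of 1,000%, 100% and 10%.
#'
#' @param re relative error(s) as fractions (1.0 = 100%).
#' @param eps floor applied to zero values (with a warning).
#' @return log10-transformed values.
#' @export
log10_re <- function(re, eps = 1e-12) {
  if (any(re < 0)) stop("relative errors must be non-negative")
  if (any(re == 0)) {
    warning("zero relative error floored at eps = ", eps)
    re <- pmax(re, eps)
  }
  log10(re)
}

#' Run the Monte-Carlo condition grid
#'
#' For every (alpha, contrast, repetition) cell: draw one of the nine
#' artifact sources, simulate a realization, superpose it on the ground
#' truth, clean with each method and compute the relative error over the
#' early (0-50 ms) and late (50-100 ms) windows.  Every random draw is
#' derived deterministically from the master seed and the cell index, so
#' any cell can be re-run in isolation; failed cells are recorded with an
#' error message rather than dropped.
#'
#' @param ground_truth the clean `epoched_data` (its geometry defines the
#'   artifact grid geometry).
#' @param alphas,contrasts condition grids (11 x 11 by default).
#' @param amplitude_uv artifact maximum peak-to-peak amplitude.
#' @param n_reps repetitions per condition (100 in the full study).
#' @param methods subset of `c("ssp_sir", "ica")`.
#' @param seed master seed.
#' @param leadfield SIR lead field (default [sir_source_space()] through the
#'   reference model).
#' @param ica_opts list of FastICA options (`n_components`, `tol`,
#'   `max_iter`) for desk-scale runs.
#' @param early_window,late_window RE windows in ms.
#' @param progress print one line per condition.
#' @return a long-format data.frame of class `grid_results`: columns
#'   `alpha`, `contrast`, `angle_summary_deg`, `amplitude_uv`, `rep`,
#'   `method`, `seed`, `source_index`, `re_0_50`, `re_50_100`, `log10_re`,
#'   `selected_cos`, `status`.
#' @export
run_grid <- function(ground_truth, alphas = seq(0, 1, by = 0.1),
                     contrasts = default_contrasts(), amplitude_uv = 250,
                     n_reps = 100, methods = c("ssp_sir", "ica"),
                     seed = 1L, leadfield = NULL, ica_opts = list(),
                     early_window = c(0, 50), late_window = c(50, 100),
                     progress = FALSE) {
  stopifnot(length(alphas) >= 1, length(contrasts) >= 1, n_reps >= 1)
  methods <- match.arg(methods, c("ssp_sir", "ica"), several.ok = TRUE)
  leadfield <- leadfield %||% default_sir_leadfield()
  ica_n <- ica_opts$n_components %||% 60
  ica_tol <- ica_opts$tol %||% 1e-6
  ica_iter <- ica_opts$max_iter %||% 1000
  ntr <- n_trials(ground_truth)
  fs <- ground_truth$fs
  t0 <- ground_truth$times[1]
  t1 <- t0 + n_samples(ground_truth) * 1000 / fs
  angle_by_contrast <- vapply(contrasts, angle_summary_for_contrast,
                              numeric(1), data = ground_truth)
  rows <- list()
  cell <- 0L
  for (ai in seq_along(alphas)) {
    for (ci in seq_along(contrasts)) {
      if (progress)
        cat(sprintf("grid cell alpha=%.2f contrast=%.4g\n",
                    alphas[ai], contrasts[ci]))
      for (rep_i in seq_len(n_reps)) {
        cell <- cell + 1L
        cell_seed <- derive_seed(seed, cell)
        src <- with_seed(cell_seed, sample.int(9, 1))
        art <- simulate_artifact(alphas[ai], contrasts[ci], amplitude_uv,
                                 source_index = src, n_trials = ntr,
                                 fs = fs, t_start_ms = t0, t_end_ms = t1,
                                 seed = derive_seed(cell_seed, 1L))
        corrupted <- superpose(ground_truth, art)
        for (m in methods) {
          res <- tryCatch({
            cl <- if (m == "ssp_sir")
              clean_dataset_ssp_sir(corrupted, leadfield,
                                    known_topography = art$topography)
            else
              clean_dataset_ica(corrupted, art$topography,
                                n_components = ica_n,
                                seed = derive_seed(cell_seed, 2L),
                                tol = ica_tol, max_iter = ica_iter)
            re_e <- relative_error(cl$data, ground_truth, early_window)
            re_l <- relative_error(cl$data, ground_truth, late_window)
            list(re_e = re_e$mean_re, re_l = re_l$mean_re,
                 cos = cl$selected_cos %||% NA_real_, status = "ok")
          }, error = function(e) list(re_e = NA_real_, re_l = NA_real_,
                                      cos = NA_real_,
                                      status = conditionMessage(e)))
          rows[[length(rows) + 1L]] <- data.frame(
            alpha = alphas[ai], contrast = contrasts[ci],
            angle_summary_deg = angle_by_contrast[ci],
            amplitude_uv = amplitude_uv, rep = rep_i, method = m,
            seed = cell_seed, source_index = src,
            re_0_50 = res$re_e, re_50_100 = res$re_l,
            log10_re = if (is.na(res$re_e)) NA_real_ else
              log10_re(max(res$re_e, 1e-12)),
            selected_cos = res$cos, status = res$status,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("grid_results", "data.frame")
  attr(out, "master_seed") <- seed
  out
}

#' Two-way fixed-effects ANOVA with eta-squared effect sizes
#'
#' Balanced two-way ANOVA of the log-transformed relative error with
#' inter-trial variability (`alpha`) and topographical similarity
#' (conductivity contrast) as categorical factors, including the
#' interaction.  Eta squared is `SS_effect / SS_total`; p-values are
#' Bonferroni-multiplied by `bonferroni_factor` (3 tested artifact
#' amplitudes) and capped at 1.
#'
#' @param grid a `grid_results` data.frame (one method; filter first or
#'   pass `method`).
#' @param response response column (default `"log10_re"`).
#' @param method optionally select one method from a mixed table.
#' @param bonferroni_factor multiplicity correction factor (default 3).
#' @return data.frame of class `anova_table`: one row per term
#'   (variability, similarity, interaction, residual) with `sum_sq`, `df`,
#'   `F`, `p`, `p_bonferroni`, `eta_squared`.
#' @export
two_way_anova <- function(grid, response = "log10_re", method = NULL,
                          bonferroni_factor = 3) {
  d <- as.data.frame(grid)
  if (!is.null(method)) d <- d[d$method == method, ]
  if (length(unique(d$method)) > 1)
    stop("grid contains several methods; pass `method`")
  if (!response %in% names(d)) stop("no column `", response, "`")
  if (any(is.na(d[[response]]))) stop("missing cells in the grid")
  d$A <- factor(d$alpha)
  d$B <- factor(d$contrast)
  counts <- table(d$A, d$B)
  if (length(unique(as.vector(counts))) != 1 || any(counts == 0))
    stop("unbalanced grid: each (alpha, contrast) cell needs the same",
         " number of repetitions")
  y <- d[[response]]
  fit <- stats::aov(y ~ A * B, data = d)
  sm <- summary(fit)[[1]]
  ss <- sm[["Sum Sq"]]
  df <- sm[["Df"]]
  Fv <- sm[["F value"]]
  pv <- sm[["Pr(>F)"]]
  total <- sum(ss)
  # a numerically constant response has no explainable variance
  degenerate <- total <= 1e-20 * length(y) * (mean(y)^2 + 1)
  out <- data.frame(
    term = c("variability", "similarity", "interaction", "residual"),
    sum_sq = ss, df = df, F = Fv, p = pv,
    p_bonferroni = pmin(1, pv * bonferroni_factor),
    eta_squared = if (degenerate) rep(0, 4) else ss / total,
    stringsAsFactors = FALSE)
  attr(out, "bonferroni_factor") <- bonferroni_factor
  class(out) <- c("anova_table", "data.frame")
  out
}
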