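# End-to-end reproduction of the simulation study, plus a small CLI.

#' Reproduce the simulation study end to end
#'
#' Ground-truth generation, the (alpha x contrast) Monte-Carlo grid with
#' both cleaning methods, the per-method two-way ANOVA with eta-squared
#' effect sizes, and a compact report of the headline comparisons.  The
#' default configuration is a desk-scale run (reduced sampling rate, trial
#' count and repetitions); pass a full-scale [ground_truth_config()] and
#' `n_reps = 100` for the paper-scale study.
#'
#' @param gt_config [ground_truth_config()] for the ground truth.
#' @param alphas,contrasts condition grids.
#' @param amplitude_uv artifact amplitude (uV).
#' @param n_reps repetitions per condition.
#' @param seed master seed.
#' @param ica_opts FastICA options for the grid (see [run_grid()]).
#' @param out_dir if non-NULL, writes `grid.csv`, `anova_<method>.csv`,
#'   `report.md` and `manifest.json` there.
#' @param progress print per-condition progress lines.
#' @return list of class `study_result`: `grid` (a `grid_results`),
#'   `anova` (named list of `anova_table`), `summary` (headline numbers),
#'   `manifest`.
#' @export
reproduce_study <- function(gt_config = ground_truth_config(n_trials = 40,
                                                            fs = 1000),
                            alphas = seq(0, 1, by = 0.1),
                            contrasts = default_contrasts(),
                            amplitude_uv = 250, n_reps = 10, seed = 1L,
                            ica_opts = list(n_components = 20, tol = 1e-3,
                                            max_iter = 75),
                            out_dir = NULL, progress = FALSE) {
  gt <- generate_ground_truth(gt_config)
  grid <- run_grid(gt, alphas = alphas, contrasts = contrasts,
                   amplitude_uv = amplitude_uv, n_reps = n_reps,
                   seed = seed, ica_opts = ica_opts, progress = progress)
  methods <- unique(grid$method)
  anovas <- lapply(stats::setNames(methods, methods), function(m)
    two_way_anova(grid, method = m))
  mean_re <- vapply(methods, function(m)
    mean(grid$re_0_50[grid$method == m]), numeric(1))
  eta <- function(m, term)
    anovas[[m]]$eta_squared[anovas[[m]]$term == term]
  summary <- list(
    mean_re = as.list(mean_re),
    eta_squared = lapply(stats::setNames(methods, methods), function(m)
      list(variability = eta(m, "variability"),
           similarity = eta(m, "similarity"),
           interaction = eta(m, "interaction"))),
    orderings = list(
      ica_variability_gt_similarity =
        if ("ica" %in% methods)
          eta("ica", "variability") > eta("ica", "similarity") else NA,
      ssp_sir_similarity_gt_variability =
        if ("ssp_sir" %in% methods)
          eta("ssp_sir", "similarity") > eta("ssp_sir", "variability")
        else NA,
      mean_re_ssp_sir_lt_ica =
        if (all(c("ssp_sir", "ica") %in% methods))
          mean_re[["ssp_sir"]] < mean_re[["ica"]] else NA))
  manifest <- list(master_seed = seed,
                   gt_config = unclass(gt_config),
                   gt_fingerprint = config_fingerprint(gt_config),
                   amplitude_uv = amplitude_uv, n_reps = n_reps,
                   alphas = alphas, contrasts = contrasts,
                   ica_opts = ica_opts,
                   package_version =
                     as.character(utils::packageVersion("tmseegsim")))
  out <- list(grid = grid, anova = anovas, summary = summary,
              manifest = manifest)
  class(out) <- "study_result"
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(as.data.frame(grid),
                     file.path(out_dir, "grid.csv"), row.names = FALSE)
    for (m in methods)
      utils::write.csv(as.data.frame(anovas[[m]]),
                       file.path(out_dir, paste0("anova_", m, ".csv")),
                       row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(render_study_report(out), file.path(out_dir, "report.md"))
  }
  out
}

render_study_report <- function(study) {
  g <- study$grid
  s <- study$summary
  lines <- c("# Simulation-study report", "",
             sprintf("Master seed: %d; amplitude: %g uV; %d conditions x %d reps.",
                     study$manifest$master_seed, study$manifest$amplitude_uv,
                     length(unique(paste(g$alpha, g$contrast))),
                     study$manifest$n_reps), "",
             "## Grand-mean relative error (0-50 ms, fraction)", "")
  for (m in names(s$mean_re))
    lines <- c(lines, sprintf("- %s: %.4g", m, s$mean_re[[m]]))
  lines <- c(lines, "", "## Eta-squared effect sizes (log10 RE)", "")
  for (m in names(s$eta_squared)) {
    e <- s$eta_squared[[m]]
    lines <- c(lines, sprintf(
      "- %s: variability %.4f, similarity %.4f, interaction %.4f",
      m, e$variability, e$similarity, e$interaction))
  }
  lines <- c(lines, "", "## Headline orderings", "")
  for (n in names(s$orderings))
    lines <- c(lines, sprintf("- %s: %s", n, s$orderings[[n]]))
  lines <- c(lines, "", "## Median log10 RE by condition (per method)", "")
  for (m in unique(g$method)) {
    lines <- c(lines, sprintf("### %s", m), "")
    sub <- g[g$method == m, ]
    tab <- tapply(sub$log10_re, list(sub$alpha, sub$contrast), stats::median)
    hdr <- paste(c("alpha\\contrast", signif(as.numeric(colnames(tab)), 3)),
                 collapse = " | ")
    lines <- c(lines, hdr,
               paste(rep("---", length(strsplit(hdr, " \\| ")[[1]])),
                     collapse = " | "))
    for (r in seq_len(nrow(tab)))
      lines <- c(lines, paste(c(rownames(tab)[r], sprintf("%.2f", tab[r, ])),
                              collapse = " | "))
    lines <- c(lines, "")
  }
  lines
}

#' @export
print.study_result <- function(x, ...) {
  cat(render_study_report(x), sep = "\n")
  invisible(x)
}

#' Command-line interface
#'
#' A small argv-driven front end:
#' `simulate-ground-truth --seed N --out gt.bin [--trials T --fs F]`,
#' `simulate-artifact --alpha A --contrast C --amplitude-uv P --seed N
#'  --ground-truth gt.bin --out corrupted.bin`,
#' `clean --method ssp-sir|ica --in corrupted.bin --out cleaned.bin
#'  [--topography topo.csv]`, and
#' `reproduce --seed N --out-dir DIR [--reps R]`.
#'
#' @param args character vector (default: `commandArgs(trailingOnly=TRUE)`).
#' @return exit status (0 on success), invisibly.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    cat("usage: tmseegsim <simulate-ground-truth|simulate-artifact|clean|",
        "reproduce> [options]\n", sep = "")
    return(invisible(1L))
  }
  cmd <- args[1]
  opts <- parse_cli_opts(args[-1])
  getopt <- function(name, default = NULL, numeric = FALSE) {
    v <- opts[[name]] %||% default
    if (is.null(v)) stop("missing required option --", name)
    if (numeric) as.numeric(v) else v
  }
  switch(cmd,
    "simulate-ground-truth" = {
      cfg <- ground_truth_config(
        n_trials = getopt("trials", 173, TRUE),
        fs = getopt("fs", 5000, TRUE),
        seed = getopt("seed", 1, TRUE))
      write_epochs(generate_ground_truth(cfg), getopt("out"))
      cat("wrote", getopt("out"), "\n")
    },
    "simulate-artifact" = {
      gt <- read_epochs(getopt("ground-truth"))
      art <- simulate_artifact(
        alpha = getopt("alpha", numeric = TRUE),
        contrast = getopt("contrast", numeric = TRUE),
        amplitude_uv = getopt("amplitude-uv", 250, TRUE),
        source_index = getopt("source", 1, TRUE),
        n_trials = n_trials(gt), fs = gt$fs, t_start_ms = gt$times[1],
        t_end_ms = gt$times[1] + n_samples(gt) * 1000 / gt$fs,
        seed = getopt("seed", 1, TRUE))
      out <- superpose(gt, art)
      write_epochs(out, getopt("out"))
      utils::write.csv(data.frame(topography = art$topography),
                       paste0(getopt("out"), ".topography.csv"),
                       row.names = FALSE)
      cat("wrote", getopt("out"), "\n")
    },
    "clean" = {
      x <- read_epochs(getopt("in"))
      topo <- if (!is.null(opts$topography))
        utils::read.csv(opts$topography)$topography else NULL
      res <- if (getopt("method") == "ssp-sir")
        clean_dataset_ssp_sir(x, known_topography = topo)
      else clean_dataset_ica(x, topo, seed = getopt("seed", 1, TRUE))
      write_epochs(res$data, getopt("out"))
      cat("wrote", getopt("out"), "\n")
    },
    "reproduce" = {
      reproduce_study(n_reps = getopt("reps", 10, TRUE),
                      seed = getopt("seed", 1, TRUE),
                      out_dir = getopt("out-dir"))
      cat("wrote report to", getopt("out-dir"), "\n")
    },
    stop("unknown command: ", cmd))
  invisible(0L)
}

parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- substring(a, 3)
    if (i == length(args) || startsWith(args[i + 1], "--")) {
      opts[[key]] <- TRUE
      i <- i + 1L
    } else {
      opts[[key]] <- args[i + 1]
      i <- i + 2L
    }
  }
  opts
}
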