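# Study orchestration: model-prediction sweeps with per-task summary
# regressions, and cohort-level experiments (difference model, quartile
# stratification, robust regression) with JSON reports.

#' Per-task OLS regressions of task SSR on baseline SSR
#'
#' For each non-baseline task environment, regresses systems' steady-state
#' rates in that task on their rates in the baseline task (1.0, 1.0). These
#' summary regressions characterize each workload model's signature (slope
#' near/below 1, intercept sign); ordinary least squares is used here
#' because the per-task fits are descriptive summaries over hundreds of
#' simulated systems, not inferential estimates.
#'
#' @param ssr_table Output of [run_experiment()].
#' @param exclude_floor Drop systems whose SSR is 0 in either task before
#'   fitting (the models' predictions are only meaningful for systems that
#'   produce output in both tasks).
#' @return A data.frame with one row per non-baseline task: `d_a`, `d_b`,
#'   `slope`, `intercept`, `n_systems`.
#' @export
fit_task_regressions <- function(ssr_table, exclude_floor = TRUE) {
  base <- ssr_table[ssr_table$d_a == 1 & ssr_table$d_b == 1,
                    c("system_id", "ssr_hz")]
  names(base)[2] <- "ssr_base"
  tasks <- unique(ssr_table[, c("d_a", "d_b")])
  tasks <- tasks[!(tasks$d_a == 1 & tasks$d_b == 1), ]
  out <- vector("list", nrow(tasks))
  for (i in seq_len(nrow(tasks))) {
    sub <- ssr_table[ssr_table$d_a == tasks$d_a[i] &
                       ssr_table$d_b == tasks$d_b[i], ]
    m <- merge(sub, base, by = "system_id")
    if (exclude_floor) m <- m[m$ssr_hz > 0 & m$ssr_base > 0, ]
    if (nrow(m) < 3 || sd(m$ssr_base) == 0) {
      out[[i]] <- data.frame(d_a = tasks$d_a[i], d_b = tasks$d_b[i],
                             slope = NA_real_, intercept = NA_real_,
                             n_systems = nrow(m))
      next
    }
    cf <- coef(lm(ssr_hz ~ ssr_base, data = m))
    out[[i]] <- data.frame(d_a = tasks$d_a[i], d_b = tasks$d_b[i],
                           slope = unname(cf[2]), intercept = unname(cf[1]),
                           n_systems = nrow(m))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate the model-prediction sweeps and summarize their signatures
#'
#' For each requested workload model, simulates all systems in all task
#' environments, extracts steady-state rates, fits the per-task OLS
#' regressions against the baseline task, and reports slope/intercept
#' ranges together with the three diagnostic signatures: additive systems
#' give slopes near 1; multiplicative systems give slopes below 1 with
#' intercepts near 0; flexible systems give slopes below 1 with positive
#' intercepts, so the regression crosses the unity line at a positive rate
#' (Quadrant I).
#'
#' @param models Character vector of model kinds to sweep.
#' @param seed Root seed (each model's sweep derives its own substreams).
#' @param n_updates Update points per trial.
#' @param exclude_floor See [fit_task_regressions()].
#' @param detect_stride,detect_downsample See [run_experiment()].
#' @param progress Print sweep progress.
#' @return An object of class `prediction_report`: per-model regression
#'   tables, summary ranges and signature flags.
#' @export
run_model_predictions <- function(models = c("additive", "multiplicative", "flexible"),
                                  seed = 1L, n_updates = 281L,
                                  exclude_floor = TRUE, detect_stride = 50L,
                                  detect_downsample = 10L, progress = FALSE) {
  models <- match.arg(models, several.ok = TRUE)
  per_model <- list()
  for (m in models) {
    ssr <- run_experiment(m, n_updates = n_updates, seed = seed,
                          detect_stride = detect_stride,
                          detect_downsample = detect_downsample,
                          progress = progress)
    fits <- fit_task_regressions(ssr, exclude_floor = exclude_floor)
    ok <- is.finite(fits$slope)
    slopes <- fits$slope[ok]; intercepts <- fits$intercept[ok]
    crossing <- intercepts / (1 - slopes)  # x where regression meets unity line
    summary <- list(
      n_tasks = sum(ok),
      slope_min = min(slopes), slope_max = max(slopes),
      intercept_min = min(intercepts), intercept_max = max(intercepts),
      max_abs_intercept = max(abs(intercepts)),
      signature = switch(m,
        additive = all(slopes > 0.95 & slopes < 1.05),
        multiplicative = all(slopes < 1) && all(abs(intercepts) <= 0.12),
        flexible = all(slopes < 1) && all(intercepts > 0) &&
          all(crossing > 0)
      )
    )
    per_model[[m]] <- list(ssr = ssr, fits = fits, summary = summary)
  }
  structure(list(models = per_model, seed = seed, n_updates = n_updates,
                 exclude_floor = exclude_floor),
            class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat("<prediction_report>\n")
  for (m in names(x$models)) {
    s <- x$models[[m]]$summary
    cat(sprintf("  %-14s slopes [%.3f, %.3f], intercepts [%.3f, %.3f], signature %s\n",
                m, s$slope_min, s$slope_max, s$intercept_min, s$intercept_max,
                if (isTRUE(s$signature)) "OK" else "NOT MET"))
  }
  invisible(x)
}

# Quartiles of x in rank order, ties broken by original position.
quartile_of <- function(x) {
  r <- rank(x, ties.method = "first")
  as.integer(ceiling(4 * r / length(x)))
}

#' Run the full cohort-level experiment
#'
#' Given a paired-task cohort, estimates the posterior for the mean SSR
#' difference (task 2 minus task 1) with its ROPE decision, re-runs the
#' difference model within each quartile of task-1 performance, and fits
#' the robust t regression of task-2 on task-1 rates with ROPE decisions
#' for the slope and intercept. Optionally writes a JSON report and summary
#' figures.
#'
#' @param cohort A data.frame with `ssr_task1` and `ssr_task2` (see
#'   [read_cohort_csv()], [generate_cohort()]).
#' @param rope_diff ROPE for the mean difference (Hz).
#' @param rope_slope,rope_intercept ROPEs for the regression parameters.
#' @param config An [mcmc_config()]; its seed governs all samplers.
#' @param out_dir Optional directory for `report.json` and figures.
#' @return An object of class `cohort_report` with elements `difference`,
#'   `quartiles` (list of four `difference_posterior`s), `regression`.
#' @export
run_cohort_experiment <- function(cohort,
                                  rope_diff = rope_interval(-0.30, 0.30),
                                  rope_slope = rope_interval(0.95, 1.05),
                                  rope_intercept = rope_interval(-0.12, 0.12),
                                  config = mcmc_config(seed = 1L),
                                  out_dir = NULL) {
  need <- c("ssr_task1", "ssr_task2")
  if (!all(need %in% names(cohort))) stop("cohort needs ssr_task1/ssr_task2")
  if (anyNA(cohort[, need])) stop("cohort contains unpaired rows")
  diffs <- cohort$ssr_task2 - cohort$ssr_task1
  base_seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  cfg_k <- function(k) mcmc_config(config$chains, config$warmup, config$draws,
                                   seed = (base_seed + k) %% 2147483629)
  difference <- estimate_mean_difference(
    diffs, baseline_mean_1 = mean(cohort$ssr_task1),
    baseline_mean_2 = mean(cohort$ssr_task2),
    baseline_sd = sd(cohort$ssr_task1), rope = rope_diff, config = cfg_k(0))
  q <- quartile_of(cohort$ssr_task1)
  quartiles <- lapply(1:4, function(k) {
    idx <- q == k
    estimate_mean_difference(
      diffs[idx], baseline_mean_1 = mean(cohort$ssr_task1[idx]),
      baseline_mean_2 = mean(cohort$ssr_task2[idx]),
      baseline_sd = sd(cohort$ssr_task1[idx]), rope = rope_diff,
      config = cfg_k(k))
  })
  regression <- robust_linear_regression(
    cohort$ssr_task1, cohort$ssr_task2, rope_slope = rope_slope,
    rope_intercept = rope_intercept, config = cfg_k(5))
  report <- structure(list(difference = difference, quartiles = quartiles,
                           regression = regression, n = nrow(cohort)),
                      class = "cohort_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(cohort_report_to_list(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    grDevices::png(file.path(out_dir, "scatter.png"), width = 700, height = 700)
    plot(cohort$ssr_task1, cohort$ssr_task2,
         xlab = "SSR task 1 (Hz)", ylab = "SSR task 2 (Hz)",
         pch = 16, col = grDevices::adjustcolor("steelblue", 0.5))
    graphics::abline(0, 1)
    graphics::abline(regression$beta0$mode, regression$beta1$mode, col = "red")
    grDevices::dev.off()
  }
  report
}

cohort_report_to_list <- function(report) {
  # drop samplers' heavy fields and rope_interval objects (each parameter
  # summary already carries its ROPE bounds as a plain vector)
  strip <- function(p) p[setdiff(names(p), c("samples", "diagnostics", "config",
                                             "rope", "rope_slope",
                                             "rope_intercept"))]
  diag_list <- function(d) list(shrink = as.list(d$shrink),
                                ess = as.list(d$ess), pass = d$pass)
  list(
    n = report$n,
    difference = c(strip(unclass(report$difference)),
                   list(diagnostics = diag_list(report$difference$diagnostics))),
    quartiles = lapply(report$quartiles, function(qd) {
      c(strip(unclass(qd)), list(diagnostics = diag_list(qd$diagnostics)))
    }),
    regression = c(strip(unclass(report$regression)),
                   list(diagnostics = diag_list(report$regression$diagnostics)))
  )
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> n = %d\n", x$n))
  cat(sprintf("  mean difference: mode %.3f Hz -> %s\n",
              x$difference$mu$mode, x$difference$mu$decision))
  for (k in 1:4) {
    cat(sprintf("  quartile %d: mode %.3f Hz -> %s\n", k,
                x$quartiles[[k]]$mu$mode, x$quartiles[[k]]$mu$decision))
  }
  cat(sprintf("  regression: beta1 %.3f -> %s; beta0 %.3f Hz -> %s\n",
              x$regression$beta1$mode, x$regression$beta1$decision,
              x$regression$beta0$mode, x$regression$beta0$decision))
  invisible(x)
}

#' Read a run configuration file
#'
#' JSON (always available) or YAML (when the yaml package is installed)
#' with any of the keys `model`, `n_updates`, `frame_rate`, `seed`,
#' `pool_per_module`; missing keys fall back to the defaults used
#' throughout the package.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A named list of configuration values.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("yaml package required for YAML configs; use JSON instead")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  defaults <- list(model = "additive", n_updates = 281L, frame_rate = 200,
                   seed = 1L, pool_per_module = NULL)
  utils::modifyList(defaults, cfg)
}
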