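# Limited-capacity, pipelined two-module systems: task and system grids,
# per-update capacity rules for the three workload models, and trial
# simulation with linear interpolation between update points.

#' Build the grid of task environments
#'
#' A task environment is a pair of difficulty factors `(d_a, d_b)`, one per
#' processing module, where 1 is the easiest setting and values toward 0
#' make the module's work more expensive. The grid spans
#' \{0.1, 0.2, ..., 1.0\} for each module, giving 100 environments; the pair
#' (1.0, 1.0) is the baseline task used for all comparisons.
#'
#' @return A data.frame with columns `task_id`, `d_a`, `d_b`, in row-major
#'   order (`d_a` outer, `d_b` inner).
#' @export
build_task_grid <- function() {
  levels <- (1:10) / 10
  grid <- expand.grid(d_b = levels, d_a = levels,
                      KEEP.OUT.ATTRS = FALSE)[, c("d_a", "d_b")]
  grid <- grid[order(grid$d_a, grid$d_b), ]
  rownames(grid) <- NULL
  data.frame(task_id = seq_len(nrow(grid)), grid)
}

#' Enumerate the admissible mean-capacity cells
#'
#' Mean module capacities range over \{1.0, 1.1, ..., 3.5\} Hz for each
#' module. A cell (a, b) is kept only when the absolute capacity difference
#' is strictly less than a third of the first entry, so that neither module
#' is completely dominated by the other's bottleneck. The comparison is done
#' in integer tenths of a Hz (3|A - B| < A with A = 10a), which excludes
#' exact-third ties such as (1.2, 1.6) unambiguously and yields 324 cells.
#'
#' @return A data.frame with columns `mean_cap_a`, `mean_cap_b` (Hz).
#' @export
capacity_grid_cells <- function() {
  deci <- 10:35
  cells <- expand.grid(B = deci, A = deci, KEEP.OUT.ATTRS = FALSE)
  keep <- 3L * abs(cells$A - cells$B) < cells$A
  cells <- cells[keep, ]
  cells <- cells[order(cells$A, cells$B), ]
  data.frame(mean_cap_a = cells$A / 10, mean_cap_b = cells$B / 10)
}

#' Generate the grid of simulated systems
#'
#' For every admissible mean-capacity cell (see [capacity_grid_cells()]),
#' draws the system's module capacities from Normal(mean, 0.05 Hz)
#' truncated to positive values. For the flexible-capacity model,
#' `pool_per_module` Hz is then removed from each module and placed into a
#' shared central pool of size `2 * pool_per_module`, conserving the
#' system's total capability. The draws themselves do not depend on the
#' model, so the same seed produces the same underlying capacities for all
#' three models.
#'
#' @param model One of `"additive"`, `"multiplicative"`, `"flexible"`.
#' @param pool_per_module Hz removed from each module to form the shared
#'   pool (flexible model only; default 0.5 Hz there, 0 otherwise).
#' @param seed Integer seed for the capacity draws.
#' @param capacity_sd SD of the capacity draws around the cell means (Hz).
#' @return A data.frame with one row per system: `system_id`, `mean_cap_a`,
#'   `mean_cap_b`, `cap_a`, `cap_b`, `model`, `pool`.
#' @export
build_system_grid <- function(model = c("additive", "multiplicative", "flexible"),
                              pool_per_module = NULL, seed = 1L,
                              capacity_sd = 0.05) {
  model <- match.arg(model)
  if (is.null(pool_per_module)) {
    pool_per_module <- if (model == "flexible") 0.5 else 0
  }
  if (model != "flexible" && pool_per_module != 0) {
    stop("pool_per_module is only meaningful for the flexible model")
  }
  cells <- capacity_grid_cells()
  n <- nrow(cells)
  set.seed(as.integer(seed))
  cap_a <- rnorm_truncated_positive(n, cells$mean_cap_a, capacity_sd)
  cap_b <- rnorm_truncated_positive(n, cells$mean_cap_b, capacity_sd)
  if (pool_per_module >= min(cap_a, cap_b)) {
    stop("pool_per_module would leave a module with nonpositive capacity")
  }
  pool <- 0
  if (model == "flexible") {
    cap_a <- cap_a - pool_per_module
    cap_b <- cap_b - pool_per_module
    pool <- 2 * pool_per_module
  }
  data.frame(system_id = seq_len(n), cells,
             cap_a = cap_a, cap_b = cap_b,
             model = model, pool = pool,
             stringsAsFactors = FALSE)
}

# Normal draws truncated to (0, Inf) by redrawing.
rnorm_truncated_positive <- function(n, mean, sd) {
  x <- rnorm(n, mean, sd)
  bad <- which(x <= 0)
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), mean[bad], sd)
    bad <- bad[x[bad] <= 0]
  }
  x
}

#' Final module capacity under an additive workload
#'
#' Harder tasks subtract a constant from the module's capacity:
#' `capacity - 1 + d`, clamped at zero so a module can be driven to a halt
#' but never to negative throughput.
#'
#' @param cap Initial module capacity (Hz).
#' @param d Difficulty factor in \[0, 1\] (1 = easiest).
#' @return Final capacity (Hz).
#' @export
final_capacity_additive <- function(cap, d) {
  pmax(0, cap - 1 + d)
}

#' Final module capacity under a multiplicative workload
#'
#' Harder tasks scale the module's capacity: `capacity * d`.
#'
#' @inheritParams final_capacity_additive
#' @return Final capacity (Hz).
#' @export
final_capacity_multiplicative <- function(cap, d) {
  cap * d
}

#' Allocate a shared capacity pool between two modules
#'
#' If the capacity gap exceeds the pool, the weaker module receives the
#' entire pool; otherwise the pool is split so both modules end up equal.
#' Total capacity is conserved: the outputs always sum to
#' `cap_a + cap_b + pool`.
#'
#' @param cap_a,cap_b Module capacities after task-difficulty effects (Hz).
#' @param pool Shared central capacity (Hz, >= 0).
#' @return A list with vectors `cap_a` and `cap_b` of allocated capacities.
#' @export
allocate_shared <- function(cap_a, cap_b, pool) {
  stopifnot(all(pool >= 0))
  n <- max(length(cap_a), length(cap_b), length(pool))
  cap_a <- rep_len(cap_a, n); cap_b <- rep_len(cap_b, n)
  pool <- rep_len(pool, n)
  gap <- abs(cap_a - cap_b)
  out_a <- cap_a; out_b <- cap_b
  whole <- gap > pool
  a_small <- whole & (cap_a < cap_b)
  b_small <- whole & !a_small
  out_a[a_small] <- cap_a[a_small] + pool[a_small]
  out_b[b_small] <- cap_b[b_small] + pool[b_small]
  eq <- !whole
  lvl <- (cap_a[eq] + cap_b[eq] + pool[eq]) / 2
  out_a[eq] <- lvl; out_b[eq] <- lvl
  list(cap_a = out_a, cap_b = out_b)
}

#' Environmental input rate at an update point
#'
#' The input ramp `0.5 + 0.025 * step + n / 10` Hz, clamped at zero, where
#' `step` indexes the 100-frame update points and `n` is a standard-normal
#' noise draw supplied by the caller (0 for the noise-free mode). With the
#' default 281 update points the ramp runs from 0.5 Hz to 7.5 Hz over about
#' 140 s, guaranteeing that every simulated trial ends overwhelmed since the
#' largest grid capacity is 3.5 Hz.
#'
#' @param step Update-point index (0-based), vectorized.
#' @param n Standard-normal noise draw(s); defaults to 0.
#' @return Input rate (Hz).
#' @export
input_rate <- function(step, n = 0) {
  pmax(0, 0.5 + 0.025 * step + n / 10)
}

#' System output at one update point
#'
#' Pipelined processing is memoryless: throughput is the minimum of the
#' environmental input rate and both final module capacities, floored at 0.
#'
#' @param input Input rate (Hz).
#' @param cap_a_final,cap_b_final Final module capacities (Hz).
#' @return Output rate (Hz).
#' @export
step_output <- function(input, cap_a_final, cap_b_final) {
  pmax(0, pmin(input, cap_a_final, cap_b_final))
}

#' Simulate one trial of a pipelined two-module system
#'
#' Input, per-module difficulty and per-module capacity are drawn at each
#' update point (every `frames_per_update` frames); final capacities follow
#' the system's workload model; for flexible-capacity systems the shared
#' pool is then allocated; output is the pipelined minimum. All recorded
#' series are linearly interpolated across the intermediate frames, so a
#' trial with `n_updates` update points yields
#' `(n_updates - 1) * frames_per_update + 1` frames. The memoryless output
#' rule holds exactly at update points; between them the recorded output is
#' the interpolation of the update-point outputs.
#'
#' @param system One row of [build_system_grid()] (data.frame or list with
#'   `cap_a`, `cap_b`, `model`, `pool`).
#' @param task One row of [build_task_grid()] (list with `d_a`, `d_b`).
#' @param n_updates Number of update points (>= 2); default 281 gives a
#'   ~140 s trial at 200 frames/s.
#' @param seed Optional integer seed applied before the trial's draws.
#' @param noise If `FALSE`, all difficulty/capacity/input noise is disabled
#'   (deterministic trace).
#' @param frame_rate Recording rate, samples/s.
#' @param frames_per_update Frames between consecutive update points.
#' @return An object of class `trial_trace`: list with `frame_rate` and
#'   per-frame vectors `input`, `cap_a`, `cap_b`, `output`, plus the
#'   update-point values in `updates`.
#' @export
simulate_trial <- function(system, task, n_updates = 281L, seed = NULL,
                           noise = TRUE, frame_rate = 200,
                           frames_per_update = 100L) {
  if (n_updates < 2) stop("n_updates must be >= 2")
  model <- as.character(system$model)
  if (!model %in% c("additive", "multiplicative", "flexible")) {
    stop("invalid model kind: ", model)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  step <- seq_len(n_updates) - 1L
  if (noise) {
    input <- input_rate(step, rnorm(n_updates))
    d_a <- rnorm(n_updates, task$d_a, 0.05)
    d_b <- rnorm(n_updates, task$d_b, 0.05)
    ca <- rnorm(n_updates, system$cap_a, 0.05)
    cb <- rnorm(n_updates, system$cap_b, 0.05)
  } else {
    input <- input_rate(step)
    d_a <- rep(task$d_a, n_updates); d_b <- rep(task$d_b, n_updates)
    ca <- rep(system$cap_a, n_updates); cb <- rep(system$cap_b, n_updates)
  }
  if (model == "additive") {
    fa <- final_capacity_additive(ca, d_a)
    fb <- final_capacity_additive(cb, d_b)
  } else {
    fa <- final_capacity_multiplicative(ca, d_a)
    fb <- final_capacity_multiplicative(cb, d_b)
    if (model == "flexible") {
      alloc <- allocate_shared(fa, fb, system$pool)
      fa <- alloc$cap_a; fb <- alloc$cap_b
    }
  }
  out <- step_output(input, fa, fb)

  n_frames <- (n_updates - 1L) * frames_per_update + 1L
  up_frames <- (step * frames_per_update) + 1L
  frames <- seq_len(n_frames)
  interp <- function(v) stats::approx(up_frames, v, xout = frames)$y
  structure(list(
    frame_rate = frame_rate,
    input = interp(input),
    cap_a = interp(fa),
    cap_b = interp(fb),
    output = interp(out),
    updates = data.frame(step = step, input = input, cap_a_final = fa,
                         cap_b_final = fb, output = out)
  ), class = "trial_trace")
}

#' @export
print.trial_trace <- function(x, ...) {
  cat(sprintf("<trial_trace> %d frames @ %g frames/s (%.1f s)\n",
              length(x$output), x$frame_rate,
              (length(x$output) - 1) / x$frame_rate))
  cat(sprintf("  input %.2f-%.2f Hz, output plateau ~%.2f Hz\n",
              min(x$input), max(x$input),
              stats::quantile(x$output, 0.9, names = FALSE)))
  invisible(x)
}

# Deterministic per-trial substream seed below 2^31, so any single
# (system, task) trial is reproducible in isolation from the root seed.
trial_seed <- function(root_seed, system_id, task_id) {
  as.integer((as.double(root_seed) * 48271 + system_id * 1117 + task_id * 7) %%
               2147483629)
}

#' Simulate the full system-by-task sweep and extract steady-state rates
#'
#' Simulates every system in `systems` on every task in `tasks` and applies
#' the steady-state-rate extraction to each trace, using the trace's input
#' series as the creation rate and its output series as the hit rate.
#'
#' @param model Workload model kind (used to build `systems` when omitted).
#' @param n_updates Update points per trial.
#' @param seed Root seed; each trial uses a deterministic substream.
#' @param tasks,systems Optional pre-built grids.
#' @param threshold,window_s Overwhelmed-phase detection parameters (Hz, s).
#' @param detect_stride Frame stride at which the windowed median/MAD
#'   statistics are evaluated during detection (see the methods vignette);
#'   1 evaluates every frame.
#' @param detect_downsample Decimation factor for the rate-difference
#'   series inside detection (see [detect_overwhelmed_start()]). The sweep
#'   default of 10 evaluates the windowed statistics on 20 samples/s, which
#'   is ample for series that are linear between 0.5 s update points.
#' @param noise Disable all simulation noise when `FALSE`.
#' @param progress Print sweep progress every 25 systems.
#' @return A data.frame with columns `system_id`, `mean_cap_a`,
#'   `mean_cap_b`, `d_a`, `d_b`, `ssr_hz` (one row per system-task pair).
#' @export
run_experiment <- function(model = c("additive", "multiplicative", "flexible"),
                           n_updates = 281L, seed = 1L, tasks = NULL,
                           systems = NULL, threshold = 0.1, window_s = 5,
                           detect_stride = 50L, detect_downsample = 10L,
                           noise = TRUE, progress = FALSE) {
  model <- match.arg(model)
  if (is.null(tasks)) tasks <- build_task_grid()
  if (is.null(systems)) systems <- build_system_grid(model, seed = seed)
  n_sys <- nrow(systems); n_task <- nrow(tasks)
  res <- vector("list", n_sys)
  for (i in seq_len(n_sys)) {
    sys_i <- systems[i, ]
    ssr <- numeric(n_task)
    for (j in seq_len(n_task)) {
      tr <- tryCatch(
        simulate_trial(sys_i, tasks[j, ], n_updates = n_updates,
                       seed = trial_seed(seed, sys_i$system_id, j),
                       noise = noise),
        error = function(e) {
          stop(sprintf("trial failed for system %d, task %d: %s",
                       sys_i$system_id, j, conditionMessage(e)))
        })
      ssr[j] <- steady_state_rate(tr$input, tr$output,
                                  frame_rate = tr$frame_rate,
                                  threshold = threshold, window_s = window_s,
                                  stride = detect_stride,
                                  downsample = detect_downsample)$ssr
    }
    res[[i]] <- data.frame(system_id = sys_i$system_id,
                           mean_cap_a = sys_i$mean_cap_a,
                           mean_cap_b = sys_i$mean_cap_b,
                           d_a = tasks$d_a, d_b = tasks$d_b, ssr_hz = ssr)
    if (progress && i %% 25 == 0) {
      message(sprintf("  [%s] %d/%d systems", model, i, n_sys))
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
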