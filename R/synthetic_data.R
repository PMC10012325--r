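# Synthetic cohorts and object-hit-family trial event streams with the
# statistical structure the analysis pipeline assumes, so every stage can
# be exercised and validated without human data.

#' Participant specification for synthetic trials
#'
#' @param capacity_hz Latent bottleneck capacity (Hz); `Inf` for an
#'   unconstrained participant, 0 for one who never hits.
#' @param retest_sd Between-trial SD of the effective capacity (Hz). The
#'   default 0.15 Hz makes a (-0.30, 0.30) Hz ROPE approximately +/- 2 SD of
#'   the test-retest variability.
#' @return An object of class `participant_spec`.
#' @export
participant_spec <- function(capacity_hz, retest_sd = 0.15) {
  stopifnot(capacity_hz >= 0, retest_sd >= 0)
  structure(list(capacity_hz = capacity_hz, retest_sd = retest_sd),
            class = "participant_spec")
}

#' Generate one synthetic object-hit-family trial
#'
#' Schedules exactly 300 target creations (OH/TOH) or 200 targets plus 100
#' distractors (OHA/TOHA) over `duration_s` seconds with a monotonically
#' accelerating creation rate starting at 0.5 Hz. The ramp is quadratic,
#' `r(t) = 0.5 + c t^2` with `c` fixed by the exact object count: with 300
#' objects in 140 s a linear ramp from 0.5 Hz would peak below 3.8 Hz and
#' could not overwhelm the strongest capacities of interest (3.5 Hz),
#' whereas the accelerating ramp peaks around 5.4 Hz, emulating how the
#' real task compounds late-trial difficulty by speeding objects up as well
#' as creating them faster. Hit events are produced by passing creations
#' through a single bottleneck server with service time `1 / capacity`:
#' while the creation rate is below capacity every target is hit (after a
#' short service delay), and once creations outpace capacity the hit rate
#' saturates at the capacity, so every trial ends overwhelmed. A target
#' whose wait would exceed `patience_s` is missed (it has left the
#' workspace). Distractors are never hit.
#'
#' @param participant A [participant_spec()] or a plain capacity in Hz.
#' @param task One of `"OH"`, `"OHA"`, `"TOH"`, `"TOHA"`.
#' @param duration_s Trial length (s), default 140.
#' @param seed Integer seed.
#' @param patience_s How long a created target remains hittable (s).
#' @return An `event_stream` (see [read_events_csv()]) with an added
#'   `capacity_hz` field recording the trial's effective capacity.
#' @export
generate_trial_events <- function(participant, task = c("OH", "OHA", "TOH", "TOHA"),
                                  duration_s = 140, seed = NULL,
                                  patience_s = 1.3) {
  task <- match.arg(task)
  if (!inherits(participant, "participant_spec")) {
    participant <- participant_spec(participant, retest_sd = 0)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  n_targets <- if (task %in% c("OH", "TOH")) 300L else 200L
  n_distract <- if (task %in% c("OHA", "TOHA")) 100L else 0L
  n_obj <- n_targets + n_distract

  # accelerating creation rate r(t) = r0 + c t^2 with total mass n_obj;
  # creation times are the order statistics of the inhomogeneous schedule
  r0 <- 0.5
  cc <- 3 * (n_obj - r0 * duration_s) / duration_s^3
  stopifnot(cc > 0)
  big_lambda <- function(t) r0 * t + cc * t^3 / 3
  u <- sort(runif(n_obj)) * big_lambda(duration_s)
  times <- vapply(u, function(ui) {
    stats::uniroot(function(t) big_lambda(t) - ui, c(0, duration_s),
                   tol = 1e-8)$root
  }, numeric(1))
  times <- pmin(pmax(times, 0), duration_s)

  if (n_distract > 0) {
    distract_idx <- sort(sample.int(n_obj, n_distract))
  } else {
    distract_idx <- integer(0)
  }
  is_target <- !(seq_len(n_obj) %in% distract_idx)
  target_times <- times[is_target]
  distractor_times <- times[!is_target]

  cap <- participant$capacity_hz
  if (participant$retest_sd > 0 && is.finite(cap)) {
    cap <- max(rnorm(1, cap, participant$retest_sd), 0)
  }
  hit_times <- numeric(0)
  if (cap > 0) {
    service <- 1 / cap                     # 0 when capacity is infinite
    next_free <- 0
    hits <- numeric(length(target_times))
    n_hit <- 0L
    for (t in target_times) {
      start <- max(t, next_free)
      if (start - t <= patience_s) {
        done <- start + service
        if (done <= duration_s) {
          n_hit <- n_hit + 1L
          hits[n_hit] <- done
          next_free <- done
        }
      }
    }
    hit_times <- hits[seq_len(n_hit)]
  }
  structure(list(
    duration = duration_s,
    frame_rate = 200,
    creation_times = target_times,
    hit_times = hit_times,
    distractor_times = distractor_times,
    distractor_hit_times = numeric(0),
    capacity_hz = cap,
    task = task
  ), class = "event_stream")
}

#' @export
print.event_stream <- function(x, ...) {
  cat(sprintf("<event_stream> %.0f s: %d targets, %d hits, %d distractors\n",
              x$duration, length(x$creation_times), length(x$hit_times),
              length(x$distractor_times)))
  invisible(x)
}

#' Generate a synthetic paired-task cohort
#'
#' Draws baseline steady-state rates from a truncated-positive
#' Normal(`baseline_mean`, `baseline_sd`) population and maps each observed
#' baseline rate to the comparison task through
#' `intercept + slope * ssr_task1` plus t-distributed residual noise and
#' test-retest noise -- exactly the conditional structure the robust
#' regression assumes, so the regression should recover `slope` and
#' `intercept` at nominal coverage. The test-retest term represents the
#' between-trial variability of a single participant; its default, together
#' with the residual scale, keeps that variability on the scale implied by
#' a (-0.30, 0.30) Hz equivalence region.
#'
#' @param n Number of participants (>= 2).
#' @param slope,intercept True linear map between task steady-state rates.
#' @param residual_scale Scale of the t-distributed residuals (Hz).
#' @param residual_nu Degrees of freedom of the residuals.
#' @param baseline_mean,baseline_sd Population of baseline rates (Hz).
#' @param retest_sd Test-retest SD added to the comparison-task rate (Hz).
#' @param seed Integer seed.
#' @return A data.frame with `participant_id`, `ssr_task1`, `ssr_task2`.
#' @export
generate_cohort <- function(n, slope = 0.55, intercept = 0.16,
                            residual_scale = 0.1, residual_nu = 5,
                            baseline_mean = 1.7, baseline_sd = 0.4,
                            retest_sd = 0.15, seed = NULL) {
  stopifnot(n >= 2, residual_scale > 0, baseline_sd > 0, retest_sd >= 0)
  if (!is.null(seed)) set.seed(as.integer(seed))
  base <- rnorm_truncated_positive(n, rep(baseline_mean, n), baseline_sd)
  task2 <- intercept + slope * base +
    residual_scale * stats::rt(n, df = residual_nu) +
    rnorm(n, 0, retest_sd)
  data.frame(
    participant_id = seq_len(n),
    ssr_task1 = base,
    ssr_task2 = task2
  )
}

#' Read a paired-task cohort from CSV
#'
#' Expects columns `participant_id`, `ssr_task1_hz` (or `ssr_task1`) and
#' `ssr_task2_hz` (or `ssr_task2`).
#'
#' @param path CSV file path.
#' @return A data.frame with `participant_id`, `ssr_task1`, `ssr_task2`.
#' @export
read_cohort_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  pick <- function(opts) {
    hit <- intersect(opts, names(df))
    if (!length(hit)) stop("cohort CSV missing column: ", opts[1])
    df[[hit[1]]]
  }
  out <- data.frame(participant_id = pick("participant_id"),
                    ssr_task1 = pick(c("ssr_task1_hz", "ssr_task1")),
                    ssr_task2 = pick(c("ssr_task2_hz", "ssr_task2")))
  if (anyNA(out)) stop("cohort CSV contains missing values (unpaired rows?)")
  out
}
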