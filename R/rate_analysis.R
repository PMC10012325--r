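# Event streams to smoothed instantaneous rates, overwhelmed-phase
# detection via windowed median/MAD statistics, and steady-state rate
# extraction with the two refinement rules.

#' Kolmogorov-Zurbenko filter
#'
#' `iterations` passes of a centered moving average with an odd window. At
#' the boundaries the window is truncated to the available samples, so the
#' output has the same length as the input. A constant series is a fixed
#' point; two iterations of the filter are equivalent to convolving with a
#' triangular kernel in the interior.
#'
#' @param values Numeric series (e.g., a per-frame rate).
#' @param window_frames Odd window length in frames.
#' @param iterations Number of moving-average passes (>= 1).
#' @return Smoothed numeric series, same length as `values`.
#' @export
kz_filter <- function(values, window_frames, iterations = 2L) {
  if (window_frames < 1 || window_frames %% 2 == 0) {
    stop("window_frames must be a positive odd integer")
  }
  if (window_frames > length(values)) stop("window larger than series")
  if (iterations < 1) stop("iterations must be >= 1")
  for (k in seq_len(iterations)) {
    values <- ma_pass_cpp(values, as.integer(window_frames))
  }
  values
}

#' Convert event times to a smoothed instantaneous rate
#'
#' Bins events into per-frame counts (an event at time `t` lands in frame
#' `floor(t * frame_rate)`, half-open frame intervals), scales counts by the
#' frame rate to Hz, and smooths with [kz_filter()]. Total event mass is
#' conserved up to truncation at the series edges.
#'
#' @param events Numeric vector of event times (s) in `[0, duration]`.
#' @param frame_rate Samples per second (default 200).
#' @param duration Trial duration (s); defaults to the latest event time.
#' @param window_s Smoothing window width (s); 5 s at 200 frames/s gives the
#'   odd 1001-frame window.
#' @param iterations Kolmogorov-Zurbenko iterations (default 2).
#' @return Per-frame rate series (Hz) of length `duration * frame_rate + 1`.
#' @export
events_to_rate <- function(events, frame_rate = 200, duration = NULL,
                           window_s = 5, iterations = 2L) {
  stopifnot(frame_rate > 0)
  if (is.null(duration)) {
    duration <- if (length(events)) max(events) else stop("duration required for an empty event list")
  }
  if (length(events) && (any(events < 0) || any(events > duration))) {
    stop("events outside [0, duration]")
  }
  n_frames <- floor(duration * frame_rate) + 1L
  counts <- numeric(n_frames)
  if (length(events)) {
    idx <- pmin(floor(events * frame_rate) + 1L, n_frames)
    tab <- tabulate(idx, nbins = n_frames)
    counts <- as.numeric(tab)
  }
  rate <- counts * frame_rate
  window_frames <- as.integer(round(window_s * frame_rate)) + 1L
  if (window_frames %% 2 == 0) window_frames <- window_frames + 1L
  kz_filter(rate, window_frames, iterations)
}

#' Trailing-window median and median absolute deviation
#'
#' For each evaluation frame, computes the median of the trailing
#' `window_s`-second window and the MAD about that window's own median.
#' Windows end at the evaluation frame (causal), and the first evaluation
#' frame is the first one with a full window behind it.
#'
#' @param values Per-frame numeric series.
#' @param frame_rate Samples per second.
#' @param window_s Window width (s).
#' @param stride Evaluate every `stride` frames (1 = every frame).
#' @return A list with `idx` (1-based evaluation frames), `median`, `mad`.
#' @export
windowed_median_mad <- function(values, frame_rate = 200, window_s = 5,
                                stride = 1L) {
  w <- as.integer(round(window_s * frame_rate))
  if (w > length(values)) stop("window larger than series")
  roll_med_mad_cpp(as.numeric(values), w, as.integer(stride))
}

#' Detect the start of the overwhelmed phase
#'
#' Computes the per-frame creation-minus-hit rate difference and its
#' trailing windowed median and MAD. Under the default reading
#' (`overwhelmed_when = "lt"`), the start is the latest frame at which
#' `median - MAD < threshold` -- the last frame at which the participant was
#' still keeping up, i.e. the transition into the overwhelmed phase. The
#' alternative reading (`"ge"`) returns the first frame at which
#' `median - MAD >= threshold`.
#'
#' @param creation,hit Aligned per-frame rate series (Hz).
#' @param frame_rate Samples per second.
#' @param threshold Detection threshold (Hz, default 0.1).
#' @param window_s Window width for the median/MAD statistics (s).
#' @param stride Evaluate the windowed statistics every `stride` frames.
#' @param downsample Compute the windowed statistics on every
#'   `downsample`-th frame of the rate-difference series (window and stride
#'   are scaled to keep the same time spans). The rate series are smooth at
#'   the frame scale -- smoothed event rates or interpolated simulation
#'   traces -- so a modest decimation changes the windowed median and MAD
#'   negligibly while cutting the detection cost proportionally. 1 (the
#'   default) uses every frame.
#' @param overwhelmed_when `"lt"` (default) or `"ge"`, see Details.
#' @return A list with `start_frame` (1-based), `from_start` (`TRUE` when
#'   the condition is never satisfied and the trial is treated as
#'   overwhelmed from the first frame), and the evaluation grid `idx`,
#'   `stat` (median minus MAD) and `keeping_up` (logical).
#' @export
detect_overwhelmed_start <- function(creation, hit, frame_rate = 200,
                                     threshold = 0.1, window_s = 5,
                                     stride = 1L, downsample = 1L,
                                     overwhelmed_when = c("lt", "ge")) {
  overwhelmed_when <- match.arg(overwhelmed_when)
  if (length(creation) != length(hit)) stop("series must be equal length")
  d <- creation - hit
  if (downsample > 1L) {
    ds <- as.integer(downsample)
    d_eval <- d[seq(1L, length(d), by = ds)]
    mm <- windowed_median_mad(d_eval, frame_rate / ds, window_s,
                              max(1L, as.integer(stride) %/% ds))
    mm$idx <- (mm$idx - 1L) * ds + 1L      # map back to full-resolution frames
  } else {
    mm <- windowed_median_mad(d, frame_rate, window_s, stride)
  }
  stat <- mm$median - mm$mad
  keeping_up <- stat < threshold
  if (overwhelmed_when == "lt") {
    hits <- which(keeping_up)
    if (!length(hits)) {
      return(list(start_frame = 1L, from_start = TRUE, idx = mm$idx,
                  stat = stat, keeping_up = keeping_up))
    }
    start <- mm$idx[hits[length(hits)]]
  } else {
    hits <- which(!keeping_up)
    if (!length(hits)) {
      return(list(start_frame = 1L, from_start = TRUE, idx = mm$idx,
                  stat = stat, keeping_up = keeping_up))
    }
    start <- mm$idx[hits[1]]
  }
  list(start_frame = as.integer(start), from_start = FALSE, idx = mm$idx,
       stat = stat, keeping_up = keeping_up)
}

#' Extract the steady-state rate of a trial
#'
#' The steady-state rate (SSR) is the mean hit rate from the start of the
#' overwhelmed phase to the frame where the creation rate peaks. After
#' detection the start frame is advanced one frame at a time while either
#' refinement rule holds: (1) advancing increases the SSR, or (2) the
#' windowed median-minus-MAD statistic was below `threshold` at any
#' evaluation point in the preceding `window_s` seconds. The start never
#' advances past the peak-creation frame.
#'
#' @inheritParams detect_overwhelmed_start
#' @return An object of class `steady_state_result`: list with `ssr` (Hz),
#'   `overwhelmed_start` (final refined frame), `detected_start` (frame
#'   from detection, before refinement), `peak_creation_frame`,
#'   `rate_difference` (per-frame creation minus hit, Hz), and flags
#'   `from_start` (overwhelmed from the first frame) and `single_frame`
#'   (start reached the peak and the SSR is a single-frame value).
#' @export
steady_state_rate <- function(creation, hit, frame_rate = 200,
                              threshold = 0.1, window_s = 5, stride = 1L,
                              downsample = 1L,
                              overwhelmed_when = c("lt", "ge")) {
  det <- detect_overwhelmed_start(creation, hit, frame_rate, threshold,
                                  window_s, stride, downsample,
                                  overwhelmed_when)
  peak <- which.max(creation)
  w <- as.integer(round(window_s * frame_rate))
  start0 <- min(det$start_frame, peak)
  start <- start0

  true_idx <- det$idx[det$keeping_up]
  csum <- cumsum(hit)
  seg_sum <- function(a, b) csum[b] - if (a > 1) csum[a - 1] else 0

  s_sum <- seg_sum(start, peak)
  s_len <- peak - start + 1L
  p <- length(true_idx)                       # pointer: largest true_idx <= start - 1
  while (p > 0 && true_idx[p] > start - 1L) p <- p - 1L
  max_iter <- length(hit)
  iter <- 0L
  while (start < peak && iter < max_iter) {
    rule1 <- hit[start] < s_sum / s_len
    rule2 <- p > 0 && true_idx[p] >= start - w
    if (!rule1 && !rule2) break
    s_sum <- s_sum - hit[start]
    s_len <- s_len - 1L
    start <- start + 1L
    while (p < length(true_idx) && true_idx[p + 1] <= start - 1L) p <- p + 1L
    iter <- iter + 1L
  }
  ssr <- mean(hit[start:peak])
  structure(list(
    ssr = ssr,
    overwhelmed_start = as.integer(start),
    detected_start = as.integer(start0),
    peak_creation_frame = as.integer(peak),
    rate_difference = creation - hit,
    from_start = det$from_start,
    single_frame = start >= peak
  ), class = "steady_state_result")
}

#' @export
print.steady_state_result <- function(x, ...) {
  cat(sprintf("<steady_state_result> SSR = %.3f Hz over frames [%d, %d]%s%s\n",
              x$ssr, x$overwhelmed_start, x$peak_creation_frame,
              if (x$from_start) " [overwhelmed from start]" else "",
              if (x$single_frame) " [single frame]" else ""))
  invisible(x)
}

#' Read a behavioral event stream from CSV
#'
#' Expects columns `time_s` and `event_type`, the latter one of
#' `create_target`, `hit_target`, `create_distractor`, `hit_distractor`.
#'
#' @param path CSV file path.
#' @return An object of class `event_stream`: list with `duration`,
#'   `frame_rate` (NA unless recorded), `creation_times`, `hit_times`,
#'   `distractor_times`, `distractor_hit_times`.
#' @export
read_events_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "event_type")
  if (!all(need %in% names(df))) {
    stop("event CSV must have columns time_s and event_type")
  }
  known <- c("create_target", "hit_target", "create_distractor", "hit_distractor")
  bad <- setdiff(unique(df$event_type), known)
  if (length(bad)) stop("unknown event_type: ", paste(bad, collapse = ", "))
  pick <- function(kind) sort(df$time_s[df$event_type == kind])
  structure(list(
    duration = max(df$time_s),
    frame_rate = NA_real_,
    creation_times = pick("create_target"),
    hit_times = pick("hit_target"),
    distractor_times = pick("create_distractor"),
    distractor_hit_times = pick("hit_distractor")
  ), class = "event_stream")
}

#' Write a behavioral event stream to CSV
#'
#' @param stream An `event_stream` (see [read_events_csv()],
#'   [generate_trial_events()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(stream, path) {
  chunk <- function(times, kind) {
    data.frame(time_s = times, event_type = rep(kind, length(times)))
  }
  df <- rbind(
    chunk(stream$creation_times, "create_target"),
    chunk(stream$hit_times, "hit_target"),
    chunk(stream$distractor_times, "create_distractor"),
    chunk(stream$distractor_hit_times, "hit_distractor")
  )
  df <- df[order(df$time_s), ]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Steady-state rate from an event stream
#'
#' Convenience wrapper: converts target creation and target hit events to
#' smoothed rates (distractor events are ignored) and extracts the
#' steady-state rate.
#'
#' @param stream An `event_stream`.
#' @param frame_rate Samples per second for the rate series.
#' @param window_s,threshold,stride,downsample Passed to
#'   [steady_state_rate()]; the defaults evaluate the detection statistics
#'   every 50 ms on a 40 samples/s decimation, which is conservative for
#'   rates already smoothed over 5 s.
#' @return A `steady_state_result`.
#' @export
extract_ssr <- function(stream, frame_rate = 200, window_s = 5,
                        threshold = 0.1, stride = 10L, downsample = 5L) {
  duration <- stream$duration
  creation <- events_to_rate(stream$creation_times, frame_rate, duration,
                             window_s = window_s)
  hit <- events_to_rate(stream$hit_times, frame_rate, duration,
                        window_s = window_s)
  steady_state_rate(creation, hit, frame_rate, threshold, window_s, stride,
                    downsample)
}
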