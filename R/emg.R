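#' Full-wave rectify an EMG trace
#'
#' @param x Numeric amplitude vector (mV).
#' @return `abs(x)`; idempotent.
#' @examples
#' rectify(c(-1, 2, -3))
#' @export
rectify <- function(x) {
  if (length(x) == 0L) abort("cannot rectify an empty trace")
  abs(x)
}

# samples whose time (ms relative to the stimulus) falls in the closed
# interval [start, end]; both endpoints are needed so that the trapezoid of
# a constant c over a window of width w equals c * w exactly
window_indices <- function(n, sampling_rate, stimulus_index, window) {
  if (window[1] >= window[2]) {
    abort("window start must precede window end")
  }
  dt <- 1000 / sampling_rate
  t_ms <- (seq_len(n) - stimulus_index) * dt
  eps <- dt * 1e-9
  if (window[1] < t_ms[1] - eps) {
    abort(paste0("window start (", window[1], " ms) lies before the trace ",
                 "start (", round(t_ms[1], 3), " ms)"))
  }
  if (window[2] > t_ms[n] + eps) {
    abort(paste0("window end (", window[2], " ms) lies beyond the trace ",
                 "end (", round(t_ms[n], 3), " ms)"))
  }
  which(t_ms >= window[1] - eps & t_ms <= window[2] + eps)
}

# trapezoid over uniformly spaced samples (spacing dt, in ms)
trapz_area <- function(y, dt) {
  k <- length(y)
  if (k < 2L) abort("window must contain at least 2 samples")
  (sum(y) - (y[1] + y[k]) / 2) * dt
}

#' Windowed area of a rectified EMG trace
#'
#' Trapezoidal integral of the rectified trace over a time window given in ms
#' relative to the stimulus; samples are selected on the closed interval
#' `[start, end]` of the sample grid, so a constant `c` mV over a `w` ms
#' window integrates to exactly `c * w` mV·ms at any sampling rate.
#'
#' @param samples Amplitude vector (mV); rectified internally.
#' @param sampling_rate Sampling rate, Hz.
#' @param stimulus_index 1-based sample index of the TMS pulse (t = 0).
#' @param window Length-2 ms window relative to the stimulus.
#' @return Non-negative area in mV·ms.
#' @examples
#' # constant 1 mV over a 10 ms window -> 10 mV.ms
#' window_area(rep(1, 101), 1000, 51, c(-10, 0))
#' @export
window_area <- function(samples, sampling_rate, stimulus_index, window) {
  if (length(samples) == 0L) abort("cannot integrate an empty trace")
  if (stimulus_index < 1L || stimulus_index > length(samples)) {
    abort("`stimulus_index` must lie inside the trace")
  }
  idx <- window_indices(length(samples), sampling_rate, stimulus_index, window)
  trapz_area(rectify(samples[idx]), 1000 / sampling_rate)
}

#' Pre-trigger-normalized MEP size of one trial
#'
#' Ratio of the MEP-window area to the pre-trigger-window area of the
#' rectified trace. Trials whose pre-trigger area is at or below machine
#' epsilon are flagged invalid (returned as `NA` with a warning) rather than
#' producing an unstable division.
#'
#' @inheritParams window_area
#' @param mep_window,pre_window ms windows relative to the stimulus.
#' @return Unitless ratio, or `NA` for an invalid trial.
#' @export
normalized_mep <- function(samples, sampling_rate, stimulus_index,
                           mep_window = c(20, 60),
                           pre_window = c(-110, -10)) {
  pre <- window_area(samples, sampling_rate, stimulus_index, pre_window)
  if (pre <= .Machine$double.eps) {
    warn("pre-trigger area is ~0; trial flagged invalid")
    return(NA_real_)
  }
  window_area(samples, sampling_rate, stimulus_index, mep_window) / pre
}

#' Per-trial normalized MEP responses for a session
#'
#' Data-frame-first wrapper over [normalized_mep()]: adds a `response` column
#' (and a logical `valid`) to a trial tibble.
#'
#' @param trials Trial tibble with `samples` (list column), `sampling_rate`,
#'   `stimulus_index`.
#' @param mep_window,pre_window ms windows relative to the stimulus.
#' @return `trials` with `response` and `valid` columns appended.
#' @export
mep_responses <- function(trials, mep_window = c(20, 60),
                          pre_window = c(-110, -10)) {
  stopifnot(is.data.frame(trials))
  resp <- withCallingHandlers(
    pmap_dbl(list(trials$samples, trials$sampling_rate, trials$stimulus_index),
             function(s, fs, si) {
               normalized_mep(s, fs, si, mep_window, pre_window)
             }),
    warning = function(w) invokeRestart("muffleWarning")
  )
  n_bad <- sum(is.na(resp))
  if (n_bad > 0) {
    warn(paste0(n_bad, " trial(s) had ~0 pre-trigger area and were flagged invalid"))
  }
  trials %>% mutate(response = resp, valid = !is.na(resp))
}

#' Block-mean recruitment-curve points
#'
#' Averages per-trial normalized MEP responses within each stimulation block
#' (ratio first, then mean), grouped by any of `subject_id`, `hemisphere`,
#' `leg` that are present, and by `intensity`.
#'
#' @inheritParams mep_responses
#' @return A curve-point tibble: grouping columns, `intensity`, `response`
#'   (block mean), `n_trials` (valid trials averaged).
#' @examples
#' cfg <- gen_config(n_subjects = 3, seed = 5, emg_noise_sd = 0)
#' st <- generate_cohort(cfg)[1, ]
#' pts <- block_points(generate_emg_session(st, cfg))
#' head(pts)
#' @export
block_points <- function(trials, mep_window = c(20, 60),
                         pre_window = c(-110, -10)) {
  scored <- mep_responses(trials, mep_window, pre_window)
  pts <- scored %>%
    group_by(across(any_of(c("subject_id", "hemisphere", "leg"))),
             .data$intensity) %>%
    summarise(response = mean(.data$response[.data$valid]),
              n_trials = sum(.data$valid), .groups = "drop")
  if (any(pts$n_trials == 0L)) {
    bad <- pts %>% filter(.data$n_trials == 0L)
    abort(paste0("all trials invalid in ", nrow(bad), " block(s); first: ",
                 paste(unlist(bad[1, setdiff(names(bad), c("response", "n_trials"))]),
                       collapse = " / ")))
  }
  pts
}

#' Estimate the motor threshold from a multi-intensity trial set
#'
#' Returns the lowest tested intensity at which at least half of the trials
#' are response-positive, where a trial is positive when its MEP-window area
#' exceeds its pre-trigger-window area by more than `criterion` mV·ms.
#'
#' @inheritParams mep_responses
#' @param criterion Excess area (mV·ms) over the pre-trigger area required to
#'   call a trial response-positive.
#' @return The threshold intensity (same units as the `intensity` column).
#' @export
estimate_motor_threshold <- function(trials, criterion = 0.1,
                                     mep_window = c(20, 60),
                                     pre_window = c(-110, -10)) {
  stopifnot(is.data.frame(trials))
  if (length(unique(trials$intensity)) < 2L) {
    abort("threshold estimation needs trials at >= 2 intensities")
  }
  areas <- pmap(list(trials$samples, trials$sampling_rate, trials$stimulus_index),
                function(s, fs, si) {
                  c(mep = window_area(s, fs, si, mep_window),
                    pre = window_area(s, fs, si, pre_window))
                })
  scored <- trials %>%
    mutate(positive = map_dbl(areas, "mep") - map_dbl(areas, "pre") > criterion)
  by_int <- scored %>%
    group_by(.data$intensity) %>%
    summarise(prop = mean(.data$positive), .groups = "drop") %>%
    arrange(.data$intensity)
  hit <- by_int$intensity[by_int$prop >= 0.5]
  if (length(hit) == 0L) {
    abort("no tested intensity reaches the response criterion; widen the intensity grid downward/upward")
  }
  min(hit)
}
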