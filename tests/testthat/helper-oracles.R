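# independent oracles and small fixture builders used across the suite

# rectangle-sum area oracle (sum of |x| times dt over window samples)
rect_area_oracle <- function(samples, sampling_rate, stimulus_index, window) {
  dt <- 1000 / sampling_rate
  t_ms <- (seq_along(samples) - stimulus_index) * dt
  idx <- which(t_ms >= window[1] & t_ms <= window[2])
  sum(abs(samples[idx])) * dt
}

# Pearson-on-average-ranks Spearman oracle
spearman_oracle <- function(x, y) stats::cor(rank(x), rank(y))

# one synthetic trial row in the package's trial-tibble layout
trial_row <- function(samples, sampling_rate = 1000, stimulus_index = 201,
                      intensity = 100, trial = 1L, subject_id = 1L,
                      hemisphere = "lesioned", leg = "paretic") {
  tibble::tibble(
    subject_id = subject_id, hemisphere = hemisphere, leg = leg,
    intensity = intensity, trial = trial,
    sampling_rate = sampling_rate, stimulus_index = stimulus_index,
    samples = list(samples)
  )
}

# trace with known window areas: constant `pre_mv` before the stimulus,
# constant `mep_mv` after it (fs 1000 Hz, stimulus at sample 201, t in
# [-200, 200] ms)
flat_trace <- function(pre_mv, mep_mv, n = 401, stimulus_index = 201) {
  t_ms <- (seq_len(n) - stimulus_index)
  ifelse(t_ms < 0, pre_mv, mep_mv)
}

# recruitment_fit with a prescribed slope (exact line through 3 points)
fit_with_slope <- function(slope, leg = NA_character_) {
  pts <- tibble::tibble(intensity = c(100, 110, 120),
                        response = slope * c(0, 10, 20) + 1)
  if (!is.na(leg)) pts$leg <- leg
  fit_recruitment(pts)
}

# cohort table of plain numeric columns for stats-level tests
random_cohort_table <- function(n, seed) {
  withr::with_seed(seed, tibble::tibble(
    subject_id = seq_len(n),
    fm = sample(5:34, n, replace = TRUE),
    walking_speed = runif(n, 5, 90),
    fcr_paretic = runif(n, 0.2, 2.6),
    fcr_nonparetic = runif(n, 0.2, 0.9)
  ))
}
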