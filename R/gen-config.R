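#' Configuration for the synthetic stroke-cohort generator
#'
#' Builds and validates the parameter set that drives [generate_cohort()] and
#' its per-subject emitters ([generate_emg_session()], [generate_fa_volume()],
#' [generate_behavior()]). Defaults encode a chronic-stroke lower-limb cohort:
#' a paretic-leg functional connectivity ratio (FCR) centred on 1.7 spanning
#' 0.27--2.6, a non-paretic FCR centred on 0.55 spanning 0.2--0.83, and
#' internal-capsule fractional anisotropy of 0.42 (lesioned hemisphere)
#' versus 0.54 (intact hemisphere).
#'
#' A single latent `severity` in `[0, 1]` per subject drives the paretic FCR
#' (monotonically increasing), the lesioned-hemisphere FA deficit, lesion
#' size, and the behavioral scores (Fugl-Meyer and walking speed, both
#' decreasing). The non-paretic FCR is drawn independently of severity.
#'
#' @param n_subjects Number of subjects (>= 3; the correlation battery is
#'   undefined below that).
#' @param seed Integer seed; identical configurations yield bit-identical
#'   cohorts at every stage.
#' @param severity_range Ordered pair in `[0, 1]`; severities are drawn over
#'   this range by a stratified uniform draw (one draw per equal-width
#'   stratum, order shuffled) so cohort composition is stable across seeds.
#' @param paretic_fcr_mean,paretic_fcr_range Target mean and (min, max) of the
#'   paretic-leg true FCR over a full-range severity draw.
#' @param nonparetic_fcr_mean,nonparetic_fcr_range Same for the non-paretic
#'   leg (severity-independent, scaled-Beta draw).
#' @param fa_lesioned_mean,fa_intact_mean Target group-mean FA of the
#'   lesioned / intact posterior limb of the internal capsule (PLIC).
#' @param fa_noise_sd Per-voxel FA noise SD (Gaussian, clamped to `[0, 1]`).
#' @param emg_noise_sd Additive EMG noise SD in mV.
#' @param sampling_rate EMG sampling rate, Hz.
#' @param trials_per_block MEP trials per stimulation-intensity block.
#' @param intensity_grid Stimulation intensities as % of motor threshold;
#'   strictly increasing, at least 3 points (a line fit needs 2, a fit-quality
#'   r needs 3).
#' @param mep_window,pre_trigger_window Analysis windows in ms relative to the
#'   stimulus (start < end); the MEP window must lie after the stimulus and
#'   the pre-trigger window before it.
#' @param volume_shape Voxel grid (nx, ny, nz) for the FA phantom; must be
#'   large enough to hold the four internal-capsule ROIs disjointly.
#' @param voxel_dims Voxel dimensions in mm.
#' @param tonic_level_mv Deterministic pre-stimulus tonic EMG level, mV. The
#'   post-stimulus baseline outside the MEP burst is silent (cortical silent
#'   period), so at-threshold trials carry exactly zero MEP area.
#' @param burst_center_ms,burst_sd_ms Centre and SD of the Gaussian-envelope
#'   MEP burst, ms post-stimulus.
#' @param slope_scale Median contralateral recruitment-curve slope
#'   (normalized response per %MT); log-normal between-subject jitter
#'   `slope_jitter_sd` multiplies it. FCR is a slope ratio, so this scale
#'   cancels out of every ratio.
#' @param slope_jitter_sd SD of the log-normal jitter on base slopes.
#' @param fa_subject_sd Between-subject SD of intact-hemisphere FA.
#' @param fa_gap_jitter_sd Relative SD of the severity-driven FA deficit.
#' @param fm_range,fm_mean,fm_noise_sd Fugl-Meyer lower-limb score (max 34):
#'   target range and mean over a full-range severity draw, plus additive
#'   noise SD before rounding/clipping.
#' @param walk_speed_range,walk_speed_mean,walk_speed_noise_sd Walking speed
#'   (m/min from a 10 m timed walk): target range/mean and noise SD.
#' @param lesion_volume_scale Expected lesion volume in mm^3 at severity 1
#'   (log-normal jitter `lesion_jitter_sd` multiplies it, so lesion size is
#'   only loosely coupled to severity).
#' @param lesion_jitter_sd SD (log scale) of the lesion-volume jitter.
#' @param cst_sigma_vox Lateral Gaussian SD (voxels) of the corticospinal
#'   tract probability map descending through the lesioned PLIC.
#'
#' @return A validated list of class `fcr_gen_config`.
#' @examples
#' cfg <- gen_config(n_subjects = 5, seed = 1)
#' cfg$paretic_fcr_mean
#' @export
gen_config <- function(n_subjects = 13L,
                       seed = 1L,
                       severity_range = c(0, 1),
                       paretic_fcr_mean = 1.7,
                       paretic_fcr_range = c(0.27, 2.6),
                       nonparetic_fcr_mean = 0.55,
                       nonparetic_fcr_range = c(0.2, 0.83),
                       fa_lesioned_mean = 0.42,
                       fa_intact_mean = 0.54,
                       fa_noise_sd = 0.02,
                       emg_noise_sd = 0.01,
                       sampling_rate = 2000,
                       trials_per_block = 8L,
                       intensity_grid = seq(100, 150, by = 10),
                       mep_window = c(20, 60),
                       pre_trigger_window = c(-110, -10),
                       volume_shape = c(32L, 32L, 16L),
                       voxel_dims = c(2, 2, 2),
                       tonic_level_mv = 0.05,
                       burst_center_ms = 40,
                       burst_sd_ms = 6,
                       slope_scale = 0.05,
                       slope_jitter_sd = 0.15,
                       fa_subject_sd = 0.02,
                       fa_gap_jitter_sd = 0.1,
                       fm_range = c(12, 34),
                       fm_mean = 23.8,
                       fm_noise_sd = 2,
                       walk_speed_range = c(5.4, 89.75),
                       walk_speed_mean = 39.8,
                       walk_speed_noise_sd = 6,
                       lesion_volume_scale = 4000,
                       lesion_jitter_sd = 0.8,
                       cst_sigma_vox = 2) {
  cfg <- list(
    n_subjects = as.integer(n_subjects), seed = as.integer(seed),
    severity_range = as.numeric(severity_range),
    paretic_fcr_mean = paretic_fcr_mean,
    paretic_fcr_range = as.numeric(paretic_fcr_range),
    nonparetic_fcr_mean = nonparetic_fcr_mean,
    nonparetic_fcr_range = as.numeric(nonparetic_fcr_range),
    fa_lesioned_mean = fa_lesioned_mean, fa_intact_mean = fa_intact_mean,
    fa_noise_sd = fa_noise_sd, emg_noise_sd = emg_noise_sd,
    sampling_rate = sampling_rate,
    trials_per_block = as.integer(trials_per_block),
    intensity_grid = as.numeric(intensity_grid),
    mep_window = as.numeric(mep_window),
    pre_trigger_window = as.numeric(pre_trigger_window),
    volume_shape = as.integer(volume_shape),
    voxel_dims = as.numeric(voxel_dims),
    tonic_level_mv = tonic_level_mv,
    burst_center_ms = burst_center_ms, burst_sd_ms = burst_sd_ms,
    slope_scale = slope_scale, slope_jitter_sd = slope_jitter_sd,
    fa_subject_sd = fa_subject_sd, fa_gap_jitter_sd = fa_gap_jitter_sd,
    fm_range = as.numeric(fm_range), fm_mean = fm_mean,
    fm_noise_sd = fm_noise_sd,
    walk_speed_range = as.numeric(walk_speed_range),
    walk_speed_mean = walk_speed_mean,
    walk_speed_noise_sd = walk_speed_noise_sd,
    lesion_volume_scale = lesion_volume_scale,
    lesion_jitter_sd = lesion_jitter_sd,
    cst_sigma_vox = cst_sigma_vox
  )
  class(cfg) <- "fcr_gen_config"
  validate_gen_config(cfg)
}

validate_gen_config <- function(cfg) {
  chk_pair <- function(x, name, strict = FALSE) {
    if (length(x) != 2L || any(!is.finite(x))) {
      abort(paste0("`", name, "` must be a finite pair"))
    }
    if ((strict && x[1] >= x[2]) || x[1] > x[2]) {
      abort(paste0("`", name, "` must be an ordered pair (got ",
                   x[1], ", ", x[2], ")"))
    }
  }
  chk_mean_in <- function(m, rng, name) {
    # degenerate ranges carry no mean target
    if (rng[1] < rng[2] && (m <= rng[1] || m >= rng[2])) {
      abort(paste0("`", name, "` mean ", m, " must lie strictly inside its ",
                   "range (", rng[1], ", ", rng[2], ")"))
    }
  }
  chk_pair(cfg$severity_range, "severity_range")
  if (any(cfg$severity_range < 0) || any(cfg$severity_range > 1)) {
    abort("`severity_range` must lie in [0, 1]")
  }
  chk_pair(cfg$paretic_fcr_range, "paretic_fcr_range", strict = TRUE)
  chk_pair(cfg$nonparetic_fcr_range, "nonparetic_fcr_range", strict = TRUE)
  chk_mean_in(cfg$paretic_fcr_mean, cfg$paretic_fcr_range, "paretic_fcr")
  chk_mean_in(cfg$nonparetic_fcr_mean, cfg$nonparetic_fcr_range,
              "nonparetic_fcr")
  chk_pair(cfg$fm_range, "fm_range", strict = TRUE)
  chk_mean_in(cfg$fm_mean, cfg$fm_range, "fm")
  chk_pair(cfg$walk_speed_range, "walk_speed_range", strict = TRUE)
  chk_mean_in(cfg$walk_speed_mean, cfg$walk_speed_range, "walk_speed")
  sds <- c(fa_noise_sd = cfg$fa_noise_sd, emg_noise_sd = cfg$emg_noise_sd,
           slope_jitter_sd = cfg$slope_jitter_sd,
           fa_subject_sd = cfg$fa_subject_sd,
           fa_gap_jitter_sd = cfg$fa_gap_jitter_sd,
           fm_noise_sd = cfg$fm_noise_sd,
           walk_speed_noise_sd = cfg$walk_speed_noise_sd,
           lesion_jitter_sd = cfg$lesion_jitter_sd)
  if (any(sds < 0)) {
    abort(paste0("noise SDs must be >= 0; offending: ",
                 paste(names(sds)[sds < 0], collapse = ", ")))
  }
  if (cfg$sampling_rate <= 0) abort("`sampling_rate` must be > 0")
  if (cfg$trials_per_block < 1L) abort("`trials_per_block` must be >= 1")
  g <- cfg$intensity_grid
  if (length(g) < 3L || any(diff(g) <= 0)) {
    abort("`intensity_grid` must be strictly increasing with >= 3 points")
  }
  chk_pair(cfg$mep_window, "mep_window", strict = TRUE)
  chk_pair(cfg$pre_trigger_window, "pre_trigger_window", strict = TRUE)
  if (cfg$pre_trigger_window[2] > 0) {
    abort("`pre_trigger_window` must end at or before the stimulus (t = 0)")
  }
  if (cfg$mep_window[1] < 0) {
    abort("`mep_window` must start at or after the stimulus (t = 0)")
  }
  if (length(cfg$volume_shape) != 3L || any(cfg$volume_shape < 1L)) {
    abort("`volume_shape` must be three positive integers")
  }
  if (length(cfg$voxel_dims) != 3L || any(cfg$voxel_dims <= 0)) {
    abort("`voxel_dims` must be three positive lengths (mm)")
  }
  if (cfg$tonic_level_mv <= 0) {
    abort("`tonic_level_mv` must be > 0 (pre-trigger normalization divides by it)")
  }
  cfg
}

#' @export
print.fcr_gen_config <- function(x, ...) {
  cat("<fcr_gen_config>\n")
  cat("  subjects:", x$n_subjects, " seed:", x$seed, "\n")
  cat("  paretic FCR:", x$paretic_fcr_mean, "in [",
      paste(x$paretic_fcr_range, collapse = ", "), "]\n")
  cat("  non-paretic FCR:", x$nonparetic_fcr_mean, "in [",
      paste(x$nonparetic_fcr_range, collapse = ", "), "]\n")
  cat("  PLIC FA lesioned/intact:", x$fa_lesioned_mean, "/",
      x$fa_intact_mean, "\n")
  cat("  intensity grid (%MT):", paste(x$intensity_grid, collapse = " "), "\n")
  invisible(x)
}

# deterministic per-subject, per-stage sub-seed (kept inside 32-bit range)
subject_seed <- function(seed, subject_id, stage) {
  as.integer((abs(seed) * 7919 + subject_id * 104729 + stage * 611953) %%
               .Machine$integer.max)
}

# monotone map of u in [0, 1] onto [lo, hi] with E[f(U)] = target mean for
# U ~ Uniform(0, 1): f(u) = lo + (hi - lo) * u^a, a = (hi - lo)/(mean - lo) - 1
power_map <- function(u, lo, hi, mean) {
  if (hi <= lo) return(rep(lo, length(u)))
  a <- (hi - lo) / (mean - lo) - 1
  lo + (hi - lo) * u^a
}
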