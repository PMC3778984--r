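#' Generate the latent state of a synthetic stroke cohort
#'
#' Draws one latent severity per subject (stratified uniform over
#' `severity_range`) and maps it to the quantities the downstream pipeline is
#' supposed to recover: the four true recruitment-curve slopes (stimulated
#' hemisphere x recorded leg), the per-hemisphere PLIC FA, the Fugl-Meyer
#' score, the 10 m walk time, and a lesion-volume target. The paretic-leg
#' true FCR increases monotonically with severity and hits the configured
#' mean/range over a full-range draw; the non-paretic FCR is drawn
#' independently of severity.
#'
#' @param config An [gen_config()] object.
#' @return A tibble with one row per subject: `subject_id`, `severity`, the
#'   four `slope_<hemisphere>_<leg>` columns, `fcr_paretic_true`,
#'   `fcr_nonparetic_true`, `fa_lesioned_true`, `fa_intact_true`, `fm_true`,
#'   `walk_time_s`, `lesion_target_mm3`.
#' @examples
#' cohort <- generate_cohort(gen_config(n_subjects = 5, seed = 1))
#' cohort$fcr_paretic_true
#' @export
generate_cohort <- function(config) {
  config <- validate_gen_config(config)
  n <- config$n_subjects
  if (n < 3L) {
    abort("`n_subjects` must be >= 3: the correlation battery is undefined below that")
  }
  sr <- config$severity_range
  withr::with_seed(config$seed %% .Machine$integer.max, {
    # stratified draw: one uniform per equal-width stratum, order shuffled,
    # so cohort-level means are stable across seeds
    u <- (sample.int(n) - runif(n)) / n
    severity <- sr[1] + (sr[2] - sr[1]) * u
    u_rel <- if (sr[2] > sr[1]) u else rep(0.5, n)

    fcr_p <- power_map(u_rel, config$paretic_fcr_range[1],
                       config$paretic_fcr_range[2], config$paretic_fcr_mean)
    npr <- config$nonparetic_fcr_range
    if (npr[2] > npr[1]) {
      m <- (config$nonparetic_fcr_mean - npr[1]) / (npr[2] - npr[1])
      k <- 8
      fcr_np <- npr[1] + (npr[2] - npr[1]) * rbeta(n, m * k, (1 - m) * k)
    } else {
      fcr_np <- rep(npr[1], n)
    }

    js <- config$slope_jitter_sd
    base_par <- config$slope_scale * exp(rnorm(n, 0, js) - js^2 / 2)
    base_np <- config$slope_scale * exp(rnorm(n, 0, js) - js^2 / 2)

    fa_int <- clamp01(config$fa_intact_mean + rnorm(n, 0, config$fa_subject_sd),
                      0.05, 0.95)
    gap <- config$fa_intact_mean - config$fa_lesioned_mean
    delta <- 2 * severity * gap *
      pmax(0, 1 + rnorm(n, 0, config$fa_gap_jitter_sd))
    fa_les <- clamp01(fa_int - delta, 0.02, 0.98)

    fm <- power_map(1 - u_rel, config$fm_range[1], config$fm_range[2],
                    config$fm_mean) + rnorm(n, 0, config$fm_noise_sd)
    fm <- as.integer(pmin(34, pmax(0, round(fm))))

    speed <- power_map(1 - u_rel, config$walk_speed_range[1],
                       config$walk_speed_range[2], config$walk_speed_mean) +
      rnorm(n, 0, config$walk_speed_noise_sd)
    speed <- pmax(1, speed)

    lj <- config$lesion_jitter_sd
    lesion_mm3 <- severity * config$lesion_volume_scale *
      exp(rnorm(n, 0, lj) - lj^2 / 2)

    tibble(
      subject_id = seq_len(n),
      severity = severity,
      slope_lesioned_paretic = base_par,            # contralateral, paretic leg
      slope_contralesional_paretic = fcr_p * base_par,   # ipsilateral
      slope_contralesional_nonparetic = base_np,    # contralateral, non-paretic
      slope_lesioned_nonparetic = fcr_np * base_np, # ipsilateral
      fcr_paretic_true = fcr_p,
      fcr_nonparetic_true = fcr_np,
      fa_lesioned_true = fa_les,
      fa_intact_true = fa_int,
      fm_true = fm,
      walk_time_s = 600 / speed,
      lesion_target_mm3 = lesion_mm3
    )
  })
}

clamp01 <- function(x, lo = 0, hi = 1) pmax(pmin(x, hi), lo)  # keeps dim()

# pull one subject row out of a cohort tibble as a plain list
as_subject_state <- function(state) {
  if (is.data.frame(state)) {
    if (nrow(state) != 1L) {
      abort("`state` must be a single subject (one row)")
    }
    state <- as.list(state)
  }
  needed <- c("subject_id", "slope_lesioned_paretic",
              "slope_contralesional_paretic", "slope_lesioned_nonparetic",
              "slope_contralesional_nonparetic", "fa_lesioned_true",
              "fa_intact_true", "fm_true", "walk_time_s", "severity",
              "lesion_target_mm3")
  missing <- setdiff(needed, names(state))
  if (length(missing)) {
    abort(paste0("subject state lacks fields: ", paste(missing, collapse = ", ")))
  }
  state
}

#' Simulate one subject's TMS/EMG session
#'
#' Emits `trials_per_block` traces for each of the four stimulation
#' configurations (stimulated hemisphere in lesioned/contralesional, recorded
#' leg in paretic/non-paretic) at each intensity of the grid. Each trace has
#' a tonic pre-stimulus baseline, a post-stimulus silent period, and a
#' Gaussian-envelope MEP burst whose within-window area equals
#' `true_slope * (intensity - 100)` times the deterministic pre-trigger area
#' (plus additive noise), so the downstream normalized response is linear in
#' intensity with slope equal to the true slope. At 100 %MT the burst area is
#' exactly zero.
#'
#' @param state One row of [generate_cohort()] output (or an equivalent list).
#' @param config The [gen_config()] used for the cohort.
#' @return A tibble of trials: `subject_id`, `hemisphere`, `leg`, `intensity`
#'   (%MT), `trial`, `sampling_rate`, `stimulus_index`, and a `samples` list
#'   column of amplitude vectors (mV).
#' @examples
#' cfg <- gen_config(n_subjects = 3, seed = 2)
#' st <- generate_cohort(cfg)[1, ]
#' session <- generate_emg_session(st, cfg)
#' nrow(session)  # 4 configurations x 6 intensities x 8 trials
#' @export
generate_emg_session <- function(state, config) {
  config <- validate_gen_config(config)
  state <- as_subject_state(state)
  geom <- trace_geometry(config)
  seed <- subject_seed(config$seed, state$subject_id, 1L)

  slopes <- list(
    lesioned.paretic = state$slope_lesioned_paretic,
    contralesional.paretic = state$slope_contralesional_paretic,
    lesioned.nonparetic = state$slope_lesioned_nonparetic,
    contralesional.nonparetic = state$slope_contralesional_nonparetic
  )
  combos <- tidyr::expand_grid(
    hemisphere = c("lesioned", "contralesional"),
    leg = c("paretic", "non-paretic"),
    intensity = config$intensity_grid
  )

  withr::with_seed(seed, {
    blocks <- purrr::pmap(combos, function(hemisphere, leg, intensity) {
      key <- paste(hemisphere, sub("-", "", leg), sep = ".")
      slope <- slopes[[key]]
      target <- slope * max(0, intensity - 100)
      amp <- target * geom$pre_area / geom$env_area
      det <- geom$baseline + amp * geom$envelope
      k <- config$trials_per_block
      noise <- matrix(rnorm(geom$n * k, 0, config$emg_noise_sd), geom$n, k)
      tibble(
        subject_id = state$subject_id,
        hemisphere = hemisphere, leg = leg, intensity = intensity,
        trial = seq_len(k),
        sampling_rate = config$sampling_rate,
        stimulus_index = geom$stimulus_index,
        samples = lapply(seq_len(k), function(j) det + noise[, j])
      )
    })
    dplyr::bind_rows(blocks)
  })
}

# deterministic trace skeleton shared by all trials of a session
trace_geometry <- function(config) {
  fs <- config$sampling_rate
  dt <- 1000 / fs
  t_min <- min(config$pre_trigger_window[1], 0) - 20
  t_max <- max(config$mep_window[2],
               config$burst_center_ms + 4 * config$burst_sd_ms) + 20
  n_pre <- ceiling(-t_min / dt)
  n_post <- ceiling(t_max / dt)
  stimulus_index <- n_pre + 1L
  n <- n_pre + n_post + 1L
  t_ms <- (seq_len(n) - stimulus_index) * dt

  baseline <- ifelse(t_ms < 0, config$tonic_level_mv, 0)
  envelope <- exp(-(t_ms - config$burst_center_ms)^2 /
                    (2 * config$burst_sd_ms^2))
  envelope[t_ms < 0] <- 0

  pre_idx <- window_indices(n, fs, stimulus_index, config$pre_trigger_window)
  mep_idx <- window_indices(n, fs, stimulus_index, config$mep_window)
  pre_area <- config$tonic_level_mv * (length(pre_idx) - 1L) * dt
  env_area <- trapz_area(envelope[mep_idx], dt)
  list(n = n, stimulus_index = stimulus_index, t_ms = t_ms,
       baseline = baseline, envelope = envelope,
       pre_area = pre_area, env_area = env_area)
}

#' Simulate one subject's FA phantom, ROI masks, lesion, and CST map
#'
#' Builds a shared voxel grid holding: an FA volume whose PLIC voxels carry
#' the subject's per-hemisphere true FA (the anterior-limb control ROI is
#' symmetric across hemispheres), a spherical lesion in the lesioned
#' hemisphere scaled by severity, and a corticospinal-tract probability map
#' descending through the lesioned PLIC (lateral Gaussian profile, maximum
#' 1). Per-voxel Gaussian noise (`fa_noise_sd`) is added last and clamped to
#' `[0, 1]`; ROI values are written after the lesion, so with zero noise the
#' ROI means equal the true FA exactly.
#'
#' @inheritParams generate_emg_session
#' @return An object of class `fcr_volumes`: list with `fa` (3D array),
#'   `masks` (logical arrays `plic_lesioned`, `plic_contralesional`,
#'   `alic_lesioned`, `alic_contralesional`, `lesion`), `cst` (probability
#'   array), `voxel_dims`, `subject_id`.
#' @examples
#' cfg <- gen_config(n_subjects = 3, seed = 2)
#' vols <- generate_fa_volume(generate_cohort(cfg)[1, ], cfg)
#' mean(vols$fa[vols$masks$plic_lesioned])
#' @export
generate_fa_volume <- function(state, config) {
  config <- validate_gen_config(config)
  state <- as_subject_state(state)
  shape <- config$volume_shape
  boxes <- roi_boxes(shape)
  seed <- subject_seed(config$seed, state$subject_id, 2L)

  withr::with_seed(seed, {
    fa <- array(0.30, dim = shape)

    # lesion: sphere matching the severity-scaled volume target, centred
    # just off the PLIC axis inside the lesioned hemisphere
    lesion <- array(FALSE, dim = shape)
    target_vox <- state$lesion_target_mm3 / prod(config$voxel_dims)
    if (target_vox >= 0.5) {
      r <- (3 * target_vox / (4 * pi))^(1 / 3)
      ctr <- c(boxes$cst_center[1] + 2, boxes$cst_center[2] + 3,
               round(shape[3] / 2)) + stats::runif(3, -1, 1)
      idx <- as.matrix(expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]),
                                   z = seq_len(shape[3])))
      d2 <- (idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2 + (idx[, 3] - ctr[3])^2
      inside <- d2 <= r^2 & idx[, 1] <= floor(shape[1] / 2)
      lesion[idx[inside, , drop = FALSE]] <- TRUE
      fa[lesion] <- 0.15
    }

    # ROI FA written after the lesion so ROI means stay exact
    fa[boxes$plic_lesioned] <- state$fa_lesioned_true
    fa[boxes$plic_contralesional] <- state$fa_intact_true
    fa[boxes$alic_lesioned] <- state$fa_intact_true
    fa[boxes$alic_contralesional] <- state$fa_intact_true

    if (config$fa_noise_sd > 0) {
      fa <- fa + array(rnorm(prod(shape), 0, config$fa_noise_sd), dim = shape)
    }
    fa <- clamp01(fa)

    # CST probability: lateral Gaussian around the PLIC axis, all slices,
    # lesioned hemisphere only; maximum exactly 1 on the axis
    cst <- array(0, dim = shape)
    xy <- expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]))
    d2 <- (xy$x - boxes$cst_center[1])^2 + (xy$y - boxes$cst_center[2])^2
    prof <- exp(-d2 / (2 * config$cst_sigma_vox^2))
    prof[xy$x > floor(shape[1] / 2)] <- 0
    slice <- matrix(prof, shape[1], shape[2])
    for (z in seq_len(shape[3])) cst[, , z] <- slice

    structure(
      list(fa = fa,
           masks = list(plic_lesioned = boxes$plic_lesioned,
                        plic_contralesional = boxes$plic_contralesional,
                        alic_lesioned = boxes$alic_lesioned,
                        alic_contralesional = boxes$alic_contralesional,
                        lesion = lesion),
           cst = cst,
           voxel_dims = config$voxel_dims,
           subject_id = state$subject_id),
      class = "fcr_volumes"
    )
  })
}

# PLIC/ALIC boxes placed proportionally on the grid; refuses grids where the
# rounded boxes collide or fall outside the volume
roi_boxes <- function(shape) {
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  x_les <- seq(max(1L, round(0.18 * nx)), round(0.30 * nx))
  x_con <- nx + 1L - rev(x_les)
  y_plic <- seq(round(0.45 * ny), round(0.58 * ny))
  y_alic <- seq(round(0.70 * ny), round(0.85 * ny))
  z_roi <- seq(max(1L, round(0.25 * nz)), round(0.75 * nz))

  ok <- length(x_les) >= 2 && length(y_plic) >= 2 && length(y_alic) >= 2 &&
    length(z_roi) >= 1 && max(x_con) <= nx && max(y_alic) <= ny &&
    max(z_roi) <= nz && max(x_les) < min(x_con) && max(y_plic) < min(y_alic)
  if (!ok) {
    abort(paste0("volume_shape (", paste(shape, collapse = "x"),
                 ") cannot hold the PLIC/ALIC ROIs disjointly"))
  }
  box <- function(xr, yr, zr) {
    m <- array(FALSE, dim = shape)
    m[xr, yr, zr] <- TRUE
    m
  }
  masks <- list(
    plic_lesioned = box(x_les, y_plic, z_roi),
    plic_contralesional = box(x_con, y_plic, z_roi),
    alic_lesioned = box(x_les, y_alic, z_roi),
    alic_contralesional = box(x_con, y_alic, z_roi)
  )
  pairs <- utils::combn(names(masks), 2, simplify = FALSE)
  for (p in pairs) {
    if (any(masks[[p[1]]] & masks[[p[2]]])) {
      abort(paste0("overlapping ROI definitions: ", p[1], " and ", p[2]))
    }
  }
  c(masks, list(cst_center = c(mean(x_les), mean(y_plic))))
}

#' Behavioral scores for one synthetic subject
#'
#' Converts the latent walk time into walking speed
#' (`10 m / walk_time * 60`, m/min) and clips the Fugl-Meyer lower-limb
#' score to its 0--34 scale.
#'
#' @inheritParams generate_emg_session
#' @return A one-row tibble: `subject_id`, `fm`, `walking_speed`.
#' @examples
#' cfg <- gen_config(n_subjects = 3, seed = 2)
#' generate_behavior(generate_cohort(cfg)[1, ])
#' @export
generate_behavior <- function(state, config = NULL) {
  state <- as_subject_state(state)
  if (!is.finite(state$walk_time_s) || state$walk_time_s <= 0) {
    abort("walk time must be > 0 seconds")
  }
  tibble(
    subject_id = state$subject_id,
    fm = as.integer(pmin(34, pmax(0, round(state$fm_true)))),
    walking_speed = 10 / state$walk_time_s * 60
  )
}

#' Write / read an EMG session in the columnar interchange format
#'
#' The on-disk form is two CSVs: `<prefix>_signals.csv` with columns
#' `trial_id`, `time_s`, `amplitude_mV`, and `<prefix>_trials.csv` with the
#' per-trial metadata (`trial_id`, `subject_id`, `hemisphere`, `leg`,
#' `intensity`, `trial`, `sampling_rate`, `stimulus_index`).
#'
#' @param session A trial tibble as produced by [generate_emg_session()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return `write_emg_session()` returns the two paths invisibly;
#'   `read_emg_session()` returns the reconstructed trial tibble.
#' @export
write_emg_session <- function(session, dir, prefix = "emg") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- session %>%
    mutate(trial_id = dplyr::row_number()) %>%
    select(-"samples")
  signals <- purrr::map2(seq_len(nrow(session)), session$samples,
                         function(id, s) {
                           t0 <- (seq_along(s) - session$stimulus_index[id]) /
                             session$sampling_rate[id]
                           tibble(trial_id = id, time_s = t0, amplitude_mV = s)
                         }) %>%
    bind_rows()
  sig_path <- file.path(dir, paste0(prefix, "_signals.csv"))
  meta_path <- file.path(dir, paste0(prefix, "_trials.csv"))
  readr::write_csv(signals, sig_path)
  readr::write_csv(meta, meta_path)
  invisible(c(signals = sig_path, trials = meta_path))
}

#' @rdname write_emg_session
#' @export
read_emg_session <- function(dir, prefix = "emg") {
  sig <- readr::read_csv(file.path(dir, paste0(prefix, "_signals.csv")),
                         show_col_types = FALSE)
  meta <- readr::read_csv(file.path(dir, paste0(prefix, "_trials.csv")),
                          show_col_types = FALSE)
  samples <- split(sig$amplitude_mV, sig$trial_id)
  meta %>%
    arrange(.data$trial_id) %>%
    mutate(samples = unname(samples[as.character(.data$trial_id)])) %>%
    select(-"trial_id")
}
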