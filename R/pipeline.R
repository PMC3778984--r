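#' Process one subject's raw inputs into a cohort-table record
#'
#' Runs the full subject-level pipeline: EMG trials -> block-mean curve
#' points -> recruitment fits -> per-leg FCR; FA volumes -> PLIC/ALIC
#' asymmetry, lesion volume, lesion--CST overlap; behavior joined as-is.
#' Errors in any stage are re-raised with the subject id and stage name.
#'
#' @param emg_session Trial tibble ([generate_emg_session()] or
#'   [read_emg_session()]).
#' @param volumes `fcr_volumes` list ([generate_fa_volume()]).
#' @param behavior One-row tibble with `subject_id`, `fm`, `walking_speed`.
#' @param mep_window,pre_window ms analysis windows relative to the stimulus.
#' @param prob_threshold CST threshold forwarded to [lesion_cst_overlap()].
#' @return One-row tibble: ids, behavior, `fa_asymmetry_plic`,
#'   `fa_asymmetry_alic`, `fcr_paretic`, `fcr_nonparetic`, the four measured
#'   slopes, `lesion_volume`, `lesion_overlap`, `n_flagged_fits`.
#' @export
run_subject <- function(emg_session, volumes, behavior,
                        mep_window = c(20, 60), pre_window = c(-110, -10),
                        prob_threshold = 0.1) {
  sid <- behavior$subject_id[1] %||% NA_integer_
  with_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("subject ", sid, ", stage ", stage, ": ",
                   conditionMessage(e)))
    })
  }
  ids <- unique(c(sid, unique(emg_session$subject_id),
                  volumes$subject_id %||% sid))
  if (length(ids[!is.na(ids)]) > 1L) {
    abort(paste0("inconsistent subject ids across inputs: ",
                 paste(ids, collapse = ", ")))
  }

  points <- with_stage("emg", block_points(emg_session, mep_window, pre_window))
  fcr <- with_stage("recruitment", subject_fcr(points))
  roi <- with_stage("roi", roi_stats(volumes, prob_threshold))

  par <- fcr %>% filter(.data$leg == "paretic")
  np <- fcr %>% filter(.data$leg == "non-paretic")
  fits <- attr(fcr, "fits")
  tibble(
    subject_id = sid,
    fm = behavior$fm[1],
    walking_speed = behavior$walking_speed[1],
    fa_asymmetry_plic = roi$fa_asymmetry_plic,
    fa_asymmetry_alic = roi$fa_asymmetry_alic,
    fcr_paretic = par$fcr,
    fcr_nonparetic = np$fcr,
    slope_lesioned_paretic = par$slope_contralateral,
    slope_contralesional_paretic = par$slope_ipsilateral,
    slope_lesioned_nonparetic = np$slope_ipsilateral,
    slope_contralesional_nonparetic = np$slope_contralateral,
    lesion_volume = roi$lesion_volume,
    lesion_overlap = roi$lesion_overlap,
    n_flagged_fits = sum(purrr::map_lgl(fits, "flagged"))
  )
}

#' Simulate and process a whole synthetic cohort
#'
#' Generates the latent cohort, emits each subject's EMG session, FA
#' volumes, and behavior, runs [run_subject()] on each, and runs the
#' statistical battery on the assembled table. Fully deterministic for a
#' given configuration (including its seed).
#'
#' @param config A [gen_config()] object.
#' @param report Run [cohort_report()] on the table (default TRUE).
#' @return List of class `fcr_cohort`: `truth` (latent states), `table`
#'   (one record per subject), `report` (see [cohort_report()], or NULL).
#' @examples
#' \donttest{
#' coh <- run_cohort(gen_config(n_subjects = 6, seed = 3))
#' coh$table$fcr_paretic
#' }
#' @export
run_cohort <- function(config, report = TRUE) {
  config <- validate_gen_config(config)
  truth <- generate_cohort(config)
  records <- purrr::map(seq_len(nrow(truth)), function(i) {
    st <- truth[i, ]
    run_subject(
      generate_emg_session(st, config),
      generate_fa_volume(st, config),
      generate_behavior(st),
      mep_window = config$mep_window,
      pre_window = config$pre_trigger_window
    )
  })
  table <- bind_rows(records)
  structure(
    list(truth = truth, table = table,
         report = if (report) cohort_report(table) else NULL,
         config = config),
    class = "fcr_cohort"
  )
}

#' @export
print.fcr_cohort <- function(x, ...) {
  cat("<fcr_cohort> n =", nrow(x$table), "subjects\n")
  cat(sprintf("  mean paretic FCR %.3f, non-paretic %.3f\n",
              mean(x$table$fcr_paretic), mean(x$table$fcr_nonparetic)))
  cat(sprintf("  flagged fits: %d\n", sum(x$table$n_flagged_fits)))
  if (!is.null(x$report)) cat("  report: run print(x$report)\n")
  invisible(x)
}

battery_pairs <- function(table) {
  all_pairs <- tibble::tribble(
    ~var1, ~var2,
    "fcr_paretic", "walking_speed",
    "fcr_paretic", "fm",
    "fcr_nonparetic", "walking_speed",
    "fcr_nonparetic", "fm",
    "fa_asymmetry_plic", "fcr_paretic",
    "fa_asymmetry_plic", "fcr_nonparetic",
    "fa_asymmetry_plic", "fm",
    "fa_asymmetry_plic", "walking_speed",
    "fa_asymmetry_alic", "fcr_paretic",
    "lesion_volume", "fm",
    "lesion_volume", "walking_speed",
    "lesion_volume", "fcr_paretic",
    "lesion_overlap", "fm",
    "lesion_overlap", "walking_speed",
    "lesion_overlap", "fcr_paretic"
  )
  all_pairs %>%
    filter(.data$var1 %in% names(table), .data$var2 %in% names(table))
}

#' Cohort statistical battery
#'
#' Runs the full report on a Table-1-shaped cohort table: Spearman rank
#' correlations over the measure battery (with capped multiplicity
#' correction across the battery), group descriptives, the paired t of
#' paretic vs non-paretic FCR, the 2x2 within-subject ANOVA of recruitment
#' slopes (leg x side of stimulation), and the forward stepwise regression
#' of Fugl-Meyer score on the candidate markers. Components whose columns
#' are absent (e.g. slopes, when starting from a published table) are
#' skipped; degenerate inputs (constant columns) are reported per-row as
#' `NA` with a note instead of failing the whole report.
#'
#' @param table Cohort tibble; recognised columns include `fm`,
#'   `walking_speed`, `fa_asymmetry_plic`, `fa_asymmetry_alic`,
#'   `fcr_paretic`, `fcr_nonparetic`, `lesion_volume`, `lesion_overlap`, and
#'   the four `slope_*` columns.
#' @param family_size Multiplicity family for the correlation battery;
#'   defaults to the number of correlations computed.
#' @return List of class `fcr_report`: `correlations`, `descriptives`,
#'   `paired_t`, `anova`, `stepwise`, `n_flagged_fits`.
#' @export
cohort_report <- function(table, family_size = NULL) {
  stopifnot(is.data.frame(table))
  if (nrow(table) < 3L) abort("cohort report needs >= 3 subjects")
  pairs <- battery_pairs(table)
  fam <- family_size %||% nrow(pairs)

  correlations <- purrr::pmap(pairs, function(var1, var2) {
    res <- tryCatch(
      spearman_test(table[[var1]], table[[var2]], family_size = fam),
      error = function(e) {
        tibble(statistic_name = "rho", value = NA_real_, df1 = NA_real_,
               df2 = NA_real_, p_raw = NA_real_, p_corrected = NA_real_,
               n = nrow(table))
      }
    )
    note <- if (is.na(res$value)) "undefined (constant input)" else ""
    res %>% mutate(var1 = var1, var2 = var2, note = note, .before = 1)
  }) %>% bind_rows()

  desc_vars <- intersect(c("fcr_paretic", "fcr_nonparetic", "fm",
                           "walking_speed", "fa_asymmetry_plic",
                           "lesion_volume", "lesion_overlap"), names(table))
  descriptives <- purrr::map(desc_vars, function(v) {
    tibble(variable = v, mean = mean(table[[v]]), min = min(table[[v]]),
           max = max(table[[v]]))
  }) %>% bind_rows()

  paired_t <- NULL
  if (all(c("fcr_paretic", "fcr_nonparetic") %in% names(table))) {
    paired_t <- tryCatch(
      paired_t_test(table$fcr_paretic, table$fcr_nonparetic),
      error = function(e) NULL
    )
  }

  anova <- NULL
  slope_cols <- c("slope_lesioned_paretic", "slope_contralesional_paretic",
                  "slope_lesioned_nonparetic", "slope_contralesional_nonparetic")
  if (all(slope_cols %in% names(table))) {
    long <- table %>%
      select(all_of(c("subject_id", slope_cols))) %>%
      tidyr::pivot_longer(all_of(slope_cols), names_to = "key",
                          values_to = "value") %>%
      mutate(
        leg = ifelse(grepl("nonparetic", .data$key), "non-paretic", "paretic"),
        # side of stimulation relative to the recorded leg
        side = ifelse(
          (grepl("contralesional", .data$key) & .data$leg == "paretic") |
            (!grepl("contralesional", .data$key) & .data$leg == "non-paretic"),
          "ipsilateral", "contralateral"),
        subject = .data$subject_id
      )
    anova <- tryCatch(rm_anova_2x2(long), error = function(e) NULL)
  }

  stepwise <- NULL
  cand <- intersect(c("fcr_paretic", "fa_asymmetry_plic", "lesion_volume",
                      "lesion_overlap"), names(table))
  if ("fm" %in% names(table) && length(cand) >= 1L &&
      nrow(table) > length(cand) + 1L) {
    stepwise <- tryCatch(
      stepwise_regression(table, "fm", candidates = cand),
      error = function(e) NULL
    )
  }

  structure(
    list(correlations = correlations, descriptives = descriptives,
         paired_t = paired_t, anova = anova, stepwise = stepwise,
         family_size = fam,
         n_flagged_fits = if ("n_flagged_fits" %in% names(table))
           sum(table$n_flagged_fits) else NA_integer_),
    class = "fcr_report"
  )
}

#' @export
print.fcr_report <- function(x, ...) {
  cat("<fcr_report>\n")
  cat("Correlations (Spearman, corrected over family of", x$family_size, "):\n")
  print(as.data.frame(
    x$correlations %>%
      mutate(rho = round(.data$value, 2)) %>%
      select("var1", "var2", "rho", "p_raw", "p_corrected", "note")
  ), row.names = FALSE, digits = 3)
  cat("\nDescriptives:\n")
  print(as.data.frame(x$descriptives), row.names = FALSE, digits = 4)
  if (!is.null(x$paired_t)) {
    cat(sprintf("\nPaired t (paretic vs non-paretic FCR): t = %.2f, df = %d, p = %.3g\n",
                x$paired_t$value, x$paired_t$df1, x$paired_t$p_raw))
  }
  if (!is.null(x$anova)) {
    cat(sprintf("2x2 RM-ANOVA interaction: F(%d, %d) = %.2f, p = %.3g\n",
                x$anova$df1, x$anova$df2, x$anova$value, x$anova$p_raw))
  }
  if (!is.null(x$stepwise)) {
    cat("Stepwise (FM ~ markers): ",
        if (length(x$stepwise$terms)) paste(x$stepwise$terms, collapse = " -> ")
        else "empty model", "\n")
  }
  if (!is.na(x$n_flagged_fits)) {
    cat("Flagged recruitment fits:", x$n_flagged_fits, "\n")
  }
  invisible(x)
}

#' Write a cohort report to disk
#'
#' Emits the machine-readable correlation table as CSV and a human-readable
#' text report; both are written atomically (temp file + rename).
#'
#' @param report An `fcr_report`.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Named vector of paths, invisibly.
#' @export
write_report <- function(report, dir, prefix = "cohort") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv_path <- file.path(dir, paste0(prefix, "_correlations.csv"))
  txt_path <- file.path(dir, paste0(prefix, "_report.txt"))
  atomically <- function(path, writer) {
    tmp <- paste0(path, ".tmp")
    writer(tmp)
    file.rename(tmp, path)
  }
  atomically(csv_path, function(p) readr::write_csv(report$correlations, p))
  atomically(txt_path, function(p) {
    con <- file(p, open = "wt")
    on.exit(close(con))
    sink(con); on.exit(sink(), add = TRUE, after = FALSE)
    print(report)
  })
  invisible(c(correlations = csv_path, report = txt_path))
}
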