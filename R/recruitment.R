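#' Fit a linear recruitment curve
#'
#' Ordinary least squares of block-mean normalized MEP response on
#' stimulation intensity (%MT). Fit quality is summarised by the Pearson
#' correlation between intensity and response (`fit_r`); fits with
#' `fit_r <= 0.85` (or undefined, e.g. constant responses) are retained but
#' flagged, so cohort reports can count questionable curves without dropping
#' subjects.
#'
#' @param points Curve-point tibble with `intensity` and `response` columns
#'   (e.g. from [block_points()]); optional `leg` / `hemisphere` columns (one
#'   unique value each) are carried along.
#' @param r_flag Flag threshold on `fit_r` (default 0.85).
#' @return An object of class `recruitment_fit`: slope, intercept, `fit_r`,
#'   `n_points`, `flagged`, plus `leg`/`hemisphere` labels and the points.
#' @examples
#' pts <- tibble::tibble(intensity = c(100, 110, 120), response = c(0, 1, 2))
#' fit <- fit_recruitment(pts)
#' fit$slope     # 0.1 response per %MT
#' tidy(fit)
#' @export
fit_recruitment <- function(points, r_flag = 0.85) {
  stopifnot(is.data.frame(points))
  if (!all(c("intensity", "response") %in% names(points))) {
    abort("`points` needs `intensity` and `response` columns")
  }
  if (nrow(points) < 3L) {
    abort("a recruitment fit needs >= 3 points (fit quality r needs 3)")
  }
  if (length(unique(points$intensity)) < 2L) {
    abort("all intensities identical: slope undefined")
  }
  fit <- lm(response ~ intensity, data = points)
  fit_r <- suppressWarnings(cor(points$intensity, points$response))
  one_of <- function(col) {
    if (col %in% names(points) && length(unique(points[[col]])) == 1L) {
      points[[col]][1]
    } else {
      NA_character_
    }
  }
  structure(
    list(slope = unname(coef(fit)[2]),
         intercept = unname(coef(fit)[1]),
         fit_r = fit_r,
         n_points = nrow(points),
         flagged = is.na(fit_r) || fit_r <= r_flag,
         leg = one_of("leg"),
         hemisphere = one_of("hemisphere"),
         points = as_tibble(points[, intersect(c("intensity", "response", "n_trials"),
                                               names(points))])),
    class = "recruitment_fit"
  )
}

#' @export
print.recruitment_fit <- function(x, ...) {
  cat("<recruitment_fit>",
      if (!is.na(x$leg)) paste0(" leg=", x$leg),
      if (!is.na(x$hemisphere)) paste0(" stim=", x$hemisphere), "\n", sep = "")
  cat(sprintf("  slope %.5g /%%MT, intercept %.5g, fit r %.3f over %d points%s\n",
              x$slope, x$intercept, x$fit_r, x$n_points,
              if (x$flagged) " [FLAGGED]" else ""))
  invisible(x)
}

#' @rdname fit_recruitment
#' @param x A `recruitment_fit`.
#' @param ... Unused.
#' @method tidy recruitment_fit
#' @export
tidy.recruitment_fit <- function(x, ...) {
  tibble(term = c("intercept", "intensity"),
         estimate = c(x$intercept, x$slope))
}

#' @rdname fit_recruitment
#' @method glance recruitment_fit
#' @export
glance.recruitment_fit <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, fit_r = x$fit_r,
         n_points = x$n_points, flagged = x$flagged,
         leg = x$leg, hemisphere = x$hemisphere)
}

#' @rdname fit_recruitment
#' @param object A `recruitment_fit`.
#' @method autoplot recruitment_fit
#' @export
autoplot.recruitment_fit <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$intensity, y = .data$response)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         linetype = 2) +
    ggplot2::labs(
      x = "Stimulation intensity (%MT)", y = "Normalized MEP response",
      title = sprintf("Recruitment curve (slope %.3g, r = %.2f)%s",
                      object$slope, object$fit_r,
                      if (object$flagged) " [flagged]" else "")
    )
}

#' Functional connectivity ratio of two recruitment fits
#'
#' `FCR = slope(ipsilateral curve) / slope(contralateral curve)` for one leg.
#' Values above 1 are read as predominantly ipsilateral corticospinal
#' control, below 1 as predominantly contralateral; exactly 1 is labelled
#' balanced (no tolerance band).
#'
#' @param fit_ipsi,fit_contra `recruitment_fit` objects for the same leg
#'   (ipsilateral / contralateral stimulated hemisphere).
#' @return One-row tibble: `leg`, `fcr`, `slope_ipsilateral`,
#'   `slope_contralateral`, `laterality`, `flagged` (either input flagged).
#' @examples
#' f1 <- fit_recruitment(tibble::tibble(intensity = c(100, 110, 120),
#'                                      response = c(0, 2, 4)))
#' f2 <- fit_recruitment(tibble::tibble(intensity = c(100, 110, 120),
#'                                      response = c(0, 1, 2)))
#' compute_fcr(f1, f2)$fcr  # 2: ipsilateral-predominant
#' @export
compute_fcr <- function(fit_ipsi, fit_contra) {
  stopifnot(inherits(fit_ipsi, "recruitment_fit"),
            inherits(fit_contra, "recruitment_fit"))
  if (!is.na(fit_ipsi$leg) && !is.na(fit_contra$leg) &&
      fit_ipsi$leg != fit_contra$leg) {
    abort(paste0("fits are for different legs: ", fit_ipsi$leg, " vs ",
                 fit_contra$leg))
  }
  if (fit_contra$slope <= 0) {
    abort(paste0("contralateral slope is ", signif(fit_contra$slope, 4),
                 " (<= 0): FCR undefined"))
  }
  if (fit_ipsi$slope < 0) {
    abort(paste0("ipsilateral slope is negative (",
                 signif(fit_ipsi$slope, 4), "): FCR undefined"))
  }
  fcr <- fit_ipsi$slope / fit_contra$slope
  tibble(
    leg = fit_ipsi$leg,
    fcr = fcr,
    slope_ipsilateral = fit_ipsi$slope,
    slope_contralateral = fit_contra$slope,
    laterality = if (fcr > 1) "ipsilateral-predominant"
                 else if (fcr < 1) "contralateral-predominant"
                 else "balanced",
    flagged = fit_ipsi$flagged || fit_contra$flagged
  )
}

#' Reciprocity self-check for an FCR pair
#'
#' Computes the ratio both ways; the product must equal 1 to numerical
#' precision whenever both slopes are positive.
#'
#' @param fit_a,fit_b `recruitment_fit` objects.
#' @return Tibble with the two ratios and their product.
#' @export
fcr_swap_check <- function(fit_a, fit_b) {
  ab <- compute_fcr(fit_a, fit_b)$fcr
  ba <- compute_fcr(fit_b, fit_a)$fcr
  tibble(direction = c("a_over_b", "b_over_a"), fcr = c(ab, ba),
         product = ab * ba)
}

#' Per-leg FCRs for one subject's curve points
#'
#' Fits the four recruitment curves (stimulated hemisphere x leg) and forms
#' the per-leg FCR. For the paretic leg (contralateral to the lesion) the
#' ipsilateral hemisphere is the contralesional one; for the non-paretic leg
#' it is the lesioned one.
#'
#' @param points Curve points for one subject with `hemisphere`, `leg`,
#'   `intensity`, `response` columns.
#' @param r_flag Flag threshold forwarded to [fit_recruitment()].
#' @return Tibble with one row per leg: `leg`, `fcr`, `slope_ipsilateral`,
#'   `slope_contralateral`, `laterality`, `flagged`, `fit_r_ipsilateral`,
#'   `fit_r_contralateral`. The four fits are attached as attribute `fits`.
#' @export
subject_fcr <- function(points, r_flag = 0.85) {
  stopifnot(is.data.frame(points))
  needed <- c("hemisphere", "leg", "intensity", "response")
  if (!all(needed %in% names(points))) {
    abort(paste0("`points` needs columns: ", paste(needed, collapse = ", ")))
  }
  combos <- tidyr::expand_grid(hemisphere = c("lesioned", "contralesional"),
                               leg = c("paretic", "non-paretic"))
  fits <- pmap(combos, function(hemisphere, leg) {
    sub <- points %>% filter(.data$hemisphere == !!hemisphere,
                             .data$leg == !!leg)
    if (nrow(sub) == 0L) {
      abort(paste0("missing EMG configuration: stimulated hemisphere '",
                   hemisphere, "' x leg '", leg, "'"))
    }
    fit_recruitment(sub, r_flag = r_flag)
  })
  names(fits) <- paste(combos$hemisphere, combos$leg, sep = ".")

  per_leg <- function(leg) {
    ipsi_hem <- if (leg == "paretic") "contralesional" else "lesioned"
    contra_hem <- if (leg == "paretic") "lesioned" else "contralesional"
    fi <- fits[[paste(ipsi_hem, leg, sep = ".")]]
    fc <- fits[[paste(contra_hem, leg, sep = ".")]]
    compute_fcr(fi, fc) %>%
      mutate(fit_r_ipsilateral = fi$fit_r, fit_r_contralateral = fc$fit_r)
  }
  out <- bind_rows(per_leg("paretic"), per_leg("non-paretic"))
  attr(out, "fits") <- fits
  out
}
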