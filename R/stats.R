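#' Spearman rank correlation with average ranks for ties
#'
#' Rho is the Pearson correlation of the average-rank vectors, computed from
#' the covariance formula (not a wrapper around `cor()`). The two-tailed p
#' value uses the t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))`
#' with `n - 2` degrees of freedom, adequate at the cohort sizes this
#' package targets; `|rho| = 1` yields p = 0.
#'
#' @param x,y Equal-length finite numeric vectors, `n >= 3`.
#' @param family_size Multiplicity family for [correct_p()] (default 1: no
#'   correction).
#' @return One-row tibble: `statistic_name` ("rho"), `value`, `df1`, `df2`
#'   (`NA`), `p_raw`, `p_corrected`, `n`.
#' @examples
#' spearman_test(1:10, (1:10)^3)$value  # 1: monotone invariance
#' @export
spearman_test <- function(x, y, family_size = 1L) {
  check_xy(x, y, min_n = 3L)
  if (var(x) == 0 || var(y) == 0) {
    abort("rho undefined: constant input vector")
  }
  rx <- rank(x)  # average ranks for ties
  ry <- rank(y)
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  n <- length(x)
  p <- if (abs(rho) >= 1) 0 else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tval), df = n - 2)
  }
  stat_row("rho", rho, df1 = n - 2, df2 = NA_real_, p_raw = p,
           family_size = family_size, n = n)
}

check_xy <- function(x, y, min_n) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  if (length(x) < min_n) abort(paste0("need at least ", min_n, " pairs"))
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    abort("inputs must be finite")
  }
  invisible(TRUE)
}

stat_row <- function(name, value, df1, df2, p_raw, family_size, n) {
  tibble(statistic_name = name, value = value, df1 = df1, df2 = df2,
         p_raw = p_raw, p_corrected = correct_p(p_raw, family_size), n = n)
}

#' Two-tailed paired t test
#'
#' Classical paired t on the differences, `df = n - 1`, computed from the
#' textbook formula.
#'
#' @inheritParams spearman_test
#' @return One-row tibble in the same layout as [spearman_test()], with
#'   `statistic_name = "t"`.
#' @export
paired_t_test <- function(x, y, family_size = 1L) {
  check_xy(x, y, min_n = 2L)
  d <- x - y
  if (sd(d) == 0) {
    abort("paired t undefined: zero-variance differences")
  }
  n <- length(d)
  tval <- mean(d) / (sd(d) / sqrt(n))
  p <- 2 * pt(-abs(tval), df = n - 1)
  stat_row("t", tval, df1 = n - 1, df2 = NA_real_, p_raw = p,
           family_size = family_size, n = n)
}

#' Interaction F of a 2x2 within-subject ANOVA
#'
#' Repeated-measures ANOVA with two within-subject two-level factors,
#' computed by the direct sums-of-squares decomposition. Only the
#' interaction effect is returned (df 1, n - 1); for this design it equals
#' the square of the paired t on each subject's difference of differences.
#' When both the interaction and its error sum of squares vanish (all cells
#' equal within subjects) the F is reported as 0.
#'
#' @param data Long tibble with columns `subject`, and the two factor
#'   columns named by `factor_a` / `factor_b` (two levels each), and `value`.
#' @param factor_a,factor_b Names of the factor columns (default `leg`,
#'   `side`).
#' @param family_size Multiplicity family for [correct_p()].
#' @return One-row tibble in the [spearman_test()] layout,
#'   `statistic_name = "F"`, `df1 = 1`, `df2 = n - 1`.
#' @export
rm_anova_2x2 <- function(data, factor_a = "leg", factor_b = "side",
                         family_size = 1L) {
  stopifnot(is.data.frame(data))
  needed <- c("subject", factor_a, factor_b, "value")
  if (!all(needed %in% names(data))) {
    abort(paste0("`data` needs columns: ", paste(needed, collapse = ", ")))
  }
  a <- factor(data[[factor_a]]); b <- factor(data[[factor_b]])
  s <- factor(data$subject)
  if (nlevels(a) != 2L || nlevels(b) != 2L) {
    abort("both factors must have exactly 2 levels")
  }
  counts <- table(s, a, b)
  if (any(counts != 1L)) {
    abort("each subject needs exactly one observation per cell (missing or duplicated cell)")
  }
  n <- nlevels(s)
  if (n < 2L) abort("need >= 2 subjects")
  y <- data$value

  m <- mean(y)
  m_ab <- tapply(y, list(a, b), mean)            # cell means
  m_a <- tapply(y, a, mean); m_b <- tapply(y, b, mean)
  m_s <- tapply(y, s, mean)
  m_sa <- tapply(y, list(s, a), mean); m_sb <- tapply(y, list(s, b), mean)

  ss_int <- n * sum((m_ab - outer(m_a, rep(1, 2)) -
                       outer(rep(1, 2), m_b) + m)^2)
  resid <- y - m_sa[cbind(s, a)] - m_sb[cbind(s, b)] - m_ab[cbind(a, b)] +
    m_s[s] + m_a[a] + m_b[b] - m
  ss_err <- sum(resid^2)

  fval <- if (ss_err <= .Machine$double.eps^0.75 * max(1, sum(y^2))) {
    if (ss_int <= .Machine$double.eps^0.75 * max(1, sum(y^2))) 0 else Inf
  } else {
    (ss_int / 1) / (ss_err / (n - 1))
  }
  p <- if (is.infinite(fval)) 0 else pf(fval, 1, n - 1, lower.tail = FALSE)
  stat_row("F", fval, df1 = 1, df2 = n - 1, p_raw = p,
           family_size = family_size, n = n)
}

#' Multiplicity correction with capping at 1
#'
#' Bonferroni-style multiplicative correction: `min(1, p * family_size)`.
#' Any corrected value that would exceed 1 is represented as 1.
#'
#' @param p_raw Raw p value(s) in `[0, 1]`.
#' @param family_size Number of comparisons in the family (>= 1).
#' @return Corrected p value(s), never above 1, never below `p_raw`.
#' @examples
#' correct_p(0.02, 3)  # 0.06
#' correct_p(0.5, 4)   # capped at 1
#' @export
correct_p <- function(p_raw, family_size) {
  if (any(p_raw < 0 | p_raw > 1, na.rm = TRUE)) {
    abort("`p_raw` must lie in [0, 1]")
  }
  if (any(family_size < 1)) abort("`family_size` must be >= 1")
  pmin(1, p_raw * family_size)
}

#' Forward stepwise linear regression on partial-F p values
#'
#' Forward selection: at each step the candidate with the smallest
#' partial-F p value enters if that p is below `alpha_enter`; after each
#' entry, any included term whose drop-one partial-F p exceeds
#' `alpha_remove` is removed. Candidates that are aliased (collinear) with
#' the current model are dropped with a warning.
#'
#' @param data Data frame holding outcome and candidate columns.
#' @param outcome Name of the outcome column.
#' @param candidates Character vector of candidate predictor columns
#'   (default: every other column).
#' @param alpha_enter,alpha_remove Entry / removal thresholds on the
#'   partial-F p value (defaults 0.05 / 0.10).
#' @return Object of class `stepwise_fit`: `steps` (tibble of actions with
#'   p values and cumulative R^2), `terms` (final predictors, entry order),
#'   `model` (the final `lm`, intercept-only if nothing entered).
#' @examples
#' d <- tibble::tibble(y = rnorm(30)); d$x <- d$y + rnorm(30, sd = 0.1)
#' sw <- stepwise_regression(d, "y")
#' sw$terms
#' @export
stepwise_regression <- function(data, outcome, candidates = NULL,
                                alpha_enter = 0.05, alpha_remove = 0.10) {
  stopifnot(is.data.frame(data))
  if (!outcome %in% names(data)) abort("`outcome` column not found")
  if (is.null(candidates)) candidates <- setdiff(names(data), outcome)
  if (length(candidates) == 0L) abort("no candidate predictors")
  data <- as.data.frame(data)[, c(outcome, candidates)]
  if (nrow(data) <= length(candidates) + 1L) {
    abort("need n > number of candidate predictors + 1")
  }

  fit_of <- function(terms) {
    rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
    lm(stats::as.formula(paste(outcome, "~", rhs)), data = data)
  }
  partial_p <- function(small, big) {
    tab <- anova(small, big)
    tab$`Pr(>F)`[2]
  }

  included <- character(0)
  pool <- candidates
  steps <- list()
  current <- fit_of(included)

  repeat {
    if (length(pool) == 0L) break
    trial <- purrr::map_dbl(pool, function(cand) {
      big <- fit_of(c(included, cand))
      if (anyNA(coef(big))) return(NA_real_)  # aliased
      partial_p(current, big)
    })
    if (any(is.na(trial))) {
      dropped <- pool[is.na(trial)]
      warn(paste0("dropping aliased candidate(s): ",
                  paste(dropped, collapse = ", ")))
      pool <- pool[!is.na(trial)]
      trial <- trial[!is.na(trial)]
      if (length(pool) == 0L) break
    }
    best <- which.min(trial)
    if (trial[best] >= alpha_enter) break
    included <- c(included, pool[best])
    current <- fit_of(included)
    steps[[length(steps) + 1L]] <- tibble(
      step = length(steps) + 1L, action = "enter", term = pool[best],
      p_partial = trial[best], r.squared = summary(current)$r.squared
    )
    pool <- pool[-best]

    # backward sweep at the removal threshold
    repeat {
      if (length(included) < 2L) break
      drop_p <- purrr::map_dbl(included, function(tm) {
        partial_p(fit_of(setdiff(included, tm)), current)
      })
      worst <- which.max(drop_p)
      if (drop_p[worst] <= alpha_remove) break
      removed <- included[worst]
      included <- included[-worst]
      current <- fit_of(included)
      pool <- c(pool, removed)
      steps[[length(steps) + 1L]] <- tibble(
        step = length(steps) + 1L, action = "remove", term = removed,
        p_partial = drop_p[worst], r.squared = summary(current)$r.squared
      )
    }
  }

  structure(
    list(steps = if (length(steps)) bind_rows(steps) else
           tibble(step = integer(), action = character(), term = character(),
                  p_partial = double(), r.squared = double()),
         terms = included,
         model = current,
         outcome = outcome),
    class = "stepwise_fit"
  )
}

#' @export
print.stepwise_fit <- function(x, ...) {
  cat("<stepwise_fit> outcome:", x$outcome, "\n")
  if (length(x$terms) == 0L) {
    cat("  empty model (no candidate met the entry criterion)\n")
  } else {
    cat("  entered:", paste(x$terms, collapse = " -> "), "\n")
    cat(sprintf("  final R^2 = %.3f\n", summary(x$model)$r.squared))
  }
  invisible(x)
}

#' @rdname stepwise_regression
#' @param x,object A `stepwise_fit`.
#' @param ... Unused.
#' @method tidy stepwise_fit
#' @export
tidy.stepwise_fit <- function(x, ...) {
  cf <- summary(x$model)$coefficients
  tibble(term = rownames(cf), estimate = cf[, 1], std.error = cf[, 2],
         statistic = cf[, 3], p.value = cf[, 4])
}

#' @rdname stepwise_regression
#' @method glance stepwise_fit
#' @export
glance.stepwise_fit <- function(x, ...) {
  s <- summary(x$model)
  tibble(r.squared = s$r.squared, adj.r.squared = s$adj.r.squared,
         n_terms = length(x$terms), n_steps = nrow(x$steps),
         nobs = length(stats::residuals(x$model)))
}
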