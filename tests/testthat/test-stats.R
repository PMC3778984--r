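test_that("spearman matches the Pearson-on-average-ranks oracle on random instances", {
  withr::with_seed(101, {
    for (i in 1:100) {
      n <- sample(5:20, 1)
      # integer draws force ties, exercising average ranks
      x <- sample(1:6, n, replace = TRUE)
      y <- sample(1:6, n, replace = TRUE)
      if (var(x) == 0 || var(y) == 0) next
      expect_equal(spearman_test(x, y)$value, spearman_oracle(x, y),
                   tolerance = 1e-12)
    }
  })
})

test_that("spearman is monotone-invariant, antisymmetric, and rejects constants", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3)
  y <- exp(x)
  expect_equal(spearman_test(x, y)$value, 1)
  expect_equal(spearman_test(x, x^3)$value, spearman_test(x, x)$value)
  z <- c(2, 7, 1, 8, 2.8, 1.8, 9)
  expect_equal(spearman_test(x, -z)$value, -spearman_test(x, z)$value)
  expect_error(spearman_test(rep(1, 5), 1:5), "constant")
  expect_error(spearman_test(1:3, 1:4), "equal length")
  expect_error(spearman_test(c(1, 2, NA), 1:3), "finite")
})

test_that("paired t equals the textbook formula and t.test, and rejects zero variance", {
  withr::with_seed(5, {
    for (i in 1:20) {
      x <- rnorm(10); y <- rnorm(10)
      mine <- paired_t_test(x, y)
      ref <- t.test(x, y, paired = TRUE)
      expect_equal(mine$value, unname(ref$statistic), tolerance = 1e-12)
      expect_equal(mine$p_raw, ref$p.value, tolerance = 1e-12)
      expect_equal(mine$df1, unname(ref$parameter))
    }
  })
  # consistent large shift in one direction -> large positive t
  d <- 1:8 / 100
  expect_gt(paired_t_test(2 + d, 1 + d * 0.99)$value, 50)
  expect_error(paired_t_test(1:5, 1:5), "zero-variance")
})

test_that("2x2 within-subject interaction F equals the difference-of-differences t squared", {
  withr::with_seed(202, {
    for (i in 1:20) {
      n <- sample(4:12, 1)
      d <- tidyr::expand_grid(subject = seq_len(n),
                              leg = c("P", "N"), side = c("I", "C"))
      d$value <- rnorm(nrow(d))
      res <- rm_anova_2x2(d)
      wide <- tidyr::pivot_wider(d, names_from = c("leg", "side"),
                                 values_from = "value")
      dd <- (wide$P_I - wide$P_C) - (wide$N_I - wide$N_C)
      tt <- t.test(dd)
      expect_equal(res$value, unname(tt$statistic)^2, tolerance = 1e-10)
      expect_equal(res$df1, 1); expect_equal(res$df2, n - 1)
      # independent route: stats::aov with an within-subject error stratum
      d$subject <- factor(d$subject)
      av <- summary(stats::aov(value ~ leg * side + Error(subject / (leg * side)),
                               data = d))
      f_aov <- av[["Error: subject:leg:side"]][[1]]["leg:side", "F value"]
      expect_equal(res$value, f_aov, tolerance = 1e-8)
    }
  })
})

test_that("degenerate 2x2 designs are handled per contract", {
  # all cells equal within each subject -> F = 0
  d <- tidyr::expand_grid(subject = 1:5, leg = c("P", "N"), side = c("I", "C"))
  d$value <- rep(c(3, 1, 4, 1, 5), each = 4)
  expect_equal(rm_anova_2x2(d)$value, 0)
  # additive leg and side effects, no interaction, noise off -> F = 0
  d2 <- tidyr::expand_grid(subject = 1:6, leg = c("P", "N"), side = c("I", "C"))
  d2$value <- 2 * (d2$leg == "P") + 5 * (d2$side == "I") + d2$subject / 10
  expect_equal(rm_anova_2x2(d2)$value, 0)
  expect_error(rm_anova_2x2(d[-1, ]), "per cell")
})

test_that("multiplicity correction multiplies then caps at one", {
  expect_equal(correct_p(0.02, 3), 0.06)
  expect_equal(correct_p(0.5, 4), 1)
  expect_equal(correct_p(0.123, 1), 0.123)
  p <- seq(0, 1, by = 0.05)
  expect_true(all(correct_p(p, 7) <= 1))
  expect_true(all(diff(correct_p(p, 7)) >= 0))          # monotone in p
  expect_true(all(correct_p(0.3, 1:10) == pmin(1, 0.3 * 1:10)))
  expect_error(correct_p(1.2, 2), "\\[0, 1\\]")
  expect_error(correct_p(0.2, 0), ">= 1")
})

test_that("stepwise selection enters a perfect predictor and reports R^2 = 1", {
  d <- tibble::tibble(y = c(3, 1, 4, 1, 5, 9, 2, 6))
  d$x <- d$y
  d$z <- c(1, 2, 1, 2, 1, 2, 1, 2)
  sw <- suppressWarnings(stepwise_regression(d, "y", candidates = c("x", "z")))
  expect_equal(sw$terms[1], "x")
  expect_equal(suppressWarnings(glance(sw))$r.squared, 1, tolerance = 1e-12)
  expect_equal(sw$steps$action[1], "enter")
})

test_that("stepwise returns an empty model for outcome-independent candidates", {
  empty <- vapply(1:200, function(s) {
    withr::with_seed(5000 + s, {
      d <- tibble::tibble(y = rnorm(50), a = rnorm(50), b = rnorm(50))
      length(stepwise_regression(d, "y")$terms) == 0L
    })
  }, logical(1))
  expect_gte(mean(empty), 0.85)
})

test_that("stepwise drops aliased candidates with a warning and ranks the dominant driver first", {
  withr::with_seed(303, {
    d <- tibble::tibble(x1 = rnorm(40))
    d$x2 <- 2 * d$x1            # aliased with x1 once x1 is in
    d$y <- d$x1 + rnorm(40, sd = 0.1)
    expect_warning(sw <- stepwise_regression(d, "y", candidates = c("x1", "x2")),
                   "aliased")
    expect_equal(sw$terms, "x1")

    # cohort where the paretic FCR is the dominant generative driver of FM
    sev <- runif(60)
    tab <- tibble::tibble(
      fcr_paretic = 0.27 + 2.33 * sev,
      fa_asymmetry_plic = 0.3 * sev + rnorm(60, sd = 0.12),
      lesion_volume = exp(rnorm(60, 8, 1)),
      fm = 34 - 22 * sev + rnorm(60, sd = 1)
    )
    sw2 <- stepwise_regression(tab, "fm",
                               candidates = c("fcr_paretic", "fa_asymmetry_plic",
                                              "lesion_volume"))
    expect_equal(sw2$terms[1], "fcr_paretic")
  })
})
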