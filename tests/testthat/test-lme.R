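test_that("paired_t matches the closed form and stats::t.test", {
  # differences {1,2,3}: t = 2 / (1/sqrt(3)) = 2*sqrt(3)
  res <- paired_t(c(2, 4, 6), c(1, 2, 3))
  expect_equal(res$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(res$df, 2)
  withr::with_seed(42, {
    for (i in 1:20) {
      n <- sample(5:40, 1)
      x <- rnorm(n); y <- rnorm(n) + rnorm(1)
      mine <- paired_t(x, y)
      ref <- stats::t.test(x, y, paired = TRUE)
      expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
      expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
      expect_equal(mine$df, unname(ref$parameter))
    }
  })
})

test_that("paired_t handles degenerate inputs per contract", {
  x <- c(1, 2, 3)
  same <- paired_t(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  shifted <- paired_t(x + 2, x)
  expect_equal(shifted$t, Inf)
  expect_equal(shifted$p, 0)
  expect_true(shifted$flagged)
  expect_error(paired_t(1, c(1, 2)), "equal length")
  expect_error(paired_t(1, 1), "at least 2")
})

test_that("paired_t and pearson are invariant to joint reordering of pairs", {
  withr::with_seed(11, {
    x <- rnorm(15); y <- x * 0.5 + rnorm(15)
    ord <- sample(15)
    expect_equal(paired_t(x, y), paired_t(x[ord], y[ord]))
    expect_equal(pearson(x, y), pearson(x[ord], y[ord]))
  })
})

test_that("pearson recovers exact linear relations and matches cor.test", {
  x <- c(1, 2, 5, 7)
  expect_equal(pearson(x, 2 * x + 1)$r, 1)
  expect_equal(pearson(x, -x)$r, -1)
  expect_error(pearson(x, rep(1, 4)), "zero variance")
  expect_error(pearson(1:2, 2:1), "at least 3")
  withr::with_seed(2, {
    a <- rnorm(25); b <- 0.4 * a + rnorm(25)
    ref <- stats::cor.test(a, b)
    mine <- pearson(a, b)
    expect_equal(mine$r, unname(ref$estimate))
    expect_equal(mine$p, ref$p.value)
  })
})

test_that("fit_lme agrees with the paired t on balanced two-timepoint data", {
  checked <- 0
  for (seed in 1:40) {
    df <- balanced_two_tp(seed)
    fit <- try(fit_lme(df, "y", fixed = "time"), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (lme4::isSingular(fit$fit)) next   # boundary fits use a pooled variance
    checked <- checked + 1
    wide <- tidyr::pivot_wider(df, names_from = timepoint, values_from = y)
    ref <- paired_t(wide$`3`, wide$`0`)
    row <- tidy(fit)[2, ]
    expect_equal(row$t, ref$t, tolerance = 1e-6)
    expect_equal(row$estimate, ref$estimate, tolerance = 1e-8)
  }
  expect_gt(checked, 20)
})

test_that("fit_lme approaches OLS when there is no participant clustering", {
  withr::with_seed(5, {
    n <- 40
    df <- tibble::tibble(
      participant = rep(sprintf("p%02d", 1:n), 2),
      timepoint = rep(c(0, 3), each = n),
      y = rnorm(2 * n) + 0.4 * rep(c(0, 1), each = n)
    )
  })
  fit <- fit_lme(df, "y", fixed = "time")
  ols <- summary(stats::lm(y ~ factor(timepoint), df))$coefficients
  expect_lt(glance(fit)$subject_var, 0.05)
  expect_equal(tidy(fit)$t[2], ols[2, "t value"], tolerance = 0.1)
})

test_that("degenerate responses raise singular-fit errors", {
  df <- tibble::tibble(participant = rep(c("a", "b", "c"), 2),
                       timepoint = rep(c(0, 3), each = 3),
                       y = 1)
  expect_error(fit_lme(df, "y", fixed = "time"), "singular")
  # response an exact copy of the time dummy: zero residual variance
  # (lme4 emits a boundary-gradient warning before our check fires)
  df$y <- as.numeric(df$timepoint == 3)
  expect_error(suppressWarnings(fit_lme(df, "y", fixed = "time")), "singular")
})

test_that("fit_lme supports the score fixed effect and df conventions", {
  withr::with_seed(9, {
    n <- 25
    b <- rnorm(n, 0, 0.6)
    df <- tibble::tibble(
      participant = rep(sprintf("p%02d", 1:n), 2),
      timepoint = rep(c(3, 6), each = n),
      score = c(rnorm(n, 60, 8), rnorm(n, 75, 8)),
      y = NA_real_
    )
    df$y <- 0.02 * df$score + b[match(df$participant,
                                      sprintf("p%02d", 1:n))] +
      rnorm(2 * n, 0, 0.3)
  })
  fit <- fit_lme(df, "y", fixed = "score")
  expect_equal(tidy(fit)$term[2], "score")
  expect_equal(tidy(fit)$df[2], 2 * 25 - 2)
  ref <- lme4::lmer(y ~ score + (1 | participant), df, REML = TRUE)
  expect_equal(tidy(fit)$t[2],
               summary(ref)$coefficients["score", "t value"],
               tolerance = 1e-6)
  if (requireNamespace("lmerTest", quietly = TRUE)) {
    fit2 <- fit_lme(df, "y", fixed = "score", df_method = "satterthwaite")
    expect_true(all(tidy(fit2)$df > 0))
  }
  expect_s3_class(glance(fit), "tbl_df")
  expect_equal(glance(fit)$n_participants, 25)
})

test_that("contrasts recover planted shifts and telescope on noise-free data", {
  # planted +delta at 6 months
  withr::with_seed(14, {
    n <- 60
    b <- rnorm(n, 0, 0.5)
    base <- rnorm(n, 0, 0.2)
    df <- tibble::tibble(
      participant = rep(sprintf("p%02d", 1:n), 3),
      timepoint = rep(c(0, 3, 6), each = n),
      y = rep(b + base, 3) + rnorm(3 * n, 0, 0.2) +
        0.5 * rep(c(0, 0, 1), each = n)
    )
  })
  c36 <- contrast(df, "y", c(3, 6))
  expect_equal(c36$estimate, 0.5, tolerance = 3 * 0.2 * sqrt(2 / 60))
  expect_lt(c36$p, 0.001)

  # identical values at both timepoints -> t = 0
  df0 <- tibble::tibble(participant = rep(letters[1:5], 2),
                        timepoint = rep(c(0, 3), each = 5),
                        y = rep(rnorm(5), 2))
  c03 <- contrast(df0, "y", c(0, 3))
  expect_equal(c03$t, 0)
  expect_equal(c03$p, 1)

  # noise-free telescoping: (0,6) estimate = (0,3) + (3,6)
  df2 <- tibble::tibble(participant = rep(letters[1:6], 3),
                        timepoint = rep(c(0, 3, 6), each = 6),
                        y = rep(rnorm(6), 3) + rep(c(0, 0.3, 0.8), each = 6))
  e <- vapply(list(c(0, 3), c(3, 6), c(0, 6)),
              function(pr) contrast(df2, "y", pr)$estimate, 0)
  expect_equal(e[3], e[1] + e[2], tolerance = 1e-10)
  expect_error(contrast(df2, "y", c(0, 12)), "not present")
})
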