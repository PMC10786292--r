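#' Paired t-test
#'
#' Classical two-sided paired t-test on participant-matched values, with
#' defined behaviour at the degenerate boundaries the network summaries can
#' produce: all-zero differences give `t = 0, p = 1`; zero-variance
#' differences with a nonzero mean give `t = +/-Inf, p = 0`, flagged.
#'
#' @param x,y Numeric vectors of equal length, matched by participant.
#' @return A one-row tibble: `estimate` (mean difference), `t`, `df`, `p`,
#'   `n`, `flagged`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  ok <- is.finite(x) & is.finite(y)
  d <- (x - y)[ok]
  n <- length(d)
  if (n < 2) abort("need at least 2 complete pairs")
  m <- mean(d)
  s <- sd(d)
  if (s == 0) {
    if (m == 0) {
      return(tibble(estimate = 0, t = 0, df = n - 1, p = 1, n = n,
                    flagged = FALSE))
    }
    return(tibble(estimate = m, t = sign(m) * Inf, df = n - 1, p = 0, n = n,
                  flagged = TRUE))
  }
  tval <- m / (s / sqrt(n))
  tibble(estimate = m, t = tval, df = n - 1,
         p = 2 * pt(-abs(tval), n - 1), n = n, flagged = FALSE)
}

#' Pearson correlation
#'
#' Pearson's r with a two-sided p-value from the t transform (via
#' [stats::cor.test()]).
#'
#' @param x,y Numeric vectors, `n >= 3`, finite.
#' @return A one-row tibble: `r`, `p`, `n`.
#' @export
pearson <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance in `x` or `y`")
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Fit a participant random-intercept mixed model
#'
#' Fits `y ~ time + (1 | participant)` (time categorical, treatment-coded
#' against the baseline timepoint) or `y ~ score + (1 | participant)` by
#' REML via \pkg{lme4}. Participants with a single observation are retained
#' (they inform the fixed effects); unbalanced timepoints are allowed.
#' p-values use residual degrees of freedom `n_obs - rank(X)` by default;
#' Satterthwaite degrees of freedom (via \pkg{lmerTest}) are available as an
#' alternative convention.
#'
#' @param data Long data frame with one row per participant-timepoint.
#' @param response Name of the response column.
#' @param fixed `"time"` or `"score"`.
#' @param participant,time,score Column names.
#' @param ref Reference timepoint for treatment coding (default: earliest).
#' @param df_method `"residual"` or `"satterthwaite"`.
#' @param REML Use REML (default) or ML.
#' @return An object of class `"conn_lme"`; see [tidy.conn_lme()] and
#'   [glance.conn_lme()].
#' @export
fit_lme <- function(data, response, fixed = c("time", "score"),
                    participant = "participant", time = "timepoint",
                    score = "score", ref = NULL,
                    df_method = c("residual", "satterthwaite"),
                    REML = TRUE) {
  fixed <- match.arg(fixed)
  df_method <- match.arg(df_method)
  data <- as_tibble(data)
  y <- data[[response]]
  if (is.null(y)) abort(paste0("no column `", response, "`"))
  if (sd(y) == 0) abort("singular fit: all responses identical")
  pp <- factor(data[[participant]])
  tab <- table(pp)
  if (sum(tab >= 2) < 2) abort("need >= 2 participants with >= 2 observations")
  mf <- tibble(.y = y, .pp = pp)
  if (fixed == "time") {
    tvals <- data[[time]]
    if (is.null(ref)) ref <- min(tvals)
    mf$.x <- stats::relevel(factor(tvals), ref = as.character(ref))
    form <- .y ~ .x + (1 | .pp)
  } else {
    mf$.x <- data[[score]]
    if (sd(mf$.x) == 0) abort("zero variance in the score fixed effect")
    form <- .y ~ .x + (1 | .pp)
  }
  if (df_method == "satterthwaite") {
    if (!requireNamespace("lmerTest", quietly = TRUE)) {
      abort("`df_method = \"satterthwaite\"` needs the lmerTest package")
    }
    fit <- lmerTest::lmer(form, data = mf, REML = REML)
  } else {
    fit <- lme4::lmer(form, data = mf, REML = REML)
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  resid_var <- vc$vcov[vc$grp == "Residual"]
  subj_var <- vc$vcov[vc$grp == ".pp"]
  if (resid_var < 1e-10 * max(var(y), .Machine$double.eps)) {
    abort("singular fit: residual variance is zero")
  }
  cf <- as.data.frame(summary(fit)$coefficients)
  n_obs <- nrow(mf)
  rank_x <- length(lme4::fixef(fit))
  if (df_method == "residual") {
    dfs <- rep(n_obs - rank_x, nrow(cf))
    tval <- cf[, "t value"]
    pval <- 2 * pt(-abs(tval), dfs)
  } else {
    dfs <- cf[, "df"]
    tval <- cf[, "t value"]
    pval <- cf[, "Pr(>|t|)"]
  }
  term <- rownames(cf)
  term <- sub("^\\.x", if (fixed == "time") "time" else "score", term)
  out <- list(
    coefficients = tibble(term = term, estimate = cf[, "Estimate"],
                          se = cf[, "Std. Error"], t = cf[, "t value"],
                          df = dfs, p = pval),
    varcomp = c(subject = subj_var, residual = resid_var),
    n_obs = n_obs,
    n_participants = nlevels(pp),
    fixed = fixed, ref = if (fixed == "time") ref else NA,
    REML = REML, df_method = df_method,
    fit = fit
  )
  class(out) <- "conn_lme"
  out
}

#' @export
print.conn_lme <- function(x, ...) {
  cat("Participant random-intercept LME (", x$fixed, " fixed effect, ",
      if (x$REML) "REML" else "ML", ")\n", sep = "")
  cat(x$n_obs, "observations,", x$n_participants, "participants\n")
  cat("variance components: subject =", signif(x$varcomp["subject"], 4),
      ", residual =", signif(x$varcomp["residual"], 4), "\n\n")
  print(x$coefficients)
  invisible(x)
}

#' Tidy a mixed-model fit
#'
#' @param x A `"conn_lme"` object.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `se`, `t`, `df`, `p`.
#' @export
tidy.conn_lme <- function(x, ...) x$coefficients

#' One-row summary of a mixed-model fit
#'
#' @param x A `"conn_lme"` object.
#' @param ... Unused.
#' @return A one-row tibble: observation counts, variance components and the
#'   intraclass correlation.
#' @export
glance.conn_lme <- function(x, ...) {
  tibble(n_obs = x$n_obs, n_participants = x$n_participants,
         subject_var = unname(x$varcomp["subject"]),
         resid_var = unname(x$varcomp["residual"]),
         icc = unname(x$varcomp["subject"] /
                        (x$varcomp["subject"] + x$varcomp["residual"])),
         REML = x$REML, df_method = x$df_method)
}

#' Adjacent-timepoint contrast
#'
#' Refits the random-intercept time model on the observations of two
#' timepoints (releveled to the earlier one) and returns the later
#' timepoint's coefficient: the post-hoc period contrast. Balanced
#' two-timepoint subsets use the paired-difference closed form (identical to
#' the mixed-model t); unbalanced subsets use the profiled-REML engine.
#'
#' @param data Long data frame with one row per participant-timepoint.
#' @param response Name of the response column.
#' @param pair Length-2 numeric vector of timepoints, e.g. `c(3, 6)`.
#' @param participant,time Column names.
#' @return A one-row tibble: `term`, `estimate`, `se`, `t`, `df`, `p`,
#'   `flagged`.
#' @export
contrast <- function(data, response, pair,
                     participant = "participant", time = "timepoint") {
  pair <- sort(as.numeric(pair))
  sub <- as_tibble(data) |> filter(.data[[time]] %in% pair)
  if (length(unique(sub[[time]])) < 2) abort("`pair` not present in the data")
  both <- sub |>
    count(.data[[participant]]) |>
    filter(.data$n == 2)
  if (nrow(both) < 2) abort("need both timepoints observed for >= 2 participants")
  res <- edge_stats_engine(
    Y = matrix(sub[[response]], ncol = 1),
    participant = factor(sub[[participant]]),
    timepoint = sub[[time]]
  )
  tibble(term = paste0("time", pair[2]),
         estimate = unname(res$estimate[1, 1]), se = unname(res$se[1, 1]),
         t = unname(res$t[1, 1]), df = res$df, p = unname(res$p[1, 1]),
         flagged = unname(res$flagged[1]))
}
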