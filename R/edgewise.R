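# Edge-wise random-intercept LME screening engines.
#
# Both engines operate on a response matrix Y (rows = participant-timepoint
# observations, columns = edges) so that one call scores every edge, and --
# because the permutation schemes leave the per-participant ingredients
# intact -- permutation nulls reuse almost all precomputation.

#' Profiling grid for the variance ratio
#'
#' Grid of candidate values for the variance ratio
#' \eqn{\theta = \sigma_b^2 / \sigma_\epsilon^2} profiled over by the REML
#' engine (zero plus a log-spaced grid); the grid optimum is polished by a
#' parabolic step on the log scale.
#'
#' @param from,to,by Limits and step on the log10 scale.
#' @return Numeric vector of theta values.
#' @export
reml_theta_grid <- function(from = -3, to = 3, by = 0.05) {
  c(0, 10^seq(from, to, by = by))
}

# Balanced-design fast path: every participant observed exactly once at every
# timepoint. The edge statistic is the within-subject (subject + time two-way)
# ANOVA t for each non-baseline timepoint against baseline; at T = 2 this is
# exactly the paired t, and it equals the REML LME t whenever the intercept
# variance estimate is interior.
stat_balanced <- function(Y, gp, gt) {
  Y <- as.matrix(Y)
  gp <- as.integer(factor(gp))
  gt <- as.integer(gt)   # 1..T in time order
  n <- max(gp); T_ <- max(gt); N <- nrow(Y)
  M <- rowsum(Y, gt) / n                       # T x E timepoint means
  S <- rowsum(Y, gp) / T_                      # n x E subject means
  gm <- colMeans(Y)
  q0 <- colSums(Y^2)
  RSS <- pmax(q0 - n * colSums(M^2) - T_ * colSums(S^2) + N * gm^2, 0)
  df2 <- (n - 1) * (T_ - 1)
  MSE <- RSS / df2
  se_row <- sqrt(2 * MSE / n)
  est <- M[-1, , drop = FALSE] - rep(M[1, ], each = T_ - 1)
  se <- matrix(rep(se_row, each = T_ - 1), nrow = T_ - 1)
  t <- est / se
  t[se == 0 & est == 0] <- 0
  t[se == 0 & est != 0] <- sign(est[se == 0 & est != 0]) * Inf
  p <- 2 * pt(-abs(t), df2)
  p[t == 0 & se == 0] <- 1
  p[is.infinite(t)] <- 0
  flagged <- unname(se_row == 0)
  dimnames(est) <- dimnames(se) <- dimnames(t) <- dimnames(p) <- NULL
  list(estimate = est, se = se, t = t, p = p, df = df2, flagged = flagged,
       engine = "balanced")
}

# Precompute everything the profiled-REML solver needs that does not depend
# on the permuted part of the problem. For the time model, within-participant
# label permutations change only X'Y, so one context serves a whole
# permutation run. V = participant sums of Y (n x E), q0 = colSums(Y^2).
make_reml_ctx <- function(X, gp, V, q0, contrasts,
                          theta_grid = reml_theta_grid()) {
  X <- as.matrix(X)
  p <- ncol(X)
  gp <- as.integer(gp)
  n_i <- tabulate(gp)
  N <- nrow(X)
  E <- ncol(V)
  U <- t(rowsum(X, gp))                        # p x n, columns u_i = X_i' 1
  XtX <- crossprod(X)
  groups <- lapply(split(seq_along(n_i), n_i), function(ix) {
    Ug <- U[, ix, drop = FALSE]
    Vg <- V[ix, , drop = FALSE]
    list(n = n_i[ix[1]], m = length(ix), UU = tcrossprod(Ug),
         W = Ug %*% Vg, s = colSums(Vg^2))
  })
  theta_tab <- lapply(theta_grid, function(th) {
    A <- XtX; B1 <- matrix(0, p, E); qy <- q0; ldV <- 0
    for (g in groups) {
      cg <- th / (1 + th * g$n)
      A <- A - cg * g$UU
      B1 <- B1 + cg * g$W
      qy <- qy - cg * g$s
      ldV <- ldV + g$m * log1p(th * g$n)
    }
    R <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(R)) return(NULL)
    Ainv <- chol2inv(R)
    list(Ainv = Ainv, B1 = B1, qy = qy,
         const = ldV + 2 * sum(log(diag(R))),
         w = lapply(contrasts, function(cc) drop(Ainv %*% cc)),
         cvc = vapply(contrasts, function(cc) sum(cc * drop(Ainv %*% cc)), 0))
  })
  keep <- !vapply(theta_tab, is.null, TRUE)
  if (!any(keep)) abort("REML profiling failed: singular design")
  totvar <- q0 - colSums(V)^2 / N
  list(p = p, N = N, E = E, XtX = XtX, q0 = q0, groups = groups,
       contrasts = contrasts, ncon = length(contrasts),
       theta_grid = theta_grid[keep], theta_tab = theta_tab[keep],
       zerovar = totvar <= 1e-12 * pmax(q0, 1))
}

# Evaluate the profiled-REML quantities at a per-edge theta vector using
# closed-form small-matrix inverses (p <= 3 covers the time and score
# designs; larger designs fall back to a per-edge solve).
reml_eval_theta <- function(theta, XtY, ctx) {
  p <- ctx$p; E <- length(theta)
  qy <- ctx$q0
  B <- XtY
  ldV <- numeric(E)
  nA <- p * (p + 1) / 2
  ij <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  A <- lapply(seq_len(nA), function(r) rep(ctx$XtX[ij[r, 1], ij[r, 2]], E))
  for (g in ctx$groups) {
    cg <- theta / (1 + theta * g$n)
    ldV <- ldV + g$m * log1p(theta * g$n)
    qy <- qy - cg * g$s
    B <- B - g$W * rep(cg, each = p)
    for (r in seq_len(nA)) {
      A[[r]] <- A[[r]] - cg * g$UU[ij[r, 1], ij[r, 2]]
    }
  }
  inv <- vector("list", nA)   # symmetric inverse, same upper-tri layout
  if (p == 1) {
    det <- A[[1]]
    inv[[1]] <- 1 / det
  } else if (p == 2) {
    a11 <- A[[1]]; a12 <- A[[2]]; a22 <- A[[3]]
    det <- a11 * a22 - a12^2
    inv[[1]] <- a22 / det; inv[[2]] <- -a12 / det; inv[[3]] <- a11 / det
  } else if (p == 3) {
    a11 <- A[[1]]; a12 <- A[[2]]; a22 <- A[[3]]
    a13 <- A[[4]]; a23 <- A[[5]]; a33 <- A[[6]]
    c11 <- a22 * a33 - a23^2
    c12 <- -(a12 * a33 - a13 * a23)
    c13 <- a12 * a23 - a13 * a22
    c22 <- a11 * a33 - a13^2
    c23 <- -(a11 * a23 - a12 * a13)
    c33 <- a11 * a22 - a12^2
    det <- a11 * c11 + a12 * c12 + a13 * c13
    inv[[1]] <- c11 / det; inv[[2]] <- c12 / det; inv[[3]] <- c22 / det
    inv[[4]] <- c13 / det; inv[[5]] <- c23 / det; inv[[6]] <- c33 / det
  } else {
    # generic fallback: per-edge dense solve
    beta <- matrix(NA_real_, p, E)
    logdet <- numeric(E)
    invmats <- vector("list", E)
    for (e in seq_len(E)) {
      Ae <- matrix(0, p, p)
      for (r in seq_len(nA)) {
        Ae[ij[r, 1], ij[r, 2]] <- Ae[ij[r, 2], ij[r, 1]] <- A[[r]][e]
      }
      R <- chol(Ae)
      logdet[e] <- 2 * sum(log(diag(R)))
      Ai <- chol2inv(R)
      invmats[[e]] <- Ai
      beta[, e] <- Ai %*% B[, e]
    }
    RSS <- pmax(qy - colSums(B * beta), 0)
    est <- matrix(NA_real_, ctx$ncon, E)
    cvc <- matrix(NA_real_, ctx$ncon, E)
    for (j in seq_len(ctx$ncon)) {
      cj <- ctx$contrasts[[j]]
      est[j, ] <- drop(crossprod(cj, beta))
      cvc[j, ] <- vapply(invmats, function(Ai) sum(cj * (Ai %*% cj)), 0)
    }
    f <- ldV + logdet + (ctx$N - p) * log(pmax(RSS, 1e-300))
    return(list(f = f, RSS = RSS, est = est, cvc = cvc))
  }
  # symmetric multiply: beta_i = sum_l inv[i,l] B_l
  full <- matrix(0L, p, p)
  full[cbind(ij[, 1], ij[, 2])] <- seq_len(nA)
  full[cbind(ij[, 2], ij[, 1])] <- seq_len(nA)
  beta <- matrix(0, p, E)
  for (i in seq_len(p)) {
    acc <- 0
    for (l in seq_len(p)) acc <- acc + inv[[full[i, l]]] * B[l, ]
    beta[i, ] <- acc
  }
  RSS <- pmax(qy - colSums(B * beta), 0)
  est <- matrix(0, ctx$ncon, E)
  cvc <- matrix(0, ctx$ncon, E)
  for (j in seq_len(ctx$ncon)) {
    cj <- ctx$contrasts[[j]]
    est[j, ] <- drop(crossprod(cj, beta))
    acc <- 0
    for (i in seq_len(p)) for (l in seq_len(p)) {
      if (cj[i] != 0 && cj[l] != 0) {
        acc <- acc + cj[i] * cj[l] * inv[[full[i, l]]]
      }
    }
    cvc[j, ] <- acc
  }
  f <- ldV + log(pmax(det, 1e-300)) + (ctx$N - p) * log(pmax(RSS, 1e-300))
  list(f = f, RSS = RSS, est = est, cvc = cvc)
}

# Core solver: per edge, the REML criterion is minimised over the shared
# theta grid and polished with one parabolic interpolation step on log10
# scale; the polished value is kept only when it improves the criterion, so
# the statistic is a deterministic function of (X'Y, context) and identical
# for observed and permuted data.
reml_core <- function(XtY, ctx) {
  grid <- ctx$theta_grid
  nth <- length(grid)
  E <- ctx$E
  F <- matrix(NA_real_, nth, E)
  for (i in seq_len(nth)) {
    tt <- ctx$theta_tab[[i]]
    B <- XtY - tt$B1
    beta <- tt$Ainv %*% B
    RSS <- pmax(tt$qy - colSums(B * beta), 0)
    F[i, ] <- tt$const + (ctx$N - ctx$p) * log(pmax(RSS, 1e-300))
  }
  k <- max.col(-t(F), ties.method = "first")
  eseq <- seq_len(E)
  theta0 <- grid[k]
  theta_star <- theta0
  can <- k >= 3 & k <= nth - 1           # neighbours both on the log grid
  if (any(can)) {
    xg <- log10(grid)
    f1 <- F[cbind(pmax(k - 1, 1), eseq)]
    f2 <- F[cbind(k, eseq)]
    f3 <- F[cbind(pmin(k + 1, nth), eseq)]
    h <- xg[pmin(k + 1, nth)] - xg[k]
    denom <- f1 - 2 * f2 + f3
    shift <- ifelse(can & denom > 0, 0.5 * h * (f1 - f3) / denom, 0)
    shift <- pmin(pmax(shift, -abs(h)), abs(h))
    theta_star <- ifelse(can, 10^(xg[k] + shift), theta0)
  }
  ev_star <- reml_eval_theta(theta_star, XtY, ctx)
  f_grid <- F[cbind(k, eseq)]
  use_star <- is.finite(ev_star$f) & ev_star$f <= f_grid
  theta_fin <- ifelse(use_star, theta_star, theta0)
  ev <- if (all(use_star)) ev_star else reml_eval_theta(theta_fin, XtY, ctx)
  df2 <- ctx$N - ctx$p
  sigma2 <- ev$RSS / df2
  se <- sqrt(ev$cvc * rep(sigma2, each = ctx$ncon))
  t <- ev$est / se
  zero <- se == 0
  t[zero & ev$est == 0] <- 0
  t[zero & ev$est != 0] <- sign(ev$est[zero & ev$est != 0]) * Inf
  pv <- 2 * pt(-abs(t), df2)
  pv[t == 0 & zero] <- 1
  pv[is.infinite(t)] <- 0
  t[, ctx$zerovar] <- 0
  pv[, ctx$zerovar] <- 1
  flagged <- ctx$zerovar | sigma2 == 0
  list(estimate = ev$est, se = se, t = t, p = pv, df = df2,
       flagged = flagged, theta = theta_fin, engine = "reml")
}

# Profiled-REML general path for the random-intercept model
# y = X beta + b_participant + eps.
stat_reml <- function(Y, X, gp, contrasts, theta_grid = reml_theta_grid(),
                      V = NULL, q0 = NULL) {
  Y <- as.matrix(Y)
  gp <- as.integer(factor(gp))
  if (is.null(V)) V <- rowsum(Y, gp)
  if (is.null(q0)) q0 <- colSums(Y^2)
  ctx <- make_reml_ctx(X, gp, V, q0, contrasts, theta_grid)
  reml_core(crossprod(as.matrix(X), Y), ctx)
}

# Dispatch: time model (categorical, cell-means coding with baseline
# contrasts) or score model (intercept + slope). `engine = "auto"` uses the
# balanced fast path when every participant is observed at every timepoint.
edge_stats_engine <- function(Y, participant, timepoint = NULL, score = NULL,
                              engine = c("auto", "balanced", "reml"),
                              theta_grid = reml_theta_grid()) {
  engine <- match.arg(engine)
  gp <- factor(participant)
  if (is.null(score)) {
    tps <- sort(unique(timepoint))
    gt <- match(timepoint, tps)
    balanced <- all(table(gp, gt) == 1)
    if (engine == "balanced" && !balanced) {
      abort("balanced engine requested on an unbalanced design")
    }
    use_balanced <- balanced && engine != "reml"
    if (use_balanced) {
      res <- stat_balanced(Y, gp, gt)
    } else {
      X <- outer(gt, seq_along(tps), `==`) * 1
      cons <- lapply(seq_along(tps)[-1], function(j) {
        v <- numeric(length(tps)); v[j] <- 1; v[1] <- -1; v
      })
      res <- stat_reml(Y, X, gp, cons, theta_grid)
    }
    res$contrast <- paste0("time", tps[-1])
  } else {
    if (sd(score) == 0) abort("zero variance in the score fixed effect")
    X <- cbind(1, score)
    res <- stat_reml(Y, X, gp, list(c(0, 1)), theta_grid)
    res$contrast <- "score"
  }
  res
}

# Response matrix for the retained edges: rows are observed
# participant-timepoint matrices, pairs absent from a matrix count as zero.
build_edge_matrix <- function(data, edges) {
  obs <- observed_matrices(data)
  okey <- paste(obs$participant, obs$timepoint)
  ekey <- paste(edges$region_a, edges$region_b)
  sub <- data |> semi_join(edges, by = c("region_a", "region_b"))
  Y <- matrix(0, nrow(obs), length(ekey))
  Y[cbind(match(paste(sub$participant, sub$timepoint), okey),
          match(paste(sub$region_a, sub$region_b), ekey))] <- sub$weight
  list(Y = Y, obs = obs, edges = edges)
}

#' Edge-wise mixed-model statistics
#'
#' Fits the participant random-intercept model to every retained edge and
#' returns per-edge, per-contrast statistics: for the time model, one
#' baseline contrast per later timepoint (`time3`, `time6`, ...); for the
#' score model, the score slope. Balanced cohorts are scored by the
#' within-subject ANOVA fast path; unbalanced cohorts by the profiled-REML
#' engine. Degenerate edges (zero variance) are flagged and carry `p = 1`.
#'
#' @param data A long connectome tibble.
#' @param mask An edge mask from [group_threshold()].
#' @param fixed `"time"` or `"score"`.
#' @param scores For the score model, a tibble `participant`, `timepoint`,
#'   `score`; only participant-timepoints with a score enter the fit.
#' @param engine `"auto"`, `"balanced"` or `"reml"`.
#' @param theta_grid Profiling grid for the REML engine.
#' @return A tibble of class `"edge_stat_map"`: `region_a`, `region_b`,
#'   `contrast`, `estimate`, `se`, `t`, `p`, `flagged`, with the residual
#'   `df`, engine and design kept as attributes.
#' @export
edgewise_stats <- function(data, mask, fixed = c("time", "score"),
                           scores = NULL, engine = "auto",
                           theta_grid = reml_theta_grid()) {
  fixed <- match.arg(fixed)
  edges <- retained_edges(mask)
  if (nrow(edges) == 0) abort("empty edge mask")
  score_vec <- NULL
  if (fixed == "score") {
    if (is.null(scores)) abort("the score model needs a `scores` table")
    scores <- as_tibble(scores) |>
      mutate(participant = as.character(.data$participant),
             timepoint = as.numeric(.data$timepoint))
    data <- data |> filter(.data$timepoint %in% unique(scores$timepoint))
    obs_all <- observed_matrices(data)
    obs_scored <- obs_all |>
      inner_join(scores, by = c("participant", "timepoint")) |>
      filter(is.finite(.data$score))
    if (nrow(obs_scored) < 0.5 * nrow(obs_all)) {
      abort("scores missing for more than half of the observations")
    }
    data <- data |>
      semi_join(obs_scored, by = c("participant", "timepoint"))
  }
  em <- build_edge_matrix(data, edges)
  if (fixed == "score") {
    score_vec <- (em$obs |>
                    left_join(scores, by = c("participant", "timepoint")))$score
  }
  res <- edge_stats_engine(em$Y, em$obs$participant,
                           timepoint = if (fixed == "time") em$obs$timepoint,
                           score = score_vec, engine = engine,
                           theta_grid = theta_grid)
  ncon <- length(res$contrast)
  out <- tibble(
    region_a = rep(edges$region_a, each = ncon),
    region_b = rep(edges$region_b, each = ncon),
    contrast = rep(res$contrast, times = nrow(edges)),
    estimate = as.vector(res$estimate),
    se = as.vector(res$se),
    t = as.vector(res$t),
    p = as.vector(res$p),
    flagged = rep(res$flagged, each = ncon)
  )
  structure(out, df = res$df, engine = res$engine, fixed = fixed,
            n_obs = nrow(em$Y),
            n_participants = length(unique(em$obs$participant)),
            class = c("edge_stat_map", class(out)))
}
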