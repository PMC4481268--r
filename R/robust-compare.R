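# Rank-based inferential layer: two-way ANOVA-type statistics with
# Box-approximated fractional degrees of freedom, Tukey-type nonparametric
# contrasts on relative effects, the Patel-Hoel 2x2 interaction test, and
# significance T-graphs with transitive reduction.
#
# Throughout, ties are handled by midranks and the effect scale is the
# relative effect: the probability that an observation drawn from the
# pooled data is smaller than one drawn from a specific cell/group.

# diagonal variance matrix of the cell relative-effect estimators,
# shared by the ATS and the contrasts: V = N * diag(sigma_i^2 / n_i),
# sigma_i^2 = S_i^2 / N^2 with S_i^2 the sample variance of the cell's ranks
.rank_cell_stats <- function(values, cell) {
  N <- length(values)
  r <- rank(values, ties.method = "average")
  n_i <- tapply(r, cell, length)
  rbar <- tapply(r, cell, mean)
  s2 <- tapply(r, cell, stats::var)
  p_hat <- (rbar - 0.5) / N
  list(N = N, n = as.vector(n_i), p = as.vector(p_hat),
       sigma2 = as.vector(s2) / N^2, labels = names(rbar))
}

.ats_effect <- function(T_, p_hat, V, n, N, effect) {
  TV <- T_ %*% V
  trTV <- sum(diag(TV))
  F_ <- as.numeric(N / trTV * (p_hat %*% T_ %*% p_hat))
  df1 <- trTV^2 / sum(diag(TV %*% TV))
  df2 <- trTV^2 / sum((diag(T_) * diag(V))^2 / (n - 1))
  p <- stats::pf(F_, df1, df2, lower.tail = FALSE)
  data.frame(effect = effect, statistic = F_, df1 = df1, df2 = df2, p = p,
             eta_p2 = (df1 * F_) / (df1 * F_ + df2),
             stringsAsFactors = FALSE)
}

#' Rank-based two-way ANOVA-type tests (Brunner-Dette-Munk construction)
#'
#' Computes global midranks, cell relative effects
#' `(mean cell rank - 0.5) / N`, and the heteroscedasticity-robust
#' ANOVA-type statistic (ATS) with Box-approximated fractional degrees of
#' freedom for both main effects and the interaction of a crossed two-way
#' layout. The partial effect size is reported as the approximation
#' `eta_p2 = df1*F / (df1*F + df2)`.
#'
#' @param values Numeric response vector.
#' @param factorA,factorB Factors (or coercible) of the same length;
#'   at least 2 levels each, every cell non-empty.
#' @return An object of class `bdm_ats`: a data.frame with rows `factorA`,
#'   `factorB`, `interaction` and columns `statistic`, `df1`, `df2`, `p`,
#'   `eta_p2`; attribute `relative_effects` is the a x b matrix of cell
#'   relative effects (its cell-size-weighted mean is exactly 0.5) and
#'   attribute `cell_n` the cell counts.
#' @export
bdm_two_way <- function(values, factorA, factorB) {
  fA <- factor(factorA); fB <- factor(factorB)
  stopifnot(length(values) == length(fA), length(values) == length(fB))
  a <- nlevels(fA); b <- nlevels(fB)
  if (a < 2L || b < 2L) stop("each factor needs at least 2 levels",
                             call. = FALSE)
  ok <- is.finite(values)
  values <- values[ok]; fA <- fA[ok]; fB <- fB[ok]
  cell <- interaction(fA, fB, sep = ":", lex.order = TRUE)  # A-major order
  tab <- table(fA, fB)
  if (any(tab == 0L)) {
    empty <- which(tab == 0L, arr.ind = TRUE)
    stop("empty cell(s): ",
         paste(levels(fA)[empty[, 1]], levels(fB)[empty[, 2]],
               sep = ":", collapse = ", "), call. = FALSE)
  }
  if (any(tab < 2L)) stop("every cell needs at least 2 observations",
                          call. = FALSE)
  cs <- .rank_cell_stats(values, cell)
  degenerate <- all(cs$sigma2 == 0)
  V <- cs$N * diag(cs$sigma2 / cs$n)

  P <- function(k) diag(k) - matrix(1 / k, k, k)
  J <- function(k) matrix(1 / k, k, k)
  T_A  <- kronecker(P(a), J(b))
  T_B  <- kronecker(J(a), P(b))
  T_AB <- kronecker(P(a), P(b))

  res <- rbind(.ats_effect(T_A, cs$p, V, cs$n, cs$N, "factorA"),
               .ats_effect(T_B, cs$p, V, cs$n, cs$N, "factorB"),
               .ats_effect(T_AB, cs$p, V, cs$n, cs$N, "interaction"))
  rel <- matrix(cs$p, a, b, byrow = TRUE,
                dimnames = list(levels(fA), levels(fB)))
  structure(res, class = c("bdm_ats", "data.frame"),
            relative_effects = rel,
            cell_n = matrix(cs$n, a, b, byrow = TRUE,
                            dimnames = list(levels(fA), levels(fB))),
            degenerate = degenerate)
}

#' @export
print.bdm_ats <- function(x, ...) {
  cat("Rank-based ANOVA-type tests (Box-approximated df)\n")
  df <- as.data.frame(x)
  df$statistic <- round(df$statistic, 3)
  df$df1 <- round(df$df1, 2); df$df2 <- round(df$df2, 2)
  df$p <- signif(df$p, 3); df$eta_p2 <- round(df$eta_p2, 3)
  print(df, row.names = FALSE)
  cat("eta_p2 is an approximation derived from the ATS and its df.\n")
  invisible(x)
}

#' Tukey-type nonparametric contrasts on relative effects
#'
#' For each group, the relative effect is estimated from global midranks as
#' `(mean rank - 0.5) / N` (the probability that an observation randomly
#' chosen from all groups is smaller than a randomly chosen observation
#' from that group). All pairwise differences of relative effects are
#' reported with simultaneous two-sided confidence intervals whose
#' equicoordinate critical value comes from the estimated joint normal
#' distribution of the contrast statistics (`method = "mvn"`), with a
#' Bonferroni fallback.
#'
#' @param values Numeric response vector.
#' @param groups Group labels (>= 2 groups, each with >= 2 observations).
#' @param alpha Simultaneous two-sided level (default 0.05).
#' @param method `"mvn"` (multivariate-normal equicoordinate critical
#'   value) or `"bonferroni"`.
#' @return A data.frame of class `iat_contrasts` with one row per ordered
#'   pair (i < j): columns `group_i`, `group_j`, `effect`
#'   (= relative effect of i minus that of j), `se`, `ci_low`, `ci_high`,
#'   adjusted `p`, `significant`. Attributes: `relative_effects` (named
#'   vector), `alpha`, `crit`.
#' @export
tukey_relative_contrasts <- function(values, groups, alpha = 0.05,
                                     method = c("mvn", "bonferroni")) {
  method <- match.arg(method)
  g <- factor(groups)
  stopifnot(length(values) == length(g))
  ok <- is.finite(values)
  values <- values[ok]; g <- droplevels(g[ok])
  k <- nlevels(g)
  if (k < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(table(g) < 2L)) stop("every group needs at least 2 observations",
                               call. = FALSE)
  cs <- .rank_cell_stats(values, g)
  p_hat <- stats::setNames(cs$p, cs$labels)
  v <- cs$sigma2 / cs$n       # estimated variance of each relative effect

  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  eff <- p_hat[pairs[1, ]] - p_hat[pairs[2, ]]
  se <- sqrt(v[pairs[1, ]] + v[pairs[2, ]])

  # correlation of the contrast statistics under the diagonal covariance of
  # the relative-effect estimators
  Cmat <- matrix(0, m, k)
  for (j in seq_len(m)) {
    Cmat[j, pairs[1, j]] <- 1
    Cmat[j, pairs[2, j]] <- -1
  }
  Sig <- Cmat %*% diag(v, k) %*% t(Cmat)
  Dinv <- diag(1 / sqrt(pmax(diag(Sig), .Machine$double.eps)), m)
  R <- Dinv %*% Sig %*% Dinv
  R <- (R + t(R)) / 2
  diag(R) <- 1

  crit <- if (method == "mvn" && m > 1L) {
    q <- tryCatch(
      mvtnorm::qmvnorm(1 - alpha, tail = "both.tails", corr = R)$quantile,
      error = function(e) NA_real_)
    if (is.finite(q)) q else stats::qnorm(1 - alpha / (2 * m))
  } else {
    stats::qnorm(1 - alpha / (2 * m))
  }

  tstat <- ifelse(se > 0, eff / se, ifelse(eff == 0, 0, sign(eff) * Inf))
  p_adj <- vapply(seq_len(m), function(j) {
    t0 <- abs(tstat[j])
    if (!is.finite(t0)) return(0)
    if (method == "mvn" && m > 1L) {
      pr <- tryCatch(
        mvtnorm::pmvnorm(lower = rep(-t0, m), upper = rep(t0, m), corr = R),
        error = function(e) NA_real_)
      if (is.finite(pr)) return(max(0, 1 - as.numeric(pr)))
    }
    min(1, m * 2 * stats::pnorm(t0, lower.tail = FALSE))
  }, numeric(1))

  out <- data.frame(group_i = cs$labels[pairs[1, ]],
                    group_j = cs$labels[pairs[2, ]],
                    effect = as.numeric(eff), se = as.numeric(se),
                    ci_low = as.numeric(eff - crit * se),
                    ci_high = as.numeric(eff + crit * se),
                    p = p_adj, stringsAsFactors = FALSE)
  out$significant <- out$ci_low > 0 | out$ci_high < 0
  structure(out, class = c("iat_contrasts", "data.frame"),
            relative_effects = p_hat, alpha = alpha, crit = crit)
}

# Brunner-Munzel estimate of P(X < Y) + 0.5 P(X = Y) with its variance,
# via placements
.bm_prob <- function(x, y) {
  m <- length(x); n <- length(y)
  r_all <- rank(c(x, y), ties.method = "average")
  rx <- r_all[seq_len(m)]; ry <- r_all[m + seq_len(n)]
  qx <- rx - rank(x, ties.method = "average")  # counts of y below each x
  qy <- ry - rank(y, ties.method = "average")  # counts of x below each y
  p_hat <- mean(qy) / m
  v <- stats::var(qx) / (m * n^2) + stats::var(qy) / (n * m^2)
  list(p = p_hat, var = v)
}

#' Patel-Hoel nonparametric 2x2 interaction test
#'
#' Estimates `delta = P(A1 < A2 | B = b1) - P(A1 < A2 | B = b2)` with
#' midrank-based dominance probabilities (ties counted half) and a
#' normal-approximation confidence interval, the per-level variances coming
#' from Brunner-Munzel placement statistics. A nonzero delta means the
#' stochastic ordering of the two A levels differs across the B levels.
#'
#' @param values Numeric response vector.
#' @param factorA,factorB Two-level factors of the same length; all four
#'   cells need at least 2 observations.
#' @param alpha Two-sided level for the CI (default 0.05).
#' @return An object of class `patel_hoel`: list with `delta`, `ci_low`,
#'   `ci_high`, `p`, `se`, and the per-level dominance probabilities
#'   `p_level`.
#' @export
patel_hoel <- function(values, factorA, factorB, alpha = 0.05) {
  fA <- factor(factorA); fB <- factor(factorB)
  stopifnot(length(values) == length(fA), length(values) == length(fB))
  ok <- is.finite(values)
  values <- values[ok]; fA <- droplevels(fA[ok]); fB <- droplevels(fB[ok])
  if (nlevels(fA) != 2L || nlevels(fB) != 2L) {
    stop("patel_hoel requires exactly 2 levels per factor", call. = FALSE)
  }
  if (any(table(fA, fB) < 2L)) {
    stop("every cell needs at least 2 observations", call. = FALSE)
  }
  lev <- levels(fB)
  est <- lapply(lev, function(b) {
    sel <- fB == b
    .bm_prob(values[sel & fA == levels(fA)[1]],
             values[sel & fA == levels(fA)[2]])
  })
  delta <- est[[1]]$p - est[[2]]$p
  se <- sqrt(est[[1]]$var + est[[2]]$var)
  z <- stats::qnorm(1 - alpha / 2)
  p <- if (se > 0) 2 * stats::pnorm(abs(delta) / se, lower.tail = FALSE)
       else as.numeric(delta == 0)
  structure(list(delta = delta, se = se,
                 ci_low = delta - z * se, ci_high = delta + z * se, p = p,
                 p_level = stats::setNames(c(est[[1]]$p, est[[2]]$p), lev),
                 alpha = alpha),
            class = "patel_hoel")
}

#' @export
print.patel_hoel <- function(x, ...) {
  cat(sprintf("Patel-Hoel interaction test: delta = %.3f, %d%% CI [%.3f, %.3f], p = %.4g\n",
              x$delta, round(100 * (1 - x$alpha)), x$ci_low, x$ci_high, x$p))
  invisible(x)
}
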