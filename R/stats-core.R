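#' Storey q-values with smoothed pi0 estimation
#'
#' Computes false-discovery-rate q-values from a vector of p-values using
#' the proportion-of-true-nulls estimator \eqn{\hat\pi_0}: the fraction of
#' p-values above each threshold \eqn{\lambda} in `lambda`, divided by
#' \eqn{1 - \lambda}, is smoothed with a natural cubic spline (df = 3) and
#' evaluated at the largest \eqn{\lambda}. The q-value of a p-value is the
#' minimum estimated FDR over all rejection regions containing it:
#' \eqn{q_i = \min_{p_j \ge p_i} \hat\pi_0 \, n \, p_j / \mathrm{rank}(p_j)}.
#'
#' With `pi0 = 1` the result is exactly the Benjamini-Hochberg step-up
#' adjusted p-value. With fewer than 20 finite p-values the spline fit is
#' unstable, so \eqn{\hat\pi_0} is forced to 1 with a warning.
#'
#' `NA` p-values are carried through as `NA` q-values and do not count
#' towards the family size.
#'
#' @param p numeric vector of p-values in \[0, 1\] (`NA` allowed).
#' @param lambda grid of thresholds for the pi0 estimate.
#' @param pi0 optional fixed pi0 overriding estimation (e.g. `1` for plain
#'   Benjamini-Hochberg behaviour).
#' @return object of class `"qvalue_result"`: a list with elements `p`,
#'   `q`, `pi0`, and `lambda`.
#' @examples
#' set.seed(1)
#' p <- c(runif(90), rbeta(10, 0.2, 8))
#' res <- storey_qvalue(p)
#' res$pi0
#' sum(res$q <= 0.1)
#' @export
storey_qvalue <- function(p, lambda = seq(0.05, 0.90, by = 0.05), pi0 = NULL) {
  stopifnot(is.numeric(p))
  ok <- !is.na(p)
  pv <- p[ok]
  if (length(pv) && (min(pv) < 0 || max(pv) > 1))
    stop("p-values must lie in [0, 1]")
  n <- length(pv)
  if (is.null(pi0)) {
    if (n < 20L) {
      warning("fewer than 20 p-values; pi0 forced to 1")
      pi0 <- 1
    } else {
      lambda <- sort(lambda)
      pi0_raw <- vapply(lambda, function(l) mean(pv > l) / (1 - l), 0)
      fit <- stats::smooth.spline(lambda, pi0_raw, df = 3)
      pi0 <- stats::predict(fit, x = max(lambda))$y
      pi0 <- min(pi0, 1)
      if (pi0 <= 0) {
        warning("pi0 estimate non-positive; falling back to smallest positive raw estimate")
        pos <- pi0_raw[pi0_raw > 0]
        pi0 <- if (length(pos)) min(c(pos, 1)) else 1
      }
    }
  } else {
    stopifnot(pi0 > 0, pi0 <= 1)
  }
  q <- rep(NA_real_, length(p))
  if (n) {
    o <- order(pv, decreasing = TRUE)
    qs <- pi0 * n * pv[o] / (n:1)       # ranks n..1 in decreasing p order
    qs <- cummin(pmin(qs, 1))
    qv <- numeric(n)
    qv[o] <- qs
    q[ok] <- qv
  }
  structure(list(p = p, q = q, pi0 = pi0, lambda = lambda),
            class = "qvalue_result")
}

#' @export
print.qvalue_result <- function(x, ...) {
  n <- sum(!is.na(x$p))
  cat("Storey q-values: ", n, " p-values, pi0 = ", signif(x$pi0, 4),
      ", ", sum(x$q <= 0.1, na.rm = TRUE), " with q <= 0.1\n", sep = "")
  invisible(x)
}

#' Wilcoxon rank-sum test
#'
#' Two-sample rank-sum test with an exact null distribution for small
#' tie-free samples and a tie- and continuity-corrected normal
#' approximation otherwise. The exact branch is used when the combined
#' sample size is at most `exact_max` and no value is shared between or
#' within the groups; its tail probabilities come from the exact
#' Mann-Whitney U distribution.
#'
#' @param x,y numeric vectors (both non-empty).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`,
#'   referring to the location of `x` relative to `y`.
#' @param exact_max combined-size cutoff for the exact branch.
#' @return list with elements `statistic` (Mann-Whitney U for `x`), `p`,
#'   and `exact` (logical).
#' @examples
#' wilcoxon_ranksum(c(1, 2, 3), c(4, 5, 6))$p  # exact two-sided 0.1
#' @export
wilcoxon_ranksum <- function(x, y, alternative = c("two.sided", "less", "greater"),
                             exact_max = 20L) {
  alternative <- match.arg(alternative)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stop("both groups must be non-empty")
  all_v <- c(x, y)
  r <- rank(all_v)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2   # Mann-Whitney U for x
  ties <- any(duplicated(all_v))
  if (all(all_v == all_v[1L]))
    return(list(statistic = u, p = 1, exact = FALSE))
  if (!ties && (n1 + n2) <= exact_max) {
    p <- switch(alternative,
      two.sided = {
        lo <- stats::pwilcox(u, n1, n2)
        hi <- stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE)
        min(1, 2 * min(lo, hi))
      },
      less    = stats::pwilcox(u, n1, n2),
      greater = stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE))
    return(list(statistic = u, p = p, exact = TRUE))
  }
  mu <- n1 * n2 / 2
  tab <- table(all_v)
  tie_term <- sum(tab^3 - tab) / ((n1 + n2) * (n1 + n2 - 1))
  sigma2 <- n1 * n2 / 12 * ((n1 + n2 + 1) - tie_term)
  if (sigma2 <= 0) return(list(statistic = u, p = 1, exact = FALSE))
  s <- sqrt(sigma2)
  p <- switch(alternative,
    two.sided = min(1, 2 * stats::pnorm((abs(u - mu) - 0.5) / s, lower.tail = FALSE)),
    less      = stats::pnorm((u - mu + 0.5) / s),
    greater   = stats::pnorm((u - mu - 0.5) / s, lower.tail = FALSE))
  list(statistic = u, p = p, exact = FALSE)
}

#' Elementary tests used across the pipeline
#'
#' Thin, guard-railed wrappers around the standard inferential primitives:
#' Welch's two-sample t-test (Welch-Satterthwaite degrees of freedom),
#' the paired t-test, Spearman rank correlation with a t-approximation
#' p-value, and the one-way fixed-effects ANOVA F-test. Degenerate inputs
#' (too few observations, zero variance where the test requires it)
#' return `NA` with a warning instead of erroring, so that per-probe and
#' per-component screens can proceed.
#'
#' @param x,y numeric vectors; for `paired_t` they must be aligned.
#' @param pre,post aligned numeric vectors of paired measurements.
#' @param values numeric vector of observations for `oneway_anova`.
#' @param groups factor (or coercible) of group labels, same length as
#'   `values`.
#' @return `welch_t` and `paired_t`: list(`statistic`, `df`, `p`);
#'   `spearman_cor`: list(`rho`, `p`); `oneway_anova`: list(`statistic`,
#'   `df1`, `df2`, `p`).
#' @name basic-tests
NULL

#' @rdname basic-tests
#' @export
welch_t <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) {
    warning("welch_t: need >= 2 observations per group")
    return(list(statistic = NA_real_, df = NA_real_, p = NA_real_))
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    eq <- isTRUE(all.equal(mean(x), mean(y)))
    return(list(statistic = if (eq) 0 else Inf, df = NA_real_,
                p = if (eq) 1 else 0))
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' @rdname basic-tests
#' @export
paired_t <- function(pre, post) {
  ok <- !is.na(pre) & !is.na(post)
  pre <- pre[ok]; post <- post[ok]
  if (length(pre) < 2L) {
    warning("paired_t: need >= 2 complete pairs")
    return(list(statistic = NA_real_, df = NA_real_, p = NA_real_))
  }
  d <- post - pre
  if (stats::var(d) == 0)
    return(list(statistic = if (mean(d) == 0) 0 else Inf,
                df = length(d) - 1, p = if (mean(d) == 0) 1 else 0))
  tt <- stats::t.test(post, pre, paired = TRUE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' @rdname basic-tests
#' @export
spearman_cor <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("spearman_cor: degenerate input")
    return(list(rho = NA_real_, p = NA_real_))
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) return(list(rho = rho, p = 0))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tstat), df = n - 2))
}

#' @rdname basic-tests
#' @export
oneway_anova <- function(values, groups) {
  groups <- factor(groups)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(groups[ok])
  if (nlevels(groups) < 2L || length(values) <= nlevels(groups)) {
    warning("oneway_anova: need >= 2 groups and residual df > 0")
    return(list(statistic = NA_real_, df1 = NA_real_, df2 = NA_real_,
                p = NA_real_))
  }
  if (stats::var(values) == 0)
    return(list(statistic = 0, df1 = nlevels(groups) - 1,
                df2 = length(values) - nlevels(groups), p = 1))
  # anova(lm()) rather than oneway.test: identical F-test, but tolerant
  # of singleton groups (ethnicity strata can have one subject)
  tab <- stats::anova(stats::lm(values ~ groups))
  list(statistic = tab[1L, "F value"], df1 = tab[1L, "Df"],
       df2 = tab[2L, "Df"], p = tab[1L, "Pr(>F)"])
}
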