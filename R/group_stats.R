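#' Welch unequal-variance t-test
#'
#' `t = (mean(x) - mean(y)) / sqrt(s2x/nx + s2y/ny)` with Welch-Satterthwaite
#' degrees of freedom and a two-sided p from the t distribution. The study's
#' "non-parametric Welch's test" phrasing is internally inconsistent; this
#' implements the classical Welch t-test, and `mode = "permutation"` (or
#' `"both"`) adds a genuinely nonparametric permutation p-value for the
#' difference of means (seed the RNG before calling for reproducibility).
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @param mode `"t"`, `"permutation"` or `"both"`.
#' @param n_perm permutations for the nonparametric mode.
#' @return a `test_result` list: `statistic`, `df`, `p_value`, `method`,
#'   optional `p_permutation`, `degenerate` flag.
#' @export
welch_test <- function(x, y, mode = c("t", "permutation", "both"),
                       n_perm = 10000L) {
  mode <- match.arg(mode)
  if (length(x) < 2 || length(y) < 2)
    stop_retinaquant("welch_test needs n >= 2 per group", "stats_input_error")
  if (any(!is.finite(c(x, y))))
    stop_retinaquant("inputs must be finite", "stats_input_error")
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  degenerate <- FALSE
  if (vx == 0 && vy == 0) {
    degenerate <- TRUE
    if (mean(x) == mean(y)) {
      t_stat <- 0; df <- nx + ny - 2; p <- 1
    } else {
      t_stat <- sign(mean(x) - mean(y)) * Inf; df <- nx + ny - 2; p <- 0
    }
  } else {
    se2 <- vx / nx + vy / ny
    t_stat <- (mean(x) - mean(y)) / sqrt(se2)
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
    p <- 2 * pt(-abs(t_stat), df)
  }
  res <- list(statistic = t_stat, df = df, p_value = p,
              method = "Welch two-sample t-test", degenerate = degenerate)
  if (mode %in% c("permutation", "both")) {
    pooled <- c(x, y)
    obs <- abs(mean(x) - mean(y))
    hits <- 0L
    for (b in seq_len(n_perm)) {
      idx <- sample.int(nx + ny, nx)
      d <- abs(mean(pooled[idx]) - mean(pooled[-idx]))
      if (d >= obs - 1e-12) hits <- hits + 1L
    }
    res$p_permutation <- (hits + 1) / (n_perm + 1)
    if (mode == "permutation") {
      res$p_value <- res$p_permutation
      res$method <- "permutation test (difference of means)"
    }
  }
  class(res) <- "test_result"
  res
}

# mid-ranks of the pooled data and the tie-correction ingredients
.pooled_ranks <- function(groups) {
  vals <- unlist(groups, use.names = FALSE)
  if (any(!is.finite(vals)))
    stop_retinaquant("inputs must be finite", "stats_input_error")
  r <- rank(vals, ties.method = "average")
  sizes <- lengths(groups)
  list(ranks = split(r, rep(seq_along(groups), sizes)), pooled = r,
       sizes = sizes, n = length(vals),
       tie_sizes = as.integer(table(vals)))
}

#' Kruskal-Wallis rank-sum test with tie correction
#'
#' Mid-ranks over the pooled data;
#' `H = 12/(N(N+1)) * sum(R_i^2/n_i) - 3(N+1)`, divided by the tie
#' correction `1 - sum(t^3 - t)/(N^3 - N)`; p from the chi-squared
#' distribution with k-1 degrees of freedom.
#'
#' @param groups named list of numeric vectors (>= 2 groups, total N >= 3).
#' @return a `test_result` list.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2)
    stop_retinaquant("need >= 2 groups", "stats_input_error")
  pr <- .pooled_ranks(groups)
  if (pr$n < 3)
    stop_retinaquant("need total N >= 3", "stats_input_error")
  N <- pr$n
  rs <- vapply(pr$ranks, sum, 0)
  H <- 12 / (N * (N + 1)) * sum(rs^2 / pr$sizes) - 3 * (N + 1)
  tie <- 1 - sum(pr$tie_sizes^3 - pr$tie_sizes) / (N^3 - N)
  degenerate <- tie <= 0   # all observations identical
  H <- if (degenerate) 0 else H / tie
  k <- length(groups)
  p <- if (degenerate) 1 else pchisq(H, df = k - 1, lower.tail = FALSE)
  structure(list(statistic = H, df = k - 1, p_value = p,
                 method = "Kruskal-Wallis rank sum test (tie-corrected)",
                 degenerate = degenerate),
            class = "test_result")
}

#' Conover-Iman post hoc pairwise comparisons
#'
#' Rank-based pairwise tests following a Kruskal-Wallis omnibus: for groups i
#' and j, `t_ij = (Rbar_i - Rbar_j) / sqrt(S2 * (N-1-H)/(N-k) *
#' (1/n_i + 1/n_j))` with `S2 = (sum(R^2) - N(N+1)^2/4) / (N-1)` on
#' mid-ranks; two-sided p from the t distribution with N-k degrees of
#' freedom, then multiplicity-adjusted (Holm by default; the original report
#' does not state an adjustment, so it is configurable).
#'
#' @param groups named list of numeric vectors.
#' @param adjust `"holm"`, `"bonferroni"` or `"none"`.
#' @return a `test_result` with the omnibus `statistic`/`p_value` and a
#'   symmetric `pairwise_p` matrix with unit diagonal.
#' @export
conover_posthoc <- function(groups, adjust = c("holm", "bonferroni",
                                               "none")) {
  adjust <- match.arg(adjust)
  kw <- kruskal_wallis(groups)
  pr <- .pooled_ranks(groups)
  N <- pr$n; k <- length(groups)
  if (N - k <= 0)
    stop_retinaquant("need N > k for Conover post hoc", "stats_input_error")
  H <- kw$statistic
  S2 <- (sum(pr$pooled^2) - N * (N + 1)^2 / 4) / (N - 1)
  rbar <- vapply(pr$ranks, mean, 0)
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("group", seq_len(k))
  pmat <- matrix(1, k, k, dimnames = list(nm, nm))
  tmat <- matrix(0, k, k, dimnames = list(nm, nm))
  praw <- c(); pairs <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    denom2 <- S2 * (N - 1 - H) / (N - k) *
      (1 / pr$sizes[i] + 1 / pr$sizes[j])
    if (denom2 <= 0) {  # degenerate: omnibus saturated or constant data
      t_ij <- if (rbar[i] == rbar[j]) 0 else sign(rbar[i] - rbar[j]) * Inf
    } else {
      t_ij <- (rbar[i] - rbar[j]) / sqrt(denom2)
    }
    p_ij <- if (is.infinite(t_ij)) 0 else 2 * pt(-abs(t_ij), N - k)
    tmat[i, j] <- t_ij; tmat[j, i] <- -t_ij
    praw <- c(praw, p_ij); pairs[[length(pairs) + 1]] <- c(i, j)
  }
  padj <- p.adjust(praw, method = adjust)
  for (q in seq_along(pairs)) {
    i <- pairs[[q]][1]; j <- pairs[[q]][2]
    pmat[i, j] <- padj[q]; pmat[j, i] <- padj[q]
  }
  structure(list(statistic = kw$statistic, df = kw$df,
                 p_value = kw$p_value,
                 method = paste0("Conover-Iman post hoc (", adjust,
                                 " adjustment)"),
                 pairwise_t = tmat, pairwise_p = pmat,
                 degenerate = kw$degenerate),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("statistic = %.6g, df = %s, p = %.6g\n", x$statistic,
              paste(signif(x$df, 6), collapse = ", "), x$p_value))
  if (!is.null(x$pairwise_p)) {
    cat("pairwise p-values:\n")
    print(signif(x$pairwise_p, 4))
  }
  invisible(x)
}
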