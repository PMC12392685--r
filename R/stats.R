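#' Wilcoxon signed-rank test for paired frame metrics
#'
#' Tests whether paired differences (e.g. tumor minus healthy per frame)
#' are symmetric about zero. Zero differences are dropped before ranking
#' (Wilcoxon's original rule); the statistic `W` is the sum of the ranks
#' of the positive differences. For `n <= 25` retained pairs the exact
#' two-sided p-value is computed from the full null distribution of `W`
#' (every sign assignment equally likely, ties handled by midranks);
#' above that a normal approximation with continuity and tie correction
#' is used.
#'
#' @param x Paired differences, or the first member of each pair if `y`
#'   is given.
#' @param y Optional second member; differences are `x - y`.
#' @param exact_limit Largest `n` for which the exact distribution is
#'   enumerated.
#' @return A `wilcoxon_sr` list: `statistic` (W), `p.value`, `n`
#'   (retained pairs), `n_zero_dropped`, `method`.
#' @examples
#' wilcoxon_signed_rank(c(1.2, 0.8, 1.5, 0.9, 1.1)) # all positive, n = 5
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_limit = 25L) {
  d <- if (is.null(y)) as.numeric(x) else as.numeric(x) - as.numeric(y)
  d <- d[!is.na(d)]
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    stop("all paired differences are zero: signed-rank test undefined",
         call. = FALSE)
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_limit) {
    p <- exact_signed_rank_p(w, r)
    method <- "exact enumeration"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 -
                    sum(ties^3 - ties) / 48)
    z <- (w - mu - sign(w - mu) * 0.5) / sigma
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation with continuity correction"
  }
  structure(list(statistic = w, p.value = p, n = n,
                 n_zero_dropped = n_zero, method = method),
            class = "wilcoxon_sr")
}

# Exact null distribution of W by dynamic programming over the doubled
# midranks (doubling makes tied half-ranks integral). Two-sided p is
# 2 * min(P(W <= w), P(W >= w)), capped at 1.
exact_signed_rank_p <- function(w, ranks) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  dist <- numeric(total + 1)
  dist[1] <- 1
  for (rk in r2) {
    shifted <- c(rep(0, rk), dist[seq_len(total + 1 - rk)])
    dist <- (dist + shifted) / 2
  }
  w2 <- as.integer(round(2 * w))
  lower <- sum(dist[seq_len(w2 + 1)])
  upper <- sum(dist[(w2 + 1):(total + 1)])
  min(1, 2 * min(lower, upper))
}

#' @export
print.wilcoxon_sr <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank: W = %g, n = %d, p = %.5g (%s)\n",
              x$statistic, x$n, x$p.value, x$method))
  if (x$n_zero_dropped > 0) {
    cat(sprintf("  (%d zero difference(s) dropped)\n", x$n_zero_dropped))
  }
  invisible(x)
}

#' Mean and standard error of a metric
#'
#' `SE = sd / sqrt(n)` with the sample (n - 1) standard deviation. A
#' single observation reports `SE = 0` with a warning rather than `NA`,
#' matching the error-bar convention of single-frame groups.
#'
#' @param values Numeric vector, `n >= 1`.
#' @return Named numeric `c(mean, se)`.
#' @export
summarize_mean_se <- function(values) {
  values <- as.numeric(values)
  if (!length(values)) stop("no values to summarize", call. = FALSE)
  if (length(values) == 1) {
    warning("single observation: SE reported as 0", call. = FALSE)
    return(c(mean = values, se = 0))
  }
  c(mean = mean(values), se = stats::sd(values) / sqrt(length(values)))
}

#' Significance stars for a p-value
#'
#' Strict-inequality banding: `***` for p < 0.001, `**` for p < 0.01,
#' `*` for p < 0.05, otherwise `n.s.`.
#'
#' @param p P-value(s) in \[0, 1\]; vectorized.
#' @return Character vector of star codes.
#' @export
significance_stars <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "n.s.")))
}

#' Paired healthy-versus-tumor comparison of one metric
#'
#' Runs the signed-rank test on frame-paired values and summarizes both
#' groups as mean +/- SE. Frames with `NA` in either member (e.g. an
#' undefined ECI) are excluded pairwise and counted.
#'
#' @param healthy,tumor Equal-length per-frame metric vectors.
#' @param metric_name Name carried into the result row.
#' @return One-row data.frame with group means/SEs, `n_pairs`, `W`, `p`,
#'   and `stars`.
#' @export
compare_paired_metric <- function(healthy, tumor, metric_name = "metric") {
  stopifnot(length(healthy) == length(tumor))
  ok <- !is.na(healthy) & !is.na(tumor)
  test <- wilcoxon_signed_rank(tumor[ok], healthy[ok])
  hs <- summarize_mean_se(healthy[ok])
  ts <- summarize_mean_se(tumor[ok])
  data.frame(
    metric = metric_name, n_pairs = sum(ok),
    n_excluded = sum(!ok),
    healthy_mean = hs[["mean"]], healthy_se = hs[["se"]],
    tumor_mean = ts[["mean"]], tumor_se = ts[["se"]],
    W = test$statistic, p = test$p.value,
    stars = significance_stars(test$p.value),
    stringsAsFactors = FALSE
  )
}
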