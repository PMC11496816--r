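# Two-group comparison exactly as used for the compartment measures:
# two-sided Wilcoxon rank-sum with mid-ranks for ties, exact enumeration
# for small pooled samples (a count-by-dynamic-programming over the pooled
# rank multiset) and a tie-corrected normal approximation otherwise;
# group descriptives as mean +/- SD.

# Distribution of the size-na subset rank sums of the pooled (doubled)
# mid-ranks: C[k+1, s+1] = number of subsets of size k with sum s.
ranksum_distribution <- function(r2, na) {
  smax <- sum(sort(r2, decreasing = TRUE)[seq_len(na)])
  C <- matrix(0, nrow = na + 1L, ncol = smax + 1L)
  C[1, 1] <- 1
  for (r in r2) {
    kmax <- min(na, nrow(C) - 1L)
    for (k in seq(kmax, 1L)) {
      shifted <- c(rep(0, r), C[k, seq_len(ncol(C) - r)])
      C[k + 1L, ] <- C[k + 1L, ] + shifted
    }
  }
  C[na + 1L, ]
}

wilcoxon_exact_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  r2 <- as.integer(round(2 * r))
  na <- length(a)
  w2 <- sum(r2[seq_len(na)])
  counts <- ranksum_distribution(r2, na)
  mu2 <- na * (length(pooled) + 1)
  s_vals <- seq_along(counts) - 1L
  extreme <- abs(s_vals - mu2) >= abs(w2 - mu2) - 1e-9
  sum(counts[extreme]) / sum(counts)
}

wilcoxon_normal_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a); nb <- length(b)
  r <- rank(pooled)
  W <- sum(r[seq_len(na)])
  mu <- na * (n + 1) / 2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(1)
  z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * pnorm(-abs(z)))
}

#' Two-sided Wilcoxon rank-sum test with group summaries
#'
#' Mid-ranks handle ties. For pooled sample sizes up to `exact_max` the
#' two-sided p-value is exact, obtained by enumerating the null
#' distribution of the rank sum over all equally likely group assignments
#' (p = probability of a rank sum at least as far from its null mean as
#' observed); larger samples use the tie-corrected normal approximation
#' with continuity correction. Whenever the pooled size allows (<= 20)
#' both values are computed and reported so the two routes can be compared.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @param exact_max Pooled-size threshold for the exact path.
#' @param alpha Significance level for the flag (p <= alpha).
#' @param labels Length-2 character: group names.
#' @return An object of class `group_comparison` with per-group n, mean,
#'   sd, the rank-sum statistic of the first group, `p_value`, `method`,
#'   and both `p_exact` / `p_normal` where computed.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p_value  # exactly 0.1
#' @export
wilcoxon_rank_sum <- function(a, b, exact_max = 12L, alpha = 0.05,
                              labels = c("a", "b")) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 1L || length(b) < 1L)
    abort("both groups must be non-empty")
  if (any(!is.finite(a)) || any(!is.finite(b)))
    abort("groups must contain finite values only")
  n <- length(a) + length(b)
  p_exact <- if (n <= max(exact_max, 20L)) wilcoxon_exact_p(a, b) else NA_real_
  p_normal <- wilcoxon_normal_p(a, b)
  use_exact <- n <= exact_max
  p <- if (use_exact) p_exact else p_normal
  W <- sum(rank(c(a, b))[seq_along(a)])
  structure(
    list(labels = labels,
         n = c(length(a), length(b)),
         mean = c(mean(a), mean(b)),
         sd = c(sd_div(a, "n-1"), sd_div(b, "n-1")),
         statistic = W,
         p_value = p,
         method = if (use_exact) "exact" else "normal",
         p_exact = p_exact,
         p_normal = p_normal,
         alpha = alpha,
         significant = p <= alpha,
         data = list(a = a, b = b)),
    class = "group_comparison")
}

sd_div <- function(x, divisor) {
  if (length(x) == 1L) return(0)
  if (divisor == "n-1") sd(x) else sqrt(mean((x - mean(x))^2))
}

#' Group descriptives as mean +/- SD
#'
#' @param values Numeric vector (n >= 1).
#' @param divisor `"n-1"` (sample SD, default) or `"n"`.
#' @return A one-row tibble with `n`, `mean`, `sd` and a `report` string
#'   rounded to integers in the house style (`"38 +/- 8"`).
#' @examples
#' group_summary(c(30, 46))  # 38 +/- 11.3 (n-1 divisor)
#' @export
group_summary <- function(values, divisor = c("n-1", "n")) {
  divisor <- match.arg(divisor)
  if (length(values) < 1L) abort("need at least one value")
  m <- mean(values); s <- sd_div(values, divisor)
  tibble::tibble(n = length(values), mean = m, sd = s,
                 report = sprintf("%d ± %d", round(m), round(s)))
}

#' Compare a measure between two groups of samples
#'
#' Tidy front end to [wilcoxon_rank_sum()]: takes a records table (e.g.
#' from [quantify_masks()] or [read_quant_csv()]), splits one value column
#' by a two-level group column and runs the comparison.
#'
#' @param data A data frame of per-sample records.
#' @param group_col Name of the grouping column (exactly two levels).
#' @param value_col Name of the numeric measure column.
#' @param ... Passed to [wilcoxon_rank_sum()].
#' @return A `group_comparison`.
#' @export
compare_groups <- function(data, group_col, value_col, ...) {
  g <- data[[group_col]]; v <- data[[value_col]]
  if (is.null(g) || is.null(v))
    abort("`group_col` and `value_col` must name columns of `data`")
  keep <- !is.na(v)
  g <- as.character(g[keep]); v <- v[keep]
  lv <- sort(unique(g))
  if (length(lv) != 2L)
    abort(sprintf("`%s` must have exactly 2 levels, found %d", group_col,
                  length(lv)))
  wilcoxon_rank_sum(v[g == lv[1]], v[g == lv[2]], labels = lv, ...)
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> Wilcoxon rank sum (two-sided, %s p)\n",
              x$method))
  for (i in 1:2)
    cat(sprintf("  %s: n = %d, %.1f ± %.1f\n", x$labels[i], x$n[i],
                x$mean[i], x$sd[i]))
  cat(sprintf("  W = %g, p = %.4g%s\n", x$statistic, x$p_value,
              if (x$significant) sprintf(" (significant at %.2f)", x$alpha)
              else ""))
  if (!is.na(x$p_exact) && x$method != "exact")
    cat(sprintf("  exact p = %.4g (normal approximation used)\n", x$p_exact))
  invisible(x)
}

#' @export
tidy.group_comparison <- function(x, ...) {
  tibble::tibble(
    group1 = x$labels[1], group2 = x$labels[2],
    n1 = x$n[1], n2 = x$n[2],
    mean1 = x$mean[1], mean2 = x$mean[2],
    sd1 = x$sd[1], sd2 = x$sd[2],
    statistic = x$statistic, p_value = x$p_value, method = x$method,
    p_exact = x$p_exact, p_normal = x$p_normal,
    significant = x$significant)
}

#' @export
glance.group_comparison <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value,
                 method = x$method, alpha = x$alpha,
                 significant = x$significant)
}

#' @export
autoplot.group_comparison <- function(object, ...) {
  df <- tibble::tibble(
    group = factor(rep(object$labels, object$n), levels = object$labels),
    value = c(object$data$a, object$data$b))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.08, height = 0, alpha = 0.7) +
    ggplot2::labs(
      subtitle = sprintf("Wilcoxon rank sum (two-sided): p = %.3g (%s)",
                         object$p_value, object$method),
      x = NULL, y = "value") +
    ggplot2::theme_minimal()
}

#' Boxplot of a compartment measure by stage
#'
#' @param records Records tibble (see [quantify_masks()]).
#' @param value_col Measure column to plot.
#' @param group_col Grouping column.
#' @return A ggplot object.
#' @export
plot_compartment_contents <- function(records, value_col = "medulla_pct",
                                      group_col = "stage") {
  ggplot2::ggplot(records,
                  ggplot2::aes(x = .data[[group_col]],
                               y = .data[[value_col]])) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.08, height = 0, alpha = 0.7) +
    ggplot2::labs(x = NULL, y = value_col) +
    ggplot2::theme_minimal()
}
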