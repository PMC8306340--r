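#' Welch's unequal-variance t-test
#'
#' Unpaired, unequal-variance Student's t-test with Satterthwaite degrees of
#' freedom and a two-tailed p-value (wraps [stats::t.test()]).
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @return A list with `t`, `df`, `p`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("each sample needs n >= 2")
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Holm-Bonferroni step-down adjustment
#'
#' Step-down family-wise error control: with p-values sorted ascending,
#' `p'_(i) = max_{j <= i} min(1, (m - j + 1) p_(j))`, returned in the
#' original order (wraps [stats::p.adjust()]).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
holm_bonferroni <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "holm")
}

#' Mean and 95% confidence half-width
#'
#' t-distribution interval: `mean +/- t_{0.975, n-1} * sd / sqrt(n)`.
#'
#' @param x Numeric sample, length >= 2.
#' @return A list with `mean` and `half_width`.
#' @export
ci95 <- function(x) {
  n <- length(x)
  if (n < 2L) stop("ci95 needs n >= 2")
  list(mean = mean(x),
       half_width = stats::qt(0.975, n - 1) * stats::sd(x) / sqrt(n))
}

#' Pairwise Welch comparisons with Holm correction per family
#'
#' Runs all pairwise Welch t-tests within each family (by default one
#' metric at one pacing rate forms one family) and Holm-adjusts p-values
#' within the family. Flags use two-tailed alpha = 0.05 on the adjusted
#' p-values.
#'
#' @param data data.frame with columns `group`, `metric`, `value`, and
#'   optionally extra family keys (e.g. a pacing-rate column).
#' @param family_keys Columns defining a correction family (default
#'   `"metric"` plus any extra columns passed).
#' @param alpha Significance level.
#' @return A list of class `comparison_report`: `summaries` (per group and
#'   metric: n, mean, sd, 95% CI half-width) and `comparisons` (t, Welch
#'   df, raw and Holm-adjusted p, significance flag).
#' @export
compare_groups <- function(data, family_keys = "metric", alpha = 0.05) {
  stopifnot(all(c("group", "metric", "value") %in% names(data)),
            all(family_keys %in% names(data)))
  fam <- interaction(data[family_keys], drop = TRUE)
  summaries <- do.call(rbind, lapply(split(data, list(fam, data$group),
                                           drop = TRUE), function(d) {
    ci <- ci95(d$value)
    cbind(d[1, family_keys, drop = FALSE],
          data.frame(group = d$group[1], n = nrow(d), mean = ci$mean,
                     sd = stats::sd(d$value), ci95 = ci$half_width))
  }))
  rownames(summaries) <- NULL

  comparisons <- do.call(rbind, lapply(split(data, fam), function(d) {
    groups <- sort(unique(d$group))
    if (length(groups) < 2L) return(NULL)
    pairs <- utils::combn(groups, 2, simplify = FALSE)
    res <- do.call(rbind, lapply(pairs, function(pr) {
      w <- welch_t(d$value[d$group == pr[1]], d$value[d$group == pr[2]])
      cbind(d[1, family_keys, drop = FALSE],
            data.frame(group_a = pr[1], group_b = pr[2],
                       t = w$t, df = w$df, p = w$p))
    }))
    res$p_adjusted <- holm_bonferroni(res$p)
    res$m <- nrow(res)
    res
  }))
  rownames(comparisons) <- NULL
  comparisons$significant <- comparisons$p_adjusted < alpha
  structure(list(summaries = summaries, comparisons = comparisons,
                 alpha = alpha),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n")
  print(x$comparisons, digits = 4)
  invisible(x)
}
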