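# Thin nonparametric group-comparison utilities.

#' Two-sided Wilcoxon rank-sum comparison
#'
#' Exact p value for small samples without ties, normal approximation with
#' tie correction (and continuity correction) otherwise — the conventions of
#' [stats::wilcox.test()].
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2.
#' @return The two-sided p value.
#' @export
compare_groups <- function(values_a, values_b) {
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop_invalid("each group needs n >= 2")
  suppressWarnings(
    stats::wilcox.test(values_a, values_b, alternative = "two.sided",
                       exact = NULL)$p.value)
}

#' Kruskal-Wallis rank-sum comparison across several groups
#'
#' @param groups A list of numeric vectors, each of length >= 2.
#' @return The p value of the Kruskal-Wallis chi-squared test.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop_invalid("need a list of >= 2 groups")
  if (any(vapply(groups, length, 1L) < 2L))
    stop_invalid("each group needs n >= 2")
  stats::kruskal.test(groups)$p.value
}
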