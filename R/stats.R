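#' Nonparametric group comparisons
#'
#' Wilcoxon rank-sum for two independent groups, Wilcoxon signed-rank for
#' paired samples, or Kruskal-Wallis for a single factor with several
#' levels. Two-sided by default; exact p-values are used where the
#' underlying tests provide them at small n. The effect size reported is
#' the variance accounted for by the grouping factor (between-group sum of
#' squares over total).
#'
#' @param x Numeric values of the first group, or all values when
#'   `groups` is given.
#' @param y Second group (ranksum/signedrank).
#' @param groups Factor of group membership (kruskal, or ranksum with two
#'   levels).
#' @param test `"ranksum"`, `"signedrank"` or `"kruskal"`.
#' @return One-row tibble: `test`, `statistic`, `p_value`, `effect_size`,
#'   `n`.
#' @export
compare_groups <- function(x, y = NULL, groups = NULL,
                           test = c("ranksum", "signedrank", "kruskal")) {
  test <- match.arg(test)
  if (!is.null(groups)) {
    groups <- as.factor(groups)
    split_vals <- split(x, groups)
    if (any(lengths(split_vals) == 0)) stop("empty group")
    if (test != "kruskal" && length(split_vals) == 2) {
      y <- split_vals[[2]]
      x <- split_vals[[1]]
    }
  }
  if (test %in% c("ranksum", "signedrank")) {
    if (is.null(y)) stop("two groups required")
    if (!length(x) || !length(y)) stop("empty group")
    ht <- stats::wilcox.test(x, y, paired = test == "signedrank",
                             exact = NULL)
    vals <- c(x, y)
    grp <- rep(1:2, c(length(x), length(y)))
  } else {
    if (is.null(groups)) stop("kruskal requires `groups`")
    ht <- stats::kruskal.test(x, groups)
    vals <- x
    grp <- groups
  }
  tibble::tibble(
    test = test,
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    effect_size = variance_accounted(vals, grp),
    n = length(vals))
}

#' Variance accounted for by a grouping factor
#'
#' Between-group sum of squares divided by the total sum of squares.
#'
#' @param values Numeric vector.
#' @param groups Group membership.
#' @return Scalar in `[0, 1]`.
#' @export
variance_accounted <- function(values, groups) {
  groups <- as.factor(groups)
  gm <- mean(values)
  ss_tot <- sum((values - gm)^2)
  if (ss_tot == 0) return(0)
  means <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  sum(ns * (means - gm)^2) / ss_tot
}

#' Bonferroni correction
#'
#' @param p Vector of p-values.
#' @param n Number of comparisons (defaults to `length(p)`).
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p, n = length(p)) {
  stats::p.adjust(p, method = "bonferroni", n = n)
}

#' Exact one-sided binomial test against chance
#'
#' Upper-tail probability of observing at least `correct` successes in
#' `total` trials at the chance success probability.
#'
#' @param correct Number of correct classifications.
#' @param total Number of trials.
#' @param chance_p Chance probability, in (0, 1).
#' @return Exact p-value.
#' @export
binomial_above_chance <- function(correct, total, chance_p) {
  if (chance_p <= 0 || chance_p >= 1) stop("chance_p must be in (0, 1)")
  if (correct > total) stop("correct > total")
  if (correct < 0 || total < 1) stop("invalid counts")
  stats::binom.test(correct, total, p = chance_p,
                    alternative = "greater")$p.value
}
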