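# Nonparametric group statistics and effect sizes. Effect size r = z / sqrt(N)
# with z the Wilcoxon statistic on the normal scale and N the total number of
# cases (twice the sample size for paired, within-group comparisons). z is
# computed from midranks with tie correction and a continuity correction.

#' Wilcoxon z statistic (normal approximation)
#'
#' Rank-sum (two independent samples) or signed-rank (`paired = TRUE`)
#' Wilcoxon statistic converted to a z score using the midrank normal
#' approximation with tie correction and continuity correction. The sign of
#' z follows `x` relative to `y` (positive when `x` tends larger).
#'
#' @param x,y Numeric samples; for `paired = TRUE`, matched observations.
#' @param paired Within-group (signed-rank) comparison.
#' @return List with `z`, `p` (two-sided), `statistic`, `n_cases` (the `N`
#'   for the effect-size formula: `n1 + n2` unpaired, `2 * n_pairs` paired).
#' @export
wilcoxon_z <- function(x, y, paired = FALSE) {
  if (paired) {
    d <- x - y
    n_pairs <- length(d)
    d <- d[d != 0]
    m <- length(d)
    if (m == 0) return(list(z = 0, p = 1, statistic = 0, n_cases = 2 * n_pairs))
    r <- rank(abs(d))
    w <- sum(r[d > 0])
    mu <- m * (m + 1) / 4
    ties <- table(r)
    sig2 <- m * (m + 1) * (2 * m + 1) / 24 - sum(ties^3 - ties) / 48
    cc <- 0.5 * sign(w - mu)
    z <- if (sig2 > 0) (w - mu - cc) / sqrt(sig2) else 0
    list(z = z, p = 2 * stats::pnorm(-abs(z)), statistic = w,
         n_cases = 2 * n_pairs)
  } else {
    n1 <- length(x); n2 <- length(y); n <- n1 + n2
    r <- rank(c(x, y))
    w <- sum(r[seq_len(n1)])
    mu <- n1 * (n + 1) / 2
    ties <- table(r)
    sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    cc <- 0.5 * sign(w - mu)
    z <- if (sig2 > 0) (w - mu - cc) / sqrt(sig2) else 0
    list(z = z, p = 2 * stats::pnorm(-abs(z)), statistic = w, n_cases = n)
  }
}

#' Effect size r from a Wilcoxon z statistic
#'
#' `r = z / sqrt(N)` where `N` is the total number of cases -- twice the
#' sample size for within-group (paired) comparisons.
#'
#' @param z Wilcoxon statistic on the normal scale.
#' @param n_cases Total number of cases.
#' @return Effect size r in \[-1, 1\].
#' @export
effect_size_r <- function(z, n_cases) {
  stopifnot(n_cases > 0)
  z / sqrt(n_cases)
}

#' Two-group comparison with effect size
#'
#' Convenience wrapper producing the test statistic, p-value and effect size
#' r for a signed-rank (paired) or rank-sum (unpaired) comparison.
#'
#' @param x,y Numeric samples.
#' @param paired Within-group comparison.
#' @return List of class `group_comparison` with `test`, `statistic`, `z`,
#'   `p`, `effect_size_r`, `n_cases`.
#' @export
group_test <- function(x, y, paired = FALSE) {
  wz <- wilcoxon_z(x, y, paired = paired)
  structure(list(test = if (paired) "signed-rank" else "rank-sum",
                 statistic = wz$statistic, z = wz$z, p = wz$p,
                 effect_size_r = effect_size_r(wz$z, wz$n_cases),
                 n_cases = wz$n_cases),
            class = "group_comparison")
}

#' Kruskal-Wallis comparison across layers with Bonferroni post-hoc tests
#'
#' Tests for differences of a per-unit quantity across layer groups with the
#' Kruskal-Wallis test; when significant at `alpha`, all pairwise rank-sum
#' comparisons are run at the Bonferroni-corrected threshold
#' `alpha / n_pairs`. Empty groups are dropped; by default L1 is excluded
#' from layer-group statistics (single-unit layers are reported but not
#' contrasted).
#'
#' @param values_by_group Named list of numeric vectors (e.g. one per layer).
#' @param alpha Familywise significance level.
#' @param exclude Group names dropped before testing (default `"L1"` and
#'   `"unassigned"`).
#' @return List of class `group_comparison`: `test`, `statistic` (chi-square),
#'   `df`, `p`, `n_cases`, `groups`, `post_hoc` (data.frame of pairwise
#'   results, or `NULL` when the omnibus test is not significant).
#' @export
layer_group_test <- function(values_by_group, alpha = 0.05,
                             exclude = c("L1", "unassigned")) {
  values_by_group <- values_by_group[!(names(values_by_group) %in% exclude)]
  values_by_group <- Filter(function(v) length(v) > 0, values_by_group)
  if (length(values_by_group) < 2) {
    stop("layer group test needs >=2 nonempty groups")
  }
  kw <- stats::kruskal.test(values_by_group)
  post <- NULL
  if (kw$p.value < alpha) {
    pairs <- utils::combn(names(values_by_group), 2)
    alpha_adj <- alpha / ncol(pairs)
    post <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      a <- pairs[1, j]; b <- pairs[2, j]
      gt <- group_test(values_by_group[[a]], values_by_group[[b]])
      data.frame(group_a = a, group_b = b, p = gt$p,
                 effect_size_r = gt$effect_size_r,
                 significant = gt$p < alpha_adj, alpha_adj = alpha_adj,
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(test = "kruskal-wallis",
                 statistic = unname(kw$statistic),
                 df = unname(kw$parameter), p = kw$p.value,
                 n_cases = sum(lengths(values_by_group)),
                 groups = lengths(values_by_group), post_hoc = post,
                 alpha = alpha),
            class = "group_comparison")
}
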