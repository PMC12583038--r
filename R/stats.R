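# Cell-size stratification and the statistical battery.
#
# Cells are pooled across all groups of an experiment and split into "small"
# (below pooled median length) and "large" (above) classes; group differences
# are then tested per stratum with the Mann-Whitney test and corrected across
# the per-metric family by the Benjamini-Hochberg FDR procedure. Kruskal-
# Wallis + Dunn post hoc, Welch t and two-way ANOVA cover the multi-group and
# parametric designs.

#' Classify cells as small or large by the pooled median length
#'
#' Below-median cells are "small", above-median "large". With an odd cell
#' count the cell providing the median joins the class containing its closest
#' neighbor by length; an exact neighbor tie goes to "small" (deterministic
#' documented rule). With ties at the median in an even count, median-valued
#' cells are assigned "small".
#'
#' @param length_um numeric vector of cell lengths (>= 2 values).
#' @return factor with levels `small`, `large`; the pooled median is attached
#'   as attribute `median`.
#' @export
classify_by_median <- function(length_um) {
  n <- length(length_um)
  stopifnot(n >= 2)
  if (diff(range(length_um)) == 0)
    stop("degenerate split: all cell lengths equal")
  med <- stats::median(length_um)
  cls <- ifelse(length_um < med, "small",
                ifelse(length_um > med, "large", NA))
  if (n %% 2 == 1) {
    # the median cell itself: join the class of its nearest neighbor
    i_med <- which(length_um == med)
    others <- length_um[-i_med[1]]
    below <- others[others < med]; above <- others[others > med]
    d_below <- if (length(below)) med - max(below) else Inf
    d_above <- if (length(above)) min(above) - med else Inf
    cls[is.na(cls)] <- if (d_below <= d_above) "small" else "large"
  } else {
    cls[is.na(cls)] <- "small"  # even-count ties at the median
  }
  out <- factor(cls, levels = c("small", "large"))
  attr(out, "median") <- med
  out
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Exact enumeration when the combined sample size is at most `exact_max_n`
#' and there are no ties; tie-corrected normal approximation (no continuity
#' correction) otherwise. Two-sided throughout.
#'
#' @param x,y numeric samples (each non-empty).
#' @param exact_max_n combined-size bound for the exact branch.
#' @return list with `U` (statistic for `x`), `p`, and `method`.
#' @export
mann_whitney <- function(x, y, exact_max_n = 12L) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  ties <- any(duplicated(c(x, y)))
  exact <- (length(x) + length(y)) <= exact_max_n && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = FALSE))
  list(U = unname(wt$statistic), p = wt$p.value,
       method = if (exact) "exact" else "normal approximation (tie-corrected)")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: sort ascending, `q_(i) = min_{j >= i}
#' p_(j) m / j` capped at 1, returned in the input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Significance stars for the reported p-value bands
#'
#' `**` for p <= 0.01, `*` for 0.01 < p <= 0.05, `(*)` for 0.05 < p < 0.1,
#' `NS` for p >= 0.1.
#'
#' @param p numeric vector of (adjusted) p-values.
#' @return character vector of annotations.
#' @export
significance_stars <- function(p) {
  ifelse(p <= 0.01, "**",
         ifelse(p <= 0.05, "*",
                ifelse(p < 0.1, "(*)", "NS")))
}

#' Kruskal-Wallis omnibus test with Dunn's post hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square p-value, followed by
#' Dunn's z-statistics on mean ranks for every group pair, two-sided p-values
#' adjusted across the pairs by Benjamini-Hochberg.
#'
#' @param values numeric vector of measurements.
#' @param groups factor or character vector, same length, >= 2 levels.
#' @return list with `H`, `df`, `p_omnibus`, and `pairwise`, a data frame of
#'   group pairs with `z`, `p_raw`, `p_adj`, `stars`.
#' @export
kruskal_dunn <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  kw <- stats::kruskal.test(values, groups)
  N <- length(values)
  rk <- rank(values)
  mean_ranks <- tapply(rk, groups, mean)
  n_g <- tabulate(groups)
  tie_tab <- table(values)
  tie_term <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  lv <- levels(groups)
  pairs <- utils::combn(seq_along(lv), 2)
  z <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n_g[i] + 1 / n_g[j]))
    (mean_ranks[i] - mean_ranks[j]) / se
  })
  p_raw <- 2 * stats::pnorm(-abs(z))
  p_adj <- bh_adjust(p_raw)
  list(H = unname(kw$statistic), df = unname(kw$parameter),
       p_omnibus = kw$p.value,
       pairwise = data.frame(group1 = lv[pairs[1, ]], group2 = lv[pairs[2, ]],
                             z = z, p_raw = p_raw, p_adj = p_adj,
                             stars = significance_stars(p_adj)))
}

#' Welch two-sample t-test (two-sided p)
#'
#' @param x,y numeric samples.
#' @return list with `t`, `df`, `p`.
#' @export
welch_t <- function(x, y) {
  tt <- stats::t.test(x, y)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Two-way ANOVA with interaction (type II sums of squares)
#'
#' Fits `value ~ A * B` and reports type II tests for the two main effects
#' and their interaction; valid for balanced and unbalanced layouts.
#'
#' @param values numeric response.
#' @param factor_a,factor_b factors (or coercible), same length as `values`.
#' @return data frame with columns term (`A`, `B`, `A:B`) and `p`.
#' @export
two_way_anova <- function(values, factor_a, factor_b) {
  df <- data.frame(value = values, A = factor(factor_a), B = factor(factor_b))
  fit <- stats::lm(value ~ A * B, data = df)
  tab <- car::Anova(fit, type = 2)
  terms <- rownames(tab)
  data.frame(term = c("A", "B", "A:B"),
             p = c(tab[terms == "A", "Pr(>F)"],
                   tab[terms == "B", "Pr(>F)"],
                   tab[terms == "A:B", "Pr(>F)"]))
}

#' Stratified between-group comparison of one metric
#'
#' Splits the pooled cells into small/large classes by [classify_by_median()],
#' runs the Mann-Whitney test between every pair of group labels within each
#' stratum, and adjusts the whole per-metric family of p-values with
#' Benjamini-Hochberg. Empty or single-group strata are reported as missing
#' rows, never fatal.
#'
#' @param df data frame of cell measurements.
#' @param value_col column holding the analyzed quantity (e.g. `ln_vmi`,
#'   `tti_per_um`, `r_end`).
#' @param group_col column with the genotype/treatment label.
#' @param length_col column with the cell length used for the split.
#' @return data frame (class `stats_report`) with columns metric, stratum,
#'   group1, group2, n1, n2, U, p_raw, p_adj, stars, and the pooled
#'   `median_length_um` as an attribute.
#' @export
stratified_compare <- function(df, value_col, group_col = "condition_label",
                               length_col = "length_um") {
  keep <- is.finite(df[[value_col]]) & is.finite(df[[length_col]])
  df <- df[keep, , drop = FALSE]
  size_class <- classify_by_median(df[[length_col]])
  groups <- factor(df[[group_col]])
  lv <- levels(groups)
  rows <- list()
  for (stratum in levels(size_class)) {
    in_s <- size_class == stratum
    pairs <- utils::combn(lv, 2, simplify = FALSE)
    for (pr in pairs) {
      x <- df[[value_col]][in_s & groups == pr[1]]
      y <- df[[value_col]][in_s & groups == pr[2]]
      if (length(x) == 0 || length(y) == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          metric = value_col, stratum = stratum, group1 = pr[1],
          group2 = pr[2], n1 = length(x), n2 = length(y), U = NA_real_,
          p_raw = NA_real_)
        next
      }
      mw <- mann_whitney(x, y)
      rows[[length(rows) + 1]] <- data.frame(
        metric = value_col, stratum = stratum, group1 = pr[1],
        group2 = pr[2], n1 = length(x), n2 = length(y), U = mw$U,
        p_raw = mw$p)
    }
  }
  out <- do.call(rbind, rows)
  ok <- is.finite(out$p_raw)
  out$p_adj <- NA_real_
  out$p_adj[ok] <- bh_adjust(out$p_raw[ok])
  out$stars <- ifelse(ok, significance_stars(out$p_adj), NA_character_)
  attr(out, "median_length_um") <- attr(size_class, "median")
  class(out) <- c("stats_report", class(out))
  out
}
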